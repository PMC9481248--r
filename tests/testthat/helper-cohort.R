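# shared fixtures, all built in code

.cohort_cache <- new.env(parent = emptyenv())

# the packaged full study design, generated once per test session
default_manifest <- function() {
  if (is.null(.cohort_cache$manifest)) {
    .cohort_cache$manifest <- generate_cohort(default_cohort_config())
  }
  .cohort_cache$manifest
}

default_features <- function() {
  if (is.null(.cohort_cache$features)) {
    .cohort_cache$features <- build_feature_table(default_manifest())
  }
  .cohort_cache$features
}

# a small 4-dog cohort sharing the packaged distribution parameters
small_config <- function(seed = 11, zero = c(ramp = 2, human = 1)) {
  cfg <- unclass(default_cohort_config())
  cfg$outcome_counts <- c(service_dog = 2, behavioral_release = 1,
                          breeder = 1)
  cfg$trials_per_condition <- 3L
  cfg$zero_interaction_counts <- zero
  cfg$seed <- seed
  cohort_config(cfg)
}

# one class profile with wide truncation bounds for distribution checks
wide_profile <- function(duration_mean = 0.21, sdlog = 0.9) {
  list(n_bites_lambda = 10, n_bites_min = 1, n_bites_max = 40,
       duration_meanlog = log(duration_mean) - sdlog^2 / 2,
       duration_sdlog = sdlog, duration_min = 0.01, duration_max = 2.7,
       peak_mean = 110, peak_sd = 6, peak_min = 105.5, peak_max = 140,
       interaction_meanlog = log(1000), interaction_sdlog = 0.1,
       interaction_min = 500, interaction_max = 2000)
}

# mean of a truncated lognormal by numeric integration (independent of
# the sampler under test)
trunc_lnorm_mean <- function(meanlog, sdlog, lo, hi) {
  mass <- plnorm(hi, meanlog, sdlog) - plnorm(lo, meanlog, sdlog)
  stats::integrate(function(x) x * dlnorm(x, meanlog, sdlog),
                   lo, hi, rel.tol = 1e-10)$value / mass
}

# build a noise-free sensor stream from a pressure vector (for detector
# unit tests with closed-form expectations)
pressure_stream <- function(pressure, rate = 100) {
  n <- length(pressure)
  z <- numeric(n)
  sensor_stream(data.frame(
    t_s = (seq_len(n) - 1) / rate, pressure_kpa = pressure,
    ax = z, ay = z, az = z + 1, gx = z, gy = z, gz = z,
    mx = z + 20, my = z - 12, mz = z + 35), rate, "constructed")
}

# independent brute-force bite scan: an explicit state machine over the
# samples with the same threshold/merge/min-duration rules, written
# without rle() so it cannot share a defect with the implementation
brute_force_bites <- function(stream, params = bite_detector_params()) {
  d <- stream$data
  dt <- 1 / stream$sample_rate
  base <- estimate_baseline(d$pressure_kpa, stream$sample_rate,
                            params$baseline_window)
  thr <- base + params$threshold_delta
  events <- list()
  i <- 1L; n <- nrow(d)
  while (i <= n) {
    if (d$pressure_kpa[i] >= thr[i]) {
      start <- i
      while (i <= n && d$pressure_kpa[i] >= thr[i]) i <- i + 1L
      events[[length(events) + 1L]] <- c(start = start, end = i - 1L)
    } else {
      i <- i + 1L
    }
  }
  if (!length(events)) return(empty_df())
  # merge pass
  merged <- list(events[[1L]])
  for (e in events[-1L]) {
    last <- merged[[length(merged)]]
    if (d$t_s[e[["start"]]] - d$t_s[last[["end"]]] < params$merge_gap) {
      merged[[length(merged)]] <- c(start = last[["start"]], end = e[["end"]])
    } else {
      merged[[length(merged) + 1L]] <- e
    }
  }
  rows <- list()
  for (e in merged) {
    k <- e[["end"]] - e[["start"]] + 1L
    if (k * dt < params$min_duration - 1e-12) next
    p <- d$pressure_kpa[e[["start"]]:e[["end"]]]
    rows[[length(rows) + 1L]] <- data.frame(
      onset = d$t_s[e[["start"]]], offset = d$t_s[e[["end"]]] + dt,
      duration = k * dt, peak = max(p), rms = sqrt(mean(p^2)))
  }
  if (!length(rows)) return(empty_df())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_df <- function() {
  data.frame(onset = numeric(0), offset = numeric(0), duration = numeric(0),
             peak = numeric(0), rms = numeric(0))
}

# random short synthetic trial for detector property tests
random_trial <- function() {
  profile <- wide_profile()
  profile$interaction_meanlog <- log(6); profile$interaction_sdlog <- 0.5
  profile$interaction_min <- 2; profile$interaction_max <- 15
  profile$n_bites_lambda <- sample(1:8, 1)
  plan <- plan_trial(profile, "ramp",
                     zero_interaction = stats::runif(1) < 0.1)
  synthesize_stream(plan, list(sample_rate = 100, baseline_pressure = 101.5,
                               noise_sd = 0.05))
}
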