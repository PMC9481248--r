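#' Build the study roster from configured outcome counts
#'
#' Expands the per-outcome dog counts into one record per dog. Outcomes
#' listed in `excluded_outcomes` (e.g. medical release, breeder, diabetic
#' alert) are flagged excluded and carry no placement label; outcomes in
#' `released_outcomes` (behavioral release) are the negative class; every
#' other outcome counts as placed.
#'
#' @param config A [cohort_config()].
#' @return data.frame with columns `dog_id`, `outcome`, `placed` (logical,
#'   `NA` for excluded dogs), `excluded` (logical). Deterministic given the
#'   configuration.
#' @export
build_roster <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  counts <- config$outcome_counts
  outcome <- rep(names(counts), times = counts)
  n <- length(outcome)
  excluded <- outcome %in% config$excluded_outcomes
  placed <- !excluded & !(outcome %in% config$released_outcomes)
  placed[excluded] <- NA
  data.frame(
    dog_id = sprintf("dog%02d", seq_len(n)),
    outcome = outcome,
    placed = placed,
    excluded = excluded,
    stringsAsFactors = FALSE
  )
}

# placement class used to pick generator distributions; excluded dogs'
# trials are discarded downstream so they borrow the released profile
placement_class <- function(roster_row) {
  if (roster_row$excluded || !isTRUE(roster_row$placed)) "released" else "placed"
}

#' Draw one trial plan from a class profile
#'
#' Samples interaction time, bite count, bite durations and bite peak
#' pressures from the configured distributions (lognormal durations and
#' interaction times, normal peaks, shifted-Poisson counts, each truncated
#' to its configured bounds by inverse-CDF sampling), then lays the bites
#' out sequentially with positive inter-bite gaps so planned bites never
#' overlap. Uses the current RNG state; the same seed gives an identical
#' plan.
#'
#' @param profile One per-condition entry of `class_params` (see
#'   [cohort_config()]).
#' @param condition Condition label carried onto the plan.
#' @param zero_interaction If `TRUE` the plan has no bites and interaction
#'   time zero.
#' @return A list of class `trial_plan` with fields `condition`,
#'   `zero_interaction`, `interaction_time`, `bite_onsets`,
#'   `bite_durations`, `bite_peaks` (absolute kPa).
#' @export
plan_trial <- function(profile, condition, zero_interaction = FALSE) {
  if (zero_interaction) {
    return(structure(
      list(condition = condition, zero_interaction = TRUE,
           interaction_time = 0, bite_onsets = numeric(0),
           bite_durations = numeric(0), bite_peaks = numeric(0)),
      class = "trial_plan"))
  }
  validate_class_profile(profile, condition)
  interaction <- rtrunc_lnorm(1L, profile$interaction_meanlog,
                              profile$interaction_sdlog,
                              profile$interaction_min, profile$interaction_max)
  n_target <- 1L + stats::rpois(1L, profile$n_bites_lambda)
  n_target <- min(max(n_target, profile$n_bites_min), profile$n_bites_max)
  durations <- rtrunc_lnorm(n_target, profile$duration_meanlog,
                            profile$duration_sdlog,
                            profile$duration_min, profile$duration_max)
  # gaps scale with the preceding bite so local pulse occupancy stays well
  # below half the detector's baseline window
  gaps <- 0.12 + pmax(stats::rexp(n_target, rate = 1 / 0.35),
                      1.5 * durations)
  onsets <- numeric(0)
  t <- 0.3
  for (i in seq_len(n_target)) {
    if (t + durations[i] > interaction) break
    onsets <- c(onsets, t)
    t <- t + durations[i] + gaps[i]
  }
  if (length(onsets) == 0L) {
    # the first draw did not fit a short interaction; shrink it so every
    # non-zero trial carries at least one bite
    durations[1L] <- max(min(durations[1L], interaction - 0.4),
                         profile$duration_min)
    onsets <- 0.3
  }
  k <- length(onsets)
  peaks <- rtrunc_norm(k, profile$peak_mean, profile$peak_sd,
                       profile$peak_min, profile$peak_max)
  structure(
    list(condition = condition, zero_interaction = FALSE,
         interaction_time = interaction, bite_onsets = onsets,
         bite_durations = durations[seq_len(k)], bite_peaks = peaks),
    class = "trial_plan")
}

# inverse-CDF truncated samplers: exact, vectorized, reproducible
rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  p <- stats::runif(n, stats::plnorm(lo, meanlog, sdlog),
                    stats::plnorm(hi, meanlog, sdlog))
  stats::qlnorm(p, meanlog, sdlog)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd),
                    stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Synthesize the raw sensor stream for one trial plan
#'
#' Pressure is a constant baseline plus Gaussian sensor noise, an optional
#' slow sinusoidal drift, and one smooth pulse per planned bite: half-sine
#' rise and fall edges (capped at 0.02 s) around a flat plateau at the
#' planned peak, with onsets aligned to the sample grid so the realized
#' onset/offset indices are exact. The magnetometer carries a hard-iron
#' offset, noise, and a magnet-swipe excursion near the start and end of
#' the stream; the gyroscope carries a decaying roll signature; the
#' accelerometer sits at 1 g on z with noise.
#'
#' @param plan A [plan_trial()] result.
#' @param acquisition List with `sample_rate` (Hz), `baseline_pressure`
#'   (kPa), `noise_sd` (kPa), and optional `drift_amplitude` (kPa) /
#'   `drift_period` (s).
#' @param source_id Identifier stamped on the stream.
#' @return List with `stream` (a [sensor_stream()]), `events` (data.frame
#'   of realized bites: `onset_s`, `offset_s`, `duration_s`, `peak_kpa`,
#'   `onset_idx`, `offset_idx`), `retrieval_s` (the planned interaction
#'   time) and `end_s` (trial window length).
#' @export
synthesize_stream <- function(plan, acquisition, source_id = "trial") {
  stopifnot(inherits(plan, "trial_plan"))
  rate <- acquisition$sample_rate
  base <- acquisition$baseline_pressure
  noise_sd <- acquisition$noise_sd
  drift_amp <- acquisition$drift_amplitude %||% 0
  drift_per <- acquisition$drift_period %||% 60
  k <- length(plan$bite_onsets)
  last_off <- if (k) max(plan$bite_onsets + plan$bite_durations) else 0
  end_s <- max(plan$interaction_time, last_off) + 1.5
  end_s <- max(end_s, 4)
  if (k && any(plan$bite_onsets + plan$bite_durations > end_s)) {
    stop("generation error: pulse extends beyond trial window")
  }
  n <- ceiling(end_s * rate)
  t <- (seq_len(n) - 1L) / rate
  pressure <- base + stats::rnorm(n, 0, noise_sd)
  if (drift_amp > 0) pressure <- pressure + drift_amp * sin(2 * pi * t / drift_per)

  onset_idx <- offset_idx <- integer(k)
  real_peak <- numeric(k)
  for (i in seq_len(k)) {
    i0 <- round(plan$bite_onsets[i] * rate) + 1L
    len <- max(1L, round(plan$bite_durations[i] * rate))
    if (i0 + len - 1L > n) stop("generation error: pulse extends beyond trial window")
    amp <- plan$bite_peaks[i] - base
    if (amp <= 0) stop("generation error: bite peak at or below baseline")
    pressure[i0:(i0 + len - 1L)] <-
      pressure[i0:(i0 + len - 1L)] + bite_pulse(len, amp, rate)
    onset_idx[i] <- i0
    offset_idx[i] <- i0 + len
    real_peak[i] <- plan$bite_peaks[i]
  }

  mag_noise <- function(sd) stats::rnorm(n, 0, sd)
  mx <- 20 + mag_noise(1.5); my <- -12 + mag_noise(1.5); mz <- 35 + mag_noise(1.5)
  swipe <- function(at) 400 * exp(-((t - at)^2) / (2 * 0.04^2))
  mx <- mx + swipe(0.25) + swipe(end_s - 0.25)
  gz <- 30 * exp(-t / 2) * sin(2 * pi * 1.5 * t) + stats::rnorm(n, 0, 0.5)
  df <- data.frame(
    t_s = t, pressure_kpa = pressure,
    ax = stats::rnorm(n, 0, 0.02), ay = stats::rnorm(n, 0, 0.02),
    az = 1 + stats::rnorm(n, 0, 0.02),
    gx = stats::rnorm(n, 0, 0.5), gy = stats::rnorm(n, 0, 0.5), gz = gz,
    mx = mx, my = my, mz = mz)
  events <- data.frame(
    onset_s = (onset_idx - 1L) / rate,
    offset_s = (offset_idx - 1L) / rate,
    duration_s = (offset_idx - onset_idx) / rate,
    peak_kpa = real_peak,
    onset_idx = onset_idx, offset_idx = offset_idx)
  list(stream = sensor_stream(df, rate, source_id), events = events,
       retrieval_s = plan$interaction_time, end_s = end_s)
}

# half-sine attack/decay around a flat plateau; every sample exceeds
# amp*sin(pi/2/edge) so a threshold crossing spans the full pulse
bite_pulse <- function(len, amp, rate) {
  edge <- max(1L, min(round(0.02 * rate), floor((len - 1L) / 2)))
  if (len <= 3L || edge < 1L || len - 2L * edge < 1L) {
    return(rep(amp, len))
  }
  c(amp * sin(pi / 2 * seq_len(edge) / edge),
    rep(amp, len - 2L * edge),
    amp * sin(pi / 2 * rev(seq_len(edge)) / edge))
}

#' Generate a full synthetic cohort with ground truth
#'
#' Runs the whole study design: builds the roster, assigns the configured
#' number of zero-interaction trials per condition by a seeded draw among
#' the analyzable dogs' trials, draws a bite plan per trial from the dog's
#' placement-class profile, and synthesizes every raw sensor stream. The
#' ground-truth log records every injected bite and is the oracle for
#' detector-recovery checks.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, per-trial stream CSVs,
#'   `annotations.csv`, `roster.csv`, `ground_truth_trials.csv`,
#'   `ground_truth_events.csv` and `manifest.json` are written there.
#'   When `NULL` the streams stay in memory on the manifest.
#' @return A list of class `cohort_manifest`: `config`, `roster`,
#'   `annotations` (one row per trial: window, retrieval time), `streams`
#'   (named list of [sensor_stream()] or file paths), `truth_trials`
#'   (per-trial zero flag, planned counts), `truth_events` (one row per
#'   injected bite), `out_dir`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  roster <- build_roster(config)
  grid <- expand.grid(trial_index = seq_len(config$trials_per_condition),
                      condition = config$conditions,
                      dog_id = roster$dog_id,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("dog_id", "condition", "trial_index")]
  grid <- grid[order(match(grid$dog_id, roster$dog_id), grid$condition,
                     grid$trial_index), ]
  rownames(grid) <- NULL
  grid$zero_interaction <- FALSE
  analyzable <- roster$dog_id[!roster$excluded]
  for (cond in config$conditions) {
    zc <- config$zero_interaction_counts[[cond]] %||% 0L
    pool <- which(grid$condition == cond & grid$dog_id %in% analyzable)
    if (zc > length(pool)) {
      stop("configuration error: infeasible zero_interaction count for ", cond)
    }
    grid$zero_interaction[sample(pool, zc)] <- TRUE
  }

  streams <- vector("list", nrow(grid))
  ann <- grid
  ann$start_s <- 0; ann$end_s <- NA_real_; ann$retrieval_s <- NA_real_
  events_list <- vector("list", nrow(grid))
  truth <- grid
  truth$n_bites <- 0L
  keys <- sprintf("%s_%s_%02d", grid$dog_id, grid$condition, grid$trial_index)

  for (i in seq_len(nrow(grid))) {
    row <- roster[roster$dog_id == grid$dog_id[i], ]
    cls <- placement_class(row)
    profile <- config$class_params[[cls]][[grid$condition[i]]]
    if (is.null(profile)) {
      stop("configuration error: no class_params for ", cls, "/",
           grid$condition[i])
    }
    plan <- plan_trial(profile, grid$condition[i], grid$zero_interaction[i])
    syn <- synthesize_stream(plan, config$acquisition, source_id = keys[i])
    streams[[i]] <- syn$stream
    ann$end_s[i] <- syn$end_s
    ann$retrieval_s[i] <- syn$retrieval_s
    truth$n_bites[i] <- nrow(syn$events)
    if (nrow(syn$events)) {
      ev <- syn$events
      ev$dog_id <- grid$dog_id[i]; ev$condition <- grid$condition[i]
      ev$trial_index <- grid$trial_index[i]
      events_list[[i]] <- ev
    }
  }
  names(streams) <- keys
  truth_events <- do.call(rbind, events_list[!vapply(events_list, is.null, TRUE)])
  if (is.null(truth_events)) {
    truth_events <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                               duration_s = numeric(0), peak_kpa = numeric(0),
                               onset_idx = integer(0), offset_idx = integer(0),
                               dog_id = character(0), condition = character(0),
                               trial_index = integer(0))
  }
  rownames(truth_events) <- NULL

  manifest <- structure(
    list(config = config, roster = roster, annotations = ann,
         streams = streams, truth_trials = truth,
         truth_events = truth_events, out_dir = out_dir),
    class = "cohort_manifest")

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "streams"), recursive = TRUE,
               showWarnings = FALSE)
    paths <- file.path(out_dir, "streams", paste0(keys, ".csv"))
    for (i in seq_along(streams)) write_stream(streams[[i]], paths[i])
    utils::write.csv(roster, file.path(out_dir, "roster.csv"), row.names = FALSE)
    utils::write.csv(ann, file.path(out_dir, "annotations.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "ground_truth_trials.csv"),
                     row.names = FALSE)
    utils::write.csv(truth_events, file.path(out_dir, "ground_truth_events.csv"),
                     row.names = FALSE)
    manifest$streams <- stats::setNames(as.list(paths), keys)
    jsonlite::write_json(
      list(name = config$name %||% "cohort", seed = config$seed,
           n_dogs = nrow(roster), n_trials = nrow(grid),
           conditions = config$conditions,
           files = list(roster = "roster.csv", annotations = "annotations.csv",
                        truth_trials = "ground_truth_trials.csv",
                        truth_events = "ground_truth_events.csv",
                        streams = file.path("streams", paste0(keys, ".csv")))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  manifest
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf(
    "<cohort_manifest: %d dogs (%d excluded), %d trials, %d injected bites, seed %d>\n",
    nrow(x$roster), sum(x$roster$excluded), nrow(x$annotations),
    nrow(x$truth_events), x$config$seed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fetch one trial stream from a manifest (in-memory or on disk)
manifest_stream <- function(manifest, key) {
  s <- manifest$streams[[key]]
  if (is.null(s)) stop("missing stream for trial ", key)
  if (inherits(s, "sensor_stream")) s else read_stream(s)
}
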