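#' Cohort configuration
#'
#' Assembles and validates the configuration that drives the synthetic
#' cohort generator: the roster composition (dog counts per outcome
#' category), the trial design (conditions and trials per condition), the
#' cohort-wide number of zero-interaction trials to inject per condition,
#' the acquisition parameters of the simulated ball, and the per-class
#' distributions from which bite plans are drawn.
#'
#' @param x A named list with the fields below (typically parsed from
#'   YAML); missing acquisition fields fall back to defaults.
#' @return A validated list of class `cohort_config`.
#'
#' @section Fields:
#' \describe{
#'   \item{outcome_counts}{named integer vector, dogs per outcome label.}
#'   \item{released_outcomes, excluded_outcomes}{outcome labels mapped to
#'     the released (not placed) class and to exclusion from analysis.}
#'   \item{conditions}{condition labels, e.g. `c("ramp", "human")`.}
#'   \item{trials_per_condition}{trials per dog per condition.}
#'   \item{zero_interaction_counts}{named vector, exact number of
#'     zero-interaction trials to inject per condition among analyzable
#'     dogs.}
#'   \item{acquisition}{`sample_rate` (Hz), `baseline_pressure` (kPa),
#'     `noise_sd` (kPa), `drift_amplitude` (kPa), `drift_period` (s).}
#'   \item{class_params}{per placement class (`placed`, `released`) and
#'     condition: bite-count, duration, peak-pressure and interaction-time
#'     distribution parameters (see [plan_trial()]).}
#'   \item{seed}{integer seed making the whole cohort reproducible.}
#' }
#' @export
cohort_config <- function(x) {
  stopifnot(is.list(x))
  x$outcome_counts <- unlist(x$outcome_counts)
  if (any(x$outcome_counts < 0)) stop("configuration error: negative outcome count")
  x$conditions <- as.character(x$conditions)
  if (is.null(x$trials_per_condition)) x$trials_per_condition <- 10L
  x$trials_per_condition <- as.integer(x$trials_per_condition)
  if (x$trials_per_condition < 0L) stop("configuration error: negative trial count")
  if (is.null(x$released_outcomes)) x$released_outcomes <- "behavioral_release"
  if (is.null(x$excluded_outcomes)) x$excluded_outcomes <- character(0)
  x$zero_interaction_counts <- unlist(x$zero_interaction_counts)
  if (is.null(x$zero_interaction_counts)) {
    x$zero_interaction_counts <- stats::setNames(
      rep(0L, length(x$conditions)), x$conditions)
  }
  if (any(x$zero_interaction_counts < 0)) {
    stop("configuration error: negative zero_interaction count")
  }
  acq_defaults <- list(sample_rate = 100, baseline_pressure = 101.5,
                       noise_sd = 0.05, drift_amplitude = 0, drift_period = 60)
  x$acquisition <- utils::modifyList(acq_defaults, as.list(x$acquisition))
  if (x$acquisition$sample_rate <= 0) stop("configuration error: sample_rate <= 0")
  if (is.null(x$seed)) x$seed <- 1L
  x$seed <- as.integer(x$seed)
  for (cls in names(x$class_params)) {
    for (cond in names(x$class_params[[cls]])) {
      validate_class_profile(x$class_params[[cls]][[cond]],
                             sprintf("%s/%s", cls, cond))
    }
  }
  class(x) <- "cohort_config"
  x
}

validate_class_profile <- function(p, label) {
  need <- c("n_bites_lambda", "n_bites_min", "n_bites_max",
            "duration_meanlog", "duration_sdlog", "duration_min", "duration_max",
            "peak_mean", "peak_sd", "peak_min", "peak_max",
            "interaction_meanlog", "interaction_sdlog",
            "interaction_min", "interaction_max")
  missing_f <- setdiff(need, names(p))
  if (length(missing_f)) {
    stop("configuration error: class_params ", label, " missing ",
         paste(missing_f, collapse = ", "))
  }
  for (b in c("n_bites", "duration", "peak", "interaction")) {
    if (p[[paste0(b, "_min")]] > p[[paste0(b, "_max")]]) {
      stop("configuration error: inverted ", b, " bounds in ", label)
    }
  }
  invisible(p)
}

#' @rdname cohort_config
#' @param path Path to a YAML file mirroring the structure above.
#' @export
read_cohort_config <- function(path) {
  cohort_config(yaml::read_yaml(path))
}

#' @rdname cohort_config
#' @details `default_cohort_config()` loads the packaged study design
#'   `cci_study.yaml`: 48 dogs across nine outcome categories (8 of them
#'   excluded from analysis), 10 trials in each of the ramp and human
#'   conditions, and 41 (ramp) / 36 (human) injected zero-interaction
#'   trials among the 40 analyzable dogs.
#' @export
default_cohort_config <- function() {
  read_cohort_config(system.file("extdata", "cci_study.yaml",
                                 package = "toysense", mustWork = TRUE))
}
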