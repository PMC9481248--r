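#' Bite detector parameters
#'
#' The detector is rule-based: a bite is a maximal run of samples whose
#' pressure exceeds a local baseline by `threshold_delta`, after merging
#' runs separated by less than `merge_gap` and discarding runs shorter
#' than `min_duration`. The baseline is a rolling median over
#' `baseline_window`, which is insensitive to bite pulses occupying less
#' than half the window and tracks slow barometric drift. The default
#' window of 10 s keeps even the longest plausible bites (up to ~2.7 s)
#' plus their neighbours below half the window; a much shorter window can
#' ride up onto sustained bites and split or miss them.
#'
#' @param threshold_delta kPa above baseline (default 2).
#' @param min_duration Minimum event duration in s (default 0.01).
#' @param merge_gap Events closer than this (s) are merged (default 0.05).
#' @param baseline_window Rolling-median window in s (default 10).
#' @return List of class `bite_detector_params`.
#' @export
bite_detector_params <- function(threshold_delta = 2, min_duration = 0.01,
                                 merge_gap = 0.05, baseline_window = 10) {
  stopifnot(threshold_delta > 0, min_duration > 0, merge_gap > 0,
            baseline_window > 0)
  structure(list(threshold_delta = threshold_delta,
                 min_duration = min_duration, merge_gap = merge_gap,
                 baseline_window = baseline_window),
            class = "bite_detector_params")
}

#' Rolling-median pressure baseline
#'
#' @param pressure Numeric vector of pressure samples (kPa).
#' @param sample_rate Hz.
#' @param baseline_window Window length in s.
#' @return Numeric vector, one baseline value per sample.
#' @export
estimate_baseline <- function(pressure, sample_rate, baseline_window = 2) {
  if (length(pressure) == 0L) stop("empty pressure series")
  if (length(pressure) < 3L) return(rep(stats::median(pressure), length(pressure)))
  k <- round(baseline_window * sample_rate)
  k <- min(k, length(pressure))
  if (k %% 2 == 0) k <- k - 1L
  k <- max(k, 3L)
  # constant endrule: the first/last full-window median extends to the
  # edges, so an event near a stream end cannot drag the baseline up
  as.numeric(stats::runmed(pressure, k, endrule = "constant"))
}

#' Detect bite events in a trial slice
#'
#' @param trial A [sensor_stream()] slice covering one trial.
#' @param params A [bite_detector_params()].
#' @return data.frame with one row per event: `onset` and `offset` (s,
#'   half-open: offset is the first sample time past the run), `duration`
#'   (= offset - onset), `peak` and `rms` (kPa, over the raw samples in
#'   the run). Zero rows when nothing crosses the threshold.
#' @export
detect_bites <- function(trial, params = bite_detector_params()) {
  stopifnot(inherits(trial, "sensor_stream"),
            inherits(params, "bite_detector_params"))
  d <- trial$data
  rate <- trial$sample_rate
  dt <- 1 / rate
  if (params$min_duration < dt) {
    stop("min_duration below one sample interval")
  }
  base <- estimate_baseline(d$pressure_kpa, rate, params$baseline_window)
  above <- d$pressure_kpa >= base + params$threshold_delta
  if (!any(above)) return(empty_bites())
  runs <- run_bounds(above)
  runs <- merge_runs(runs, d$t_s, params$merge_gap)
  dur <- (runs$end - runs$start + 1L) * dt
  runs <- runs[dur >= params$min_duration - 1e-12, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty_bites())
  out <- data.frame(
    onset = d$t_s[runs$start],
    offset = d$t_s[runs$end] + dt,
    duration = (runs$end - runs$start + 1L) * dt,
    peak = NA_real_, rms = NA_real_)
  for (i in seq_len(nrow(runs))) {
    p <- d$pressure_kpa[runs$start[i]:runs$end[i]]
    out$peak[i] <- max(p)
    out$rms[i] <- sqrt(mean(p^2))
  }
  out
}

empty_bites <- function() {
  data.frame(onset = numeric(0), offset = numeric(0), duration = numeric(0),
             peak = numeric(0), rms = numeric(0))
}

#' Summarize one trial's bite events into the engineered feature row
#'
#' Implements the per-trial features: interaction time (annotated retrieval
#' time, falling back to the last event offset), number of bites, the
#' average/maximum/total of bite strength (peak pressure), duration and
#' RMS pressure, average bite frequency (bites per trial second), and peak
#' bite frequency. A trial with no events is the all-zero
#' `zero_interaction` case.
#'
#' @param window One annotation row (`start_s`, `end_s` at minimum).
#' @param events A [detect_bites()] result, ordered by onset.
#' @param retrieval_time Annotated retrieval time in stream seconds, or
#'   `NA` to fall back to the last event offset.
#' @param peak_freq_method `"inter_onset"` (default): peak frequency is the
#'   reciprocal of the smallest inter-onset interval, falling back to
#'   `n_bites / trial length` when fewer than 2 bites; `"per_trial"`: always
#'   `n_bites / trial length`.
#' @return One-row data.frame with the feature columns (see
#'   [build_feature_table()]).
#' @export
summarize_trial <- function(window, events, retrieval_time = NA,
                            peak_freq_method = c("inter_onset", "per_trial")) {
  peak_freq_method <- match.arg(peak_freq_method)
  trial_len <- window$end_s - window$start_s
  if (!is.finite(trial_len) || trial_len <= 0) stop("degenerate trial window")
  n <- nrow(events)
  row <- data.frame(
    zero_interaction = n == 0L, interaction_time_s = 0, n_bites = n,
    avg_strength_kpa = 0, max_strength_kpa = 0, total_strength_kpa = 0,
    avg_duration_s = 0, max_duration_s = 0, total_duration_s = 0,
    avg_rms_kpa = 0, max_rms_kpa = 0, total_rms_kpa = 0,
    avg_freq_hz = 0, peak_freq_hz = 0)
  if (n == 0L) return(row)
  if (is.unsorted(events$onset)) stop("events not ordered by onset")
  it <- if (is.na(retrieval_time)) max(events$offset) - window$start_s
        else retrieval_time - window$start_s
  row$interaction_time_s <- it
  agg <- function(x) c(mean(x), max(x), sum(x))
  row[c("avg_strength_kpa", "max_strength_kpa", "total_strength_kpa")] <-
    as.list(agg(events$peak))
  row[c("avg_duration_s", "max_duration_s", "total_duration_s")] <-
    as.list(agg(events$duration))
  row[c("avg_rms_kpa", "max_rms_kpa", "total_rms_kpa")] <-
    as.list(agg(events$rms))
  row$avg_freq_hz <- n / trial_len
  row$peak_freq_hz <- if (peak_freq_method == "per_trial" || n < 2L) {
    n / trial_len
  } else {
    1 / min(diff(events$onset))
  }
  row
}

#' Build the per-trial feature table for a cohort
#'
#' Runs bite detection and trial summarization over every annotated trial
#' of a cohort manifest, drops trials of excluded dogs, and joins the
#' roster's placement outcome. One row per analyzable trial; deterministic.
#'
#' @param manifest A [generate_cohort()] manifest (streams in memory or on
#'   disk).
#' @param params A [bite_detector_params()].
#' @param peak_freq_method Passed to [summarize_trial()].
#' @return data.frame with columns `dog_id, condition, trial_index,
#'   zero_interaction, interaction_time_s, n_bites, avg_strength_kpa,
#'   max_strength_kpa, total_strength_kpa, avg_duration_s, max_duration_s,
#'   total_duration_s, avg_rms_kpa, max_rms_kpa, total_rms_kpa,
#'   avg_freq_hz, peak_freq_hz, placed`.
#' @export
build_feature_table <- function(manifest, params = bite_detector_params(),
                                peak_freq_method = "inter_onset") {
  stopifnot(inherits(manifest, "cohort_manifest"))
  roster <- manifest$roster
  ann <- manifest$annotations
  keep <- !roster$excluded[match(ann$dog_id, roster$dog_id)]
  ann <- ann[keep, , drop = FALSE]
  rows <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    key <- sprintf("%s_%s_%02d", ann$dog_id[i], ann$condition[i],
                   ann$trial_index[i])
    stream <- manifest_stream(manifest, key)
    events <- detect_bites(stream, params)
    retrieval <- if ("retrieval_s" %in% names(ann) &&
                     nrow(events) > 0L) ann$retrieval_s[i] else NA
    feat <- summarize_trial(ann[i, ], events, retrieval_time = retrieval,
                            peak_freq_method = peak_freq_method)
    rows[[i]] <- cbind(
      data.frame(dog_id = ann$dog_id[i], condition = ann$condition[i],
                 trial_index = ann$trial_index[i], stringsAsFactors = FALSE),
      feat)
  }
  out <- do.call(rbind, rows)
  out$placed <- roster$placed[match(out$dog_id, roster$dog_id)]
  rownames(out) <- NULL
  # column order of the exported CSV schema
  out[c("dog_id", "condition", "trial_index", "zero_interaction",
        "interaction_time_s", "n_bites",
        "avg_strength_kpa", "max_strength_kpa", "total_strength_kpa",
        "avg_duration_s", "max_duration_s", "total_duration_s",
        "avg_rms_kpa", "max_rms_kpa", "total_rms_kpa",
        "avg_freq_hz", "peak_freq_hz", "placed")]
}
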