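#' Sensor stream container
#'
#' A `sensor_stream` holds one recording session from the instrumented ball:
#' a strictly increasing time base, barometric pressure in kilopascals, and
#' the nine IMU channels (accelerometer in g, gyroscope in deg/s,
#' magnetometer in microtesla).
#'
#' @param data data.frame with columns
#'   `t_s,pressure_kpa,ax,ay,az,gx,gy,gz,mx,my,mz`.
#' @param sample_rate Sampling rate in Hz.
#' @param source_id Identifier for the recording (used in error messages).
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(data, sample_rate, source_id = "stream") {
  stopifnot(is.data.frame(data), nrow(data) >= 1L)
  missing_cols <- setdiff(stream_columns(), names(data))
  if (length(missing_cols)) {
    stop("stream is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(data) > 1L && any(diff(data$t_s) <= 0)) {
    bad <- which(diff(data$t_s) <= 0)[1L] + 1L
    stop("time not strictly increasing at row ", bad, " of ", source_id)
  }
  if (any(data$pressure_kpa <= 0)) stop("non-positive pressure in ", source_id)
  structure(
    list(data = data[stream_columns()], sample_rate = sample_rate,
         source_id = source_id),
    class = "sensor_stream"
  )
}

stream_columns <- function() {
  c("t_s", "pressure_kpa", "ax", "ay", "az", "gx", "gy", "gz",
    "mx", "my", "mz")
}

#' @export
print.sensor_stream <- function(x, ...) {
  d <- x$data
  cat(sprintf(
    "<sensor_stream '%s': %d samples @ %g Hz, %.2f-%.2f s, pressure %.2f-%.2f kPa>\n",
    x$source_id, nrow(d), x$sample_rate, d$t_s[1L], d$t_s[nrow(d)],
    min(d$pressure_kpa), max(d$pressure_kpa)))
  invisible(x)
}

#' @export
length.sensor_stream <- function(x) nrow(x$data)

#' Read or write a sensor-stream CSV
#'
#' The on-disk dialect is a UTF-8 CSV with header
#' `t_s,pressure_kpa,ax,ay,az,gx,gy,gz,mx,my,mz`, one row per sample, '.'
#' decimal separator. `write_stream()` followed by `read_stream()` is an
#' identity up to float formatting (relative error below 1e-9).
#'
#' @param path Path to the CSV file.
#' @param sample_rate Sampling rate recorded on the returned object; if
#'   `NULL` it is inferred from the median time step.
#' @return `read_stream()` returns a [sensor_stream()]; `write_stream()`
#'   returns `path` invisibly.
#' @export
read_stream <- function(path, sample_rate = NULL) {
  header <- utils::read.csv(path, nrows = 1L, check.names = FALSE)
  if (!identical(names(header), stream_columns())) {
    stop("malformed header in ", path, ": expected ",
         paste(stream_columns(), collapse = ","))
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  num <- suppressWarnings(
    as.data.frame(lapply(df, as.numeric), check.names = FALSE))
  bad <- which(!stats::complete.cases(num))
  if (length(bad)) {
    stop("non-numeric cell at row ", bad[1L], " of ", path)
  }
  if (nrow(num) > 1L && any(diff(num$t_s) <= 0)) {
    bad <- which(diff(num$t_s) <= 0)[1L] + 1L
    stop("time not strictly increasing at row ", bad, " of ", path)
  }
  if (is.null(sample_rate)) {
    sample_rate <- if (nrow(num) > 1L) 1 / stats::median(diff(num$t_s)) else NA_real_
  }
  sensor_stream(num, sample_rate, source_id = basename(path))
}

#' @rdname read_stream
#' @param stream A [sensor_stream()].
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  utils::write.csv(format(stream$data, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect magnet sync swipes in the magnetometer channels
#'
#' Sessions are book-ended by running a small magnet along the ball, which
#' produces a large excursion of the magnetic-field magnitude. An event is a
#' maximal excursion of `|B| - median(|B|)` above `mag_threshold`; excursions
#' closer than `min_separation` are merged into one event, timed at the
#' sample of peak excursion.
#'
#' @param stream A [sensor_stream()].
#' @param mag_threshold Excursion threshold in microtesla (default 200,
#'   well above the ambient noise floor).
#' @param min_separation Merge window in seconds (default 1).
#' @return data.frame with columns `time` (s) and `magnitude` (peak
#'   excursion, microtesla), ordered by time; zero rows when no swipe.
#' @export
detect_sync <- function(stream, mag_threshold = 200, min_separation = 1) {
  stopifnot(inherits(stream, "sensor_stream"), mag_threshold > 0)
  d <- stream$data
  mag <- sqrt(d$mx^2 + d$my^2 + d$mz^2)
  dev <- mag - stats::median(mag)
  above <- dev > mag_threshold
  if (!any(above)) {
    return(data.frame(time = numeric(0), magnitude = numeric(0)))
  }
  runs <- run_bounds(above)
  # merge runs whose gap is below min_separation
  merged <- merge_runs(runs, d$t_s, min_separation)
  time <- magnitude <- numeric(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    idx <- merged$start[i]:merged$end[i]
    peak <- idx[which.max(dev[idx])]
    time[i] <- d$t_s[peak]
    magnitude[i] <- dev[peak]
  }
  data.frame(time = time, magnitude = magnitude)
}

# maximal runs of TRUE as (start, end) sample indices
run_bounds <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# merge consecutive runs separated by less than gap_s (in time units of t)
merge_runs <- function(runs, t, gap_s) {
  if (nrow(runs) <= 1L) return(runs)
  keep_start <- runs$start[1L]
  out_start <- integer(0); out_end <- integer(0)
  cur_end <- runs$end[1L]
  for (i in 2L:nrow(runs)) {
    if (t[runs$start[i]] - t[cur_end] < gap_s) {
      cur_end <- runs$end[i]
    } else {
      out_start <- c(out_start, keep_start); out_end <- c(out_end, cur_end)
      keep_start <- runs$start[i]; cur_end <- runs$end[i]
    }
  }
  out_start <- c(out_start, keep_start); out_end <- c(out_end, cur_end)
  data.frame(start = out_start, end = out_end)
}

#' Slice a session stream into annotated trial windows
#'
#' Windows are half-open `[start, end)` in seconds from stream start and
#' must be non-overlapping and within the stream span.
#'
#' @param stream A [sensor_stream()].
#' @param windows data.frame with columns `dog_id, condition, trial_index,
#'   start_s, end_s` (extra columns are carried through).
#' @return A list with one element per window: `list(window = <row>,
#'   stream = <sensor_stream slice>)`.
#' @export
segment_trials <- function(stream, windows) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (is.null(windows) || nrow(windows) == 0L) stop("no trials annotated")
  need <- c("dog_id", "condition", "trial_index", "start_s", "end_s")
  if (!all(need %in% names(windows))) {
    stop("annotation is missing columns: ",
         paste(setdiff(need, names(windows)), collapse = ", "))
  }
  if (any(windows$start_s >= windows$end_s)) {
    stop("annotation error: degenerate window (start >= end)")
  }
  ord <- order(windows$start_s)
  w <- windows[ord, , drop = FALSE]
  if (nrow(w) > 1L && any(w$start_s[-1L] < w$end_s[-nrow(w)])) {
    stop("annotation error: overlapping windows")
  }
  span <- range(stream$data$t_s)
  if (any(w$start_s < span[1L]) || any(w$end_s > span[2L] + 1 / stream$sample_rate)) {
    stop("annotation error: window outside stream span")
  }
  lapply(seq_len(nrow(w)), function(i) {
    sel <- stream$data$t_s >= w$start_s[i] & stream$data$t_s < w$end_s[i]
    slice <- sensor_stream(
      stream$data[sel, , drop = FALSE], stream$sample_rate,
      source_id = sprintf("%s[%g,%g)", stream$source_id,
                          w$start_s[i], w$end_s[i]))
    list(window = w[i, , drop = FALSE], stream = slice)
  })
}
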