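#' Preprocessing configuration
#'
#' Parameters governing the ECG-to-network-input pipeline: inter-beat
#' intervals are filtered by removing values more than
#' `outlier_sd_threshold` standard deviations from the night's mean, the
#' instantaneous heart rate is resampled to `target_rate`, and the series is
#' zero padded to a constant length of `max_duration` hours
#' (`max_duration * target_rate * 3600` samples; 72,000 by default).
#'
#' @param outlier_sd_threshold Dimensionless z-score cut for IBI outliers
#'   (default 5).
#' @param target_rate Resampling rate in Hz (default 2).
#' @param max_duration Padded duration in hours (default 10).
#' @param epoch_length Scoring epoch in seconds (default 30).
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(outlier_sd_threshold = 5, target_rate = 2,
                              max_duration = 10, epoch_length = 30) {
  stopifnot(outlier_sd_threshold > 0, target_rate > 0, max_duration > 0,
            epoch_length > 0)
  structure(list(outlier_sd_threshold = outlier_sd_threshold,
                 target_rate = target_rate, max_duration = max_duration,
                 epoch_length = epoch_length),
            class = "preprocess_config")
}

padded_length <- function(config) {
  as.integer(round(config$max_duration * config$target_rate * 3600))
}

n_epochs_padded <- function(config) {
  as.integer(round(config$max_duration * 3600 / config$epoch_length))
}

#' Construct an inter-beat-interval series
#'
#' @param anchor_times Seconds; the time of the later beat of each pair.
#' @param intervals Seconds between consecutive beats.
#' @return A list of class `"ibi_series"`.
#' @export
ibi_series <- function(anchor_times, intervals) {
  stopifnot(length(anchor_times) == length(intervals))
  if (length(intervals) > 0) {
    if (any(intervals <= 0)) stop("intervals must be positive")
    if (any(diff(anchor_times) <= 0))
      stop("anchor times must be strictly increasing")
  }
  structure(list(anchor_times = as.numeric(anchor_times),
                 intervals = as.numeric(intervals)),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series: %d intervals spanning %.1f s>\n",
              length(x$intervals),
              if (length(x$anchor_times)) max(x$anchor_times) else 0))
  invisible(x)
}

#' Beat times to filtered inter-beat intervals
#'
#' Consecutive differences of the R-wave times form the inter-beat-interval
#' (IBI) series; values more than `outlier_sd_threshold` standard deviations
#' from the whole night's mean (a single pass over the raw intervals) are
#' removed together with their anchor times, discarding artefacts of missed
#' or spurious peak detection.
#'
#' @param beats Numeric vector of strictly increasing beat times (seconds).
#' @param config A [preprocess_config()].
#' @return An [ibi_series()]; each interval is anchored at the time of the
#'   later beat of its pair.
#' @examples
#' beats_to_ibi(c(0, 1, 2, 3))
#' @export
beats_to_ibi <- function(beats, config = preprocess_config()) {
  beats <- as.numeric(beats)
  if (length(beats) < 2)
    stop("insufficient data: at least 2 beat times are required")
  if (any(diff(beats) <= 0)) stop("beat times must be strictly increasing")
  if (any(beats < 0)) stop("beat times must be non-negative")
  intervals <- diff(beats)
  anchors <- beats[-1]
  mu <- mean(intervals)
  s <- stats::sd(intervals)
  if (is.finite(s) && s > 0) {
    keep <- abs(intervals - mu) <= config$outlier_sd_threshold * s
  } else {
    keep <- rep(TRUE, length(intervals))
  }
  ibi_series(anchors[keep], intervals[keep])
}

#' Filtered IBI series to the fixed-size normalized network input
#'
#' The instantaneous heart rate (IHR) is the reciprocal of each inter-beat
#' interval, anchored at the later beat of the pair.  The IHR is
#' z-normalized per night (mean subtracted, divided by the standard
#' deviation, both computed over the beat-anchored values before
#' resampling), linearly interpolated onto a uniform `target_rate` grid
#' spanning the recording, and zero padded to the constant model input
#' length (72,000 samples for the 10-h default).
#'
#' @param ibi An [ibi_series()].
#' @param config A [preprocess_config()].
#' @param night_id Optional identifier attached to the result.
#' @return A list of class `"ihr_input"` with elements `samples` (length
#'   72,000), `valid_epochs` (logical, length 1200: epochs fully covered by
#'   the recording) and `night_id`.
#' @export
ibi_to_ihr_input <- function(ibi, config = preprocess_config(),
                             night_id = NA_character_) {
  stopifnot(inherits(ibi, "ibi_series"))
  if (length(ibi$intervals) < 2)
    stop("insufficient data: need at least 2 surviving intervals")
  anchors <- ibi$anchor_times
  max_s <- config$max_duration * 3600
  if (max(anchors) > max_s) {
    warning(sprintf("recording longer than %g h; truncated", config$max_duration))
    keep <- anchors <= max_s
    anchors <- anchors[keep]
    ibi <- ibi_series(anchors, ibi$intervals[keep])
    if (length(ibi$intervals) < 2)
      stop("insufficient data: need at least 2 surviving intervals")
  }
  ihr <- 1 / ibi$intervals
  mu <- mean(ihr)
  s <- stats::sd(ihr)
  if (!is.finite(s) || s == 0) {
    warning("zero-variance IHR; normalized values set to zero")
    ihr_n <- rep(0, length(ihr))
  } else {
    ihr_n <- (ihr - mu) / s
  }
  len <- padded_length(config)
  duration <- max(anchors)
  n_grid <- min(len, floor(duration * config$target_rate) + 1L)
  grid <- (seq_len(n_grid) - 1L) / config$target_rate
  vals <- stats::approx(anchors, ihr_n, xout = grid, rule = 2)$y
  samples <- numeric(len)
  samples[seq_len(n_grid)] <- vals
  spe <- config$epoch_length * config$target_rate
  n_ep <- n_epochs_padded(config)
  covered <- floor(duration / config$epoch_length)
  valid <- seq_len(n_ep) <= covered
  structure(list(samples = samples, valid_epochs = valid,
                 night_id = night_id),
            class = "ihr_input")
}

#' @export
print.ihr_input <- function(x, ...) {
  cat(sprintf("<ihr_input: %d samples, %d/%d valid epochs, night '%s'>\n",
              length(x$samples), sum(x$valid_epochs), length(x$valid_epochs),
              x$night_id))
  invisible(x)
}
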