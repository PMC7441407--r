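#' Detect R peaks in an ECG waveform (Pan-Tompkins)
#'
#' Classic QRS detection pipeline: band-pass filter (5--15 Hz, zero-phase),
#' five-point derivative, squaring, 150-ms moving-window integration, and
#' adaptive dual thresholds with a 200-ms refractory period and a
#' search-back pass at half threshold when an expected beat is missed.
#' Peak times are refined to the local maximum of the filtered ECG so they
#' land on the R wave itself rather than on the integration envelope.
#'
#' @param ecg Numeric waveform samples.
#' @param sampling_rate Sampling rate in Hz; at least 100.
#' @return Numeric vector of strictly increasing R-peak times in seconds
#'   from the start of the recording (empty when no peaks are detectable).
#' @examples
#' sim <- simulate_ecg(ibi_series(cumsum(rep(1, 10)), rep(1, 10)),
#'                     sampling_rate = 250, noise = 0, seed = 1)
#' detect_r_peaks(sim$signal, sim$sampling_rate)
#' @export
detect_r_peaks <- function(ecg, sampling_rate) {
  if (sampling_rate < 100)
    stop("invalid input: sampling_rate must be at least 100 Hz")
  ecg <- as.numeric(ecg)
  if (length(ecg) < 10 * sampling_rate)
    stop("invalid input: waveform must be at least 10 s long")
  if (all(ecg == ecg[1])) return(numeric(0))
  fs <- sampling_rate
  ecg <- (ecg - mean(ecg)) / stats::sd(ecg)

  # band-pass 5-15 Hz, zero phase so no group-delay correction is needed
  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, ecg)

  # five-point derivative, squaring, moving-window integration (150 ms)
  der <- signal::filter(signal::Ma(c(1, 2, 0, -2, -1) * fs / 8), bp)
  sq <- as.numeric(der)^2
  win <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 1))
  mwi[is.na(mwi)] <- 0

  refractory <- round(0.200 * fs)
  # candidate peaks: local maxima of the integrated signal separated by at
  # least the refractory period
  n <- length(mwi)
  is_max <- c(FALSE, mwi[2:(n - 1)] >= mwi[1:(n - 2)] &
                     mwi[2:(n - 1)] > mwi[3:n], FALSE)
  cand <- which(is_max & mwi > 0)
  if (length(cand) == 0) return(numeric(0))

  # adaptive dual thresholds (Pan-Tompkins running estimates)
  spki <- max(mwi[seq_len(min(n, 2 * fs))]) * 0.5
  npki <- mean(mwi[seq_len(min(n, 2 * fs))]) * 0.5
  thr <- npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  rr_hist <- numeric(0)
  last_cand_below <- integer(0)
  for (i in cand) {
    if (length(peaks) > 0 && (i - peaks[length(peaks)]) < refractory) next
    if (mwi[i] > thr) {
      peaks <- c(peaks, i)
      spki <- 0.125 * mwi[i] + 0.875 * spki
      if (length(peaks) > 1)
        rr_hist <- tail(c(rr_hist, diff(tail(peaks, 2))), 8)
    } else {
      last_cand_below <- c(last_cand_below, i)
      npki <- 0.125 * mwi[i] + 0.875 * npki
      # search back: if the gap since the last beat exceeds 1.66 x the
      # running RR average, accept the largest missed candidate at thr/2
      if (length(peaks) > 0 && length(rr_hist) > 0) {
        gap <- i - peaks[length(peaks)]
        if (gap > 1.66 * mean(rr_hist)) {
          miss <- last_cand_below[last_cand_below > peaks[length(peaks)] +
                                    refractory]
          if (length(miss) > 0) {
            best <- miss[which.max(mwi[miss])]
            if (mwi[best] > thr / 2) {
              peaks <- sort(c(peaks, best))
              spki <- 0.25 * mwi[best] + 0.75 * spki
              last_cand_below <- integer(0)
            }
          }
        }
      }
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (length(peaks) == 0) return(numeric(0))

  # refine each detection to the local maximum of the band-passed ECG
  # within +/-150 ms (the integration envelope lags the R wave)
  half <- as.integer(round(0.150 * fs))
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, as.integer(i) - half)
    hi <- min(n, as.integer(i) + half)
    lo + which.max(bp[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period after refinement
  if (length(refined) > 1) {
    keep <- c(TRUE, diff(refined) >= refractory)
    while (!all(keep)) {
      refined <- refined[keep]
      keep <- c(TRUE, diff(refined) >= refractory)
    }
  }
  (refined - 1) / fs
}
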