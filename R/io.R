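# Minimal EDF and WFDB support: single-channel continuous recordings with
# 16-bit samples, which covers the ECG interchange needs of this package.
# No R package for either format is available in the supported dependency
# set, so the small subset used here is implemented directly and guarded by
# round-trip tests.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a single-channel ECG to an EDF file
#'
#' European Data Format, one signal, one-second data records, 16-bit
#' samples.  The signal is scaled to the full digital range; the recording
#' is padded with zeros to a whole number of seconds.  `sampling_rate` must
#' be an integer number of samples per second.
#'
#' @param signal Numeric waveform.
#' @param sampling_rate Hz (integer valued).
#' @param path Output file.
#' @param label Signal label (default "ECG").
#' @export
write_ecg_edf <- function(signal, sampling_rate, path, label = "ECG") {
  fs <- as.integer(round(sampling_rate))
  stopifnot(fs >= 1, abs(sampling_rate - fs) < 1e-9, length(signal) > 0)
  n_rec <- as.integer(ceiling(length(signal) / fs))
  x <- c(signal, numeric(n_rec * fs - length(signal)))
  pmin_ <- min(x); pmax_ <- max(x)
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) * 65535 - 32768))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad_field("0", 8), pad_field("synthetic", 80),
                pad_field("cardiostager", 80), pad_field("01.01.00", 8),
                pad_field("00.00.00", 8), pad_field(512, 8),
                pad_field("", 44), pad_field(n_rec, 8), pad_field(1, 8),
                pad_field(1, 4))
  sig <- paste0(pad_field(label, 16), pad_field("", 80), pad_field("mV", 8),
                pad_field(sprintf("%.6g", pmin_), 8),
                pad_field(sprintf("%.6g", pmax_), 8),
                pad_field(-32768, 8), pad_field(32767, 8), pad_field("", 80),
                pad_field(fs, 8), pad_field("", 32))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a single-channel EDF recording
#'
#' Supports the subset written by [write_ecg_edf()]: continuous recordings
#' whose signals have integer samples-per-record.  Returns the requested
#' channel in physical units.
#'
#' @param path EDF file.
#' @param channel Channel label or 1-based index (default 1).
#' @return List with `signal`, `sampling_rate`, `label`.
#' @export
read_ecg_edf <- function(path, channel = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr) < 256) stop("format error: truncated EDF header")
  n_rec <- as.integer(substr(hdr, 237, 244))
  rec_dur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  if (is.na(ns) || ns < 1) stop("format error: bad EDF signal count")
  field <- function(sighdr, off, width, i)
    substr(sighdr, off * ns + (i - 1) * width + 1,
           off * ns + i * width)
  sighdr <- readChar(con, 256 * ns, useBytes = TRUE)
  # per-signal fields are stored field-major: all labels, all transducers...
  offs <- cumsum(c(0, 16, 80, 8, 8, 8, 8, 8, 80, 8))
  getf <- function(fi, width, i)
    trimws(substr(sighdr, offs[fi] * ns + (i - 1) * width + 1,
                  offs[fi] * ns + i * width))
  labels <- vapply(seq_len(ns), function(i) getf(1, 16, i), "")
  ch <- if (is.character(channel)) match(channel, labels) else as.integer(channel)
  if (is.na(ch) || ch < 1 || ch > ns)
    stop("channel not found: ", channel)
  pmin_ <- as.numeric(getf(4, 8, ch)); pmax_ <- as.numeric(getf(5, 8, ch))
  dmin_ <- as.numeric(getf(6, 8, ch)); dmax_ <- as.numeric(getf(7, 8, ch))
  spr <- vapply(seq_len(ns), function(i) as.integer(getf(9, 8, i)), 1L)
  vals <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", spr[i], size = 2, endian = "little",
                   signed = TRUE)
      if (i == ch) vals[[r]] <- d
    }
  }
  dig <- unlist(vals)
  phys <- pmin_ + (dig - dmin_) / (dmax_ - dmin_) * (pmax_ - pmin_)
  list(signal = phys, sampling_rate = spr[ch] / rec_dur, label = labels[ch])
}

#' Write a single-channel ECG as a WFDB record
#'
#' Writes `<record>.hea` and `<record>.dat` using signal format 16 (16-bit
#' little-endian two's complement) with a fixed gain.
#'
#' @param signal Numeric waveform (physical units).
#' @param sampling_rate Hz.
#' @param record Record path without extension.
#' @param gain ADC units per physical unit (default 200).
#' @export
write_ecg_wfdb <- function(signal, sampling_rate, record, gain = 200) {
  adc <- as.integer(pmin(pmax(round(signal * gain), -32768), 32767))
  base <- basename(record)
  hea <- sprintf("%s 1 %g %d", base, sampling_rate, length(signal))
  sig <- sprintf("%s.dat 16 %g 16 0 %d 0 0 ECG", base, gain,
                 if (length(adc)) adc[1] else 0)
  writeLines(c(hea, sig), paste0(record, ".hea"))
  con <- file(paste0(record, ".dat"), "wb")
  on.exit(close(con))
  writeBin(adc, con, size = 2, endian = "little")
  invisible(record)
}

#' Read a WFDB record (format 16, single signal)
#'
#' @param record Record path without extension.
#' @return List with `signal` (physical units), `sampling_rate`, `label`.
#' @export
read_ecg_wfdb <- function(record) {
  hea <- readLines(paste0(record, ".hea"))
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  sig <- strsplit(trimws(hea[2]), "\\s+")[[1]]
  if (sig[2] != "16")
    stop("format error: only WFDB signal format 16 is supported")
  gain <- as.numeric(strsplit(sig[3], "[(/]")[[1]][1])
  if (!is.finite(gain) || gain == 0) gain <- 200
  con <- file(paste0(record, ".dat"), "rb")
  on.exit(close(con))
  adc <- readBin(con, "integer", n, size = 2, endian = "little",
                 signed = TRUE)
  list(signal = adc / gain, sampling_rate = fs,
       label = if (length(sig) >= 9) sig[9] else "ECG")
}

#' Read an ECG from EDF, WFDB or CSV
#'
#' CSV input is either one column of samples (the rate must be supplied) or
#' two columns (time in seconds, value).
#'
#' @param path File path (for WFDB, the record name without extension).
#' @param format One of `"edf"`, `"wfdb"`, `"csv"`.
#' @param channel Channel label or index (EDF only).
#' @param sampling_rate Required for single-column CSV.
#' @return List with `signal` and `sampling_rate`.
#' @export
read_ecg <- function(path, format = c("edf", "wfdb", "csv"), channel = 1,
                     sampling_rate = NULL) {
  format <- match.arg(format)
  switch(format,
    edf = read_ecg_edf(path, channel),
    wfdb = read_ecg_wfdb(path),
    csv = {
      d <- utils::read.csv(path)
      if (ncol(d) >= 2) {
        tt <- d[[1]]
        fs <- 1 / stats::median(diff(tt))
        list(signal = as.numeric(d[[2]]), sampling_rate = fs)
      } else {
        if (is.null(sampling_rate))
          stop("sampling_rate is required for single-column CSV input")
        list(signal = as.numeric(d[[1]]), sampling_rate = sampling_rate)
      }
    })
}

#' Read and write beat-time CSV files
#'
#' One column `time_s` of R-wave times in seconds.
#'
#' @param beats Numeric beat times.
#' @param path File path.
#' @export
write_beats_csv <- function(beats, path) {
  utils::write.csv(data.frame(time_s = as.numeric(beats)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_beats_csv
#' @return For `read_beats_csv`, a numeric vector of beat times.
#' @export
read_beats_csv <- function(path) {
  as.numeric(utils::read.csv(path)$time_s)
}

#' Read and write IBI series CSV files
#'
#' Columns `anchor_time_s` and `interval_s`.
#'
#' @param ibi An [ibi_series()].
#' @param path File path.
#' @export
write_ibi_csv <- function(ibi, path) {
  utils::write.csv(data.frame(anchor_time_s = ibi$anchor_times,
                              interval_s = ibi$intervals),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ibi_csv
#' @export
read_ibi_csv <- function(path) {
  d <- utils::read.csv(path)
  ibi_series(d$anchor_time_s, d$interval_s)
}

#' Read and write hypnogram CSV files
#'
#' Columns `epoch_index` (0-based; epoch `i` covers seconds
#' `[30i, 30(i+1))`) and `stage`.  With `vocabulary = "raw"` the stage
#' column holds the six expert symbols (W, N1--N4, REM) and is mapped
#' through [map_raw_stages()]; with `"fourclass"` it holds the package
#' vocabulary directly.
#'
#' @param h A [hypnogram()].
#' @param path File path.
#' @export
write_hypnogram_csv <- function(h, path) {
  utils::write.csv(data.frame(epoch_index = seq_along(h) - 1L,
                              stage = as.character(h)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @param vocabulary `"raw"` or `"fourclass"`.
#' @export
read_hypnogram_csv <- function(path, vocabulary = c("fourclass", "raw")) {
  vocabulary <- match.arg(vocabulary)
  d <- utils::read.csv(path, colClasses = c("integer", "character"))
  if (nrow(d) == 0) {
    warning("empty hypnogram file")
    return(hypnogram(character(0)))
  }
  if (anyDuplicated(d$epoch_index))
    stop("format error: duplicate epoch index")
  d <- d[order(d$epoch_index), ]
  if (vocabulary == "raw") map_raw_stages(d$stage) else hypnogram(d$stage)
}

#' Read and write cohort tables
#'
#' Column encodings: `gender` female 0 / male 1; `age_class` 0 (<55),
#' 1 (55--60), 2 (61--70), 3 (>70); `apnea_class` 0 (AHI<5), 1 (5--15),
#' 2 (15--30), 3 (>30); `hypertension` 0/1; plus the four sleep metrics
#' and `mean_rem_bout` in minutes.
#'
#' @param table Cohort data frame.
#' @param path File path.
#' @export
write_cohort_csv <- function(table, path) {
  check_cohort(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort <- function(path) {
  check_cohort(utils::read.csv(path))
}

#' Write an IHR network input (samples plus validity mask) to CSV
#'
#' @param input An `ihr_input`.
#' @param path File path.
#' @export
write_ihr_csv <- function(input, path) {
  utils::write.csv(data.frame(sample = input$samples), path,
                   row.names = FALSE)
  mask_path <- paste0(path, ".mask")
  writeLines(as.character(as.integer(input$valid_epochs)), mask_path)
  invisible(path)
}

#' @rdname write_ihr_csv
#' @param night_id Identifier for the restored input.
#' @export
read_ihr_csv <- function(path, night_id = NA_character_) {
  samples <- utils::read.csv(path)$sample
  valid <- as.logical(as.integer(readLines(paste0(path, ".mask"))))
  structure(list(samples = samples, valid_epochs = valid,
                 night_id = night_id),
            class = "ihr_input")
}
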