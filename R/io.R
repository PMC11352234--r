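#' Read and write single-channel EEG recordings
#'
#' Two on-disk formats are supported:
#'
#' * **csv** — the package's plain-text dialect: comment header lines
#'   `# fs=`, `# channel=`, `# phase=`, `# subject=`, then a `uV` column and
#'   an optional `poor_signal` column, comma-separated, `.` decimal. Values
#'   are written at full double precision, so a CSV round trip is bit-exact.
#' * **edf** — a minimal single-channel European Data Format file for
#'   interoperability with clinical viewers. EDF stores 16-bit integers, so a
#'   round trip is exact only up to the quantization step
#'   `(physical max − physical min) / 65535`; the poor-signal series is not
#'   carried in EDF.
#'
#' @param rec An [eeg_recording()].
#' @param path File path.
#' @param format `"csv"` or `"edf"`; by default inferred from the file
#'   extension.
#' @return `read_recording()` returns a validated [eeg_recording()];
#'   `write_recording()` returns `path` invisibly.
#' @examples
#' rec <- eeg_recording(rnorm(1024), fs = 512, subject = "S01")
#' p <- tempfile(fileext = ".csv")
#' write_recording(rec, p)
#' identical(read_recording(p)$uV, rec$uV)
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec) == 0L) abort("refusing to write an empty recording.")
  format <- resolve_format(match.arg(format), path)
  switch(format,
         csv = write_recording_csv(rec, path),
         edf = write_recording_edf(rec, path))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  format <- resolve_format(match.arg(format), path)
  switch(format,
         csv = read_recording_csv(path),
         edf = read_recording_edf(path))
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") "edf" else "csv"
}

write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%s", format(eeg_fs(rec), digits = 17)),
               sprintf("# channel=%s", eeg_channel(rec)),
               sprintf("# phase=%s", eeg_phase(rec)),
               sprintf("# subject=%s", eeg_subject(rec))), con)
  has_ps <- "poor_signal" %in% names(rec)
  writeLines(if (has_ps) "uV,poor_signal" else "uV", con)
  v <- sprintf("%.17g", rec$uV)
  writeLines(if (has_ps) paste(v, rec$poor_signal, sep = ",") else v, con)
}

read_recording_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) == 0L || any(diff(hdr_idx) != 1L) || hdr_idx[1] != 1L) {
    abort(sprintf("%s: header comment lines must be contiguous at the top.",
                  path))
  }
  meta <- list()
  for (i in hdr_idx) {
    m <- regmatches(lines[i], regexec("^#\\s*([a-z_]+)\\s*=\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3L) {
      abort(sprintf("%s: malformed header at line %d: %s", path, i, lines[i]))
    }
    meta[[m[2]]] <- trimws(m[3])
  }
  if (is.null(meta$fs)) abort(sprintf("%s: missing `# fs=` header.", path))
  fs <- suppressWarnings(as.numeric(meta$fs))
  if (is.na(fs)) abort(sprintf("%s: non-numeric fs header.", path))
  body <- lines[-hdr_idx]
  if (length(body) < 2L) abort(sprintf("%s: no samples.", path))
  cols <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (cols[1] != "uV") abort(sprintf("%s: expected `uV` column, got `%s`.",
                                     path, cols[1]))
  data_lines <- body[-1]
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != length(cols))) {
    bad <- which(nfield != length(cols))[1]
    abort(sprintf("%s: wrong field count at data line %d.", path, bad))
  }
  uV <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  if (anyNA(uV) || any(!is.finite(uV))) {
    bad <- which(is.na(uV) | !is.finite(uV))[1]
    abort(sprintf("%s: non-finite or non-numeric sample at data line %d.",
                  path, bad))
  }
  ps <- NULL
  if ("poor_signal" %in% cols) {
    ps <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
    if (anyNA(ps)) abort(sprintf("%s: non-numeric poor_signal value.", path))
  }
  eeg_recording(uV, fs = fs,
                channel = meta$channel %||% "fp1",
                phase = meta$phase %||% "before",
                subject = meta$subject %||% "S01",
                poor_signal = ps)
}

# ---- Minimal single-channel EDF ------------------------------------------
# Classic EDF: 256-byte fixed header + 256 bytes per signal, then data
# records of 16-bit little-endian integers. One data record per second, so
# fs must be a whole number of samples per second.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_physical_range <- function(uV) {
  m <- max(1, ceiling(max(abs(uV))))
  c(-m, m)
}

#' EDF amplitude quantization step
#'
#' The voltage resolution of a 16-bit EDF file with the given physical range:
#' `(phys_max - phys_min) / (digital max - digital min)` with digital range
#' -32768..32767.
#'
#' @param phys_min,phys_max Physical (microvolt) range stored in the header.
#' @return Step size in microvolts.
#' @export
edf_quantization_step <- function(phys_min, phys_max) {
  (phys_max - phys_min) / (32767 - (-32768))
}

write_recording_edf <- function(rec, path) {
  fs <- eeg_fs(rec)
  if (fs != round(fs)) abort("EDF export requires an integer sampling rate.")
  uV <- rec$uV
  n_rec <- ceiling(length(uV) / fs)
  pr <- edf_physical_range(uV)
  step <- edf_quantization_step(pr[1], pr[2])
  # pad the last record with zeros; the true sample count is in the header
  padded <- c(uV, rep(0, n_rec * fs - length(uV)))
  dig <- as.integer(round((padded - pr[1]) / step) - 32768)
  dig <- pmin(pmax(dig, -32768L), 32767L)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(sprintf("subject=%s n=%d", eeg_subject(rec), length(uV)), 80),
    pad_field(sprintf("phase=%s", eeg_phase(rec)), 80),
    pad_field("01.01.20", 8), pad_field("00.00.00", 8),
    pad_field(256 + 256, 8),      # header bytes
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),              # record duration, seconds
    pad_field(1, 4))              # number of signals
  sig <- paste0(
    pad_field(eeg_channel(rec), 16),
    pad_field("EEG", 80),
    pad_field("uV", 8),
    pad_field(pr[1], 8), pad_field(pr[2], 8),
    pad_field(-32768, 8), pad_field(32767, 8),
    pad_field("", 80),
    pad_field(fs, 8),
    pad_field("", 32))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  writeBin(dig, con, size = 2L, endian = "little")
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  patient <- trimws(substr(hdr, 9, 88))
  recording_id <- trimws(substr(hdr, 89, 168))
  n_rec <- as.integer(trimws(substr(hdr, 237, 244)))
  n_sig <- as.integer(trimws(substr(hdr, 253, 256)))
  if (is.na(n_sig) || n_sig != 1L) {
    abort(sprintf("%s: expected a single-channel EDF file.", path))
  }
  sig <- readChar(con, 256, useBytes = TRUE)
  label <- trimws(substr(sig, 1, 16))
  phys_min <- as.numeric(trimws(substr(sig, 105, 112)))
  phys_max <- as.numeric(trimws(substr(sig, 113, 120)))
  fs <- as.integer(trimws(substr(sig, 217, 224)))
  dig <- readBin(con, "integer", n = n_rec * fs, size = 2L, signed = TRUE,
                 endian = "little")
  step <- edf_quantization_step(phys_min, phys_max)
  uV <- (dig + 32768) * step + phys_min
  subject <- sub("^subject=(\\S+).*$", "\\1", patient)
  n_true <- suppressWarnings(as.integer(sub("^.*n=(\\d+).*$", "\\1", patient)))
  if (!is.na(n_true) && n_true <= length(uV)) uV <- uV[seq_len(n_true)]
  phase <- sub("^phase=", "", recording_id)
  if (!phase %in% PHASES) phase <- "before"
  eeg_recording(uV, fs = fs, channel = label, phase = phase, subject = subject)
}

#' First stabilized sample of a poor-signal quality series
#'
#' Consumer EEG front-ends report a 0–255 "poor signal" quality flag; the
#' signal is considered stabilized once the flag falls to 51 or below. This
#' returns the first (0-based) index at which that happens.
#'
#' @param poor_signal Integer vector of quality flags in 0–255 (per sample or
#'   per packet; the index is on whatever grid the series uses).
#' @param threshold Stabilization threshold in 0–255 (default 51).
#' @return The 0-based index of the first value `<= threshold`, or `NA` if
#'   the series never stabilizes.
#' @examples
#' stabilization_index(c(200, 80, 51, 0)) # 2
#' @export
stabilization_index <- function(poor_signal, threshold = 51) {
  if (length(poor_signal) == 0L) abort("`poor_signal` must be non-empty.")
  check_poor_signal(poor_signal)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 255) {
    abort("`threshold` must be a single value in [0, 255].")
  }
  i <- which(poor_signal <= threshold)
  if (length(i) == 0L) return(NA_integer_)
  i[1] - 1L
}

#' Drop the unstabilized head of a recording
#'
#' Removes all samples before the stabilization index of the recording's
#' poor-signal series. Recordings without a poor-signal column are returned
#' unchanged.
#'
#' @inheritParams write_recording
#' @param threshold Stabilization threshold passed to [stabilization_index()].
#' @return An [eeg_recording()] starting at the first stabilized sample.
#' @export
trim_unstabilized <- function(rec, threshold = 51) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!"poor_signal" %in% names(rec)) return(rec)
  idx <- stabilization_index(rec$poor_signal, threshold)
  if (is.na(idx)) abort(sprintf(
    "recording %s/%s never stabilizes (poor_signal > %d throughout).",
    eeg_subject(rec), eeg_phase(rec), threshold))
  if (idx == 0L) return(rec)
  out <- rec[-seq_len(idx), , drop = FALSE]
  out$t <- out$t - out$t[1]
  new_eeg_recording(out, fs = eeg_fs(rec), channel = eeg_channel(rec),
                    phase = eeg_phase(rec), subject = eeg_subject(rec))
}
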