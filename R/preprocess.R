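#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero-phase), so event-related waveforms keep their latencies. The
#' default 0.5–60 Hz passband spans the five canonical rhythm bands.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @return A filtered copy of `rec` (same length, same metadata).
#' @export
eeg_bandpass <- function(rec, low = 0.5, high = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- eeg_fs(rec)
  if (!(low > 0 && low < high && high < fs / 2)) {
    abort(sprintf("band edges must satisfy 0 < low < high < fs/2 = %g.", fs / 2))
  }
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  set_samples(rec, signal::filtfilt(bf, rec$uV))
}

#' Zero-phase notch filter for mains interference
#'
#' Narrow band-stop (2nd-order Butterworth, forward-backward) centered on
#' the power-line frequency. Default 60 Hz; use `line_freq = 50` for 50 Hz
#' mains.
#'
#' @inheritParams eeg_bandpass
#' @param line_freq Line frequency in Hz (`0 < line_freq < fs/2`).
#' @param q Quality factor; the stop band is
#'   `line_freq * (1 +/- 1/(2q))` (default 30, i.e. a 2 Hz-wide notch at
#'   60 Hz).
#' @return A filtered copy of `rec`.
#' @export
eeg_notch <- function(rec, line_freq = 60, q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- eeg_fs(rec)
  if (!(line_freq > 0 && line_freq < fs / 2)) {
    abort(sprintf("`line_freq` must lie in (0, fs/2 = %g).", fs / 2))
  }
  edges <- line_freq * c(1 - 1 / (2 * q), 1 + 1 / (2 * q))
  bf <- signal::butter(2, edges / (fs / 2), type = "stop")
  set_samples(rec, signal::filtfilt(bf, rec$uV))
}

#' Cut a recording into fixed-length epochs
#'
#' Slides a window of `window_s` seconds across the recording with the
#' given fractional overlap and returns every complete window; a trailing
#' partial window is dropped. With window length `w = window_s * fs` samples
#' and step `w * (1 - overlap)`, the number of epochs is
#' `floor((N - w) / step) + 1`.
#'
#' @inheritParams eeg_bandpass
#' @param window_s Epoch length in seconds; `window_s * fs` must be >= 2.
#' @param overlap Fractional overlap between consecutive epochs, in `[0, 1)`.
#' @return A tibble with one row per epoch: `subject`, `phase`, `epoch`
#'   (1-based counter), `start` (0-based sample index into the parent
#'   recording) and `samples` (list-column of equal-length numeric vectors).
#'   A window longer than the recording yields zero rows with a warning.
#' @examples
#' rec <- generate_recording(rest_profile(), 10, fs = 512, seed = 1)
#' nrow(epoch_signal(rec, window_s = 4, overlap = 0.5)) # 4
#' @export
epoch_signal <- function(rec, window_s = 4, overlap = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- eeg_fs(rec)
  w <- round(window_s * fs)
  if (w < 2) abort("`window_s * fs` must be at least 2 samples.")
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1).")
  n <- nrow(rec)
  empty <- tibble(subject = character(), phase = character(),
                  epoch = integer(), start = integer(), samples = list())
  if (w > n) {
    warn(sprintf("window (%d samples) longer than recording (%d); no epochs.",
                 w, n))
    return(empty)
  }
  step <- max(1L, round(w * (1 - overlap)))
  starts <- seq(0L, n - w, by = step)
  tibble(
    subject = eeg_subject(rec),
    phase = eeg_phase(rec),
    epoch = seq_along(starts),
    start = as.integer(starts),
    samples = purrr::map(starts, function(s) rec$uV[(s + 1):(s + w)])
  )
}

#' Reject epochs containing large-amplitude artifacts
#'
#' Blinks and muscle activity produce voltage excursions far beyond
#' neural EEG. Epochs whose peak absolute amplitude exceeds the threshold
#' are dropped.
#'
#' @param epochs An epoch tibble from [epoch_signal()].
#' @param reject_uV Peak-to-baseline rejection threshold in microvolts
#'   (default 100).
#' @return The epoch tibble with offending rows removed.
#' @export
reject_artifacts <- function(epochs, reject_uV = 100) {
  if (nrow(epochs) == 0L) return(epochs)
  keep <- purrr::map_lgl(epochs$samples, function(x) max(abs(x)) <= reject_uV)
  epochs[keep, , drop = FALSE]
}

#' Epoch every recording of a cohort
#'
#' Convenience wrapper: band-pass filters (optional), trims unstabilized
#' samples (optional), then epochs each recording of a cohort tibble and
#' binds the results.
#'
#' @param cohort Cohort tibble from [generate_cohort()] (columns `subject`,
#'   `phase`, `recording`).
#' @param window_s,overlap Passed to [epoch_signal()].
#' @param bandpass Either `NULL` (no filtering) or a length-2 numeric of
#'   band edges in Hz (default `c(0.5, 60)`).
#' @param trim If `TRUE` (default), drop samples before the poor-signal
#'   stabilization index of each recording.
#' @param reject_uV Artifact-rejection threshold, or `NULL` to keep all
#'   epochs.
#' @return A combined epoch tibble.
#' @export
epoch_cohort <- function(cohort, window_s = 4, overlap = 0,
                         bandpass = c(0.5, 60), trim = TRUE,
                         reject_uV = NULL) {
  stopifnot(all(c("subject", "phase", "recording") %in% names(cohort)))
  out <- purrr::map(cohort$recording, function(rec) {
    if (trim) rec <- trim_unstabilized(rec)
    if (!is.null(bandpass)) rec <- eeg_bandpass(rec, bandpass[1], bandpass[2])
    epoch_signal(rec, window_s = window_s, overlap = overlap)
  })
  out <- dplyr::bind_rows(out)
  if (!is.null(reject_uV)) out <- reject_artifacts(out, reject_uV)
  out
}
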