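#' Single-channel EEG recording
#'
#' An `eeg_recording` is a tibble with one row per sample and columns:
#'
#' * `t` — time in seconds from the start of the recording (sample index / fs;
#'   0-based sample indexing, so the first sample is at `t = 0`),
#' * `uV` — voltage in microvolts,
#' * `poor_signal` — optional per-sample signal-quality flag in 0–255 as
#'   reported by consumer EEG front-ends (values at or below 51 indicate a
#'   stabilized, usable signal).
#'
#' Acquisition metadata travel as attributes: `fs` (sampling rate, Hz),
#' `channel` (electrode label, 10–20 system), `phase` (one of `"before"`,
#' `"during"`, `"after"` relative to the therapy session) and `subject`.
#' Use the accessors [eeg_fs()], [eeg_channel()], [eeg_phase()],
#' [eeg_subject()] rather than `attr()`.
#'
#' @param uV Numeric vector of voltages in microvolts. Must be non-empty and
#'   finite.
#' @param fs Sampling rate in Hz (default 512, the rate of single-channel
#'   consumer EEG modules).
#' @param channel Electrode label (default `"fp1"`, the first frontopolar
#'   electrode of the 10–20 placement system).
#' @param phase Phase label: `"before"`, `"during"` or `"after"`.
#' @param subject Subject identifier string.
#' @param poor_signal Optional integer vector of per-sample quality flags in
#'   0–255, recycled if of length 1.
#'
#' @return A tibble of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(sin(2 * pi * 10 * (0:511) / 512), fs = 512,
#'                      phase = "before", subject = "S01")
#' eeg_fs(rec)
#' eeg_duration(rec)
#' @export
eeg_recording <- function(uV, fs = 512, channel = "fp1", phase = "before",
                          subject = "S01", poor_signal = NULL) {
  if (length(uV) == 0L) abort("`uV` must contain at least one sample.")
  if (!is.numeric(uV) || !all(is.finite(uV))) {
    abort("`uV` must be numeric and finite everywhere.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  phase <- match.arg(phase, PHASES)
  if (!is.null(poor_signal)) {
    if (length(poor_signal) == 1L) poor_signal <- rep(poor_signal, length(uV))
    if (length(poor_signal) != length(uV)) {
      abort("`poor_signal` must have length 1 or length(uV).")
    }
    check_poor_signal(poor_signal)
  }
  out <- tibble(t = (seq_along(uV) - 1) / fs, uV = as.numeric(uV))
  if (!is.null(poor_signal)) out$poor_signal <- as.integer(poor_signal)
  new_eeg_recording(out, fs = fs, channel = channel, phase = phase,
                    subject = subject)
}

new_eeg_recording <- function(df, fs, channel, phase, subject) {
  structure(df,
            class = c("eeg_recording", class(tibble())),
            fs = fs, channel = channel, phase = phase, subject = subject)
}

check_poor_signal <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 255)) {
    abort("poor-signal values must lie in [0, 255].")
  }
  invisible(x)
}

#' Accessors for recording metadata
#'
#' @param rec An [eeg_recording()].
#' @return `eeg_fs()` the sampling rate in Hz; `eeg_channel()` the electrode
#'   label; `eeg_phase()` the phase label; `eeg_subject()` the subject id;
#'   `eeg_duration()` the duration in seconds (`nrow / fs`).
#' @export
eeg_fs <- function(rec) attr(rec, "fs")

#' @rdname eeg_fs
#' @export
eeg_channel <- function(rec) attr(rec, "channel")

#' @rdname eeg_fs
#' @export
eeg_phase <- function(rec) attr(rec, "phase")

#' @rdname eeg_fs
#' @export
eeg_subject <- function(rec) attr(rec, "subject")

#' @rdname eeg_fs
#' @export
eeg_duration <- function(rec) nrow(rec) / eeg_fs(rec)

# Replace the sample column, keeping metadata. Used by filters.
set_samples <- function(rec, uV) {
  stopifnot(length(uV) == nrow(rec))
  rec$uV <- as.numeric(uV)
  rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s | %s | phase=%s | fs=%g Hz | %.4g s\n",
              eeg_subject(x), eeg_channel(x), eeg_phase(x), eeg_fs(x),
              eeg_duration(x)))
  NextMethod()
}
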