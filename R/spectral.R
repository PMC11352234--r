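#' Welch power spectral density
#'
#' Estimates the one-sided power spectral density of a recording by Welch's
#' method: the signal is split into overlapping segments, each segment is
#' windowed and Fourier transformed, and the squared magnitudes are
#' averaged. Averaging over segments trades frequency resolution for a much
#' lower-variance, more interpretable spectrum than a single periodogram.
#'
#' The estimate is density-scaled (microvolts squared per Hz): the integral
#' of the PSD over frequency approximates the signal's mean square power
#' (Parseval), up to window bias.
#'
#' @param rec An [eeg_recording()], or a numeric vector (then `fs` must be
#'   given).
#' @param segment_s Segment length in seconds (default 2 s, giving 0.5 Hz
#'   resolution).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param window Taper name: `"hann"` (default) or `"rect"`.
#' @param fs Sampling rate in Hz, only needed when `rec` is a bare vector.
#' @return A tibble of class `eeg_psd` with columns `freq` (Hz, strictly
#'   increasing, 0..fs/2) and `power` (µV²/Hz, non-negative), and the
#'   estimation parameters as attributes.
#' @examples
#' rec <- generate_recording(rest_profile(), 30, fs = 512, seed = 1)
#' psd <- welch_psd(rec)
#' @export
welch_psd <- function(rec, segment_s = 2, overlap = 0.5, window = "hann",
                      fs = NULL) {
  if (inherits(rec, "eeg_recording")) {
    x <- rec$uV
    fs <- eeg_fs(rec)
  } else {
    x <- as.numeric(rec)
    if (is.null(fs)) abort("`fs` must be supplied for a bare numeric vector.")
  }
  nseg <- round(segment_s * fs)
  if (nseg < 2) abort("`segment_s * fs` must be at least 2 samples.")
  if (nseg > length(x)) {
    abort(sprintf(
      "recording (%d samples) is shorter than one segment (%d); use a smaller `segment_s`.",
      length(x), nseg))
  }
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1).")
  w <- switch(match.arg(window, c("hann", "rect")),
              hann = 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)),
              rect = rep(1, nseg))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  U <- sum(w^2)                     # window power normalization
  nfreq <- nseg %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    X <- fft(seg)[seq_len(nfreq)]
    p <- (Mod(X)^2) / (fs * U)
    # one-sided: double everything except DC and (for even nseg) Nyquist
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  out <- tibble(freq = seq(0, by = fs / nseg, length.out = nfreq),
                power = acc / length(starts))
  structure(out, class = c("eeg_psd", class(tibble())),
            fs = fs, window = window, segment_s = segment_s,
            overlap = overlap, n_segments = length(starts))
}

# trapezoid integral of (freq, power) over [lo, hi], interpolating the
# band edges so adjacent bands tile the broadband range exactly
band_integral <- function(freq, power, lo, hi) {
  inside <- freq > lo & freq < hi
  f <- freq[inside]
  p <- power[inside]
  if (lo >= min(freq) && lo <= max(freq)) {
    f <- c(lo, f)
    p <- c(approx(freq, power, xout = lo)$y, p)
  }
  if (hi >= min(freq) && hi <= max(freq)) {
    f <- c(f, hi)
    p <- c(p, approx(freq, power, xout = hi)$y)
  }
  if (length(f) < 2) return(0)
  pracma::trapz(f, p)
}

#' Band decomposition of a power spectrum
#'
#' Integrates a Welch PSD over the five canonical rhythm bands
#' ([eeg_bands()]) by the trapezoid rule, inserting interpolated points at
#' the band edges so that the five absolute powers sum exactly to the
#' broadband (0.5–60 Hz) power. Relative power is each band's share of
#' broadband power, so relative powers always sum to 1.
#'
#' @param psd An `eeg_psd` from [welch_psd()]; its frequency grid must reach
#'   60 Hz.
#' @return A tibble of class `band_powers` with columns `band`, `low`,
#'   `high`, `absolute` (µV²) and `relative` (unitless, sums to 1), with
#'   the broadband power as attribute `broadband`.
#' @examples
#' rec <- generate_recording(band_profile(alpha = 5), 30, seed = 1)
#' band_powers(welch_psd(rec))
#' @export
band_powers <- function(psd) {
  stopifnot(inherits(psd, "eeg_psd"))
  if (max(psd$freq) < BROADBAND[2]) {
    abort(sprintf("PSD only reaches %g Hz; band decomposition needs %g Hz.",
                  max(psd$freq), BROADBAND[2]))
  }
  bands <- eeg_bands()
  absolute <- purrr::map2_dbl(bands$low, bands$high,
                              ~ band_integral(psd$freq, psd$power, .x, .y))
  broadband <- sum(absolute)
  relative <- if (broadband > 0) absolute / broadband else rep(0, length(absolute))
  out <- dplyr::mutate(bands, absolute = absolute, relative = relative)
  structure(out, class = c("band_powers", class(tibble())),
            broadband = broadband)
}

#' Minimum alias-free sampling rate
#'
#' The Nyquist criterion: a signal whose highest frequency component is
#' `fmax` must be sampled at `fs >= 2 * fmax` to avoid aliasing. EEG carries
#' no neural activity above 60 Hz, so 120 samples/s would suffice, though
#' consumer modules commonly sample at 512.
#'
#' @param fmax Highest signal frequency in Hz (>= 0).
#' @return `2 * fmax` in Hz.
#' @examples
#' nyquist_min_fs(60) # 120
#' @export
nyquist_min_fs <- function(fmax) {
  if (!is.numeric(fmax) || any(fmax < 0)) abort("`fmax` must be >= 0.")
  2 * fmax
}
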