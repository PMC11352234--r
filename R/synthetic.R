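#' Spectral profile of a synthetic EEG state
#'
#' Describes the band structure of a brain state to be synthesized: one
#' root-mean-square amplitude per canonical rhythm band, a 1/f background
#' exponent, and a broadband white-noise floor. [generate_recording()] turns
#' a profile into a voltage time series.
#'
#' @param delta,theta,alpha,beta,gamma RMS amplitude (microvolts) of each
#'   band-limited component (delta 0.5–4 Hz, theta 4–8 Hz, alpha 8–12 Hz,
#'   beta 12–30 Hz, gamma 30–60 Hz). All must be `>= 0`.
#' @param background_exponent Exponent of the 1/f^a background process
#'   (unitless; 0 = white, 1 = pink). The background inherits its scale from
#'   `noise_sd`.
#' @param noise_sd Standard deviation (microvolts) of the background process
#'   before spectral shaping; 0 disables the background entirely.
#' @param mode `"noise"` synthesizes each band as Gaussian white noise
#'   band-pass filtered to its range (the default; matches the broadband
#'   character of real rhythms). `"sine"` uses a pure sinusoid at the band's
#'   midpoint frequency with RMS equal to the band amplitude, for analytic
#'   tests.
#' @return A `band_profile` object (named list).
#' @examples
#' rest <- band_profile(alpha = 6, beta = 2)
#' @export
band_profile <- function(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0,
                         background_exponent = 1, noise_sd = 0,
                         mode = c("noise", "sine")) {
  amps <- c(delta = delta, theta = theta, alpha = alpha, beta = beta,
            gamma = gamma)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    abort("band amplitudes must be finite and >= 0.")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(list(amplitudes = amps,
                 background_exponent = background_exponent,
                 noise_sd = noise_sd,
                 mode = match.arg(mode)),
            class = "band_profile")
}

#' Default rest and therapy profiles
#'
#' Placeholder brain-state profiles for synthetic cohorts. Rest shows the
#' prominent alpha rhythm of a relaxed eyes-closed state; the therapy state
#' shifts power toward beta/gamma and suppresses alpha, a generic arousal /
#' engagement signature. No quantitative description of how the therapy
#' alters band powers exists, so these are documented defaults, not claims.
#'
#' @return A `band_profile`.
#' @export
rest_profile <- function() {
  band_profile(delta = 4, theta = 3, alpha = 6, beta = 2, gamma = 1,
               background_exponent = 1, noise_sd = 2)
}

#' @rdname rest_profile
#' @export
therapy_profile <- function() {
  band_profile(delta = 4, theta = 3, alpha = 3, beta = 5, gamma = 3,
               background_exponent = 1, noise_sd = 2)
}

#' Synthetic-cohort specification
#'
#' Describes a cohort of subjects each recorded in three phases around a
#' therapy session: a rest recording before, the session itself, and a rest
#' recording after. Phase durations default to the acquisition protocol the
#' pipeline assumes (60 s before, 5 min during, 60 s after, 512 samples/s).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param durations Named numeric vector of phase durations in seconds,
#'   names `before`, `during`, `after`.
#' @param fs Sampling rate in Hz; must be at least 120 (twice the 60 Hz
#'   upper band edge).
#' @param rest [band_profile()] used for the before/after phases.
#' @param therapy [band_profile()] used for the during phase; must differ
#'   from `rest` in at least one band amplitude.
#' @param seed Master seed. Subject `i`, phase index `p` (before = 1,
#'   during = 2, after = 3) uses sub-seed `seed + 1000 * i + p`, so any
#'   single recording can be regenerated in isolation.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 4,
                        durations = c(before = 60, during = 300, after = 60),
                        fs = 512,
                        rest = rest_profile(),
                        therapy = therapy_profile(),
                        seed = 1) {
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.")
  if (!all(PHASES %in% names(durations))) {
    abort("`durations` must be named before/during/after.")
  }
  if (any(durations <= 0)) abort("phase durations must be positive.")
  if (fs < 2 * 60) abort("`fs` must be at least 120 Hz (Nyquist for 60 Hz).")
  stopifnot(inherits(rest, "band_profile"), inherits(therapy, "band_profile"))
  if (all(rest$amplitudes == therapy$amplitudes)) {
    warn("rest and therapy profiles have identical band amplitudes; the cohort carries no phase signal.")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 durations = durations[PHASES], fs = fs,
                 rest = rest, therapy = therapy, seed = as.integer(seed)),
            class = "cohort_spec")
}

# spectrally shaped 1/f^a background, rescaled to sd = noise_sd
one_over_f_noise <- function(n, exponent, noise_sd) {
  if (noise_sd == 0) return(numeric(n))
  w <- rnorm(n)
  if (exponent == 0) return(w * noise_sd / stats::sd(w))
  W <- fft(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f) # two-sided frequency index
  h <- c(0, f[-1]^(-exponent / 2))
  x <- Re(fft(W * h, inverse = TRUE)) / n
  x * noise_sd / stats::sd(x)
}

band_component <- function(n, fs, low, high, amplitude, mode) {
  if (amplitude == 0) return(numeric(n))
  if (mode == "sine") {
    fc <- (low + high) / 2
    phase <- runif(1, 0, 2 * pi)
    return(sqrt(2) * amplitude * sin(2 * pi * fc * (0:(n - 1)) / fs + phase))
  }
  w <- rnorm(n)
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, w)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * amplitude / s
}

#' Generate one synthetic EEG recording
#'
#' Synthesizes a single-channel recording as the sum of five band-limited
#' rhythm components (band-passed Gaussian noise or pure sinusoids, per the
#' profile's `mode`), a 1/f^a background, and an optional artifact spike
#' train. A poor-signal quality series is attached: a high flag value for an
#' initial settling window, then 0, emulating sensor stabilization.
#'
#' @param profile A [band_profile()].
#' @param duration_s Recording length in seconds (> 0).
#' @param fs Sampling rate in Hz (>= 120).
#' @param phase Phase label for the recording.
#' @param seed Integer seed; the sample array is bit-reproducible given the
#'   seed.
#' @param subject Subject identifier.
#' @param settle_s Length (s) of the initial unstabilized window flagged
#'   with `settle_flag` in the poor-signal series (default 0.5 s at flag
#'   200; 0 disables).
#' @param settle_flag Poor-signal value during the settling window.
#' @param n_artifacts Number of spike artifacts (default 0); each is a
#'   single-sample excursion of `artifact_uV` microvolts at a random
#'   position.
#' @param artifact_uV Artifact spike amplitude.
#' @return An [eeg_recording()] with `duration_s * fs` samples.
#' @examples
#' rec <- generate_recording(rest_profile(), duration_s = 2, fs = 512,
#'                           phase = "before", seed = 7)
#' nrow(rec) # 1024
#' @export
generate_recording <- function(profile, duration_s, fs = 512,
                               phase = "before", seed = 1, subject = "S01",
                               settle_s = 0.5, settle_flag = 200,
                               n_artifacts = 0, artifact_uV = 150) {
  stopifnot(inherits(profile, "band_profile"))
  if (!is.finite(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be positive.")
  }
  if (!is.finite(fs) || fs < 120) abort("`fs` must be at least 120 Hz.")
  n <- round(duration_s * fs)
  bands <- eeg_bands()
  uV <- withr::with_seed(seed, {
    x <- one_over_f_noise(n, profile$background_exponent, profile$noise_sd)
    for (b in seq_len(nrow(bands))) {
      x <- x + band_component(n, fs, bands$low[b], bands$high[b],
                              profile$amplitudes[[b]], profile$mode)
    }
    if (n_artifacts > 0) {
      at <- sample.int(n, n_artifacts)
      x[at] <- x[at] + artifact_uV * sample(c(-1, 1), n_artifacts, TRUE)
    }
    x
  })
  n_settle <- min(n, round(settle_s * fs))
  ps <- c(rep(settle_flag, n_settle), rep(0L, n - n_settle))
  eeg_recording(uV, fs = fs, phase = phase, subject = subject,
                poor_signal = ps)
}

#' Generate a synthetic cohort
#'
#' Produces `3 * n_subjects` recordings: before/after phases from the rest
#' profile, the during phase from the therapy profile. Each recording uses
#' the reproducible sub-seed described in [cohort_spec()].
#'
#' @param spec A [cohort_spec()].
#' @param ... Further arguments passed to [generate_recording()] (settling
#'   window, artifacts).
#' @return A tibble with columns `subject`, `phase` and a `recording`
#'   list-column of [eeg_recording()] objects, one row per subject x phase.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 1,
#'   durations = c(before = 2, during = 2, after = 2)))
#' nrow(cohort) # 3
#' @export
generate_cohort <- function(spec, ...) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- tidyr::expand_grid(
    i = seq_len(spec$n_subjects),
    p = seq_along(PHASES)
  )
  rows <- purrr::pmap(grid, function(i, p) {
    phase <- PHASES[p]
    prof <- if (phase == "during") spec$therapy else spec$rest
    rec <- generate_recording(
      prof, duration_s = spec$durations[[phase]], fs = spec$fs,
      phase = phase, seed = spec$seed + 1000L * i + p,
      subject = sprintf("S%02d", i), ...)
    tibble(subject = sprintf("S%02d", i), phase = phase,
           recording = list(rec))
  })
  out <- dplyr::bind_rows(rows)
  out$phase <- factor(out$phase, levels = PHASES)
  out
}
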