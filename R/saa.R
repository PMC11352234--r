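#' Event-related potential: average across epochs
#'
#' Pointwise arithmetic mean of a set of equal-length epochs, the classical
#' estimate of the neural response time-locked to an event.
#'
#' @param epochs An epoch tibble from [epoch_signal()] (list-column
#'   `samples`), or a plain list of equal-length numeric vectors.
#' @return A numeric waveform (microvolts) of the common epoch length.
#' @examples
#' erp_average(list(c(1, 2, 3), c(3, 2, 1))) # c(2, 2, 2)
#' @export
erp_average <- function(epochs) {
  xs <- if (is.data.frame(epochs)) epochs$samples else epochs
  if (length(xs) == 0L) abort("need at least one epoch.")
  lens <- lengths(xs)
  if (length(unique(lens)) != 1L) {
    abort("all epochs must have the same length.")
  }
  Reduce(`+`, xs) / length(xs)
}

#' Self-affine fluctuation analysis
#'
#' Characterizes the scale-dependence of a signal's fluctuations: the
#' signal is integrated into a cumulative profile, the profile is split
#' into non-overlapping windows of length `s` for a log-spaced set of
#' scales, each window is linearly detrended, and the root-mean-square
#' residual `F(s)` is recorded. For a self-affine process `F(s) ~ s^H` so
#' the curve is a straight line in log-log coordinates; uncorrelated noise
#' gives slope (Hurst exponent) 1/2. The curve's least-squares line is
#' stored as its reference for crossover detection.
#'
#' @param signal Numeric vector (microvolts), length at least 16 (four
#'   times the smallest scale).
#' @param n_scales Number of log-spaced scales between 4 samples and a
#'   quarter of the signal length (default 32; duplicates after rounding
#'   are collapsed).
#' @return A tibble of class `saa_curve` with columns `scale` (samples),
#'   `log_scale`, `fluct` and `log_fluct` (base-10 logs), plus attributes
#'   `slope`, `intercept` (the least-squares reference line) and
#'   `degenerate` (`TRUE` for a constant input, whose fluctuations are all
#'   zero and whose log-curve is undefined).
#' @examples
#' curve <- saa_curve(rnorm(4096))
#' attr(curve, "slope") # ~ 0.5
#' @export
saa_curve <- function(signal, n_scales = 32) {
  x <- as.numeric(signal)
  n <- length(x)
  if (n < 16) abort("`signal` must have at least 16 samples.")
  scales <- unique(round(10^seq(log10(4), log10(n / 4), length.out = n_scales)))
  y <- cumsum(x - mean(x))
  fluct <- vapply(scales, function(s) {
    nw <- n %/% s
    idx <- seq_len(nw * s)
    win <- matrix(y[idx], nrow = s)       # one column per window
    tt <- seq_len(s)
    # closed-form linear detrend per window
    tc <- tt - mean(tt)
    denom <- sum(tc^2)
    slope <- colSums(win * tc) / denom
    resid <- win - matrix(colMeans(win), nrow = s, ncol = nw, byrow = TRUE) -
      outer(tc, slope)
    sqrt(mean(resid^2))
  }, numeric(1))
  degenerate <- all(fluct == 0)
  out <- tibble(scale = scales,
                log_scale = log10(scales),
                fluct = fluct,
                log_fluct = ifelse(fluct > 0, log10(fluct), -Inf))
  if (degenerate || any(fluct == 0)) {
    slope <- NA_real_; intercept <- NA_real_
    degenerate <- TRUE
  } else {
    fit <- stats::lm.fit(cbind(1, out$log_scale), out$log_fluct)
    intercept <- fit$coefficients[1]
    slope <- fit$coefficients[2]
  }
  structure(out, class = c("saa_curve", class(tibble())),
            slope = unname(slope), intercept = unname(intercept),
            degenerate = degenerate)
}

#' Crossover of a fluctuation curve against its reference line
#'
#' A crossover is a point where the log-log fluctuation curve crosses its
#' reference line — a change of scaling regime in a fractal process. The
#' residual (curve minus reference) is scanned for sign changes;
#' `"first_crossing"` returns the 0-based index of the first point after a
#' sign change, `"crossing_count"` the total number of sign changes. Zero
#' residuals carry the preceding sign.
#'
#' @param curve An `saa_curve` from [saa_curve()]; must not be degenerate.
#' @param mode `"first_crossing"` (default) or `"crossing_count"`.
#' @param reference `"fitted"` (default) measures crossings against the
#'   curve's least-squares line; `"zero"` against the zero line of the
#'   log-fluctuation axis.
#' @return A non-negative integer (0-based index or count). When the curve
#'   never crosses the reference, 0 is returned with attribute
#'   `no_crossing = TRUE`.
#' @examples
#' curve <- saa_curve(rnorm(4096))
#' detect_crossover(curve, mode = "crossing_count")
#' @export
detect_crossover <- function(curve,
                             mode = c("first_crossing", "crossing_count"),
                             reference = c("fitted", "zero")) {
  stopifnot(inherits(curve, "saa_curve"))
  mode <- match.arg(mode)
  reference <- match.arg(reference)
  if (isTRUE(attr(curve, "degenerate"))) {
    abort("cannot detect crossovers on a degenerate (constant-signal) curve.")
  }
  resid <- switch(reference,
    fitted = curve$log_fluct -
      (attr(curve, "intercept") + attr(curve, "slope") * curve$log_scale),
    zero = curve$log_fluct)
  crossover_from_residuals(resid, mode)
}

# shared by detect_crossover and its direct-residual tests
crossover_from_residuals <- function(resid, mode) {
  s <- sign(resid)
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  changes <- which(s[-1] * s[-length(s)] < 0)
  if (mode == "crossing_count") return(length(changes))
  if (length(changes) == 0L) {
    return(structure(0L, no_crossing = TRUE))
  }
  as.integer(changes[1]) # 0-based index of the first point past the change
}

#' Crossover-similarity statistics
#'
#' Summarize how far the during-therapy fluctuation regime departs from the
#' resting regimes, using the per-phase crossover values `C_B` (before),
#' `C_D` (during) and `C_A` (after):
#'
#' * `similarity_before_after()` — `S_BA = |C_A - C_B|`, the absolute
#'   distance between the two resting curves. Small values mean the brain
#'   returns to its pre-session regime.
#' * `similarity_during()` — `S_DR = (|C_A - C_D| + |C_D - C_B|) / 2`, the
#'   mean absolute distance from the during-therapy crossover to both
#'   resting crossovers. Large values mean the session drove the signal far
#'   from rest.
#'
#' Both are vectorized.
#'
#' @param C_B,C_D,C_A Non-negative crossover values per phase.
#' @return A non-negative numeric vector.
#' @examples
#' similarity_before_after(210, 203) # 7
#' similarity_during(210, 193, 203)  # 13.5
#' @export
similarity_before_after <- function(C_B, C_A) {
  check_crossovers(C_B, C_A)
  abs(C_A - C_B)
}

#' @rdname similarity_before_after
#' @export
similarity_during <- function(C_B, C_D, C_A) {
  check_crossovers(C_B, C_D, C_A)
  (abs(C_A - C_D) + abs(C_D - C_B)) / 2
}

check_crossovers <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("crossover values must be finite and non-negative.")
  }
  invisible(vals)
}

#' Crossover-similarity table
#'
#' Data-frame-first wrapper around [similarity_before_after()] and
#' [similarity_during()]: takes a table with per-phase crossover columns
#' and appends the two similarity statistics.
#'
#' @param data A data frame with columns `before`, `during`, `after`
#'   (crossover values); any other columns (patient, day, ...) pass
#'   through.
#' @return `data` as a tibble with columns `S_BA` and `S_DR` appended.
#' @examples
#' crossover_similarity(data.frame(before = 11, during = 107, after = 17))
#' @export
crossover_similarity <- function(data) {
  stopifnot(all(c("before", "during", "after") %in% names(data)))
  dplyr::mutate(as_tibble(data),
                S_BA = similarity_before_after(.data$before, .data$after),
                S_DR = similarity_during(.data$before, .data$during,
                                         .data$after))
}

#' Per-subject crossover analysis of a cohort
#'
#' For each subject: epoch and average each phase's recording into an
#' event-related waveform, run the self-affine analysis, detect the
#' per-phase crossover, and compute `S_BA` and `S_DR`.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param window_s Epoch length used for the event-related average.
#' @param n_scales,mode,reference Passed to [saa_curve()] /
#'   [detect_crossover()].
#' @return A tibble with one row per subject: `before`, `during`, `after`
#'   crossovers plus `S_BA` and `S_DR`.
#' @export
crossover_analysis <- function(cohort, window_s = 4, n_scales = 32,
                               mode = "first_crossing",
                               reference = "fitted") {
  per_phase <- dplyr::group_by(cohort, .data$subject, .data$phase)
  per_phase <- dplyr::summarise(per_phase, crossover = {
    rec <- .data$recording[[1]]
    rec <- trim_unstabilized(rec)
    erp <- erp_average(epoch_signal(rec, window_s = window_s))
    as.integer(detect_crossover(saa_curve(erp, n_scales = n_scales),
                                mode = mode, reference = reference))
  }, .groups = "drop")
  wide <- tidyr::pivot_wider(per_phase, names_from = "phase",
                             values_from = "crossover")
  crossover_similarity(wide)
}
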