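#' Tidiers and plots for fitted objects
#'
#' Broom-style accessors: `tidy()` returns the per-epoch training log of a
#' fit (or the rows of a report), `glance()` a one-row summary.
#' `autoplot()` methods give quick ggplot2 views of recordings, spectra,
#' fluctuation curves, training logs and biomarker reports.
#'
#' @param x A fitted/summary object from this package.
#' @param ... Unused.
#' @name datbio-tidiers
NULL

#' @rdname datbio-tidiers
#' @export
tidy.siamese_fit <- function(x, ...) x$log

#' @rdname datbio-tidiers
#' @export
glance.siamese_fit <- function(x, ...) {
  n_par <- sum(vapply(x$params$layers,
                      function(l) length(l$W) + length(l$b), numeric(1))) +
    length(x$params$proj$W) + length(x$params$proj$b)
  tibble(mode = x$mode, epochs = nrow(x$log),
         final_loss = x$log$loss[nrow(x$log)],
         n_embed = x$config$n_embed, n_parameters = n_par,
         normalized = x$config$normalize)
}

#' @rdname datbio-tidiers
#' @export
glance.saa_curve <- function(x, ...) {
  tibble(slope = attr(x, "slope"), intercept = attr(x, "intercept"),
         n_scales = nrow(x), degenerate = attr(x, "degenerate"))
}

#' @rdname datbio-tidiers
#' @export
glance.band_powers <- function(x, ...) {
  tibble(broadband = attr(x, "broadband"),
         dominant_band = as.character(x$band[which.max(x$relative)]))
}

#' @rdname datbio-tidiers
#' @param object Object to plot.
#' @export
autoplot.eeg_recording <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$t, .data$uV)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "voltage (µV)",
                  title = sprintf("%s / %s", eeg_subject(object),
                                  eeg_phase(object)))
}

#' @rdname datbio-tidiers
#' @export
autoplot.eeg_psd <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$freq, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "PSD (µV²/Hz)")
}

#' @rdname datbio-tidiers
#' @export
autoplot.band_powers <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$band, .data$relative)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative band power")
}

#' @rdname datbio-tidiers
#' @export
autoplot.saa_curve <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$log_scale, .data$log_fluct)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log10 scale (samples)", y = "log10 fluctuation")
  if (!isTRUE(attr(object, "degenerate"))) {
    p <- p + ggplot2::geom_abline(slope = attr(object, "slope"),
                                  intercept = attr(object, "intercept"),
                                  linetype = 2)
  }
  p
}

#' @rdname datbio-tidiers
#' @export
autoplot.siamese_fit <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean batch loss")
}

#' @rdname datbio-tidiers
#' @export
autoplot.qb_report <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$pair_type, .data$mean_QB)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mean QB (dB)")
}
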