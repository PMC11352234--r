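#' Canonical EEG frequency bands
#'
#' The five brain-rhythm bands used throughout the package, plus the
#' broadband range they tile:
#' delta 0.5–4 Hz, theta 4–8 Hz, alpha 8–12 Hz, beta 12–30 Hz,
#' gamma 30–60 Hz; broadband 0.5–60 Hz.
#'
#' Adjacent bands share printed endpoints; integration treats each band as
#' half-open `[low, high)` except gamma, which is closed at 60 Hz, so the
#' five bands partition the broadband range exactly.
#'
#' @return A tibble with columns `band` (factor in canonical order), `low`
#'   and `high` (Hz).
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function() {
  tibble(
    band = factor(c("delta", "theta", "alpha", "beta", "gamma"),
                  levels = c("delta", "theta", "alpha", "beta", "gamma")),
    low  = c(0.5, 4, 8, 12, 30),
    high = c(4, 8, 12, 30, 60)
  )
}

BROADBAND <- c(0.5, 60)
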