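#' Similarity index from an embedding distance
#'
#' Maps the Euclidean distance between two unit-normalized embeddings
#' (range `[0, 2]`) onto a unitless similarity `S` in `(0, 1]`, with 1 for
#' identical embeddings: `S = 1 - D/2`, clamped below at `1e-6` so the
#' decibel biomarker stays finite (antipodal embeddings cap the biomarker
#' at 60 dB).
#'
#' @param distance Non-negative embedding distance(s); values above 2
#'   violate the unit-normalization contract and raise an error.
#' @return Similarity value(s) in `(0, 1]`, monotone decreasing in
#'   distance.
#' @examples
#' similarity_index(c(0, 1, 2)) # 1, 0.5, 1e-6
#' @export
similarity_index <- function(distance) {
  if (any(distance < 0)) abort("`distance` must be >= 0.")
  if (any(distance > 2 + 1e-9)) {
    abort("distance > 2: embeddings are not unit-normalized (contract violation).")
  }
  pmin(pmax(1 - distance / 2, 1e-6), 1)
}

#' Therapy-efficacy biomarker in decibels
#'
#' The quantitative biomarker `QB = 10 * log10(1 / S)` dB, computed from
#' the similarity `S` between resting-state and during-therapy embeddings.
#' `QB = 0` dB means the brain state during therapy is indistinguishable
#' from rest; the more the session drives neural activity away from the
#' resting regime, the smaller `S` and the larger `QB` (10 dB at
#' `S = 0.1`, unbounded as `S` tends to 0).
#'
#' @param S Similarity value(s) in `(0, 1]` (see [similarity_index()]).
#' @return Biomarker value(s) in dB, `>= 0`.
#' @examples
#' qb_dat(c(1, 0.5, 0.1)) # 0, 3.0103, 10
#' @export
qb_dat <- function(S) {
  if (any(S <= 0 | S > 1)) abort("`S` must lie in (0, 1].")
  -10 * log10(S)
}

#' Cohort-level biomarker report
#'
#' Aggregates per-pair similarities by comparison type. Two aggregates are
#' always reported, because they answer different questions and differ
#' whenever similarities vary (Jensen's inequality): the mean of the
#' per-pair decibel values (`mean_QB`, the headline number) and the
#' decibel value of the mean similarity (`QB_of_mean_S`).
#'
#' @param pairs A tibble with a similarity column `S` in `(0, 1]` and a
#'   grouping column `pair_type` (e.g. `"rest_vs_rest"`,
#'   `"rest_vs_DAT"`). Extra columns pass through [tidy()]-style.
#' @param expected Character vector of group labels that ought to be
#'   present; missing ones trigger a warning and are omitted.
#' @return A tibble of class `qb_report`, one row per pair type:
#'   `pair_type`, `n`, `mean_S`, `mean_QB` (dB), `QB_of_mean_S` (dB).
#' @examples
#' cohort_report(tibble::tibble(pair_type = c("rest_vs_rest", "rest_vs_DAT"),
#'                              S = c(0.9, 0.2)))
#' @export
cohort_report <- function(pairs,
                          expected = c("rest_vs_rest", "rest_vs_DAT")) {
  stopifnot(is.data.frame(pairs), all(c("pair_type", "S") %in% names(pairs)))
  if (nrow(pairs) == 0L) abort("`pairs` must be non-empty.")
  missing <- setdiff(expected, unique(pairs$pair_type))
  if (length(missing) > 0L) {
    warn(sprintf("no pairs of type: %s (omitted from report).",
                 paste(missing, collapse = ", ")))
  }
  out <- dplyr::summarise(
    dplyr::group_by(pairs, .data$pair_type),
    n = dplyr::n(),
    mean_S = mean(.data$S),
    mean_QB = mean(qb_dat(.data$S)),
    QB_of_mean_S = qb_dat(mean(.data$S)),
    .groups = "drop")
  structure(out, class = c("qb_report", class(tibble())))
}
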