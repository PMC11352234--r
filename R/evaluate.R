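#' Decimate epoch samples to a lower rate
#'
#' Downsamples each epoch by an integer factor with an anti-aliasing
#' low-pass filter. EEG content is band-limited to 60 Hz, so decimating a
#' 512 Hz recording by 4 (to 128 Hz, still above the 120 Hz Nyquist
#' minimum) loses no band content while shrinking the encoder input
#' four-fold.
#'
#' @param epochs An epoch tibble from [epoch_signal()] / [epoch_cohort()].
#' @param factor Integer decimation factor (default 4).
#' @return The epoch tibble with shortened `samples`.
#' @export
decimate_epochs <- function(epochs, factor = 4) {
  stopifnot(is.data.frame(epochs), "samples" %in% names(epochs))
  factor <- as.integer(factor)
  if (factor < 1L) abort("`factor` must be a positive integer.")
  if (factor == 1L) return(epochs)
  epochs$samples <- purrr::map(epochs$samples,
                               ~ as.numeric(signal::decimate(.x, factor)))
  epochs
}

# rest = before/after; during = therapy session
phase_to_class <- function(phase) {
  ifelse(as.character(phase) == "during", "during", "rest")
}

#' Prepare cohort epochs for metric learning
#'
#' Epochs, filters and decimates a cohort's recordings and attaches the
#' binary training label (`"rest"` for before/after phases, `"during"`
#' for the therapy phase).
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param window_s,overlap,bandpass,trim Passed to [epoch_cohort()].
#' @param decimate Integer decimation factor applied to the epochs
#'   (default 4; see [decimate_epochs()]).
#' @return An epoch tibble with an added `label` column.
#' @export
prepare_training_epochs <- function(cohort, window_s = 4, overlap = 0,
                                    bandpass = c(0.5, 60), trim = TRUE,
                                    decimate = 4) {
  ep <- epoch_cohort(cohort, window_s = window_s, overlap = overlap,
                     bandpass = bandpass, trim = trim)
  ep <- decimate_epochs(ep, decimate)
  ep$label <- phase_to_class(ep$phase)
  ep
}

#' Score rest-vs-rest and rest-vs-therapy recording pairs
#'
#' Embeds every epoch with the trained encoder, averages the epoch
#' embeddings of each recording into one per-recording embedding
#' (re-normalized when the encoder is normalizing), then scores all
#' unordered pairs of resting recordings (`rest_vs_rest`) and all
#' rest-during pairs (`rest_vs_DAT`) with the embedding distance, the
#' similarity index and the decibel biomarker.
#'
#' @param fit A `siamese_fit`.
#' @param epochs A labeled epoch tibble from [prepare_training_epochs()]
#'   (typically for held-out subjects).
#' @return A tibble with one row per pair: `pair_type`, `subject_a`,
#'   `phase_a`, `subject_b`, `phase_b`, `distance`, `S`, `QB_dB`.
#' @export
score_pairs <- function(fit, epochs) {
  emb <- encode(fit, epochs)
  per_rec <- dplyr::group_by(emb, .data$subject, .data$phase)
  per_rec <- dplyr::summarise(per_rec, embedding = {
    m <- colMeans(do.call(rbind, .data$embedding))
    if (fit$config$normalize) m <- m / sqrt(sum(m^2))
    list(m)
  }, .groups = "drop")
  per_rec$class <- phase_to_class(per_rec$phase)
  idx <- seq_len(nrow(per_rec))
  combos <- utils::combn(idx, 2)
  rows <- purrr::map(seq_len(ncol(combos)), function(k) {
    i <- combos[1, k]; j <- combos[2, k]
    ci <- per_rec$class[i]; cj <- per_rec$class[j]
    type <- if (ci == "rest" && cj == "rest") {
      "rest_vs_rest"
    } else if (xor(ci == "during", cj == "during")) {
      "rest_vs_DAT"
    } else {
      return(NULL) # during-vs-during pairs are not part of the biomarker
    }
    d <- retrieval_distance(per_rec$embedding[[i]], per_rec$embedding[[j]])
    tibble(pair_type = type,
           subject_a = per_rec$subject[i], phase_a = as.character(per_rec$phase[i]),
           subject_b = per_rec$subject[j], phase_b = as.character(per_rec$phase[j]),
           distance = d)
  })
  out <- dplyr::bind_rows(rows)
  out$S <- similarity_index(out$distance)
  out$QB_dB <- qb_dat(out$S)
  out
}

#' Permutation test for rest/therapy separation
#'
#' Tests whether rest-vs-rest pairs are more similar than rest-vs-therapy
#' pairs. The statistic is `mean S(rest_vs_rest) - mean S(rest_vs_DAT)`;
#' pair-type labels are permuted uniformly and the one-sided p-value is
#' `(1 + #{permuted >= observed}) / (n_perm + 1)`.
#'
#' @param pairs Pair table from [score_pairs()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation draw.
#' @return A list: `statistic` (observed mean-similarity gap), `p_value`,
#'   `n_perm`.
#' @export
permutation_test_separation <- function(pairs, n_perm = 1000, seed = 1) {
  stopifnot(all(c("pair_type", "S") %in% names(pairs)))
  types <- pairs$pair_type
  if (length(unique(types)) < 2L) {
    abort("need both pair types for a permutation test.")
  }
  stat <- function(tp) {
    mean(pairs$S[tp == "rest_vs_rest"]) - mean(pairs$S[tp == "rest_vs_DAT"])
  }
  obs <- stat(types)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat(sample(types)), numeric(1))
  })
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}
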