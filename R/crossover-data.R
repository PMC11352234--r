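#' Worked crossover examples
#'
#' Bundled table of per-phase crossover values from two therapy courses of
#' three sessions each, used as worked examples for the crossover
#' similarity statistics: applying [crossover_similarity()] to these
#' triples reproduces the published `S_BA` / `S_DR` values exactly.
#'
#' @return A tibble with columns `patient`, `day`, `before`, `during`,
#'   `after`.
#' @examples
#' crossover_similarity(crossover_examples())
#' @export
crossover_examples <- function() {
  path <- system.file("extdata", "crossover_examples.tsv", package = "datbio",
                      mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t")
  as_tibble(df)
}
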