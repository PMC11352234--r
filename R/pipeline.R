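#' Default pipeline configuration
#'
#' The full two-stage design — simulate (or load) a cohort, preprocess,
#' summarize spectra and self-affine crossovers, train the triplet encoder
#' on a subset of subjects, then score the held-out subjects and report
#' the decibel biomarker — is driven by a single nested configuration
#' list. Unknown keys are rejected at validation time.
#'
#' @param ... Named overrides, nested lists merged over the defaults
#'   (e.g. `cohort = list(n_subjects = 2)`).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    cohort = list(n_subjects = 4L,
                  durations = list(before = 60, during = 300, after = 60),
                  fs = 512),
    preprocess = list(filter = list(low = 0.5, high = 60),
                      notch = list(freq = NULL),
                      epoch = list(window_s = 4, overlap = 0),
                      artifact = list(reject_uV = 100)),
    spectral = list(segment_s = 2, overlap = 0.5),
    saa = list(n_scales = 32, mode = "first_crossing", reference = "fitted"),
    train = list(mode = "triplet", epochs = 30, lr = 1e-3, batch_size = 32,
                 alpha = 0.5, margin = 1, n_embed = 64, decimate = 4,
                 holdout_subjects = NULL),
    score = list(n_perm = 1000))
  overrides <- list(...)
  check_keys <- function(ov, def, path = "") {
    bad <- setdiff(names(ov), names(def))
    if (length(bad) > 0L) {
      abort(sprintf("unknown config key%s: %s",
                    if (length(bad) > 1) "s" else "",
                    paste0(path, bad, collapse = ", ")))
    }
    for (nm in names(ov)) {
      if (is.list(def[[nm]]) && is.list(ov[[nm]]) &&
          !is.null(names(def[[nm]]))) {
        check_keys(ov[[nm]], def[[nm]], paste0(path, nm, "."))
      }
    }
  }
  check_keys(overrides, defaults)
  cfg <- modifyList(defaults, overrides)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the end-to-end biomarker pipeline
#'
#' Executes, in order: cohort simulation, preprocessing and epoching,
#' per-recording spectral band summaries, per-subject self-affine
#' crossover analysis, encoder training on the training subjects, and
#' biomarker scoring on the held-out subjects. All tabular outputs are
#' written as TSV under `out_dir` together with a JSON summary and a
#' manifest (config, seed, package version, config hash); a rerun with
#' the same config writes byte-identical tables. Any stage failure aborts
#' with the stage name; partial outputs are moved under `failed/`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the cohort, the spectral and crossover
#'   summary tibbles, the fitted encoder, the pair table, the
#'   [cohort_report()] and the permutation-test result, plus `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failed <- file.path(out_dir, "failed")
      dir.create(failed, showWarnings = FALSE)
      done <- list.files(out_dir, pattern = "\\.(tsv|json)$",
                         full.names = TRUE)
      file.rename(done, file.path(failed, basename(done)))
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }

  cohort <- stage("simulate", {
    spec <- cohort_spec(
      n_subjects = config$cohort$n_subjects,
      durations = unlist(config$cohort$durations)[PHASES],
      fs = config$cohort$fs,
      seed = config$seed)
    generate_cohort(spec)
  })

  epochs <- stage("preprocess", {
    ep <- prepare_training_epochs(
      cohort,
      window_s = config$preprocess$epoch$window_s,
      overlap = config$preprocess$epoch$overlap,
      bandpass = c(config$preprocess$filter$low,
                   config$preprocess$filter$high),
      decimate = config$train$decimate)
    reject_artifacts(ep, config$preprocess$artifact$reject_uV)
  })

  spectra <- stage("spectral", {
    rows <- purrr::pmap(cohort, function(subject, phase, recording) {
      bp <- band_powers(welch_psd(recording,
                                  segment_s = config$spectral$segment_s,
                                  overlap = config$spectral$overlap))
      dplyr::mutate(as_tibble(bp), subject = subject,
                    phase = as.character(phase), .before = 1)
    })
    out <- dplyr::bind_rows(rows)
    write_tsv(out, file.path(out_dir, "band_powers.tsv"))
    out
  })

  crossovers <- stage("saa", {
    out <- crossover_analysis(cohort,
                              window_s = config$preprocess$epoch$window_s,
                              n_scales = config$saa$n_scales,
                              mode = config$saa$mode,
                              reference = config$saa$reference)
    write_tsv(out, file.path(out_dir, "crossovers.tsv"))
    out
  })

  subjects <- unique(epochs$subject)
  holdout <- config$train$holdout_subjects %||%
    tail(subjects, max(1L, length(subjects) %/% 2))
  fit <- stage("train", {
    train_ep <- epochs[!epochs$subject %in% holdout, , drop = FALSE]
    if (length(unique(train_ep$label)) < 2L) {
      abort("training cohort has a single class; cannot form negatives.")
    }
    cfg <- train_config(margin = config$train$margin,
                        alpha = config$train$alpha,
                        n_embed = config$train$n_embed,
                        epochs = config$train$epochs,
                        lr = config$train$lr,
                        batch_size = config$train$batch_size,
                        seed = config$seed + 101L)
    f <- fit_siamese(train_ep, mode = config$train$mode, config = cfg)
    write_tsv(f$log, file.path(out_dir, "training_log.tsv"))
    f
  })

  scored <- stage("score", {
    eval_ep <- epochs[epochs$subject %in% holdout, , drop = FALSE]
    pairs <- score_pairs(fit, eval_ep)
    report <- cohort_report(pairs)
    perm <- permutation_test_separation(pairs,
                                        n_perm = config$score$n_perm,
                                        seed = config$seed + 202L)
    write_tsv(pairs, file.path(out_dir, "report.tsv"))
    jsonlite::write_json(
      list(report = report,
           separation = perm[c("statistic", "p_value", "n_perm")],
           holdout_subjects = holdout),
      file.path(out_dir, "summary.json"),
      digits = NA, auto_unbox = TRUE, pretty = TRUE)
    list(pairs = pairs, report = report, permutation = perm)
  })

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  jsonlite::write_json(
    list(seed = config$seed,
         config_md5 = unname(tools::md5sum(cfg_path)),
         package_version = as.character(utils::packageVersion("datbio"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, epochs = epochs, spectra = spectra,
                 crossovers = crossovers, fit = fit, pairs = scored$pairs,
                 report = scored$report, permutation = scored$permutation,
                 out_dir = out_dir))
}

#' Write a miniature test corpus
#'
#' Generates a 2-subject cohort with 10 s phases (CSV recordings in the
#' package's dialect) and copies the bundled crossover-example table, for
#' use as regression fixtures. Regenerating with the same seed reproduces
#' identical files.
#'
#' @param seed Master seed.
#' @param out Output directory.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(seed, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort_spec(n_subjects = 2,
                      durations = c(before = 10, during = 10, after = 10),
                      seed = seed)
  cohort <- generate_cohort(spec)
  paths <- purrr::pmap_chr(cohort, function(subject, phase, recording) {
    p <- file.path(out, sprintf("%s_%s.csv", subject, phase))
    write_recording(recording, p)
    p
  })
  xo <- file.path(out, "crossover_examples.tsv")
  file.copy(system.file("extdata", "crossover_examples.tsv",
                        package = "datbio", mustWork = TRUE),
            xo, overwrite = TRUE)
  invisible(c(paths, xo))
}
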