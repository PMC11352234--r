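test_that("an all-zero profile synthesizes an all-zero signal", {
  rec <- generate_recording(band_profile(), duration_s = 2, fs = 512, seed = 1)
  expect_equal(nrow(rec), 1024)
  expect_true(all(rec$uV == 0))
})

test_that("a dominant alpha amplitude dominates relative band power", {
  rec <- generate_recording(
    band_profile(delta = 0.5, theta = 0.5, alpha = 10, beta = 0.5,
                 gamma = 0.5, noise_sd = 0.5),
    duration_s = 20, fs = 512, seed = 2)
  bp <- band_powers(welch_psd(rec))
  expect_identical(as.character(bp$band[which.max(bp$relative)]), "alpha")
})

test_that("generation is bit-deterministic given the seed", {
  a <- generate_recording(rest_profile(), 3, seed = 9)
  b <- generate_recording(rest_profile(), 3, seed = 9)
  expect_identical(a$uV, b$uV)
  c <- generate_recording(rest_profile(), 3, seed = 10)
  expect_false(identical(a$uV, c$uV))
})

test_that("invalid generation parameters are rejected", {
  expect_error(generate_recording(rest_profile(), 0), "positive")
  expect_error(generate_recording(rest_profile(), 1, fs = 100), "120")
  expect_error(band_profile(alpha = -1), ">= 0")
  expect_error(band_profile(noise_sd = -1), ">= 0")
})

test_that("a cohort has one recording per subject and phase", {
  cohort <- generate_cohort(cohort_spec(
    n_subjects = 4, durations = c(before = 2, during = 2, after = 2)))
  expect_equal(nrow(cohort), 12)
  counts <- table(cohort$subject, cohort$phase)
  expect_true(all(counts == 1))
  durs <- vapply(cohort$recording, eeg_duration, numeric(1))
  expect_true(all(durs == 2))
})

test_that("1-subject cohort with 2 s phases gives 3 recordings of 1024 samples", {
  cohort <- generate_cohort(cohort_spec(
    n_subjects = 1, durations = c(before = 2, during = 2, after = 2),
    fs = 512))
  expect_equal(nrow(cohort), 3)
  expect_true(all(vapply(cohort$recording, nrow, numeric(1)) == 1024))
})

test_that("cohorts are reproducible and sub-seeds reproduce single recordings", {
  spec <- cohort_spec(n_subjects = 2,
                      durations = c(before = 2, during = 2, after = 2),
                      seed = 77)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  for (k in seq_len(nrow(c1))) {
    expect_identical(c1$recording[[k]]$uV, c2$recording[[k]]$uV)
  }
  # subject 2, during phase (phase index 2) in isolation
  solo <- generate_recording(therapy_profile(), 2, fs = 512,
                             phase = "during", seed = 77 + 1000 * 2 + 2,
                             subject = "S02")
  k <- which(c1$subject == "S02" & c1$phase == "during")
  expect_identical(solo$uV, c1$recording[[k]]$uV)
})

test_that("a single nonzero band concentrates >= 90% of broadband power", {
  for (b in c("delta", "theta", "alpha", "beta", "gamma")) {
    args <- stats::setNames(list(5), b)
    prof <- do.call(band_profile, args)
    rec <- generate_recording(prof, 30, fs = 512, seed = 4)
    bp <- band_powers(welch_psd(rec))
    expect_gte(bp$relative[as.character(bp$band) == b], 0.9)
  }
})

test_that("quality flags settle after the configured window", {
  rec <- generate_recording(rest_profile(), 2, fs = 512, seed = 1,
                            settle_s = 0.5, settle_flag = 200)
  expect_equal(stabilization_index(rec$poor_signal), 256L)
  rec0 <- generate_recording(rest_profile(), 2, fs = 512, seed = 1,
                             settle_s = 0)
  expect_equal(stabilization_index(rec0$poor_signal), 0L)
})

test_that("artifact spikes are injected on demand", {
  clean <- generate_recording(rest_profile(), 4, seed = 3)
  spiky <- generate_recording(rest_profile(), 4, seed = 3, n_artifacts = 3,
                              artifact_uV = 500)
  expect_gte(max(abs(spiky$uV)), 400)
  expect_gt(sum(abs(spiky$uV - clean$uV) > 100), 0)
})

test_that("identical rest/therapy profiles yield no rest-vs-DAT separation", {
  prof <- band_profile(alpha = 4, beta = 2, noise_sd = 1)
  cohort <- suppressWarnings(generate_cohort(cohort_spec(
    n_subjects = 2, durations = c(before = 12, during = 12, after = 12),
    rest = prof, therapy = prof, seed = 21)))
  ep <- prepare_training_epochs(cohort)
  fit <- fit_siamese(ep, "triplet", tiny_train_config(seed = 6))
  pairs <- score_pairs(fit, ep)
  perm <- permutation_test_separation(pairs, n_perm = 500, seed = 3)
  expect_gt(perm$p_value, 0.05)
  expect_lt(abs(perm$statistic), 0.2)
})
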