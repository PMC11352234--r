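# steady-state portion of a filtered signal (filtfilt edge transients trimmed)
steady <- function(x) {
  n <- length(x)
  x[round(n * 0.25):round(n * 0.75)]
}

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  inband <- sine_recording(10, duration_s = 8)
  out <- eeg_bandpass(inband)
  expect_lt(abs(rms(steady(out$uV)) / rms(steady(inband$uV)) - 1), 0.01)

  hf <- sine_recording(100, duration_s = 8)
  out_hf <- eeg_bandpass(hf)
  expect_lt(rms(out_hf$uV) / rms(hf$uV), 0.05)

  zero <- eeg_recording(rep(0, 2048))
  expect_true(all(eeg_bandpass(zero)$uV == 0))
})

test_that("band-pass validates its edges", {
  rec <- sine_recording(10)
  expect_error(eeg_bandpass(rec, low = 0, high = 60), "band edges")
  expect_error(eeg_bandpass(rec, low = 30, high = 10), "band edges")
  expect_error(eeg_bandpass(rec, low = 1, high = 300), "band edges")
})

test_that("notch removes the line frequency and spares the pass band", {
  mains <- sine_recording(60, duration_s = 8)
  out <- eeg_notch(mains)
  expect_lt(rms(steady(out$uV)) / rms(steady(mains$uV)), 0.10)

  neural <- sine_recording(10, duration_s = 8)
  out_n <- eeg_notch(neural)
  expect_lt(abs(rms(steady(out_n$uV)) / rms(steady(neural$uV)) - 1), 0.01)

  zero <- eeg_recording(rep(0, 2048))
  expect_true(all(eeg_notch(zero)$uV == 0))
})

test_that("filters are linear within float tolerance", {
  withr::with_seed(3, {
    x <- eeg_recording(rnorm(2048))
    y <- eeg_recording(rnorm(2048))
    combo <- eeg_recording(2 * x$uV - 3 * y$uV)
    lhs <- eeg_bandpass(combo)$uV
    rhs <- 2 * eeg_bandpass(x)$uV - 3 * eeg_bandpass(y)$uV
    # the narrow low edge (0.5/256 normalized) makes the filter recursion
    # ill-conditioned, so roundoff accumulates beyond machine precision
    expect_equal(lhs, rhs, tolerance = 1e-5)
  })
})

test_that("epoch counts follow floor((N - w)/step) + 1", {
  rec60 <- generate_recording(rest_profile(), 60, fs = 512, seed = 1)
  expect_equal(nrow(epoch_signal(rec60, 4, 0)), 15)
  rec10 <- generate_recording(rest_profile(), 10, fs = 512, seed = 1)
  expect_equal(nrow(epoch_signal(rec10, 4, 0.5)), 4)
  expect_warning(ep <- epoch_signal(rec60, 70, 0), "longer than recording")
  expect_equal(nrow(ep), 0)
})

test_that("non-overlapping epochs reconstruct the recording prefix", {
  rec <- generate_recording(rest_profile(), 10, fs = 512, seed = 2)
  ep <- epoch_signal(rec, 3, 0)
  rebuilt <- unlist(ep$samples)
  expect_identical(rebuilt, rec$uV[seq_along(rebuilt)])
  expect_equal(ep$start, (seq_len(nrow(ep)) - 1L) * 3L * 512L)
})

test_that("epoching validates window and overlap", {
  rec <- generate_recording(rest_profile(), 4, seed = 1)
  expect_error(epoch_signal(rec, overlap = 1), "overlap")
  expect_error(epoch_signal(rec, window_s = 1e-3), "at least 2 samples")
})

test_that("amplitude-threshold rejection drops artifact epochs", {
  rec <- generate_recording(band_profile(alpha = 3, noise_sd = 1), 12,
                            seed = 5, n_artifacts = 2, artifact_uV = 400)
  ep <- epoch_signal(rec, 4, 0)
  kept <- reject_artifacts(ep, reject_uV = 100)
  expect_lt(nrow(kept), nrow(ep))
  expect_true(all(purrr::map_dbl(kept$samples, ~ max(abs(.x))) <= 100))
})
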