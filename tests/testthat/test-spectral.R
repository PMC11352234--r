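make_psd <- function(freq, power, fs = 512) {
  structure(tibble::tibble(freq = freq, power = power),
            class = c("eeg_psd", class(tibble::tibble())),
            fs = fs, window = "hann", segment_s = 2, overlap = 0.5,
            n_segments = 1)
}

test_that("the PSD of a zero signal is identically zero", {
  psd <- welch_psd(eeg_recording(rep(0, 4096), fs = 512))
  expect_true(all(psd$power == 0))
})

test_that("white-noise PSD integrates to the signal variance (Parseval)", {
  withr::with_seed(8, {
    x <- rnorm(60 * 512)
    x <- x / sd(x) # unit variance
    psd <- welch_psd(x, fs = 512)
    total <- pracma::trapz(psd$freq, psd$power)
    expect_lt(abs(total - 1), 0.1)
  })
})

test_that("a 2 uV sine at 10 Hz carries ~A^2/2 = 2 uV^2 near 10 Hz", {
  rec <- sine_recording(10, amp = 2, duration_s = 30)
  psd <- welch_psd(rec)
  near <- psd$freq >= 8 & psd$freq <= 12
  expect_equal(pracma::trapz(psd$freq[near], psd$power[near]), 2,
               tolerance = 0.05)
})

test_that("welch_psd rejects a recording shorter than one segment", {
  expect_error(welch_psd(eeg_recording(rnorm(100), fs = 512)),
               "smaller `segment_s`")
})

test_that("PSD frequencies are increasing and powers non-negative", {
  withr::with_seed(12, {
    for (i in 1:10) {
      x <- rnorm(2048) * 10^runif(1, -2, 2) + runif(1, -5, 5)
      psd <- welch_psd(x, fs = 256)
      expect_true(all(diff(psd$freq) > 0))
      expect_true(all(psd$power >= 0))
      expect_lte(max(psd$freq), 128)
    }
  })
})

test_that("PSD scales quadratically with amplitude", {
  withr::with_seed(13, {
    x <- rnorm(4096)
    p1 <- welch_psd(x, fs = 512)
    p3 <- welch_psd(3 * x, fs = 512)
    expect_equal(p3$power, 9 * p1$power, tolerance = 1e-10)
  })
})

test_that("a PSD concentrated in 8-12 Hz is pure alpha", {
  freq <- seq(0, 256, by = 0.5)
  power <- ifelse(freq > 8 & freq < 12, 1, 0)
  bp <- band_powers(make_psd(freq, power))
  expect_equal(bp$relative[bp$band == "alpha"], 1)
  expect_equal(sum(bp$relative), 1, tolerance = 1e-12)
})

test_that("a flat PSD splits power proportionally to bandwidths", {
  freq <- seq(0, 256, by = 0.25)
  bp <- band_powers(make_psd(freq, rep(1, length(freq))))
  expect_equal(bp$relative,
               c(3.5, 4, 4, 18, 30) / 59.5, tolerance = 1e-9)
  expect_equal(attr(bp, "broadband"), 59.5, tolerance = 1e-9)
})

test_that("relative band powers always sum to 1 and broadband bounds each band", {
  withr::with_seed(14, {
    for (i in 1:10) {
      bp <- band_powers(welch_psd(rnorm(4096) * exp(rnorm(1)), fs = 512))
      expect_equal(sum(bp$relative), 1, tolerance = 1e-9)
      expect_true(all(attr(bp, "broadband") >= bp$absolute - 1e-12))
    }
  })
})

test_that("band decomposition needs coverage up to 60 Hz", {
  freq <- seq(0, 50, by = 0.5)
  expect_error(band_powers(make_psd(freq, rep(1, length(freq)), fs = 100)),
               "60")
})

test_that("the Nyquist minimum rate is twice the maximum frequency", {
  expect_equal(nyquist_min_fs(60), 120)
  expect_equal(nyquist_min_fs(0), 0)
  expect_equal(nyquist_min_fs(256), 512)
  expect_error(nyquist_min_fs(-1), ">= 0")
})
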