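test_that("the event-related average is the pointwise mean", {
  ep <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(erp_average(ep), c(1, 2, 3))
  s <- rnorm(10)
  expect_equal(erp_average(list(s, -s)), rep(0, 10))
  withr::with_seed(5, {
    eps <- replicate(7, rnorm(50), simplify = FALSE)
    brute <- vapply(1:50, function(i) {
      acc <- 0
      for (e in eps) acc <- acc + e[i]
      acc / length(eps)
    }, numeric(1))
    expect_equal(erp_average(eps), brute)
  })
  expect_error(erp_average(list(1:3, 1:4)), "same length")
  expect_error(erp_average(list()), "at least one")
})

test_that("white noise has fluctuation slope ~ 0.5", {
  withr::with_seed(17, {
    curve <- saa_curve(rnorm(8192))
    expect_lt(abs(attr(curve, "slope") - 0.5), 0.1)
    expect_false(attr(curve, "degenerate"))
  })
})

test_that("a constant signal yields a flagged degenerate curve, not a crash", {
  curve <- saa_curve(rep(3.2, 1024))
  expect_true(attr(curve, "degenerate"))
  expect_true(all(curve$fluct == 0))
  expect_error(detect_crossover(curve), "degenerate")
})

test_that("scaling the signal shifts the curve without changing its slope", {
  withr::with_seed(18, {
    x <- rnorm(4096)
    c1 <- saa_curve(x)
    c2 <- saa_curve(2 * x)
    expect_equal(attr(c2, "slope"), attr(c1, "slope"), tolerance = 1e-10)
    expect_equal(c2$log_fluct - c1$log_fluct,
                 rep(log10(2), nrow(c1)), tolerance = 1e-10)
  })
})

test_that("saa_curve rejects too-short inputs", {
  expect_error(saa_curve(rnorm(8)), "at least 16")
})

test_that("crossover detection follows the sign-change definition", {
  cfr <- datbio:::crossover_from_residuals
  expect_identical(cfr(c(1, 0.5, -0.2, -1), "first_crossing"), 2L)
  res <- cfr(c(1, 2, 3, 0.5), "first_crossing")
  expect_identical(as.integer(res), 0L)
  expect_true(attr(res, "no_crossing"))
  alternating <- c(1, -1, 1, -1, 1, -1, 1)
  expect_identical(cfr(alternating, "crossing_count"), 6L)
  # zeros carry the previous sign: no crossing through a touch
  expect_identical(cfr(c(1, 0, 1, -1), "crossing_count"), 1L)
})

test_that("detect_crossover works against fitted and zero references", {
  withr::with_seed(19, {
    curve <- saa_curve(rnorm(4096))
    n_fit <- detect_crossover(curve, mode = "crossing_count")
    expect_gte(n_fit, 1)
    first <- detect_crossover(curve, mode = "first_crossing")
    expect_gte(as.integer(first), 0)
    expect_lt(as.integer(first), nrow(curve))
    z <- detect_crossover(curve, mode = "crossing_count", reference = "zero")
    expect_gte(z, 0)
  })
})

test_that("S_BA is the absolute before/after distance", {
  expect_equal(similarity_before_after(210, 203), 7)
  expect_equal(similarity_before_after(11, 17), 6)
  expect_equal(similarity_before_after(5, 5), 0)
  expect_equal(similarity_before_after(3, 9), similarity_before_after(9, 3))
  expect_error(similarity_before_after(-1, 2), "non-negative")
})

test_that("S_DR is the mean absolute distance to the during crossover", {
  expect_equal(similarity_during(210, 193, 203), 13.5)
  expect_equal(similarity_during(11, 107, 17), 93)
  expect_equal(similarity_during(4, 4, 4), 0)
})

test_that("all six bundled crossover triples reproduce their statistics", {
  res <- crossover_similarity(crossover_examples())
  expect_equal(res$S_BA, c(7, 6, 33, 14, 14, 3))
  expect_equal(res$S_DR, c(13.5, 35, 37.5, 48, 71, 6.5))
})

test_that("S_DR >= S_BA/2 and S_DR = 0 iff all crossovers equal (small grids)", {
  grid <- expand.grid(b = 0:6, d = 0:6, a = 0:6)
  S_BA <- similarity_before_after(grid$b, grid$a)
  S_DR <- similarity_during(grid$b, grid$d, grid$a)
  expect_true(all(S_DR >= S_BA / 2))
  all_equal <- grid$b == grid$d & grid$d == grid$a
  expect_identical(S_DR == 0, all_equal)
})

test_that("cohort crossover analysis returns one row per subject", {
  res <- crossover_analysis(tiny_cohort(), window_s = 2, n_scales = 16)
  expect_equal(nrow(res), 2)
  expect_true(all(c("before", "during", "after", "S_BA", "S_DR") %in%
                    names(res)))
  expect_true(all(res$S_BA >= 0) && all(res$S_DR >= 0))
})
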