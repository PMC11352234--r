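test_that("pair_distance matches hand computations", {
  expect_equal(pair_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(pair_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_equal(pair_distance(1:4, 1:4), 0)
  expect_error(pair_distance(1:3, 1:4), "dimension")
})

test_that("pair_distance satisfies the metric axioms", {
  withr::with_seed(23, {
    for (i in 1:25) {
      n <- sample(2:16, 1)
      a <- rnorm(n); b <- rnorm(n); c <- rnorm(n)
      expect_equal(pair_distance(a, b), pair_distance(b, a))
      expect_gte(pair_distance(a, b), 0)
      expect_equal(pair_distance(a, a), 0)
      expect_lte(pair_distance(a, c),
                 pair_distance(a, b) + pair_distance(b, c) + 1e-12)
      if (any(a != b)) expect_gt(pair_distance(a, b), 0)
    }
  })
})

test_that("contrastive loss honors margins under both conventions", {
  expect_equal(contrastive_loss(0, 1), 0)         # coincident same-class pair
  expect_equal(contrastive_loss(1, 0, m = 1), 0)  # margin satisfied
  expect_equal(contrastive_loss(2, 0, m = 1), 0)
  expect_equal(contrastive_loss(0, 0, m = 1), 0.5)
  expect_equal(contrastive_loss(0.5, 1, m = 1), 0.125)
  # literal published variant: hinge on the same-class label
  expect_equal(contrastive_loss(0, 0, m = 1, as_printed = TRUE), 0)
  expect_equal(contrastive_loss(0, 1, m = 1, as_printed = TRUE), 0.5)
  expect_error(contrastive_loss(1, 2), "0 or 1")
  expect_error(contrastive_loss(1, 1, m = 0), "> 0")
  withr::with_seed(24, {
    D <- runif(50, 0, 3)
    Y <- sample(0:1, 50, replace = TRUE)
    expect_true(all(contrastive_loss(D, Y, m = 1.5) >= 0))
  })
})

test_that("triplet distances reduce to pair distances and swap symmetrically", {
  withr::with_seed(25, {
    a <- rnorm(8); p <- rnorm(8); n <- rnorm(8)
    d <- triplet_distances(a, p, n)
    expect_equal(unname(d["D_ap"]), pair_distance(a, p))
    expect_equal(unname(d["D_an"]), pair_distance(a, n))
    swapped <- triplet_distances(a, n, p)
    expect_equal(unname(swapped), unname(rev(d)))
    expect_equal(triplet_distances(a, a, a), c(D_ap = 0, D_an = 0))
  })
})

test_that("triplet loss follows the squared-distance hinge", {
  expect_equal(triplet_loss(sqrt(2), 1, alpha = 0.5), 1.5) # 2 - 1 + 0.5
  expect_equal(triplet_loss(0, 0, alpha = 0.5), 0.5)       # coincident triplet
  expect_equal(triplet_loss(c(0, 0), c(2, 3), alpha = 0.5), 0)
  expect_warning(z <- triplet_loss(numeric(0), numeric(0)), "empty")
  expect_equal(z, 0)
  expect_error(triplet_loss(1, 1, alpha = -1), "> 0")
  withr::with_seed(26, {
    expect_true(all(replicate(20, triplet_loss(runif(5, 0, 2),
                                               runif(5, 0, 2))) >= 0))
  })
})

test_that("encoder backward pass matches numerical gradients", {
  withr::with_seed(27, {
    params <- datbio:::init_encoder(20, channels = c(2, 3), kernel = 3,
                                    stride = 2, n_embed = 4)
    X <- matrix(rnorm(3 * 20), 3, 20)
    R <- matrix(rnorm(3 * 4), 3, 4)
    loss_of <- function(p) {
      sum(datbio:::encoder_forward(p, X, normalize = TRUE) * R)
    }
    fwd <- datbio:::encoder_forward(params, X, normalize = TRUE,
                                    keep_cache = TRUE)
    g <- datbio:::encoder_backward(params, fwd, R, normalize = TRUE)
    eps <- 1e-6
    check <- function(getter, setter, ganal) {
      w <- getter(params)
      idx <- sample(length(w), min(6, length(w)))
      for (k in idx) {
        pp <- params; wp <- w; wp[k] <- wp[k] + eps
        pp <- setter(pp, wp)
        pm <- params; wm <- w; wm[k] <- wm[k] - eps
        pm <- setter(pm, wm)
        gnum <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
        expect_equal(ganal[k], gnum, tolerance = 1e-4)
      }
    }
    check(function(p) p$layers[[1]]$W,
          function(p, w) { p$layers[[1]]$W[] <- w; p }, g$layers[[1]]$W)
    check(function(p) p$layers[[2]]$W,
          function(p, w) { p$layers[[2]]$W[] <- w; p }, g$layers[[2]]$W)
    check(function(p) p$proj$W,
          function(p, w) { p$proj$W[] <- w; p }, g$proj$W)
    check(function(p) p$layers[[2]]$b,
          function(p, w) { p$layers[[2]]$b <- w; p }, g$layers[[2]]$b)
  })
})

test_that("encoding is deterministic, unit-normalized and weight-shared", {
  cohort <- tiny_cohort()
  ep <- prepare_training_epochs(cohort)
  fit <- fit_siamese(ep, "triplet", tiny_train_config(epochs = 2))
  x <- ep$samples[[1]]
  e1 <- encode(fit, x)
  e2 <- encode(fit, x)
  expect_identical(e1, e2)
  expect_equal(sqrt(sum(e1^2)), 1, tolerance = 1e-6)
  # both "branches" are the same function of the same weights
  batch <- encode(fit, rbind(x, x))
  expect_equal(batch[1, ], batch[2, ])
  expect_error(encode(fit, x[-1]), "length")
})

test_that("training reduces the loss and is seed-reproducible", {
  cohort <- tiny_cohort()
  ep <- prepare_training_epochs(cohort)
  fit1 <- fit_siamese(ep, "triplet", tiny_train_config(epochs = 6))
  expect_lte(fit1$log$loss[6], fit1$log$loss[1])
  fit2 <- fit_siamese(ep, "triplet", tiny_train_config(epochs = 6))
  expect_identical(fit1$params, fit2$params)
  # contrastive mode trains too
  fitc <- fit_siamese(ep, "siamese", tiny_train_config(epochs = 6))
  expect_lte(fitc$log$loss[6], fitc$log$loss[1])
})

test_that("single-class data cannot be trained", {
  cohort <- tiny_cohort()
  ep <- prepare_training_epochs(cohort)
  rest_only <- ep[ep$label == "rest", ]
  expect_error(fit_siamese(rest_only, "triplet", tiny_train_config()),
               "two classes")
})

test_that("retrieval distance equals pair distance and is bounded for unit vectors", {
  withr::with_seed(29, {
    for (i in 1:10) {
      a <- rnorm(16); a <- a / sqrt(sum(a^2))
      b <- rnorm(16); b <- b / sqrt(sum(b^2))
      expect_identical(retrieval_distance(a, b), pair_distance(a, b))
      expect_lte(retrieval_distance(a, b), 2 + 1e-12)
    }
  })
})

test_that("rank_database sorts by distance with stable ties", {
  q <- c(1, 0)
  db <- list(far = c(0, 1), self = c(1, 0), near = c(0.9, 0.1))
  r <- rank_database(q, db)
  expect_equal(r$id[1], "self")
  expect_equal(r$distance[1], 0)
  # brute-force oracle
  brute <- sort(vapply(db, pair_distance, numeric(1), fB = q))
  expect_equal(r$distance, unname(brute))
  single <- rank_database(q, list(only = c(3, 4)))
  expect_equal(nrow(single), 1)
  expect_equal(single$id, "only")
  # ties keep insertion order
  tied <- rank_database(c(0, 0), list(a = c(1, 0), b = c(0, 1)))
  expect_equal(tied$id, c("a", "b"))
  expect_error(rank_database(q, list()), "non-empty")
})

test_that("weights survive a JSON round trip", {
  cohort <- tiny_cohort()
  ep <- prepare_training_epochs(cohort)
  fit <- fit_siamese(ep, "triplet", tiny_train_config(epochs = 2))
  p <- withr::local_tempfile(fileext = ".json")
  save_siamese(fit, p)
  back <- load_siamese(p)
  x <- ep$samples[[3]]
  expect_equal(encode(back, x), encode(fit, x), tolerance = 1e-12)
  expect_equal(back$log$loss, fit$log$loss, tolerance = 1e-12)
})
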