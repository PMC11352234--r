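#' Training configuration for the metric-learning encoder
#'
#' Hyperparameters for [fit_siamese()]. The encoder is a small
#' one-dimensional convolutional stack — `length(channels)` blocks of
#' (valid convolution, kernel width `kernel`, stride `stride`, ReLU),
#' global average pooling, and a linear projection to an `n_embed`-
#' dimensional embedding, optionally L2-normalized (default on, so all
#' embedding distances lie in `[0, 2]`).
#'
#' @param margin Contrastive margin `m > 0`: a different-class pair further
#'   apart than `m` contributes no loss.
#' @param alpha Triplet margin `alpha > 0` separating positive from
#'   negative distances.
#' @param n_embed Embedding dimension (>= 2).
#' @param channels Channel widths of the convolutional blocks.
#' @param kernel,stride Convolution kernel width and stride.
#' @param epochs Number of training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Examples (pairs or triplets) per gradient step.
#' @param steps_per_epoch Gradient steps per epoch (default: enough for
#'   roughly one pass over the training rows).
#' @param seed Seed controlling weight initialization and pair/triplet
#'   sampling.
#' @param normalize Unit-normalize embeddings (default `TRUE`).
#' @return A `train_config` list.
#' @export
train_config <- function(margin = 1, alpha = 0.5, n_embed = 64,
                         channels = c(16, 32, 64), kernel = 7, stride = 2,
                         epochs = 50, lr = 1e-3, batch_size = 32,
                         steps_per_epoch = NULL, seed = 1, normalize = TRUE) {
  if (margin <= 0) abort("`margin` must be > 0.")
  if (alpha <= 0) abort("`alpha` must be > 0.")
  if (n_embed < 2) abort("`n_embed` must be >= 2.")
  structure(list(margin = margin, alpha = alpha, n_embed = as.integer(n_embed),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 stride = as.integer(stride), epochs = as.integer(epochs),
                 lr = lr, batch_size = as.integer(batch_size),
                 steps_per_epoch = steps_per_epoch,
                 seed = as.integer(seed), normalize = isTRUE(normalize)),
            class = "train_config")
}

#' Euclidean distance between two embeddings
#'
#' The L2 distance `sqrt(sum((a - b)^2))` used throughout the retrieval
#' stage. It is a metric: symmetric, zero exactly for identical vectors,
#' and obeying the triangle inequality.
#'
#' @param fA,fB Equal-length numeric embedding vectors.
#' @return A single non-negative number.
#' @examples
#' pair_distance(c(0, 0), c(3, 4)) # 5
#' @export
pair_distance <- function(fA, fB) {
  if (length(fA) != length(fB)) {
    abort("embeddings must have the same dimension.")
  }
  sqrt(sum((fA - fB)^2))
}

#' Contrastive loss for a labeled pair
#'
#' Margin-based pair objective: same-class pairs (`Y = 1`) are penalized by
#' their squared distance, different-class pairs (`Y = 0`) by the squared
#' shortfall below the margin `m`, so the loss is zero once a same-class
#' pair coincides or a different-class pair is at least `m` apart:
#' `L = 1/2 * Y * D^2 + 1/2 * (1 - Y) * max(0, m - D)^2`.
#'
#' `as_printed = TRUE` swaps the roles of the two terms (hinge on the
#' same-class pairs), a published variant of the formula whose label
#' convention is inverted relative to its stated intent; the default
#' follows the intent.
#'
#' @param D Non-negative embedding distance(s).
#' @param Y Binary label(s): 1 = same class, 0 = different class.
#' @param m Margin, `> 0`.
#' @param as_printed Use the literal published label convention.
#' @return Non-negative loss value(s).
#' @examples
#' contrastive_loss(0, 1)          # 0: coincident positives
#' contrastive_loss(0, 0, m = 1)   # 0.5
#' @export
contrastive_loss <- function(D, Y, m = 1, as_printed = FALSE) {
  if (any(!Y %in% c(0, 1))) abort("`Y` must be 0 or 1.")
  if (m <= 0) abort("`m` must be > 0.")
  if (any(D < 0)) abort("`D` must be >= 0.")
  same <- if (as_printed) 1 - Y else Y
  0.5 * same * D^2 + 0.5 * (1 - same) * pmax(0, m - D)^2
}

#' Anchor-positive and anchor-negative distances of a triplet
#'
#' @param e_a,e_p,e_n Equal-length embeddings of the anchor, positive
#'   (same class as anchor) and negative (different class) inputs.
#' @return Named numeric vector `c(D_ap = ..., D_an = ...)` of Euclidean
#'   distances.
#' @export
triplet_distances <- function(e_a, e_p, e_n) {
  c(D_ap = pair_distance(e_a, e_p), D_an = pair_distance(e_a, e_n))
}

#' Triplet loss over a batch
#'
#' Hinge objective on squared distances: each triplet contributes
#' `max(D_ap^2 - D_an^2 + alpha, 0)`, and the batch loss is the sum. It is
#' zero exactly when every negative is at least `alpha` (in squared
#' distance) further from its anchor than the positive; a fully degenerate
#' triplet (all three embeddings coincident) contributes `alpha`.
#'
#' @param D_ap,D_an Equal-length vectors of anchor-positive and
#'   anchor-negative distances.
#' @param alpha Margin, `> 0`.
#' @return A single non-negative number; an empty batch gives 0 with a
#'   warning.
#' @examples
#' triplet_loss(sqrt(2), 1, alpha = 0.5) # 1.5
#' @export
triplet_loss <- function(D_ap, D_an, alpha = 0.5) {
  if (alpha <= 0) abort("`alpha` must be > 0.")
  if (length(D_ap) != length(D_an)) {
    abort("`D_ap` and `D_an` must have equal length.")
  }
  if (length(D_ap) == 0L) {
    warn("empty triplet batch; loss is 0.")
    return(0)
  }
  sum(pmax(D_ap^2 - D_an^2 + alpha, 0))
}

#' Train a shared-weight encoder with contrastive or triplet loss
#'
#' Learns an embedding of EEG epochs in which same-class inputs are close
#' and different-class inputs are far, by stochastic gradient descent
#' (Adam) on either the pairwise contrastive loss (`mode = "siamese"`) or
#' the triplet loss (`mode = "triplet"`, the default). Pairs/triplets are
#' sampled uniformly at random each step under the config seed, so the fit
#' is fully reproducible. Only the synaptic weights are retained — no
#' training descriptors are stored in the fitted object.
#'
#' @param data A tibble with a `samples` list-column of equal-length
#'   numeric epochs and a `label` column with at least two classes (for
#'   the therapy pipeline: `"rest"` vs `"during"`).
#' @param mode `"triplet"` or `"siamese"`.
#' @param config A [train_config()].
#' @return A `siamese_fit` object: encoder weights, config, class levels
#'   and a per-epoch training log. Supports [encode()], [tidy()] (the
#'   log) and [glance()].
#' @export
fit_siamese <- function(data, mode = c("triplet", "siamese"),
                        config = train_config()) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(data), "samples" %in% names(data),
            "label" %in% names(data))
  labels <- as.character(data$label)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    abort("training needs at least two classes to form negative pairs.")
  }
  lens <- lengths(data$samples)
  if (length(unique(lens)) != 1L) abort("all epochs must have equal length.")
  input_len <- lens[1]
  X <- do.call(rbind, data$samples)
  by_class <- split(seq_len(nrow(X)), labels)
  if (any(lengths(by_class) < 2L)) {
    abort("every class needs at least two examples.")
  }
  B <- min(config$batch_size, nrow(X))
  steps <- config$steps_per_epoch %||% max(1L, nrow(X) %/% B)

  withr::with_seed(config$seed, {
    params <- init_encoder(input_len, config$channels, config$kernel,
                           config$stride, config$n_embed)
    opt <- adam_init(params)
    log <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0
      for (st in seq_len(steps)) {
        if (mode == "triplet") {
          tr <- sample_triplets(by_class, B)
          fwd <- encoder_forward(params, X[c(tr$a, tr$p, tr$n), , drop = FALSE],
                                 normalize = config$normalize,
                                 keep_cache = TRUE)
          U <- fwd$U
          ia <- seq_len(B); ip <- B + ia; iq <- 2L * B + ia
          dap2 <- rowSums((U[ia, , drop = FALSE] - U[ip, , drop = FALSE])^2)
          dan2 <- rowSums((U[ia, , drop = FALSE] - U[iq, , drop = FALSE])^2)
          z <- dap2 - dan2 + config$alpha
          act <- as.numeric(z > 0)
          ep_loss <- ep_loss + mean(pmax(z, 0))
          dU <- matrix(0, nrow(U), ncol(U))
          w <- 2 * act / B
          dU[ia, ] <- w * ((U[iq, , drop = FALSE] - U[ip, , drop = FALSE]))
          dU[ip, ] <- w * (U[ip, , drop = FALSE] - U[ia, , drop = FALSE])
          dU[iq, ] <- w * (U[ia, , drop = FALSE] - U[iq, , drop = FALSE])
        } else {
          pr <- sample_pairs(by_class, B)
          fwd <- encoder_forward(params, X[c(pr$i, pr$j), , drop = FALSE],
                                 normalize = config$normalize,
                                 keep_cache = TRUE)
          U <- fwd$U
          ii <- seq_len(B); jj <- B + ii
          diff <- U[ii, , drop = FALSE] - U[jj, , drop = FALSE]
          D <- sqrt(rowSums(diff^2))
          Y <- pr$Y
          ep_loss <- ep_loss + mean(contrastive_loss(D, Y, config$margin))
          # dL/dD then chain through D
          dLdD <- Y * D - (1 - Y) * pmax(0, config$margin - D)
          scale <- dLdD / pmax(D, 1e-12) / B
          dU <- matrix(0, nrow(U), ncol(U))
          dU[ii, ] <- scale * diff
          dU[jj, ] <- -scale * diff
        }
        grads <- encoder_backward(params, fwd, dU,
                                  normalize = config$normalize)
        res <- adam_step(params, grads, opt, lr = config$lr)
        params <- res$params
        opt <- res$state
      }
      log[ep] <- ep_loss / steps
    }
  })
  structure(list(params = params, config = config, mode = mode,
                 classes = classes, input_len = input_len,
                 log = tibble(epoch = seq_len(config$epochs), loss = log)),
            class = "siamese_fit")
}

sample_triplets <- function(by_class, B) {
  cls <- names(by_class)
  a_cls <- sample(cls, B, replace = TRUE)
  a <- p <- n <- integer(B)
  for (k in seq_len(B)) {
    pool <- by_class[[a_cls[k]]]
    pick <- sample(pool, 2L)
    a[k] <- pick[1]; p[k] <- pick[2]
    neg_cls <- sample(setdiff(cls, a_cls[k]), 1L)
    n[k] <- sample(by_class[[neg_cls]], 1L)
  }
  list(a = a, p = p, n = n)
}

sample_pairs <- function(by_class, B) {
  cls <- names(by_class)
  Y <- sample(c(0, 1), B, replace = TRUE)
  i <- j <- integer(B)
  for (k in seq_len(B)) {
    if (Y[k] == 1) {
      c1 <- sample(cls, 1L)
      pick <- sample(by_class[[c1]], 2L)
      i[k] <- pick[1]; j[k] <- pick[2]
    } else {
      c2 <- sample(cls, 2L)
      i[k] <- sample(by_class[[c2[1]]], 1L)
      j[k] <- sample(by_class[[c2[2]]], 1L)
    }
  }
  list(i = i, j = j, Y = Y)
}

#' Embed epochs with a trained encoder
#'
#' Runs the shared encoder on new inputs. Identical inputs always give
#' identical embeddings (the forward pass is deterministic), and every
#' branch of the pair/triplet architecture uses this same function — weight
#' sharing is structural.
#'
#' @param fit A `siamese_fit` from [fit_siamese()].
#' @param data Either a tibble with a `samples` list-column, a numeric
#'   matrix (one row per epoch), or a single numeric vector.
#' @return For a single vector, the embedding as a numeric vector; for
#'   tabular input, the input tibble with an `embedding` list-column
#'   appended.
#' @export
encode <- function(fit, data) {
  stopifnot(inherits(fit, "siamese_fit"))
  single <- is.numeric(data) && is.null(dim(data))
  X <- if (single) {
    matrix(data, nrow = 1)
  } else if (is.matrix(data)) {
    data
  } else {
    stopifnot(is.data.frame(data), "samples" %in% names(data))
    do.call(rbind, data$samples)
  }
  if (ncol(X) != fit$input_len) {
    abort(sprintf("encoder expects inputs of length %d, got %d.",
                  fit$input_len, ncol(X)))
  }
  U <- encoder_forward(fit$params, X, normalize = fit$config$normalize)
  if (single) return(drop(U))
  if (is.matrix(data)) return(U)
  data$embedding <- lapply(seq_len(nrow(U)), function(i) U[i, ])
  data
}

#' Embedding distance between a query and a reference
#'
#' The retrieval-stage similarity measure: the Euclidean distance between
#' the encoder outputs for a resting-state recording and a during-therapy
#' recording. Identical to [pair_distance()]; with unit-normalized
#' embeddings the value lies in `[0, 2]`.
#'
#' @param query,reference Equal-length embedding vectors.
#' @return Non-negative distance.
#' @export
retrieval_distance <- function(query, reference) pair_distance(query, reference)

#' Rank a database of embeddings by similarity to a query
#'
#' Sorts database entries by ascending embedding distance to the query;
#' ties keep insertion order.
#'
#' @param query An embedding vector.
#' @param db A list of embedding vectors (optionally named), or a matrix
#'   with one embedding per row.
#' @return A tibble with columns `rank`, `id` (name or index) and
#'   `distance`, sorted by distance.
#' @export
rank_database <- function(query, db) {
  if (is.matrix(db)) db <- asplit(db, 1)
  if (length(db) == 0L) abort("`db` must be non-empty.")
  d <- vapply(db, pair_distance, numeric(1), fB = query)
  ids <- names(db) %||% as.character(seq_along(db))
  ord <- order(d) # stable: preserves insertion order on ties
  tibble(rank = seq_along(ord), id = ids[ord], distance = unname(d[ord]))
}

#' Persist / restore trained encoder weights
#'
#' Weights and config are written as a plain-JSON archive (arrays plus a
#' manifest), so a trained model survives a round trip through text.
#'
#' @param fit A `siamese_fit`.
#' @param path File path (JSON).
#' @return `save_siamese()` returns `path` invisibly; `load_siamese()`
#'   a `siamese_fit`.
#' @export
save_siamese <- function(fit, path) {
  stopifnot(inherits(fit, "siamese_fit"))
  ser <- list(
    mode = fit$mode, classes = fit$classes, input_len = fit$input_len,
    config = unclass(fit$config),
    log = as.list(fit$log),
    layers = lapply(fit$params$layers, function(l)
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b)),
    proj = list(W = as.vector(fit$params$proj$W),
                dim = dim(fit$params$proj$W), b = fit$params$proj$b),
    kernel = fit$params$kernel, stride = fit$params$stride,
    channels = fit$params$channels, n_embed = fit$params$n_embed)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_siamese
#' @export
load_siamese <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  params <- list(
    layers = lapply(ser$layers, function(l) {
      d <- as.integer(unlist(l$dim))
      list(W = matrix(num(l$W), d[1], d[2]), b = num(l$b))
    }),
    proj = {
      d <- as.integer(unlist(ser$proj$dim))
      list(W = matrix(num(ser$proj$W), d[1], d[2]), b = num(ser$proj$b))
    },
    input_len = ser$input_len, kernel = as.integer(ser$kernel),
    stride = as.integer(ser$stride),
    channels = as.integer(unlist(ser$channels)),
    n_embed = as.integer(ser$n_embed))
  cfg <- ser$config
  config <- train_config(margin = cfg$margin, alpha = cfg$alpha,
                         n_embed = cfg$n_embed,
                         channels = as.integer(unlist(cfg$channels)),
                         kernel = cfg$kernel, stride = cfg$stride,
                         epochs = cfg$epochs, lr = cfg$lr,
                         batch_size = cfg$batch_size, seed = cfg$seed,
                         normalize = cfg$normalize)
  structure(list(params = params, config = config, mode = ser$mode,
                 classes = unlist(ser$classes), input_len = ser$input_len,
                 log = tibble(epoch = num(lapply(ser$log$epoch, identity)),
                              loss = num(lapply(ser$log$loss, identity)))),
            class = "siamese_fit")
}

#' @export
print.siamese_fit <- function(x, ...) {
  cat(sprintf(
    "<siamese_fit> mode=%s | input %d samples -> %d-d embedding | %d epochs, final loss %.4g\n",
    x$mode, x$input_len, x$config$n_embed, nrow(x$log),
    x$log$loss[nrow(x$log)]))
  invisible(x)
}
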