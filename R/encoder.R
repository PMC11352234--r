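# Internal 1-D convolutional encoder with hand-written forward/backward
# passes and Adam. The shared-weight property of the Siamese/triplet
# architecture is structural here: there is a single parameter set and every
# branch input passes through the same forward function.
#
# Architecture: `length(channels)` blocks of (valid conv, kernel `kernel`,
# stride `stride`, ReLU), global average pooling over time, linear
# projection to the embedding dimension, optional L2 normalization.
#
# Activations are (batch, length, channels) arrays; convolutions are
# computed as patch-matrix products (im2col), with the flattening of the
# (batch, position) pair kept column-major throughout.

conv_out_len <- function(L, kernel, stride) (L - kernel) %/% stride + 1L

init_encoder <- function(input_len, channels = c(16, 32, 64), kernel = 7L,
                         stride = 2L, n_embed = 64L) {
  L <- input_len
  c_in <- 1L
  layers <- list()
  for (c_out in channels) {
    if (conv_out_len(L, kernel, stride) < 1L) {
      abort(sprintf("input length %d too short for %d conv blocks (kernel %d, stride %d).",
                    input_len, length(channels), kernel, stride))
    }
    fan_in <- kernel * c_in
    layers[[length(layers) + 1L]] <- list(
      W = matrix(rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out),
      b = numeric(c_out))
    L <- conv_out_len(L, kernel, stride)
    c_in <- c_out
  }
  proj <- list(
    W = matrix(rnorm(c_in * n_embed, sd = sqrt(1 / c_in)), c_in, n_embed),
    b = numeric(n_embed))
  list(layers = layers, proj = proj, input_len = input_len,
       kernel = as.integer(kernel), stride = as.integer(stride),
       channels = channels, n_embed = as.integer(n_embed))
}

# X: (B, L, C) array -> patches (B*L_out, kernel*C), offset-major blocks
im2col <- function(X, kernel, stride) {
  d <- dim(X)
  B <- d[1]; L <- d[2]; C <- d[3]
  L_out <- conv_out_len(L, kernel, stride)
  pos <- seq(1L, by = stride, length.out = L_out)
  blocks <- vector("list", kernel)
  for (o in seq_len(kernel)) {
    sl <- X[, pos + o - 1L, , drop = FALSE]
    dim(sl) <- c(B * L_out, C)
    blocks[[o]] <- sl
  }
  list(P = do.call(cbind, blocks), B = B, L_out = L_out, C = C, pos = pos)
}

# reverse of im2col: scatter-add column blocks of dP back onto (B, L, C)
col2im <- function(dP, B, L, C, kernel, stride, pos) {
  L_out <- length(pos)
  dX <- array(0, c(B, L, C))
  for (o in seq_len(kernel)) {
    blk <- dP[, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
    dim(blk) <- c(B, L_out, C)
    dX[, pos + o - 1L, ] <- dX[, pos + o - 1L, , drop = FALSE] + blk
  }
  dX
}

encoder_forward <- function(params, X, normalize = TRUE, keep_cache = FALSE) {
  B <- nrow(X)
  A <- array(X, c(B, ncol(X), 1L))
  caches <- list()
  for (li in seq_along(params$layers)) {
    lay <- params$layers[[li]]
    ic <- im2col(A, params$kernel, params$stride)
    Y <- ic$P %*% lay$W
    Y <- sweep(Y, 2L, lay$b, `+`)
    mask <- Y > 0
    Y[!mask] <- 0
    if (keep_cache) {
      caches[[li]] <- list(P = ic$P, mask = mask, B = ic$B, L_in = dim(A)[2],
                           C_in = dim(A)[3], L_out = ic$L_out, pos = ic$pos)
    }
    A <- array(Y, c(B, ic$L_out, ncol(lay$W)))
  }
  Lf <- dim(A)[2]; Cf <- dim(A)[3]
  G <- matrix(0, B, Cf)
  for (cc in seq_len(Cf)) {
    G[, cc] <- rowMeans(A[, , cc, drop = FALSE])
  }
  E <- sweep(G %*% params$proj$W, 2L, params$proj$b, `+`)
  norms <- NULL
  U <- E
  if (normalize) {
    norms <- sqrt(rowSums(E^2)) + 1e-12
    U <- E / norms
  }
  if (!keep_cache) return(U)
  list(U = U, E = E, G = G, norms = norms, Lf = Lf, caches = caches)
}

# dU: gradient w.r.t. the (possibly normalized) embedding output.
encoder_backward <- function(params, fwd, dU, normalize = TRUE) {
  if (normalize) {
    U <- fwd$U
    dE <- (dU - U * rowSums(dU * U)) / fwd$norms
  } else {
    dE <- dU
  }
  g <- list(layers = vector("list", length(params$layers)), proj = NULL)
  g$proj <- list(W = crossprod(fwd$G, dE), b = colSums(dE))
  dG <- dE %*% t(params$proj$W)
  # undo global average pooling: each time step receives dG / Lf
  B <- nrow(dG); Lf <- fwd$Lf; Cf <- ncol(dG)
  dA <- array(0, c(B, Lf, Cf))
  for (cc in seq_len(Cf)) dA[, , cc] <- dG[, cc] / Lf
  for (li in rev(seq_along(params$layers))) {
    ch <- fwd$caches[[li]]
    lay <- params$layers[[li]]
    dY <- dA
    dim(dY) <- c(ch$B * ch$L_out, ncol(lay$W))
    dY[!ch$mask] <- 0
    g$layers[[li]] <- list(W = crossprod(ch$P, dY), b = colSums(dY))
    dP <- dY %*% t(lay$W)
    dA <- col2im(dP, ch$B, ch$L_in, ch$C_in, params$kernel, params$stride,
                 ch$pos)
  }
  g
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) list(W = p$W * 0, b = p$b * 0)
  list(m = list(layers = lapply(params$layers, zero_like),
                proj = zero_like(params$proj)),
       v = list(layers = lapply(params$layers, zero_like),
                proj = zero_like(params$proj)),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m$W <- beta1 * m$W + (1 - beta1) * g$W
    m$b <- beta1 * m$b + (1 - beta1) * g$b
    v$W <- beta2 * v$W + (1 - beta2) * g$W^2
    v$b <- beta2 * v$b + (1 - beta2) * g$b^2
    mh_W <- m$W / (1 - beta1^state$t); vh_W <- v$W / (1 - beta2^state$t)
    mh_b <- m$b / (1 - beta1^state$t); vh_b <- v$b / (1 - beta2^state$t)
    p$W <- p$W - lr * mh_W / (sqrt(vh_W) + eps)
    p$b <- p$b - lr * mh_b / (sqrt(vh_b) + eps)
    list(p = p, m = m, v = v)
  }
  for (li in seq_along(params$layers)) {
    r <- upd(params$layers[[li]], grads$layers[[li]],
             state$m$layers[[li]], state$v$layers[[li]])
    params$layers[[li]] <- r$p
    state$m$layers[[li]] <- r$m
    state$v$layers[[li]] <- r$v
  }
  r <- upd(params$proj, grads$proj, state$m$proj, state$v$proj)
  params$proj <- r$p
  state$m$proj <- r$m
  state$v$proj <- r$v
  list(params = params, state = state)
}
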