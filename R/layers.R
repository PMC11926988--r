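# Neural-network primitives with hand-derived reverse-mode gradients.
# Every *_fwd returns the output (and, where needed, a cache); every *_bwd
# maps the upstream gradient back onto inputs and parameters. Token
# sequences are L x C matrices (rows = tokens, cols = channels).

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

silu_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

softplus <- function(x) {
  # overflow-safe log(1 + exp(x)), branch-free
  pmax(x, 0) + log1p(exp(-abs(x)))
}

relu <- function(x) pmax(x, 0)

lin_fwd <- function(x, W, b) {
  sweep(x %*% W, 2, b, "+")
}

lin_bwd <- function(x, W, dy) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

# Depthwise 1-D convolution along the token axis with per-channel taps.
# `W` is C x M; `offsets` (length M) gives the token displacement of each
# tap, so offsets -1:1 is a width-3 same-padded kernel and -(w-1):0 a
# causal one. Zero padding outside the sequence.
dwconv_fwd <- function(x, W, b, offsets) {
  L <- nrow(x); C <- ncol(x)
  y <- matrix(0, L, C)
  for (m in seq_along(offsets)) {
    off <- offsets[m]
    d0 <- max(1L, 1L - off); d1 <- min(L, L - off)
    if (d0 > d1) next
    dst <- d0:d1
    y[dst, ] <- y[dst, ] + x[dst + off, , drop = FALSE] *
      matrix(W[, m], length(dst), C, byrow = TRUE)
  }
  if (!is.null(b)) y <- sweep(y, 2, b, "+")
  y
}

dwconv_bwd <- function(x, W, offsets, dy, has_bias = TRUE) {
  L <- nrow(x); C <- ncol(x); M <- length(offsets)
  dx <- matrix(0, L, C)
  dW <- matrix(0, C, M)
  for (m in seq_len(M)) {
    off <- offsets[m]
    d0 <- max(1L, 1L - off); d1 <- min(L, L - off)
    if (d0 > d1) next
    dst <- d0:d1; src <- dst + off
    xs <- x[src, , drop = FALSE]
    dys <- dy[dst, , drop = FALSE]
    dW[, m] <- colSums(dys * xs)
    dx[src, ] <- dx[src, ] + dys * matrix(W[, m], length(dst), C, byrow = TRUE)
  }
  out <- list(dx = dx, dW = dW)
  if (has_bias) out$db <- colSums(dy)
  out
}

softmax_rows <- function(z) {
  m <- z[, 1]
  if (ncol(z) > 1) for (j in 2:ncol(z)) m <- pmax(m, z[, j])
  e <- exp(z - m)
  e / rowSums(e)
}

softmax_rows_bwd <- function(s, ds) {
  s * (ds - rowSums(ds * s))
}

# Adaptive average pooling of the token axis down to `M` taps, torch
# segment convention: tap m averages tokens floor((m-1)L/M)+1 .. ceil(mL/M).
adaptive_pool_fwd <- function(x, M) {
  L <- nrow(x)
  out <- matrix(0, M, ncol(x))
  for (m in seq_len(M)) {
    i0 <- floor((m - 1) * L / M) + 1L
    i1 <- ceiling(m * L / M)
    out[m, ] <- colMeans(x[i0:i1, , drop = FALSE])
  }
  out
}

adaptive_pool_bwd <- function(L, M, dout) {
  dx <- matrix(0, L, ncol(dout))
  for (m in seq_len(M)) {
    i0 <- floor((m - 1) * L / M) + 1L
    i1 <- ceiling(m * L / M)
    n <- i1 - i0 + 1L
    dx[i0:i1, ] <- dx[i0:i1, ] +
      matrix(dout[m, ] / n, n, ncol(dout), byrow = TRUE)
  }
  dx
}

# Token-wise layer normalization over the channel axis (learnable affine).
ln_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = y, cache = list(xhat = xhat, inv = inv))
}

ln_bwd <- function(dy, gamma, ca) {
  xhat <- ca$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxh <- sweep(dy, 2, gamma, "*")
  dx <- ca$inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- parameter-tree helpers -------------------------------------------------

rmat <- function(nr, nc, sd = NULL) {
  if (is.null(sd)) sd <- 1 / sqrt(nr)
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zero <- function(a) tree_map(function(x) x * 0, a)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_scale <- function(a, s) tree_map(function(x) x * s, a)

tree_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, tree_flatten), use.names = FALSE)
  else as.numeric(a)
}

tree_all_finite <- function(a) all(is.finite(tree_flatten(a)))

# Adam optimizer over a parameter tree.
adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
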