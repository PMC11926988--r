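# Independent reference implementations used as oracles. These are written
# as plain scalar loops straight from the defining equations and share no
# code with the package internals they check.

# Naive bidirectional selective-scan block: explicit per-timestep,
# per-channel, per-state recurrence.
naive_bimamba <- function(x, p, n_state) {
  L <- nrow(x)
  xz <- x %*% p$W_in + matrix(p$b_in, L, length(p$b_in), byrow = TRUE)
  d_inner <- ncol(xz) / 2
  xs <- xz[, 1:d_inner, drop = FALSE]
  zs <- xz[, d_inner + 1:d_inner, drop = FALSE]
  sig <- function(v) 1 / (1 + exp(-v))
  run_dir <- function(xd, dp) {
    w <- ncol(dp$W_conv)
    xc <- matrix(0, L, d_inner)
    for (t in 1:L) for (cc in 1:d_inner) {
      acc <- dp$b_conv[cc]
      for (m in 1:w) {
        src <- t + m - w            # taps cover offsets -(w-1)..0
        if (src >= 1 && src <= L) acc <- acc + dp$W_conv[cc, m] * xd[src, cc]
      }
      xc[t, cc] <- acc
    }
    x1 <- xc * sig(xc)
    B <- x1 %*% dp$W_B
    Cm <- x1 %*% dp$W_C
    dtp <- x1 %*% dp$W_dt + matrix(dp$b_dt, L, d_inner, byrow = TRUE)
    dt <- log1p(exp(dtp))
    A <- -exp(dp$A_log)
    y <- matrix(0, L, d_inner)
    for (cc in 1:d_inner) {
      h <- numeric(n_state)
      for (t in 1:L) {
        for (n in 1:n_state) {
          z <- dt[t, cc] * A[cc, n]
          ab <- exp(z)
          bb <- if (abs(z) < 1e-9) dt[t, cc] * B[t, n]
                else (ab - 1) / A[cc, n] * B[t, n]
          h[n] <- ab * h[n] + bb * x1[t, cc]
        }
        y[t, cc] <- sum(Cm[t, ] * h)
      }
    }
    y
  }
  Yf <- run_dir(xs, p$fwd)
  Yb <- run_dir(xs[L:1, , drop = FALSE], p$bwd)[L:1, , drop = FALSE]
  ((Yf + Yb) * (zs * sig(zs))) %*% p$W_out +
    matrix(p$b_out, L, length(p$b_out), byrow = TRUE)
}

# Naive same-padded per-channel convolution with a given C x M kernel.
naive_depthwise_conv <- function(x, W) {
  L <- nrow(x); C <- ncol(x); M <- ncol(W)
  half <- (M - 1) / 2
  y <- matrix(0, L, C)
  for (t in 1:L) for (cc in 1:C) {
    acc <- 0
    for (m in 1:M) {
      src <- t + (m - 1) - half
      if (src >= 1 && src <= L) acc <- acc + W[cc, m] * x[src, cc]
    }
    y[t, cc] <- acc
  }
  y
}

# O(n^2) concordance by explicit pair enumeration.
brute_cindex <- function(times, censor, risks) {
  num <- den <- 0
  n <- length(times)
  for (i in 1:n) for (j in 1:n) {
    if (i != j && censor[i] == 0 && times[i] < times[j]) {
      den <- den + 1
      if (risks[i] > risks[j]) num <- num + 1
      else if (risks[i] == risks[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Small random cohort with cheap embedding dimensions for io / pipeline
# tests (statistical behaviour does not depend on d).
tiny_sim <- function(n = 6, seed = 1, beta = 1, censor_rate = 0.3, ...) {
  sim_params(n_patients = n, patch_range = c(2L, 5L), pathway_count = 3L,
             d_path = 7L, d_gen = 5L, beta = beta, censor_rate = censor_rate,
             informative_pathway_count = 2L, seed = seed, ...)
}

tiny_config <- function(...) {
  run_config(d_model = 16L, d_path = 7L, d_gen = 5L, n_state = 4L,
             attn_groups = 2L, reduction = 4L, ste_reduction = 4L, ...)
}

random_bimamba_params <- function(C_in, n_state, conv_width = 3L,
                                  expand = 2L, seed = 1) {
  set.seed(seed)
  p <- mambasurv:::bimamba_init(C_in, n_state, conv_width, expand)
  # randomize biases too so zero-structure does not mask errors
  p$b_in <- rnorm(length(p$b_in), sd = 0.2)
  p$b_out <- rnorm(length(p$b_out), sd = 0.2)
  p$fwd$b_conv <- rnorm(length(p$fwd$b_conv), sd = 0.2)
  p$bwd$b_conv <- rnorm(length(p$bwd$b_conv), sd = 0.2)
  p
}
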