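# Bidirectional selective-scan (Mamba) block.
#
# The input token sequence is linearly projected into a data path x and a
# gate path z. Each direction runs a causal depthwise convolution + SiLU on
# x, derives per-timestep B_t, C_t and a softplus-positive timescale
# delta_t from linear projections, discretizes the diagonal state matrix
# A = -exp(A_log) by zero-order hold, and evaluates the selective scan.
# The backward direction is the forward algorithm on the reversed sequence
# with its own parameters, re-reversed. Direction outputs are gated by
# SiLU(z), summed and projected back to the block width.

bimamba_init <- function(C_in, n_state = 16L, conv_width = 4L, expand = 2L) {
  d_inner <- expand * C_in
  dir_init <- function() list(
    W_conv = rmat(d_inner, conv_width, sd = 1 / sqrt(conv_width)),
    b_conv = numeric(d_inner),
    W_B    = rmat(d_inner, n_state),
    W_C    = rmat(d_inner, n_state),
    W_dt   = rmat(d_inner, d_inner),
    b_dt   = rep(log(expm1(0.05)), d_inner),  # softplus^{-1}(0.05)
    A_log  = matrix(log(seq_len(n_state)), d_inner, n_state, byrow = TRUE)
  )
  list(W_in = rmat(C_in, 2L * d_inner), b_in = numeric(2L * d_inner),
       fwd = dir_init(), bwd = dir_init(),
       W_out = rmat(d_inner, C_in), b_out = numeric(C_in))
}

mamba_dir_fwd <- function(xd, dp, n_state) {
  offs <- -(ncol(dp$W_conv) - 1L):0L
  xc <- dwconv_fwd(xd, dp$W_conv, dp$b_conv, offs)
  x1 <- silu(xc)
  Bmat <- x1 %*% dp$W_B
  Cmat <- x1 %*% dp$W_C
  dt_pre <- sweep(x1 %*% dp$W_dt, 2, dp$b_dt, "+")
  dt <- softplus(dt_pre)
  A <- -exp(dp$A_log)                      # C x n_state, negative diagonal
  sc <- mamba_inner_fwd_cpp(x1, dt, A, Bmat, Cmat)
  list(y = sc$y,
       cache = list(xd = xd, xc = xc, x1 = x1, Bmat = Bmat, Cmat = Cmat,
                    dt_pre = dt_pre, dt = dt, A = A,
                    H = sc$H, A_bar = sc$A_bar, Phi = sc$Phi, offs = offs))
}

mamba_dir_bwd <- function(dy, dp, ca, n_state) {
  sb <- mamba_inner_bwd_cpp(dy, ca$x1, ca$dt, ca$A, ca$Bmat, ca$Cmat,
                            ca$H, ca$A_bar, ca$Phi)
  dA_log <- sb$dA * ca$A                             # dA/dA_log = A
  dCmat <- sb$dC
  dBmat <- sb$dB
  d_dt <- sb$ddt
  dx1 <- sb$dx1 + dCmat %*% t(dp$W_C) + dBmat %*% t(dp$W_B)
  dW_C <- crossprod(ca$x1, dCmat)
  dW_B <- crossprod(ca$x1, dBmat)
  ddt_pre <- d_dt * sigmoid(ca$dt_pre)
  dW_dt <- crossprod(ca$x1, ddt_pre)
  db_dt <- colSums(ddt_pre)
  dx1 <- dx1 + ddt_pre %*% t(dp$W_dt)
  dxc <- dx1 * silu_grad(ca$xc)
  cb <- dwconv_bwd(ca$xd, dp$W_conv, ca$offs, dxc)
  list(dx = cb$dx,
       grads = list(W_conv = cb$dW, b_conv = cb$db, W_B = dW_B, W_C = dW_C,
                    W_dt = dW_dt, b_dt = db_dt, A_log = dA_log))
}

bimamba_fwd <- function(x, p, n_state = 16L) {
  L <- nrow(x)
  xz <- lin_fwd(x, p$W_in, p$b_in)
  d_inner <- ncol(xz) %/% 2L
  xs <- xz[, seq_len(d_inner), drop = FALSE]
  zs <- xz[, d_inner + seq_len(d_inner), drop = FALSE]
  f <- mamba_dir_fwd(xs, p$fwd, n_state)
  rev_i <- rev(seq_len(L))
  b <- mamba_dir_fwd(xs[rev_i, , drop = FALSE], p$bwd, n_state)
  Yf <- f$y
  Yb <- b$y[rev_i, , drop = FALSE]
  g <- silu(zs)
  pre <- (Yf + Yb) * g
  out <- lin_fwd(pre, p$W_out, p$b_out)
  list(out = out,
       cache = list(x = x, xs = xs, zs = zs, f = f$cache, b = b$cache,
                    Yf = Yf, Yb = Yb, g = g, pre = pre, rev_i = rev_i))
}

bimamba_bwd <- function(dout, p, ca, n_state = 16L) {
  lb <- lin_bwd(ca$pre, p$W_out, dout)
  dpre <- lb$dx
  dsum <- dpre * ca$g
  dg <- dpre * (ca$Yf + ca$Yb)
  dzs <- dg * silu_grad(ca$zs)
  df <- mamba_dir_bwd(dsum, p$fwd, ca$f, n_state)
  db_ <- mamba_dir_bwd(dsum[ca$rev_i, , drop = FALSE], p$bwd, ca$b, n_state)
  dxs <- df$dx + db_$dx[ca$rev_i, , drop = FALSE]
  dxz <- cbind(dxs, dzs)
  li <- lin_bwd(ca$x, p$W_in, dxz)
  list(dx = li$dx,
       grads = list(W_in = li$dW, b_in = li$db, fwd = df$grads,
                    bwd = db_$grads, W_out = lb$dW, b_out = lb$db))
}

#' Bidirectional selective-scan token mixer
#'
#' Runs a forward and a backward selective state-space scan over the token
#' sequence, gates each by SiLU of a jointly projected gate path and sums
#' them. The two directions carry independent parameters; the backward
#' direction is the forward algorithm on the reversed sequence, re-reversed.
#'
#' @param tokens L x C numeric matrix of token features.
#' @param params parameter list from the internal initializer (created by
#'   [build_model()]; see the methods vignette for the layout).
#' @param n_state state dimension of the diagonal SSM (default 16).
#' @return L x C numeric matrix.
#' @export
bimamba_block <- function(tokens, params, n_state = 16L) {
  if (!all(is.finite(tokens))) stop("non-finite values in `tokens`")
  bimamba_fwd(tokens, params, n_state)$out
}
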