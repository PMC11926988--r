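# Convolutional Mamba token mixer (CM-Mixer).
#
# The channel dimension is split in half: the first half is mixed globally
# by a bidirectional selective-scan block, the second locally by an
# input-dependent depthwise convolution (IDConv) whose per-channel kernel
# is generated from a pooled summary of the input via grouped softmax
# attention over a learnable tap bank. The halves are re-concatenated and
# passed through a squeezed token enhancer (STE): depthwise width-3 conv,
# pointwise bottleneck, residual. Token bags play the spatial role, so all
# convolutions here are 1-D along the token axis with symmetric zero
# padding (bags are unordered; no causal constraint applies).

#' Split a token sequence along the channel dimension
#'
#' @param F_mat L x C matrix with C even.
#' @return list of two L x C/2 matrices `F1` (first half) and `F2`.
#' @export
channel_split <- function(F_mat) {
  C <- ncol(F_mat)
  if (C %% 2L != 0L) stop("channel dimension must be even, got ", C)
  half <- C %/% 2L
  list(F1 = F_mat[, seq_len(half), drop = FALSE],
       F2 = F_mat[, half + seq_len(half), drop = FALSE])
}

idconv_init <- function(Cp, A = 2L, M = 3L, r = 4L) {
  if (M %% 2L != 1L) stop("IDConv kernel size must be odd")
  hidden <- Cp %/% r
  if (hidden < 1L || Cp %% r != 0L)
    stop("IDConv reduction `r` must divide the channel count")
  list(W1 = rmat(Cp, hidden), b1 = numeric(hidden),
       W2 = rmat(hidden, A * Cp), b2 = numeric(A * Cp),
       Q = array(stats::rnorm(A * Cp * M, sd = 1 / sqrt(M)), c(A, Cp, M)))
}

#' Input-dependent depthwise convolution weights
#'
#' Pools the token axis to M tap positions, maps channels through a
#' pointwise bottleneck to A x C kernel logits per tap, applies a softmax
#' across the A attention groups (independently per channel and tap) and
#' contracts the resulting weights against the learnable tap bank Q.
#' With a single attention group the softmax is identically 1 and the
#' generated kernel equals Q.
#'
#' @param F2 L x C' input tokens.
#' @param params IDConv parameter list (`W1`,`b1`,`W2`,`b2`,`Q`).
#' @param detail if TRUE, also return the attention weights and caches.
#' @return C' x M kernel matrix (or a list when `detail = TRUE`).
#' @export
idconv_weights <- function(F2, params, detail = FALSE) {
  A <- dim(params$Q)[1]; Cp <- dim(params$Q)[2]; M <- dim(params$Q)[3]
  S <- adaptive_pool_fwd(F2, M)                  # M x Cp
  S1 <- lin_fwd(S, params$W1, params$b1)         # M x Cp/r
  S2 <- lin_fwd(S1, params$W2, params$b2)        # M x A*Cp
  # logits array (A, Cp, M): group a occupies columns (a-1)*Cp + 1..Cp of S2
  logits <- array(0, c(A, Cp, M))
  for (a in seq_len(A))
    logits[a, , ] <- t(S2[, (a - 1L) * Cp + seq_len(Cp), drop = FALSE])
  Lm <- matrix(logits, nrow = A)                 # columns = (channel, tap)
  cmax <- Lm[1, ]
  if (A > 1) for (a in 2:A) cmax <- pmax(cmax, Lm[a, ])
  Lm <- sweep(Lm, 2, cmax)
  Em <- exp(Lm)
  Gm <- sweep(Em, 2, colSums(Em), "/")           # softmax over the A groups
  Qm <- matrix(params$Q, nrow = A)
  W_flat <- colSums(Gm * Qm)
  W_k <- matrix(W_flat, Cp, M)
  if (!detail) return(W_k)
  list(W_k = W_k, Gm = Gm, Qm = Qm, S = S, S1 = S1, A = A, Cp = Cp, M = M)
}

idconv_fwd <- function(F2, params) {
  wd <- idconv_weights(F2, params, detail = TRUE)
  M <- wd$M
  offs <- -((M - 1L) %/% 2L):((M - 1L) %/% 2L)
  y <- dwconv_fwd(F2, wd$W_k, NULL, offs)
  list(out = y, cache = c(wd, list(F2 = F2, offs = offs)))
}

idconv_bwd <- function(dout, params, ca) {
  cb <- dwconv_bwd(ca$F2, ca$W_k, ca$offs, dout, has_bias = FALSE)
  dx <- cb$dx
  dW_flat <- as.vector(cb$dW)
  A <- ca$A; Cp <- ca$Cp; M <- ca$M
  dWrep <- matrix(dW_flat, A, Cp * M, byrow = TRUE)
  dGm <- ca$Qm * dWrep
  dQm <- ca$Gm * dWrep
  dLm <- ca$Gm * (dGm - matrix(colSums(dGm * ca$Gm), A, Cp * M, byrow = TRUE))
  dLarr <- array(dLm, c(A, Cp, M))
  dS2 <- matrix(0, M, A * Cp)
  for (a in seq_len(A))
    dS2[, (a - 1L) * Cp + seq_len(Cp)] <- t(dLarr[a, , , drop = TRUE])
  l2 <- lin_bwd(ca$S1, params$W2, dS2)
  l1 <- lin_bwd(ca$S, params$W1, l2$dx)
  dx <- dx + adaptive_pool_bwd(nrow(ca$F2), M, l1$dx)
  list(dx = dx,
       grads = list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db,
                    Q = array(dQm, c(A, Cp, M))))
}

#' Apply the input-dependent depthwise convolution
#'
#' Depthwise 1-D convolution of `F2` with the kernel generated by
#' [idconv_weights()], same-length output with symmetric zero padding.
#'
#' @inheritParams idconv_weights
#' @return L x C' matrix.
#' @export
idconv <- function(F2, params) idconv_fwd(F2, params)$out

ste_init <- function(C, r_ste = 4L) {
  hidden <- C %/% r_ste
  if (hidden < 1L || C %% r_ste != 0L)
    stop("STE reduction must divide the channel count")
  list(W_dw = rmat(C, 3L, sd = 1 / sqrt(3)), b_dw = numeric(C),
       W1 = rmat(C, hidden), b1 = numeric(hidden),
       W2 = rmat(hidden, C), b2 = numeric(C))
}

ste_fwd <- function(Fp, params) {
  t1 <- dwconv_fwd(Fp, params$W_dw, params$b_dw, -1:1)
  t2 <- lin_fwd(t1, params$W1, params$b1)
  t3 <- lin_fwd(t2, params$W2, params$b2)
  list(out = t3 + Fp, cache = list(Fp = Fp, t1 = t1, t2 = t2))
}

ste_bwd <- function(dout, params, ca) {
  l2 <- lin_bwd(ca$t2, params$W2, dout)
  l1 <- lin_bwd(ca$t1, params$W1, l2$dx)
  cb <- dwconv_bwd(ca$Fp, params$W_dw, -1:1, l1$dx)
  list(dx = cb$dx + dout,
       grads = list(W_dw = cb$dW, b_dw = cb$db, W1 = l1$dW, b1 = l1$db,
                    W2 = l2$dW, b2 = l2$db))
}

#' Squeezed token enhancer
#'
#' Width-3 depthwise convolution, pointwise channel compression and
#' re-expansion, plus an identity residual.
#'
#' @param Fp L x C input tokens.
#' @param params STE parameter list.
#' @return L x C matrix.
#' @export
ste <- function(Fp, params) ste_fwd(Fp, params)$out

mixer_init <- function(C, attn_groups = 2L, kernel_size = 3L, reduction = 4L,
                       ste_reduction = 4L, n_state = 16L, conv_width = 4L,
                       expand = 2L) {
  if (C %% 2L != 0L) stop("mixer width must be even")
  half <- C %/% 2L
  list(bimamba = bimamba_init(half, n_state, conv_width, expand),
       idconv = idconv_init(half, attn_groups, kernel_size, reduction),
       ste = ste_init(C, ste_reduction))
}

mixer_fwd <- function(F_mat, p, cfg) {
  sp <- channel_split(F_mat)
  if (isTRUE(cfg$use_bimamba)) {
    bm <- bimamba_fwd(sp$F1, p$bimamba, cfg$n_state)
    F1p <- bm$out
  } else {
    bm <- NULL; F1p <- sp$F1
  }
  if (isTRUE(cfg$use_idconv)) {
    id <- idconv_fwd(sp$F2, p$idconv)
    F2p <- id$out
  } else {
    id <- NULL; F2p <- sp$F2
  }
  Fp <- cbind(F1p, F2p)
  if (isTRUE(cfg$use_ste)) {
    st <- ste_fwd(Fp, p$ste)
    Y <- st$out
  } else {
    st <- NULL; Y <- Fp
  }
  list(out = Y, cache = list(bm = bm$cache, id = id$cache, st = st$cache,
                             half = ncol(sp$F1)))
}

mixer_bwd <- function(dout, p, ca, cfg) {
  grads <- tree_zero(p)
  if (isTRUE(cfg$use_ste)) {
    sb <- ste_bwd(dout, p$ste, ca$st)
    dFp <- sb$dx
    grads$ste <- sb$grads
  } else dFp <- dout
  half <- ca$half
  d1 <- dFp[, seq_len(half), drop = FALSE]
  d2 <- dFp[, half + seq_len(half), drop = FALSE]
  if (isTRUE(cfg$use_bimamba)) {
    bb <- bimamba_bwd(d1, p$bimamba, ca$bm, cfg$n_state)
    dF1 <- bb$dx
    grads$bimamba <- bb$grads
  } else dF1 <- d1
  if (isTRUE(cfg$use_idconv)) {
    ib <- idconv_bwd(d2, p$idconv, ca$id)
    dF2 <- ib$dx
    grads$idconv <- ib$grads
  } else dF2 <- d2
  list(dx = cbind(dF1, dF2), grads = grads)
}

#' Convolutional Mamba token mixer forward pass
#'
#' Y = STE(concat(BiMamba(F1), IDConv(F2))) where (F1, F2) is the channel
#' split of the input. The `use_bimamba`, `use_idconv` and `use_ste`
#' entries of `cfg` replace the corresponding stage with the identity,
#' supporting component-ablation experiments.
#'
#' @param F_mat L x C token matrix, C even.
#' @param params mixer parameter list from [build_model()] internals.
#' @param cfg list with logical toggles `use_bimamba`, `use_idconv`,
#'   `use_ste` and integer `n_state` (all-on defaults).
#' @return L x C matrix.
#' @export
cm_mixer_forward <- function(F_mat, params,
                             cfg = list(use_bimamba = TRUE, use_idconv = TRUE,
                                        use_ste = TRUE, n_state = 16L)) {
  mixer_fwd(F_mat, params, cfg)$out
}
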