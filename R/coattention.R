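# Cross-modal co-attention: the information bridge between the pathology
# and genomic streams. Single-head scaled dot-product attention with
# queries from the guiding modality and keys/values from the attended one;
# d_q = d_k = d_v = d_model (the guiding equation defines one projection
# triple per direction and no heads).

coattn_init <- function(d) {
  list(W_Qp = rmat(d, d), W_Kg = rmat(d, d), W_Vg = rmat(d, d),
       W_Qg = rmat(d, d), W_Kp = rmat(d, d), W_Vp = rmat(d, d))
}

attn_fwd <- function(Qtok, KVtok, W_Q, W_K, W_V) {
  if (ncol(Qtok) != nrow(W_Q) || ncol(KVtok) != nrow(W_K))
    stop("token dimension does not match projection matrices")
  d_k <- ncol(W_K)
  Q <- Qtok %*% W_Q
  K <- KVtok %*% W_K
  V <- KVtok %*% W_V
  S <- softmax_rows(Q %*% t(K) / sqrt(d_k))
  list(out = S %*% V,
       cache = list(Qtok = Qtok, KVtok = KVtok, Q = Q, K = K, V = V, S = S,
                    d_k = d_k))
}

attn_bwd <- function(dout, ca, W_Q, W_K, W_V) {
  dV <- crossprod(ca$S, dout)
  dS <- dout %*% t(ca$V)
  dZ <- softmax_rows_bwd(ca$S, dS) / sqrt(ca$d_k)
  dQ <- dZ %*% ca$K
  dK <- crossprod(dZ, ca$Q)
  list(dQtok = dQ %*% t(W_Q),
       dKVtok = dK %*% t(W_K) + dV %*% t(W_V),
       dW_Q = crossprod(ca$Qtok, dQ),
       dW_K = crossprod(ca$KVtok, dK),
       dW_V = crossprod(ca$KVtok, dV))
}

#' Pathology-guided co-attention
#'
#' Pathology tokens form the queries; genomic tokens supply keys and
#' values. Each output row is a convex (row-stochastic) combination of the
#' projected genomic rows, i.e. a pathology-guided aggregation of genomic
#' content.
#'
#' @param path_tokens N x d pathology tokens.
#' @param gen_tokens K x d genomic tokens.
#' @param proj projection list with `W_Qp`, `W_Kg`, `W_Vg` (see
#'   [build_model()]).
#' @return N x d matrix.
#' @export
pca_coattention <- function(path_tokens, gen_tokens, proj) {
  attn_fwd(path_tokens, gen_tokens, proj$W_Qp, proj$W_Kg, proj$W_Vg)$out
}

#' Genomic-guided co-attention
#'
#' Mirror image of [pca_coattention()]: genomic tokens form the queries,
#' pathology tokens supply keys and values.
#'
#' @param gen_tokens K x d genomic tokens.
#' @param path_tokens N x d pathology tokens.
#' @param proj projection list with `W_Qg`, `W_Kp`, `W_Vp`.
#' @return K x d matrix.
#' @export
gca_coattention <- function(gen_tokens, path_tokens, proj) {
  attn_fwd(gen_tokens, path_tokens, proj$W_Qg, proj$W_Kp, proj$W_Vp)$out
}
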