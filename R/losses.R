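# Training objective: censored discrete-time negative log-likelihood for
# the hazard head, plus a representation alignment penalty weighted by
# alpha. Censoring convention throughout: censor = 0 means the death was
# observed, censor = 1 means the patient was censored at last follow-up
# (note this is the opposite of the event indicator used by several
# survival libraries).

#' Discrete-time censored negative log-likelihood
#'
#' With S(0) = 1 and S(j) = prod_{u<=j}(1 - h_u), an observed death in
#' interval y contributes -[log S(y-1) + log h_y]; a patient censored in
#' interval y contributes -log S(y). Hazards are clamped to
#' [eps, 1 - eps] before taking logs. Returns the batch mean.
#'
#' @param hazards numeric matrix (patients x intervals) or a vector for a
#'   single patient.
#' @param bin_label integer interval labels in 1..t_bins.
#' @param censor 0 = death observed, 1 = censored.
#' @param eps clamp width (default 1e-7).
#' @return nonnegative scalar.
#' @export
nll_survival_loss <- function(hazards, bin_label, censor, eps = 1e-7) {
  if (is.vector(hazards)) hazards <- matrix(hazards, nrow = 1)
  tb <- ncol(hazards)
  if (any(bin_label < 1 | bin_label > tb))
    stop("bin_label out of range 1..", tb)
  if (!all(censor %in% c(0, 1))) stop("censor must be 0 or 1")
  h <- pmin(pmax(hazards, eps), 1 - eps)
  logS <- t(apply(log1p(-h), 1, cumsum))
  if (nrow(h) == 1) logS <- matrix(logS, nrow = 1)
  n <- nrow(h)
  ll <- numeric(n)
  for (i in seq_len(n)) {
    y <- bin_label[i]
    if (censor[i] == 0) {
      ll[i] <- -((if (y > 1) logS[i, y - 1] else 0) + log(h[i, y]))
    } else {
      ll[i] <- -logS[i, y]
    }
  }
  mean(ll)
}

# Gradient of the (single-patient) NLL w.r.t. the unclamped hazards.
nll_grad <- function(hazards, bin_label, censor, eps = 1e-7) {
  h <- pmin(pmax(hazards, eps), 1 - eps)
  t_bins <- length(hazards)
  gh <- numeric(t_bins)
  y <- bin_label
  if (censor == 0) {
    if (y > 1) gh[seq_len(y - 1)] <- 1 / (1 - h[seq_len(y - 1)])
    gh[y] <- -1 / h[y]
  } else {
    gh[seq_len(y)] <- 1 / (1 - h[seq_len(y)])
  }
  # zero gradient where the clamp binds in the direction of the overshoot
  gh[hazards < eps & gh > 0] <- 0
  gh[hazards > 1 - eps & gh < 0] <- 0
  gh
}

align_term <- function(a, b, metric) {
  d <- length(a)
  switch(metric,
    l1 = sum(abs(a - b)) / d,
    mse = sum((a - b)^2) / d,
    kl = {
      p <- as.numeric(softmax_rows(matrix(a, 1)))
      q <- as.numeric(softmax_rows(matrix(b, 1)))
      sum((p - q) * (log(p) - log(q)))
    },
    stop("unknown similarity metric: ", metric))
}

#' Representation alignment loss
#'
#' Distance between each pooled representation and its cross-modal
#' counterpart, and between the two streams:
#' L_sim = (1/d)(|h - h_hat| + |g - g_hat| + |h - g| + |h_hat - g_hat|)
#' under the default L1 metric. `alignment_mode` keeps subsets of the
#' terms: `intra_only` the first two, `cross_only` the last two, `none`
#' drops all (loss 0). `metric` selects L1 (default), squared-error, or
#' symmetric KL between softmax-normalized vectors.
#'
#' @param reps list with numeric vectors `h`, `g`, `h_hat`, `g_hat` of a
#'   common dimension (as produced by [model_forward()]).
#' @param alignment_mode one of "all", "intra_only", "cross_only", "none".
#' @param metric one of "l1", "mse", "kl".
#' @return nonnegative scalar.
#' @export
alignment_loss <- function(reps, alignment_mode = "all", metric = "l1") {
  d <- length(reps$h)
  if (length(reps$g) != d || length(reps$h_hat) != d || length(reps$g_hat) != d)
    stop("representation vectors must share one dimension")
  if (alignment_mode == "none") return(0)
  terms <- switch(alignment_mode,
    all = list(c("h", "h_hat"), c("g", "g_hat"), c("h", "g"), c("h_hat", "g_hat")),
    intra_only = list(c("h", "h_hat"), c("g", "g_hat")),
    cross_only = list(c("h", "g"), c("h_hat", "g_hat")),
    stop("unknown alignment_mode: ", alignment_mode))
  sum(vapply(terms, function(tm) align_term(reps[[tm[1]]], reps[[tm[2]]], metric),
             numeric(1)))
}

# Gradient of alignment_loss at each of the four pooled vectors.
align_grad <- function(reps, alignment_mode = "all", metric = "l1") {
  d <- length(reps$h)
  g <- list(dh = numeric(d), dg = numeric(d),
            dh_hat = numeric(d), dg_hat = numeric(d))
  if (alignment_mode == "none") return(g)
  terms <- switch(alignment_mode,
    all = list(c("h", "h_hat"), c("g", "g_hat"), c("h", "g"), c("h_hat", "g_hat")),
    intra_only = list(c("h", "h_hat"), c("g", "g_hat")),
    cross_only = list(c("h", "g"), c("h_hat", "g_hat")))
  key <- c(h = "dh", g = "dg", h_hat = "dh_hat", g_hat = "dg_hat")
  for (tm in terms) {
    a <- reps[[tm[1]]]; b <- reps[[tm[2]]]
    if (metric == "l1") {
      da <- sign(a - b) / d
      db <- -da
    } else if (metric == "mse") {
      da <- 2 * (a - b) / d
      db <- -da
    } else {
      p <- as.numeric(softmax_rows(matrix(a, 1)))
      q <- as.numeric(softmax_rows(matrix(b, 1)))
      vp <- (log(p) - log(q)) + (p - q) / p
      vq <- (log(q) - log(p)) + (q - p) / q
      da <- p * (vp - sum(p * vp))
      db <- q * (vq - sum(q * vq))
    }
    g[[key[tm[1]]]] <- g[[key[tm[1]]]] + da
    g[[key[tm[2]]]] <- g[[key[tm[2]]]] + db
  }
  g
}

#' Weighted total loss
#'
#' l_total = l_sur + alpha * l_sim.
#'
#' @param l_sur survival NLL component.
#' @param l_sim alignment component.
#' @param alpha nonnegative alignment weight (study default 0.03).
#' @return one-row tibble with `l_sur`, `l_sim`, `l_total`, `alpha`.
#' @export
total_loss <- function(l_sur, l_sim, alpha = 0.03) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("`alpha` must be a nonnegative scalar")
  tibble::tibble(l_sur = l_sur, l_sim = l_sim,
                 l_total = l_sur + alpha * l_sim, alpha = alpha)
}
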