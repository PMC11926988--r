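# Full dual-stream network: modality projections, per-modality CM-Mixer
# encoders, cross-modal co-attention exchange, post-exchange CM-Mixers,
# global average pooling, additive fusion and the discrete-time hazard head.

chk_finite <- function(x, stage) {
  if (!all(is.finite(x))) stop("non-finite activations at stage: ", stage)
  x
}

mixer_cfg <- function(config) {
  list(use_bimamba = config$use_bimamba, use_idconv = config$use_idconv,
       use_ste = config$use_ste, n_state = config$n_state)
}

#' Build the dual-stream survival network
#'
#' Initializes all parameters deterministically from `config$seed`:
#' input projections (d_path -> d_model, d_gen -> d_model), one pre-cross
#' CM-Mixer per modality, the co-attention projection triples, one
#' post-cross CM-Mixer per cross stream, and the fusion MLP
#' (d_model -> d_model -> t_bins hazard logits).
#'
#' @param config a [run_config()] object.
#' @return object of class `msurv_model`: list with `params` and `config`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "msurv_config"))
  d <- config$d_model
  set.seed(config$seed)
  mk_mixer <- function() {
    mixer_init(d, config$attn_groups, config$kernel_size, config$reduction,
               config$ste_reduction, config$n_state, config$conv_width,
               config$expand)
  }
  params <- list(
    W_pp = rmat(config$d_path, d), b_pp = numeric(d),
    W_pg = rmat(config$d_gen, d),  b_pg = numeric(d),
    mx_p1 = mk_mixer(), mx_g1 = mk_mixer(),
    mx_p2 = mk_mixer(), mx_g2 = mk_mixer(),
    # token-wise layer norm after each mixer stage: stacked selective
    # scans are not gain-bounded, so each stage's output scale is pinned
    ln_p1 = list(gamma = rep(1, d), beta = numeric(d)),
    ln_g1 = list(gamma = rep(1, d), beta = numeric(d)),
    ln_p2 = list(gamma = rep(1, d), beta = numeric(d)),
    ln_g2 = list(gamma = rep(1, d), beta = numeric(d)),
    coattn = coattn_init(d),
    W_h1 = rmat(d, d), b_h1 = numeric(d),
    W_h2 = rmat(d, config$t_bins), b_h2 = numeric(config$t_bins)
  )
  structure(list(params = params, config = config), class = "msurv_model")
}

# Forward pass over one patient's bags with full caches for backprop.
net_fwd <- function(P, G, params, config) {
  mcfg <- mixer_cfg(config)
  N <- nrow(P); K <- nrow(G)
  P0 <- chk_finite(lin_fwd(P, params$W_pp, params$b_pp), "pathology projection")
  G0 <- chk_finite(lin_fwd(G, params$W_pg, params$b_pg), "genomic projection")
  lnp1 <- lng1 <- NULL
  if (isTRUE(config$use_mixer_pre)) {
    mp1 <- mixer_fwd(P0, params$mx_p1, mcfg)
    mg1 <- mixer_fwd(G0, params$mx_g1, mcfg)
    lnp1 <- ln_fwd(mp1$out, params$ln_p1$gamma, params$ln_p1$beta)
    lng1 <- ln_fwd(mg1$out, params$ln_g1$gamma, params$ln_g1$beta)
    H <- chk_finite(lnp1$out, "pre-cross mixer (pathology)")
    Gt <- chk_finite(lng1$out, "pre-cross mixer (genomic)")
  } else {
    mp1 <- mg1 <- NULL; H <- P0; Gt <- G0
  }
  use_p <- isTRUE(config$use_cross) && isTRUE(config$use_pca)
  use_g <- isTRUE(config$use_cross) && isTRUE(config$use_gca)
  at_p <- at_g <- mp2 <- mg2 <- lnp2 <- lng2 <- NULL
  d <- config$d_model
  if (use_p) {
    at_p <- attn_fwd(H, Gt, params$coattn$W_Qp, params$coattn$W_Kg,
                     params$coattn$W_Vg)
    Hc <- chk_finite(at_p$out, "pathology-guided co-attention")
    if (isTRUE(config$use_mixer_post)) {
      mp2 <- mixer_fwd(Hc, params$mx_p2, mcfg)
      lnp2 <- ln_fwd(mp2$out, params$ln_p2$gamma, params$ln_p2$beta)
      Hc <- chk_finite(lnp2$out, "post-cross mixer (pathology stream)")
    }
    pca_vec <- colMeans(Hc)
  } else pca_vec <- numeric(d)
  if (use_g) {
    at_g <- attn_fwd(Gt, H, params$coattn$W_Qg, params$coattn$W_Kp,
                     params$coattn$W_Vp)
    Gc <- chk_finite(at_g$out, "genomic-guided co-attention")
    if (isTRUE(config$use_mixer_post)) {
      mg2 <- mixer_fwd(Gc, params$mx_g2, mcfg)
      lng2 <- ln_fwd(mg2$out, params$ln_g2$gamma, params$ln_g2$beta)
      Gc <- chk_finite(lng2$out, "post-cross mixer (genomic stream)")
    }
    gca_vec <- colMeans(Gc)
  } else gca_vec <- numeric(d)
  h <- colMeans(H)
  g <- colMeans(Gt)
  if (isTRUE(config$swap_cross_roles)) {
    h_hat <- gca_vec; g_hat <- pca_vec
  } else {
    h_hat <- pca_vec; g_hat <- gca_vec
  }
  v <- h + h_hat + g + g_hat
  vr <- matrix(v, 1)
  hid_pre <- lin_fwd(vr, params$W_h1, params$b_h1)
  hid <- relu(hid_pre)
  logits <- lin_fwd(hid, params$W_h2, params$b_h2)
  hazards <- chk_finite(as.numeric(sigmoid(logits)), "hazard head")
  surv <- cumprod(1 - hazards)
  reps <- list(h = h, g = g, h_hat = h_hat, g_hat = g_hat)
  list(hazards = hazards, survival = surv, risk = -sum(surv), reps = reps,
       cache = list(P = P, G = G, P0 = P0, G0 = G0, H = H, Gt = Gt,
                    mp1 = mp1$cache, mg1 = mg1$cache,
                    lnp1 = lnp1$cache, lng1 = lng1$cache,
                    lnp2 = lnp2$cache, lng2 = lng2$cache,
                    at_p = at_p$cache, at_g = at_g$cache,
                    mp2 = mp2$cache, mg2 = mg2$cache,
                    use_p = use_p, use_g = use_g,
                    vr = vr, hid_pre = hid_pre, hid = hid,
                    logits = logits, N = N, K = K))
}

# Reverse pass. `dlogits` is the gradient at the hazard logits (length
# t_bins); `dreps` an optional list(dh, dh_hat, dg, dg_hat) carrying the
# alignment-loss gradient at the pooled representations.
net_bwd <- function(ca, params, config, dlogits, dreps = NULL) {
  mcfg <- mixer_cfg(config)
  grads <- tree_zero(params)
  d <- config$d_model
  dlog <- matrix(dlogits, 1)
  l2 <- lin_bwd(ca$hid, params$W_h2, dlog)
  grads$W_h2 <- l2$dW; grads$b_h2 <- l2$db
  dhid <- l2$dx * (ca$hid_pre > 0)
  l1 <- lin_bwd(ca$vr, params$W_h1, dhid)
  grads$W_h1 <- l1$dW; grads$b_h1 <- l1$db
  dv <- as.numeric(l1$dx)
  zero <- numeric(d)
  if (is.null(dreps)) dreps <- list(dh = zero, dh_hat = zero,
                                    dg = zero, dg_hat = zero)
  dh <- dv + dreps$dh
  dg <- dv + dreps$dg
  dh_hat <- dv + dreps$dh_hat
  dg_hat <- dv + dreps$dg_hat
  if (isTRUE(config$swap_cross_roles)) {
    dpca <- dg_hat; dgca <- dh_hat
  } else {
    dpca <- dh_hat; dgca <- dg_hat
  }
  dH <- matrix(dh / ca$N, ca$N, d, byrow = TRUE)
  dGt <- matrix(dg / ca$K, ca$K, d, byrow = TRUE)
  if (ca$use_p) {
    dHc <- matrix(dpca / ca$N, ca$N, d, byrow = TRUE)
    if (isTRUE(config$use_mixer_post)) {
      lb <- ln_bwd(dHc, params$ln_p2$gamma, ca$lnp2)
      grads$ln_p2 <- list(gamma = lb$dgamma, beta = lb$dbeta)
      mb <- mixer_bwd(lb$dx, params$mx_p2, ca$mp2, mcfg)
      grads$mx_p2 <- mb$grads
      dHc <- mb$dx
    }
    ab <- attn_bwd(dHc, ca$at_p, params$coattn$W_Qp, params$coattn$W_Kg,
                   params$coattn$W_Vg)
    grads$coattn$W_Qp <- ab$dW_Q
    grads$coattn$W_Kg <- ab$dW_K
    grads$coattn$W_Vg <- ab$dW_V
    dH <- dH + ab$dQtok
    dGt <- dGt + ab$dKVtok
  }
  if (ca$use_g) {
    dGc <- matrix(dgca / ca$K, ca$K, d, byrow = TRUE)
    if (isTRUE(config$use_mixer_post)) {
      lb <- ln_bwd(dGc, params$ln_g2$gamma, ca$lng2)
      grads$ln_g2 <- list(gamma = lb$dgamma, beta = lb$dbeta)
      mb <- mixer_bwd(lb$dx, params$mx_g2, ca$mg2, mcfg)
      grads$mx_g2 <- mb$grads
      dGc <- mb$dx
    }
    ab <- attn_bwd(dGc, ca$at_g, params$coattn$W_Qg, params$coattn$W_Kp,
                   params$coattn$W_Vp)
    grads$coattn$W_Qg <- ab$dW_Q
    grads$coattn$W_Kp <- ab$dW_K
    grads$coattn$W_Vp <- ab$dW_V
    dGt <- dGt + ab$dQtok
    dH <- dH + ab$dKVtok
  }
  if (isTRUE(config$use_mixer_pre)) {
    lbp <- ln_bwd(dH, params$ln_p1$gamma, ca$lnp1)
    grads$ln_p1 <- list(gamma = lbp$dgamma, beta = lbp$dbeta)
    mbp <- mixer_bwd(lbp$dx, params$mx_p1, ca$mp1, mcfg)
    grads$mx_p1 <- mbp$grads
    dP0 <- mbp$dx
    lbg <- ln_bwd(dGt, params$ln_g1$gamma, ca$lng1)
    grads$ln_g1 <- list(gamma = lbg$dgamma, beta = lbg$dbeta)
    mbg <- mixer_bwd(lbg$dx, params$mx_g1, ca$mg1, mcfg)
    grads$mx_g1 <- mbg$grads
    dG0 <- mbg$dx
  } else {
    dP0 <- dH; dG0 <- dGt
  }
  lp <- lin_bwd(ca$P, params$W_pp, dP0)
  grads$W_pp <- lp$dW; grads$b_pp <- lp$db
  lg <- lin_bwd(ca$G, params$W_pg, dG0)
  grads$W_pg <- lg$dW; grads$b_pg <- lg$db
  grads
}

#' Forward pass for one patient record
#'
#' Projects both bags to the model width, mixes each modality, exchanges
#' information through co-attention (optionally post-mixed), pools to the
#' four representation vectors h, h_hat, g, g_hat, and maps their sum
#' through the fusion MLP to per-interval hazards, the survival curve and
#' the scalar risk score.
#'
#' @param record patient record: list with `pathology` (N x d_path) and
#'   `genomic` (K x d_gen) matrices.
#' @param model an `msurv_model` from [build_model()] (or a bare parameter
#'   list, in which case `config` must be supplied).
#' @param config optional [run_config()] overriding the model's own.
#' @return list of class `msurv_prediction` with elements `hazards`,
#'   `survival`, `risk` and `reps` (the pooled representation vectors).
#' @export
model_forward <- function(record, model, config = NULL) {
  if (inherits(model, "msurv_model")) {
    params <- model$params
    if (is.null(config)) config <- model$config
  } else params <- model
  if (is.null(config)) stop("`config` required when `model` is a bare parameter list")
  out <- net_fwd(record$pathology, record$genomic, params, config)
  structure(out[c("hazards", "survival", "risk", "reps")],
            class = "msurv_prediction")
}

#' Discrete-time survival function from per-interval hazards
#'
#' S(j) = prod_{u <= j} (1 - hazard_u).
#'
#' @param hazards numeric vector of per-interval hazards in [0, 1].
#' @return numeric vector of survival probabilities, non-increasing.
#' @export
survival_function <- function(hazards) {
  if (!is.numeric(hazards) || any(!is.finite(hazards)) ||
      any(hazards < 0 | hazards > 1))
    stop("hazards must lie in [0, 1]")
  cumprod(1 - hazards)
}

#' Scalar risk score from a survival curve
#'
#' risk = -sum_j S(j): the negative expected number of intervals survived,
#' strictly increasing in every hazard component (higher = worse
#' prognosis, bounded in [-t, 0]).
#'
#' @param survival numeric survival vector from [survival_function()].
#' @return scalar risk.
#' @export
risk_score <- function(survival) {
  -sum(survival)
}

#' Predict risks for every patient in a cohort
#'
#' @param object an `msurv_model`.
#' @param cohort an `msurv_cohort`.
#' @param ... unused.
#' @return tibble with columns `patient_id`, `risk`, `time_months`,
#'   `censor` and one `hazard_<j>` column per interval.
#' @export
predict.msurv_model <- function(object, cohort, ...) {
  stopifnot(inherits(cohort, "msurv_cohort"))
  rows <- purrr::map(cohort$records, function(r) {
    pr <- model_forward(r, object)
    tibble::tibble(patient_id = r$patient_id, risk = pr$risk,
                   time_months = r$time, censor = r$censor,
                   hazard = list(pr$hazards))
  })
  out <- dplyr::bind_rows(rows)
  hz <- do.call(rbind, out$hazard)
  colnames(hz) <- paste0("hazard_", seq_len(ncol(hz)))
  dplyr::bind_cols(dplyr::select(out, -"hazard"), tibble::as_tibble(hz))
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' Single-file serialized parameter set with the run configuration and a
#' format version.
#'
#' @param model an `msurv_model` (or `msurv_fit`).
#' @param path checkpoint file path.
#' @return `path` invisibly; `load_model()` returns the `msurv_model`.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "msurv_fit"))
    model <- structure(list(params = model$params, config = model$config),
                       class = "msurv_model")
  stopifnot(inherits(model, "msurv_model"))
  saveRDS(list(format_version = MODEL_FORMAT_VERSION, params = model$params,
               config = model$config), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, MODEL_FORMAT_VERSION))
    stop("checkpoint format version mismatch: ", format(obj$format_version))
  structure(list(params = obj$params, config = obj$config),
            class = "msurv_model")
}

#' @export
print.msurv_model <- function(x, ...) {
  np <- length(tree_flatten(x$params))
  cat("<msurv_model> d_model =", x$config$d_model,
      "| t_bins =", x$config$t_bins, "|", np, "parameters\n")
  invisible(x)
}

#' @export
print.msurv_prediction <- function(x, ...) {
  cat("<msurv_prediction> risk =", format(x$risk, digits = 4), "\n")
  cat("  hazards: ", paste(format(x$hazards, digits = 3), collapse = " "), "\n")
  cat("  survival:", paste(format(x$survival, digits = 3), collapse = " "), "\n")
  invisible(x)
}
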