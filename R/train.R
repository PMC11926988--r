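# Training loop, weighted sampling, k-fold cross-validation and the
# ablation runner. Bags are ragged, so "batch size 32" is implemented as
# gradient accumulation over 32 per-patient passes before each Adam
# update. Sampling order is drawn with inverse-frequency weights over the
# label-by-censoring strata. All randomness flows from `config$seed`.

patient_loss_grads <- function(rec, params, config, alpha_eff) {
  P <- rec$pathology
  if (nrow(P) > config$patches_per_wsi)
    P <- P[sample(nrow(P), config$patches_per_wsi), , drop = FALSE]
  fw <- net_fwd(P, rec$genomic, params, config)
  l_sur <- nll_survival_loss(fw$hazards, rec$bin_label, rec$censor,
                             eps = config$hazard_eps)
  l_sim <- alignment_loss(fw$reps, config$alignment_mode, config$sim_metric)
  gh <- nll_grad(fw$hazards, rec$bin_label, rec$censor, eps = config$hazard_eps)
  dlogits <- gh * fw$hazards * (1 - fw$hazards)
  dreps <- NULL
  if (alpha_eff > 0) {
    ag <- align_grad(fw$reps, config$alignment_mode, config$sim_metric)
    dreps <- lapply(ag, function(v) alpha_eff * v)
  }
  grads <- net_bwd(fw$cache, params, config, dlogits, dreps)
  list(l_sur = l_sur, l_sim = l_sim, grads = grads)
}

#' Train the dual-stream survival network on a cohort
#'
#' Adam optimization at `config$learning_rate` for `config$epochs` epochs.
#' Each step processes one patient (bags are ragged); gradients are
#' averaged over `config$effective_batch` patients per update. Patients
#' are drawn with replacement using inverse-frequency weights over the
#' 2 x t_bins label/censoring strata, and pathology bags larger than
#' `config$patches_per_wsi` are randomly subsampled each epoch.
#'
#' @param cohort an `msurv_cohort` with bin labels assigned
#'   ([assign_bins()]).
#' @param config a [run_config()].
#' @param params optional warm-start parameter list; default fresh
#'   [build_model()] initialization.
#' @param verbose print per-epoch loss components to stderr.
#' @return list of class `msurv_fit` with `params`, `config` and a
#'   per-epoch `history` tibble (`epoch`, `l_sur`, `l_sim`, `l_total`).
#' @export
train_model <- function(cohort, config, params = NULL, verbose = FALSE) {
  validate_cohort(cohort)
  tab <- cohort_table(cohort)
  if (anyNA(tab$bin_label))
    stop("cohort has unset bin labels; call assign_bins() first")
  if (is.null(params)) params <- build_model(config)$params
  alpha_eff <- if (isTRUE(config$use_alignment)) config$alpha else 0
  set.seed(config$seed)
  strata <- stratify_8(tab$bin_label, tab$censor)
  w <- stratum_weights(strata)
  opt <- adam_init(params)
  n <- nrow(tab)
  hist_rows <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    acc <- NULL; n_acc <- 0L
    ep_sur <- ep_sim <- 0
    for (i in idx) {
      pl <- patient_loss_grads(cohort$records[[i]], params, config, alpha_eff)
      ep_sur <- ep_sur + pl$l_sur
      ep_sim <- ep_sim + pl$l_sim
      acc <- if (is.null(acc)) pl$grads else tree_add(acc, pl$grads)
      n_acc <- n_acc + 1L
      if (n_acc == config$effective_batch) {
        st <- adam_step(params, tree_scale(acc, 1 / n_acc), opt,
                        config$learning_rate)
        params <- st$params; opt <- st$state
        acc <- NULL; n_acc <- 0L
      }
    }
    if (n_acc > 0L) {
      st <- adam_step(params, tree_scale(acc, 1 / n_acc), opt,
                      config$learning_rate)
      params <- st$params; opt <- st$state
    }
    l_sur <- ep_sur / n; l_sim <- ep_sim / n
    hist_rows[[ep]] <- tibble::tibble(epoch = ep, l_sur = l_sur,
                                      l_sim = l_sim,
                                      l_total = l_sur + alpha_eff * l_sim)
    if (verbose)
      message(sprintf("epoch %d: l_sur %.4f l_sim %.4f l_total %.4f",
                      ep, l_sur, l_sim, l_sur + alpha_eff * l_sim))
  }
  structure(list(params = params, config = config,
                 history = dplyr::bind_rows(hist_rows)),
            class = "msurv_fit")
}

#' @export
print.msurv_fit <- function(x, ...) {
  h <- x$history
  cat("<msurv_fit>", nrow(h), "epochs | final l_total =",
      format(h$l_total[nrow(h)], digits = 4), "\n")
  invisible(x)
}

as_model <- function(fit) {
  structure(list(params = fit$params, config = fit$config),
            class = "msurv_model")
}

#' k-fold cross-validation
#'
#' Seeded patient-level fold split. For each fold, interval edges are
#' computed from the training patients only, applied to both partitions
#' (no leakage), a fresh model is trained on the training folds and the
#' concordance index is evaluated on the held-out fold.
#'
#' @param cohort an `msurv_cohort` (bin labels are recomputed per fold).
#' @param config a [run_config()]; `config$folds` folds, fold f trains
#'   with seed `config$seed + f`.
#' @param verbose print per-epoch losses.
#' @return list of class `msurv_cv`: `folds` tibble (`fold`, `c_index`,
#'   `n_val`, `seed`), `mean_c_index`, `sd_c_index`, per-fold training
#'   `histories`, per-fold `bin_edges`, pooled out-of-fold `predictions`,
#'   and the fold assignment.
#' @export
cross_validate <- function(cohort, config, verbose = FALSE) {
  validate_cohort(cohort)
  k <- config$folds
  n <- length(cohort$records)
  if (k > n) stop("more folds than patients")
  set.seed(config$seed)
  fold_id <- sample(rep(seq_len(k), length.out = n))
  rows <- vector("list", k)
  histories <- vector("list", k)
  edges_list <- vector("list", k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- which(fold_id != f)
    va_idx <- which(fold_id == f)
    tr <- new_cohort(cohort$records[tr_idx], t_bins = cohort$t_bins)
    va <- new_cohort(cohort$records[va_idx], t_bins = cohort$t_bins)
    tr_tab <- cohort_table(tr)
    edges <- discretize_times(tr_tab$time_months, tr_tab$censor,
                              cohort$t_bins)$bin_edges
    tr <- assign_bins(tr, edges)
    va <- assign_bins(va, edges)
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    fit <- train_model(tr, cfg_f, verbose = verbose)
    pred <- stats::predict(as_model(fit), va)
    ci <- concordance_index(pred$time_months, pred$censor, pred$risk)
    rows[[f]] <- tibble::tibble(fold = f, c_index = ci,
                                n_val = length(va_idx), seed = cfg_f$seed)
    histories[[f]] <- fit$history
    edges_list[[f]] <- edges
    preds[[f]] <- dplyr::mutate(pred, fold = f)
  }
  folds <- dplyr::bind_rows(rows)
  structure(list(folds = folds,
                 mean_c_index = mean(folds$c_index),
                 sd_c_index = stats::sd(folds$c_index),
                 histories = histories, bin_edges = edges_list,
                 predictions = dplyr::bind_rows(preds),
                 fold_id = fold_id, config = config),
            class = "msurv_cv")
}

#' @export
print.msurv_cv <- function(x, ...) {
  cat("<msurv_cv>", nrow(x$folds), "folds | C-index",
      sprintf("%.3f +/- %.3f", x$mean_c_index, x$sd_c_index), "\n")
  invisible(x)
}

#' The nine component-ablation toggles
#'
#' @return character vector of valid `toggle` arguments for
#'   [run_ablation()].
#' @export
ablation_toggles <- function() {
  c("no_Alignment", "no_IDConv", "no_Bi-Mamba", "no_Cross", "no_PCA",
    "no_GCA", "no_STE", "no_CM-Mixer1", "no_CM-Mixer2")
}

apply_toggle <- function(config, toggle) {
  switch(toggle,
    "no_Alignment"  = { config$use_alignment <- FALSE; config },
    "no_IDConv"     = { config$use_idconv <- FALSE; config },
    "no_Bi-Mamba"   = { config$use_bimamba <- FALSE; config },
    "no_Cross"      = { config$use_cross <- FALSE; config },
    "no_PCA"        = { config$use_pca <- FALSE; config },
    "no_GCA"        = { config$use_gca <- FALSE; config },
    "no_STE"        = { config$use_ste <- FALSE; config },
    "no_CM-Mixer1"  = { config$use_mixer_pre <- FALSE; config },
    "no_CM-Mixer2"  = { config$use_mixer_post <- FALSE; config },
    stop("unknown toggle '", toggle, "'; valid toggles: ",
         paste(ablation_toggles(), collapse = ", ")))
}

#' Run a single component ablation
#'
#' Cross-validates the full model and the model with one component
#' removed, identical in every other respect (same folds, seeds and
#' data).
#'
#' @param cohort an `msurv_cohort`.
#' @param config a [run_config()].
#' @param toggle one of [ablation_toggles()].
#' @return list of class `msurv_ablation` with `comparison` tibble
#'   (`model`, `mean_c_index`, `sd_c_index`) and both `msurv_cv` objects.
#' @export
run_ablation <- function(cohort, config, toggle) {
  cfg_t <- apply_toggle(config, toggle)
  cv_all <- cross_validate(cohort, config)
  cv_tog <- cross_validate(cohort, cfg_t)
  structure(list(
    comparison = tibble::tibble(
      model = c("ALL", toggle),
      mean_c_index = c(cv_all$mean_c_index, cv_tog$mean_c_index),
      sd_c_index = c(cv_all$sd_c_index, cv_tog$sd_c_index)),
    cv_all = cv_all, cv_toggled = cv_tog, toggle = toggle),
    class = "msurv_ablation")
}

#' @export
print.msurv_ablation <- function(x, ...) {
  print(x$comparison)
  invisible(x)
}

#' Median-risk stratification with Kaplan-Meier curves and log-rank test
#'
#' Splits patients at the median predicted risk, estimates a
#' Kaplan-Meier curve per group and tests the separation with the
#' two-group log-rank statistic (p < 0.05 read as significant).
#'
#' @param data data frame with columns `time_months`, `censor` and `risk`
#'   (e.g. the output of [predict.msurv_model()]).
#' @return list of class `msurv_strat`: `km` tibble with a `group`
#'   column, `logrank` test result, and the `group` factor.
#' @export
risk_stratification <- function(data) {
  stopifnot(all(c("time_months", "censor", "risk") %in% names(data)))
  grp <- median_risk_split(data$risk)
  lo <- grp == "low"
  km_lo <- km_curve(data$time_months[lo], data$censor[lo])
  km_hi <- km_curve(data$time_months[!lo], data$censor[!lo])
  km <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(km_lo), group = "low"),
    dplyr::mutate(tibble::as_tibble(km_hi), group = "high"))
  lr <- logrank_test(data$time_months[lo], data$censor[lo],
                     data$time_months[!lo], data$censor[!lo])
  structure(list(km = km, logrank = lr, group = grp), class = "msurv_strat")
}

#' @export
print.msurv_strat <- function(x, ...) {
  cat("<msurv_strat> log-rank chi2 =", format(x$logrank$chi2, digits = 4),
      ", p =", format(x$logrank$p_value, digits = 3),
      if (x$logrank$p_value < 0.05) "(significant)" else "", "\n")
  invisible(x)
}
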