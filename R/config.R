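# Run configuration: one validated, fail-closed container for every model,
# training and ablation setting. Unknown keys in a config file are an
# error, so an ablation typo can never silently run the full model.

msurv_config_defaults <- function() {
  list(
    d_model = 256L, t_bins = 4L, alpha = 0.03,
    learning_rate = 5e-4, epochs = 30L, effective_batch = 32L,
    patches_per_wsi = 4096L, folds = 5L, seed = 1L,
    d_path = 768L, d_gen = 256L,
    use_alignment = TRUE, use_cross = TRUE, use_pca = TRUE, use_gca = TRUE,
    use_idconv = TRUE, use_bimamba = TRUE, use_ste = TRUE,
    use_mixer_pre = TRUE, use_mixer_post = TRUE,
    alignment_mode = "all", sim_metric = "l1",
    swap_cross_roles = FALSE, hazard_eps = 1e-7,
    n_state = 16L, conv_width = 4L, expand = 2L,
    attn_groups = 2L, kernel_size = 3L, reduction = 4L, ste_reduction = 4L
  )
}

#' Create a run configuration
#'
#' All arguments default to the study settings: d_model 256, four time
#' intervals, alignment weight alpha = 0.03, Adam learning rate 5e-4,
#' 30 epochs with an effective batch of 32, 4096 patches subsampled per
#' slide per epoch, 5-fold cross-validation, and every architectural
#' component enabled. Pass only the keys to override; unknown keys error.
#'
#' @param ... named overrides of the defaults (see
#'   `mambasurv:::msurv_config_defaults()` for the full key list).
#' @return validated list of class `msurv_config`.
#' @export
run_config <- function(...) {
  defaults <- msurv_config_defaults()
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == "")))
    stop("all configuration values must be named")
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  int_keys <- c("d_model", "t_bins", "epochs", "effective_batch",
                "patches_per_wsi", "folds", "seed", "d_path", "d_gen",
                "n_state", "conv_width", "expand", "attn_groups",
                "kernel_size", "reduction", "ste_reduction")
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  if (cfg$alpha < 0) stop("alpha must be >= 0")
  if (cfg$folds < 2) stop("folds must be >= 2")
  if (cfg$t_bins < 2) stop("t_bins must be >= 2")
  pos_keys <- c("d_model", "learning_rate", "epochs", "effective_batch",
                "patches_per_wsi", "d_path", "d_gen", "n_state",
                "conv_width", "expand", "attn_groups", "kernel_size",
                "reduction", "ste_reduction", "hazard_eps")
  for (k in pos_keys)
    if (cfg[[k]] <= 0) stop(k, " must be positive")
  if (cfg$d_model %% 2L != 0L) stop("d_model must be even")
  if (cfg$kernel_size %% 2L != 1L) stop("kernel_size must be odd")
  cfg$alignment_mode <- match.arg(cfg$alignment_mode,
                                  c("all", "intra_only", "cross_only", "none"))
  cfg$sim_metric <- match.arg(cfg$sim_metric, c("l1", "mse", "kl"))
  tg <- c("use_alignment", "use_cross", "use_pca", "use_gca", "use_idconv",
          "use_bimamba", "use_ste", "use_mixer_pre", "use_mixer_post",
          "swap_cross_roles")
  for (k in tg)
    if (!is.logical(cfg[[k]]) || length(cfg[[k]]) != 1L || is.na(cfg[[k]]))
      stop(k, " must be TRUE or FALSE")
  structure(cfg, class = "msurv_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys absent from the file take the defaults of [run_config()];
#' unknown keys are an error (fail-closed).
#'
#' @param path path to a YAML key: value file.
#' @return `msurv_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

#' @export
print.msurv_config <- function(x, ...) {
  cat("<msurv_config>\n")
  keys <- names(msurv_config_defaults())
  for (k in keys) cat(sprintf("  %-16s %s\n", k, format(x[[k]])))
  invisible(x)
}
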