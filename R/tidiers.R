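# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @export
tidy.msurv_cv <- function(x, ...) x$folds

#' @export
glance.msurv_cv <- function(x, ...) {
  tibble::tibble(folds = nrow(x$folds), mean_c_index = x$mean_c_index,
                 sd_c_index = x$sd_c_index)
}

#' @export
tidy.msurv_fit <- function(x, ...) x$history

#' @export
glance.msurv_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = nrow(x$history), l_sur = h$l_sur, l_sim = h$l_sim,
                 l_total = h$l_total, alpha = x$config$alpha)
}

#' @export
tidy.msurv_strat <- function(x, ...) x$km

#' @export
glance.msurv_strat <- function(x, ...) {
  tibble::tibble(chi2 = x$logrank$chi2, p_value = x$logrank$p_value,
                 n_low = sum(x$group == "low"), n_high = sum(x$group == "high"))
}

km_step_data <- function(km) {
  # prepend S = 1 at time 0 for a right-continuous step display
  dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1,
                   group = if ("group" %in% names(km)) unique(km$group)[1] else NA),
    km[, intersect(c("time", "survival", "group"), names(km))])
}

#' @export
autoplot.msurv_km <- function(object, ...) {
  df <- dplyr::bind_rows(tibble::tibble(time = 0, survival = 1),
                         object[, c("time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.msurv_strat <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(split(object$km, object$km$group), function(g) {
    dplyr::bind_rows(tibble::tibble(time = 0, survival = 1,
                                    group = g$group[1]), g)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = c(low = "#2166ac", high = "#b2182b")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = "Risk group",
                  subtitle = sprintf("log-rank p = %.3g", object$logrank$p_value)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.msurv_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, cols = c("l_sur", "l_sim", "l_total"),
                            names_to = "component", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Loss") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.msurv_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$fold), y = .data$c_index)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = object$mean_c_index, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Fold", y = "Validation C-index") +
    ggplot2::theme_minimal()
}
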