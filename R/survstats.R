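# Evaluation statistics for discrete-time survival models: interval
# discretization, risk strata, Harrell's concordance index, the
# Kaplan-Meier estimator, the two-group log-rank test and the
# median-risk split. All hand-implemented to the classical definitions;
# the test suite cross-checks them against the `survival` package.
# Censoring convention: censor = 0 observed death, censor = 1 censored.

#' Discretize follow-up times into intervals
#'
#' Interval edges are the interior quantiles (linear-interpolation rule,
#' R type 7) of the *uncensored* follow-up times; every patient -
#' censored or not - is labeled by the interval containing their time,
#' with time in [edge_{j-1}, edge_j) mapping to label j and open outer
#' intervals.
#'
#' @param times positive follow-up times (months).
#' @param censor 0/1 censoring flags (0 = death observed).
#' @param n_bins number of intervals (default 4).
#' @return list with `bin_edges` (length n_bins - 1) and integer `labels`.
#' @export
discretize_times <- function(times, censor, n_bins = 4L) {
  stopifnot(length(times) == length(censor), all(times > 0))
  ev <- times[censor == 0]
  if (length(ev) < n_bins)
    stop("need at least ", n_bins, " uncensored patients to place ",
         n_bins, " interval edges")
  edges <- stats::quantile(ev, probs = seq_len(n_bins - 1L) / n_bins,
                           type = 7, names = FALSE)
  if (any(diff(edges) <= 0))
    stop("degenerate interval edges (tied uncensored times)")
  labels <- findInterval(times, edges) + 1L
  list(bin_edges = edges, labels = labels)
}

#' Assign patients to the 4 x 2 risk strata
#'
#' Crosses the interval label (1..n_bins) with the censoring flag:
#' stratum = 2 * (label - 1) + censor + 1, giving 2 * n_bins strata
#' (8 under the default four intervals). Used for inverse-frequency
#' weighted sampling during training.
#'
#' @param labels integer interval labels.
#' @param censor 0/1 censoring flags.
#' @return integer stratum ids.
#' @export
stratify_8 <- function(labels, censor) {
  stopifnot(all(censor %in% c(0, 1)))
  as.integer(2L * (labels - 1L) + censor + 1L)
}

# Inverse-stratum-frequency sampling weights, normalized to mean 1.
stratum_weights <- function(strata) {
  counts <- table(strata)
  w <- 1 / as.numeric(counts[as.character(strata)])
  w / mean(w)
}

#' Harrell's concordance index
#'
#' Comparable pairs are (i, j) with t_i < t_j and patient i's death
#' observed; a pair is concordant when risk_i > risk_j, and risk ties
#' earn half credit.
#'
#' @param times follow-up times.
#' @param censor 0/1 flags (0 = death observed).
#' @param risks predicted risk scores (higher = worse prognosis).
#' @return concordance in [0, 1].
#' @export
concordance_index <- function(times, censor, risks) {
  n <- length(times)
  stopifnot(length(censor) == n, length(risks) == n)
  comp <- outer(times, times, "<") & matrix(censor == 0, n, n)
  diag(comp) <- FALSE
  n_comp <- sum(comp)
  if (n_comp == 0) stop("no comparable pairs")
  conc <- sum(comp & outer(risks, risks, ">"))
  ties <- sum(comp & outer(risks, risks, "=="))
  (conc + 0.5 * ties) / n_comp
}

#' Kaplan-Meier survival curve
#'
#' Right-continuous product-limit estimator: at each distinct event time
#' with d deaths among n at risk, S <- S * (1 - d/n). Patients censored
#' at a time leave the risk set just after it.
#'
#' @param times follow-up times.
#' @param censor 0/1 flags (0 = death observed).
#' @return tibble of class `msurv_km` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` (one row per distinct time).
#' @export
km_curve <- function(times, censor) {
  stopifnot(length(times) == length(censor), length(times) >= 1)
  ord <- order(times)
  tt <- times[ord]; cc <- censor[ord]
  ut <- unique(tt)
  n <- length(tt)
  surv <- 1
  out <- purrr::map(ut, function(tau) {
    n_risk <- sum(tt >= tau)
    d <- sum(tt == tau & cc == 0)
    cens <- sum(tt == tau & cc == 1)
    if (d > 0) surv <<- surv * (1 - d / n_risk)
    tibble::tibble(time = tau, n_risk = n_risk, n_event = d,
                   n_censor = cens, survival = surv)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("msurv_km", class(res))
  res
}

#' Two-group log-rank test
#'
#' Pools the risk sets of both groups at every distinct event time,
#' accumulates observed-minus-expected deaths in group A under the
#' hypergeometric null and its variance, and refers
#' (sum O - sum E)^2 / sum V to a chi-square distribution with 1 df.
#'
#' @param times_a,censor_a group A follow-up and 0/1 censoring.
#' @param times_b,censor_b group B likewise.
#' @return list with `chi2`, `p_value`, `observed_a`, `expected_a`.
#' @export
logrank_test <- function(times_a, censor_a, times_b, censor_b) {
  if (length(times_a) == 0 || length(times_b) == 0)
    stop("both groups must be non-empty")
  times <- c(times_a, times_b)
  censor <- c(censor_a, censor_b)
  grp <- rep(c(0L, 1L), c(length(times_a), length(times_b)))
  ev_times <- sort(unique(times[censor == 0]))
  if (length(ev_times) == 0) stop("no observed events in either group")
  O <- E <- V <- 0
  for (tau in ev_times) {
    at_risk <- times >= tau
    n_tot <- sum(at_risk)
    n_a <- sum(at_risk & grp == 0L)
    d_tot <- sum(times == tau & censor == 0)
    d_a <- sum(times == tau & censor == 0 & grp == 0L)
    O <- O + d_a
    E <- E + d_tot * n_a / n_tot
    if (n_tot > 1)
      V <- V + d_tot * (n_a / n_tot) * (1 - n_a / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
  }
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed_a = O, expected_a = E)
}

#' Split patients at the median predicted risk
#'
#' Risk strictly above the median is "high"; at or below (including the
#' median element itself for odd n) is "low". A fully degenerate risk
#' vector (all equal) yields all-"low" with a warning.
#'
#' @param risks numeric risk scores, length >= 2.
#' @return factor with levels `low`, `high`.
#' @export
median_risk_split <- function(risks) {
  stopifnot(length(risks) >= 2)
  med <- stats::median(risks)
  grp <- ifelse(risks > med, "high", "low")
  if (all(grp == "low"))
    warning("degenerate risk vector: all patients in the low-risk group")
  factor(grp, levels = c("low", "high"))
}
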