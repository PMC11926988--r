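# Synthetic cohort simulator. Each patient carries a latent standard-normal
# risk r that modulates both modalities: a sigmoid(beta * r) fraction of
# pathology patches are drawn around a fixed unit "signal" direction, and a
# subset of genomic pathway embeddings is mean-shifted by beta * r along
# fixed directions. Event times are proportional-hazards exponential with
# rate lambda0 * exp(beta * r), so r is the Bayes-optimal risk ranking,
# its concordance with event times grows with the effect size beta
# (beta = 0 is an exact null), and recovery of r is a well-defined target.
# Censoring times are exponential with the rate calibrated so the expected
# censored fraction matches `censor_rate`.

#' Simulation parameters
#'
#' @param n_patients cohort size.
#' @param patch_range integer (min, max) for the per-patient patch count N.
#' @param pathway_count number K of pathway embeddings per patient.
#' @param d_path,d_gen embedding dimensions (768 / 256, matching the
#'   upstream feature extractors being emulated).
#' @param beta signal strength (latent-risk effect size, >= 0).
#' @param informative_pathway_count how many of the K pathways carry the
#'   latent-risk shift.
#' @param baseline_rate exponential event rate lambda0 at r = 0, per
#'   month (default 0.02: median survival about 35 months).
#' @param censor_rate target expected censored fraction in [0, 1).
#' @param noise_sd embedding noise standard deviation.
#' @param signal_scale norm of the signal-patch mean shift in pathology
#'   embedding space. Default `noise_sd * sqrt(d_path) / 2`: class
#'   separation of half the within-class spread, matching the clearly
#'   separated phenotype clusters that pathology foundation-model
#'   embeddings exhibit.
#' @param pathway_scale per-unit-risk norm of the informative-pathway
#'   mean shift (multiplied by `beta * r`). Default
#'   `noise_sd * sqrt(d_gen) / 8`.
#' @param decorrelate if TRUE, the genomic modality uses an independent
#'   latent draw (negative control severing the cross-modal link).
#' @param seed RNG seed; cohorts are bit-reproducible given the seed.
#' @return list of class `msurv_sim_params`.
#' @export
sim_params <- function(n_patients = 300L, patch_range = c(8L, 32L),
                       pathway_count = 16L, d_path = 768L, d_gen = 256L,
                       beta = 1, informative_pathway_count = 4L,
                       baseline_rate = 0.02, censor_rate = 0.3,
                       noise_sd = 1, signal_scale = NULL,
                       pathway_scale = NULL, decorrelate = FALSE, seed = 1L) {
  if (is.null(signal_scale)) signal_scale <- noise_sd * sqrt(d_path) / 2
  if (is.null(pathway_scale)) pathway_scale <- noise_sd * sqrt(d_gen) / 8
  p <- list(n_patients = as.integer(n_patients),
            patch_range = as.integer(patch_range),
            pathway_count = as.integer(pathway_count),
            d_path = as.integer(d_path), d_gen = as.integer(d_gen),
            beta = beta,
            informative_pathway_count = as.integer(informative_pathway_count),
            baseline_rate = baseline_rate, censor_rate = censor_rate,
            noise_sd = noise_sd, signal_scale = signal_scale,
            pathway_scale = pathway_scale, decorrelate = isTRUE(decorrelate),
            seed = as.integer(seed))
  stopifnot(p$n_patients >= 1, length(p$patch_range) == 2,
            p$patch_range[1] >= 1, p$patch_range[2] >= p$patch_range[1],
            p$pathway_count >= 1, p$beta >= 0,
            p$informative_pathway_count >= 0,
            p$informative_pathway_count <= p$pathway_count,
            p$baseline_rate > 0, p$noise_sd > 0,
            p$signal_scale >= 0, p$pathway_scale >= 0)
  if (p$censor_rate < 0 || p$censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)")
  structure(p, class = "msurv_sim_params")
}

# Censoring rate mu such that E_r[ mu / (mu + lambda0 e^{beta r}) ] = target,
# marginalized over r ~ N(0, 1).
solve_censor_rate <- function(lambda0, target, beta = 0) {
  if (target == 0) return(0)
  frac <- function(mu) {
    stats::integrate(function(r)
      stats::dnorm(r) * mu / (mu + lambda0 * exp(beta * r)),
      -Inf, Inf)$value
  }
  stats::uniroot(function(lmu) frac(exp(lmu)) - target,
                 lower = log(lambda0) - 20, upper = log(lambda0) + 20,
                 tol = 1e-10)$root |> exp()
}

#' Generate a synthetic cohort
#'
#' @param params [sim_params()].
#' @return `msurv_cohort` whose records carry no trace of the latent risk;
#'   the hidden truth table (patient_id, latent_risk) is attached as the
#'   `"truth"` attribute, retrievable with [sim_truth()], and is never
#'   written by [write_cohort()].
#' @export
generate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "msurv_sim_params"))
  p <- params
  set.seed(p$seed)
  unit <- function(n) { v <- stats::rnorm(n); v / sqrt(sum(v^2)) }
  mu_sig <- p$signal_scale * unit(p$d_path)
  gen_dirs <- if (p$informative_pathway_count > 0)
    vapply(seq_len(p$informative_pathway_count), function(i) unit(p$d_gen),
           numeric(p$d_gen))
  else NULL
  r <- stats::rnorm(p$n_patients)
  r_gen <- if (p$decorrelate) stats::rnorm(p$n_patients) else r
  mu_c <- solve_censor_rate(p$baseline_rate, p$censor_rate, p$beta)
  records <- vector("list", p$n_patients)
  for (i in seq_len(p$n_patients)) {
    N <- sample(seq(p$patch_range[1], p$patch_range[2]), 1L)
    sig <- stats::rbinom(N, 1L, sigmoid(p$beta * r[i]))
    path <- matrix(stats::rnorm(N * p$d_path, sd = p$noise_sd), N, p$d_path)
    if (any(sig == 1L))
      path[sig == 1L, ] <- path[sig == 1L, , drop = FALSE] +
        matrix(mu_sig, sum(sig), p$d_path, byrow = TRUE)
    gen <- matrix(stats::rnorm(p$pathway_count * p$d_gen, sd = p$noise_sd),
                  p$pathway_count, p$d_gen)
    if (p$informative_pathway_count > 0)
      gen[seq_len(p$informative_pathway_count), ] <-
        gen[seq_len(p$informative_pathway_count), , drop = FALSE] +
        p$beta * r_gen[i] * p$pathway_scale * t(gen_dirs)
    e_time <- stats::rexp(1, rate = p$baseline_rate * exp(p$beta * r[i]))
    c_time <- if (mu_c > 0) stats::rexp(1, rate = mu_c) else Inf
    records[[i]] <- patient_record(sprintf("P%04d", i), path, gen,
                                   time = min(e_time, c_time),
                                   censor = as.integer(c_time < e_time))
  }
  co <- new_cohort(records)
  attr(co, "truth") <- tibble::tibble(
    patient_id = vapply(records, function(x) x$patient_id, character(1)),
    latent_risk = r)
  co
}

#' Hidden truth table of a simulated cohort
#'
#' @param cohort a cohort from [generate_cohort()].
#' @return tibble with `patient_id` and `latent_risk`.
#' @export
sim_truth <- function(cohort) {
  tr <- attr(cohort, "truth")
  if (is.null(tr)) stop("cohort carries no simulation truth table")
  tr
}

#' Fraction of censored patients in a cohort
#'
#' @param cohort an `msurv_cohort`.
#' @return fraction of records with censor = 1.
#' @export
empirical_censor_rate <- function(cohort) {
  mean(vapply(cohort$records, function(r) r$censor, integer(1)) == 1L)
}
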