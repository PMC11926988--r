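test_that("interval edges follow the uncensored-quantile rule", {
  times <- seq(10, 80, by = 10)
  d <- discretize_times(times, rep(0, 8), n_bins = 4)
  expect_equal(d$bin_edges, c(27.5, 45, 62.5))
  expect_equal(d$labels, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  # censored observations are labeled by the same edges
  d2 <- discretize_times(c(times, 100), c(rep(0, 8), 1), n_bins = 4)
  expect_equal(d2$labels[9], 4L)
  d3 <- discretize_times(c(times, 30), c(rep(0, 8), 1), n_bins = 4)
  expect_equal(d3$labels[9], 2L)
  expect_error(discretize_times(rep(5, 10), rep(0, 10)), "degenerate")
  expect_error(discretize_times(c(1, 2, 3), c(0, 0, 0), n_bins = 4),
               "at least 4")
})

test_that("risk strata cross interval labels with censoring", {
  expect_equal(stratify_8(1L, 0L), 1L)
  expect_equal(stratify_8(4L, 1L), 8L)
  grid <- expand.grid(label = 1:4, censor = 0:1)
  s <- stratify_8(grid$label, grid$censor)
  expect_equal(sort(s), 1:8)
  # inverse-frequency weights normalized to mean one
  strata <- c(1, 1, 1, 2)
  w <- mambasurv:::stratum_weights(strata)
  expect_equal(mean(w), 1)
  expect_equal(w, c(1/3, 1/3, 1/3, 1) / mean(c(1/3, 1/3, 1/3, 1)))
})

test_that("the concordance index matches its defining cases", {
  expect_equal(concordance_index(c(2, 4, 6), c(0, 0, 0), c(0.9, 0.5, 0.1)), 1)
  expect_equal(concordance_index(c(2, 4, 6), c(0, 0, 0), rep(0.3, 3)), 0.5)
  expect_equal(concordance_index(c(1, 2, 3, 4), c(0, 1, 0, 1), c(4, 3, 1, 2)),
               0.75)
  expect_error(concordance_index(c(1, 2), c(1, 1), c(1, 2)), "comparable")
})

test_that("the concordance index equals brute-force enumeration and the survival package", {
  skip_if_not_installed("survival")
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(10:60, 1)
    times <- rexp(n, 0.1)
    censor <- rbinom(n, 1, 0.3)
    risks <- rnorm(n)
    ci <- concordance_index(times, censor, risks)
    expect_equal(ci, brute_cindex(times, censor, risks))
    sv <- survival::concordance(survival::Surv(times, 1 - censor) ~ risks,
                                reverse = TRUE)
    expect_equal(ci, as.numeric(sv$concordance), tolerance = 1e-12)
  }
})

test_that("perfect and random risk scores bracket the concordance range", {
  set.seed(40)
  times <- rexp(60, 0.05)
  expect_equal(concordance_index(times, rep(0, 60), -times), 1)
  cs <- replicate(200, concordance_index(times, rep(0, 60), rnorm(60)))
  expect_lt(abs(mean(cs) - 0.5), 0.02)
})

test_that("the Kaplan-Meier estimator reproduces hand-computed curves", {
  km <- km_curve(c(1, 2), c(0, 0))
  expect_equal(km$survival, c(0.5, 0))
  km <- km_curve(c(3, 5, 9), c(1, 1, 1))
  expect_equal(km$survival, rep(1, 3))
  # risk-set bookkeeping with a tie of one event and one censoring
  km <- km_curve(c(1, 1, 2, 3), c(0, 1, 0, 1))
  expect_equal(km$survival[km$time == 1], 0.75)
  expect_equal(km$survival[km$time == 2], 0.375)
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(41)
  times <- sample(1:30, 40, replace = TRUE)
  km <- km_curve(times, rep(0, 40))
  emp <- vapply(km$time, function(tau) mean(times > tau), numeric(1))
  expect_equal(km$survival, emp, tolerance = 1e-12)
})

test_that("KM agrees with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(42)
  times <- round(rexp(50, 0.08), 2)
  censor <- rbinom(50, 1, 0.4)
  km <- km_curve(times, censor)
  sf <- survival::survfit(survival::Surv(times, 1 - censor) ~ 1)
  sf_s <- summary(sf, times = km$time)$surv
  expect_equal(km$survival, sf_s, tolerance = 1e-10)
})

test_that("the log-rank test matches symmetry, hand tallies and survdiff", {
  r <- logrank_test(c(1, 2, 3), c(0, 0, 1), c(1, 2, 3), c(0, 0, 1))
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)
  # fully separated groups: manual hypergeometric tally
  r2 <- logrank_test(c(1, 2), c(0, 0), c(10, 20), c(0, 0))
  # t=1: N=4, nA=2, d=1 -> E=0.5, V=0.25; t=2: N=3, nA=1, d=1 -> E=1/3, V=2/9
  # t=10: N=2, nA=0; t=20: N=1, nA=0 -> no contribution to O-E from A
  O <- 2; E <- 0.5 + 1/3; V <- 0.25 + 2/9
  expect_equal(r2$chi2, (O - E)^2 / V, tolerance = 1e-12)
  expect_error(logrank_test(c(1, 2), c(1, 1), c(3), c(1)), "no observed events")
  expect_error(logrank_test(numeric(0), numeric(0), c(1), c(0)), "non-empty")
})

test_that("log-rank is invariant to group order and matches survdiff", {
  skip_if_not_installed("survival")
  set.seed(43)
  ta <- rexp(30, 0.1); ca <- rbinom(30, 1, 0.3)
  tb <- rexp(25, 0.2); cb <- rbinom(25, 1, 0.3)
  r_ab <- logrank_test(ta, ca, tb, cb)
  r_ba <- logrank_test(tb, cb, ta, ca)
  expect_equal(r_ab$chi2, r_ba$chi2, tolerance = 1e-12)
  sd <- survival::survdiff(survival::Surv(c(ta, tb), 1 - c(ca, cb)) ~
                             rep(c(1, 2), c(30, 25)))
  expect_equal(r_ab$chi2, sd$chisq, tolerance = 1e-10)
})

test_that("the median split assigns ties to the low-risk group", {
  g <- median_risk_split(c(1, 2, 3, 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  g3 <- median_risk_split(c(5, 1, 9))
  expect_equal(as.character(g3), c("low", "low", "high"))
  expect_warning(g0 <- median_risk_split(c(2, 2, 2)), "degenerate")
  expect_true(all(g0 == "low"))
})
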