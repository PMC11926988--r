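test_that("the censored NLL matches its analytic single-patient cases", {
  expect_equal(nll_survival_loss(c(0.5, 0.3), 1L, 0L), -log(0.5))
  expect_equal(nll_survival_loss(c(0.5, 0.5), 2L, 1L), -log(0.25))
  # near-perfect prediction of an interval-1 death drives the loss to 0
  expect_lt(nll_survival_loss(c(1 - 1e-7, 0.5, 0.5, 0.5), 1L, 0L), 1e-6)
  expect_error(nll_survival_loss(c(0.5, 0.5), 3L, 0L), "out of range")
  expect_error(nll_survival_loss(c(0.5, 0.5), 1L, 2L), "censor")
})

test_that("the NLL equals a brute-force likelihood enumeration", {
  h <- c(1/2, 1/3, 1/4, 1/5)
  S <- cumprod(1 - h)
  for (y in 1:4) {
    p_death <- (if (y > 1) S[y - 1] else 1) * h[y]
    expect_equal(nll_survival_loss(h, y, 0L), -log(p_death),
                 tolerance = 1e-12)
    expect_equal(nll_survival_loss(h, y, 1L), -log(S[y]), tolerance = 1e-12)
  }
  # batch mean over mixed patients
  hz <- rbind(h, h, h)
  expect_equal(nll_survival_loss(hz, c(1L, 2L, 3L), c(0L, 1L, 0L)),
               mean(c(-log(h[1]), -log(S[2]), -log(S[2] * h[3]))),
               tolerance = 1e-12)
})

test_that("the NLL gradient is finite at the clamp boundaries", {
  for (hz in list(c(0, 0, 0, 0), c(1, 1, 1, 1), c(0, 1, 0.5, 1))) {
    g <- mambasurv:::nll_grad(hz, 3L, 0L)
    expect_true(all(is.finite(g)))
    g <- mambasurv:::nll_grad(hz, 4L, 1L)
    expect_true(all(is.finite(g)))
  }
})

test_that("alignment loss matches its hand cases and mode structure", {
  d <- 2
  reps0 <- list(h = c(1, 2), g = c(1, 2), h_hat = c(1, 2), g_hat = c(1, 2))
  expect_equal(alignment_loss(reps0), 0)
  reps <- list(h = c(1, 0), h_hat = c(0, 0), g = c(0, 0), g_hat = c(0, 0))
  expect_equal(alignment_loss(reps), 1)   # (1/2)(1 + 0 + 1 + 0)
  expect_equal(alignment_loss(reps, alignment_mode = "none"), 0)
  expect_equal(alignment_loss(reps, alignment_mode = "intra_only"), 0.5)
  expect_equal(alignment_loss(reps, alignment_mode = "cross_only"), 0.5)
  expect_error(alignment_loss(list(h = 1:2, g = 1:3, h_hat = 1:2,
                                   g_hat = 1:2)), "dimension")
})

test_that("alignment loss is symmetric, nonnegative and zero only at equality", {
  set.seed(1)
  for (i in 1:20) {
    reps <- list(h = rnorm(4), g = rnorm(4), h_hat = rnorm(4),
                 g_hat = rnorm(4))
    swapped <- list(h = reps$g, g = reps$h, h_hat = reps$g_hat,
                    g_hat = reps$h_hat)
    l <- alignment_loss(reps)
    expect_gte(l, 0)
    expect_gt(l, 0)
    expect_equal(alignment_loss(swapped), l, tolerance = 1e-12)
  }
})

test_that("alternative similarity metrics behave sensibly", {
  set.seed(2)
  reps <- list(h = rnorm(4), g = rnorm(4), h_hat = rnorm(4), g_hat = rnorm(4))
  same <- list(h = reps$h, g = reps$h, h_hat = reps$h, g_hat = reps$h)
  for (m in c("l1", "mse", "kl")) {
    expect_equal(alignment_loss(same, metric = m), 0, tolerance = 1e-12)
    expect_gt(alignment_loss(reps, metric = m), 0)
  }
  # mse is the squared-distance analogue of the l1 form
  expect_equal(alignment_loss(reps, metric = "mse"),
               (sum((reps$h - reps$h_hat)^2) + sum((reps$g - reps$g_hat)^2) +
                  sum((reps$h - reps$g)^2) +
                  sum((reps$h_hat - reps$g_hat)^2)) / 4)
})

test_that("alignment gradients match finite differences for every metric", {
  set.seed(3)
  base <- list(h = rnorm(4), g = rnorm(4), h_hat = rnorm(4), g_hat = rnorm(4))
  h <- 1e-6
  for (m in c("mse", "kl")) {          # l1 is piecewise-constant in sign
    g <- mambasurv:::align_grad(base, metric = m)
    for (nm in names(base)) {
      for (j in 1:4) {
        rp <- base; rp[[nm]][j] <- rp[[nm]][j] + h
        rm <- base; rm[[nm]][j] <- rm[[nm]][j] - h
        g_num <- (alignment_loss(rp, metric = m) -
                    alignment_loss(rm, metric = m)) / (2 * h)
        key <- c(h = "dh", g = "dg", h_hat = "dh_hat", g_hat = "dg_hat")[nm]
        expect_equal(g[[key]][j], g_num, tolerance = 1e-5)
      }
    }
  }
})

test_that("the total loss is the alpha-weighted sum of its parts", {
  expect_equal(total_loss(1, 2, alpha = 0)$l_total, 1)
  expect_equal(total_loss(1, 2, alpha = 0.03)$l_total, 1.06)
  for (a in c(0, 0.01, 0.03, 0.1)) {
    tl <- total_loss(0.8, 1.7, alpha = a)
    expect_equal(tl$l_total, tl$l_sur + a * tl$l_sim, tolerance = 1e-15)
  }
  expect_error(total_loss(1, 1, alpha = -0.1), "nonnegative")
})
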