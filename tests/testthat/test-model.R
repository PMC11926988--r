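make_record <- function(N, K, cfg, seed = 1) {
  set.seed(seed)
  list(pathology = matrix(rnorm(N * cfg$d_path), N, cfg$d_path),
       genomic = matrix(rnorm(K * cfg$d_gen), K, cfg$d_gen))
}

test_that("model construction is deterministic and sized by the config", {
  cfg <- run_config(d_model = 16L, seed = 11L)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(mambasurv:::tree_flatten(m1$params),
                   mambasurv:::tree_flatten(m2$params))
  expect_equal(ncol(m1$params$W_h2), 4L)   # four-interval hazard head
  cfg6 <- run_config(d_model = 16L, t_bins = 6L, seed = 11L)
  expect_equal(ncol(build_model(cfg6)$params$W_h2), 6L)
})

test_that("a toy model runs forward and satisfies the hazard contracts", {
  cfg <- tiny_config(seed = 2L)
  mod <- build_model(cfg)
  pr <- model_forward(make_record(3, 2, cfg), mod)
  expect_s3_class(pr, "msurv_prediction")
  expect_length(pr$hazards, 4)
  for (seed in 1:30) {
    rec <- make_record(sample(1:9, 1), sample(1:5, 1), cfg, seed = seed)
    pr <- model_forward(rec, mod)
    expect_true(all(pr$hazards > 0 & pr$hazards < 1))
    expect_true(all(diff(pr$survival) <= 0))
    expect_true(all(pr$survival > 0 & pr$survival <= 1))
    expect_equal(pr$survival, cumprod(1 - pr$hazards))
    expect_equal(pr$risk, -sum(pr$survival))
  }
})

test_that("with order-sensitive stages disabled the prediction is patch-permutation invariant", {
  cfg <- tiny_config(seed = 3L, use_bimamba = FALSE, use_idconv = FALSE,
                     use_ste = FALSE)
  mod <- build_model(cfg)
  rec <- make_record(8, 3, cfg, seed = 4)
  set.seed(5); perm <- sample(8)
  rec_p <- rec; rec_p$pathology <- rec$pathology[perm, ]
  expect_equal(model_forward(rec_p, mod)$hazards,
               model_forward(rec, mod)$hazards, tolerance = 1e-10)
  # the bidirectional scan restores order sensitivity
  cfg2 <- tiny_config(seed = 3L)
  mod2 <- build_model(cfg2)
  expect_gt(max(abs(model_forward(rec_p, mod2)$hazards -
                      model_forward(rec, mod2)$hazards)), 1e-8)
})

test_that("disabling the cross stream zeroes both cross-modal representations", {
  cfg <- tiny_config(seed = 6L, use_cross = FALSE)
  mod <- build_model(cfg)
  pr <- model_forward(make_record(4, 3, cfg, seed = 7), mod)
  expect_equal(pr$reps$h_hat, rep(0, 16))
  expect_equal(pr$reps$g_hat, rep(0, 16))
})

test_that("every ablation toggle changes the computation graph", {
  rec <- make_record(5, 3, tiny_config(), seed = 8)
  base <- model_forward(rec, build_model(tiny_config(seed = 9L)))
  for (tg in setdiff(ablation_toggles(), "no_Alignment")) {
    cfg_t <- mambasurv:::apply_toggle(tiny_config(seed = 9L), tg)
    pr <- model_forward(rec, build_model(cfg_t))
    expect_gt(max(abs(pr$hazards - base$hazards)), 1e-9, label = tg)
  }
  # the alignment toggle acts on the loss, not the forward graph
  cfg_a <- mambasurv:::apply_toggle(tiny_config(seed = 9L), "no_Alignment")
  expect_false(cfg_a$use_alignment)
})

test_that("forward handles extreme bag sizes", {
  cfg <- tiny_config(seed = 10L)
  mod <- build_model(cfg)
  for (N in c(1, 5, 4096)) {
    pr <- model_forward(make_record(N, 3, cfg, seed = N), mod)
    expect_true(all(is.finite(pr$hazards)))
  }
  for (K in c(1, 50)) {
    pr <- model_forward(make_record(4, K, cfg, seed = K + 1), mod)
    expect_true(all(is.finite(pr$hazards)))
  }
})

test_that("survival_function and risk_score match hand-computed values", {
  expect_equal(survival_function(c(0.5, 0.5)), c(0.5, 0.25))
  expect_equal(survival_function(c(0, 0, 0)), c(1, 1, 1))
  expect_equal(survival_function(c(0.1, 0.2, 0.3, 0.4)),
               c(0.9, 0.72, 0.504, 0.3024))
  expect_error(survival_function(c(0.5, 1.2)), "0, 1")
  expect_error(survival_function(c(-0.1)), "0, 1")
  expect_equal(risk_score(c(0.5, 0.25)), -0.75)
  # bounds: hazards -> 1 gives risk -> 0; hazards -> 0 gives risk -> -t
  expect_equal(risk_score(survival_function(rep(1, 4))), 0)
  expect_equal(risk_score(survival_function(rep(0, 4))), -4)
})

test_that("risk is strictly increasing in every hazard component", {
  set.seed(11)
  for (rep in 1:20) {
    h <- runif(4, 0.05, 0.9)
    r0 <- risk_score(survival_function(h))
    j <- sample(4, 1)
    h2 <- h; h2[j] <- h2[j] + 0.02
    expect_gt(risk_score(survival_function(h2)), r0)
  }
})

test_that("analytic gradients of the total loss match finite differences", {
  cfg <- run_config(d_model = 8L, d_path = 6L, d_gen = 5L, n_state = 3L,
                    seed = 12L)
  mod <- build_model(cfg)
  params <- mod$params
  rec <- make_record(4, 3, cfg, seed = 13)
  loss_fn <- function(p) {
    fw <- mambasurv:::net_fwd(rec$pathology, rec$genomic, p, cfg)
    nll_survival_loss(fw$hazards, 2L, 0L) +
      cfg$alpha * alignment_loss(fw$reps)
  }
  fw <- mambasurv:::net_fwd(rec$pathology, rec$genomic, params, cfg)
  gh <- mambasurv:::nll_grad(fw$hazards, 2L, 0L)
  dlogits <- gh * fw$hazards * (1 - fw$hazards)
  dreps <- lapply(mambasurv:::align_grad(fw$reps), function(v) cfg$alpha * v)
  grads <- mambasurv:::net_bwd(fw$cache, params, cfg, dlogits, dreps)
  expect_true(mambasurv:::tree_all_finite(grads))
  flat_p <- mambasurv:::tree_flatten(params)
  flat_g <- mambasurv:::tree_flatten(grads)
  skel_len <- length(flat_p)
  set.seed(14)
  idx <- sample(skel_len, 25)
  h <- 1e-5
  # perturb through the flattened vector by rebuilding the tree
  rebuild <- function(flat) {
    out <- params; pos <- 0L
    walk <- function(x) {
      if (is.list(x)) return(lapply(x, walk))
      n <- length(x)
      val <- flat[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (is.null(dim(x))) val else array(val, dim(x))
    }
    walk(params)
  }
  for (j in idx) {
    fp <- flat_p; fp[j] <- fp[j] + h
    fm <- flat_p; fm[j] <- fm[j] - h
    g_num <- (loss_fn(rebuild(fp)) - loss_fn(rebuild(fm))) / (2 * h)
    expect_lt(abs(g_num - flat_g[j]),
              1e-6 + 1e-4 * max(abs(g_num), abs(flat_g[j])))
  }
})

test_that("model checkpoints round-trip through save and load", {
  cfg <- tiny_config(seed = 15L)
  mod <- build_model(cfg)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_model(mod, path)
  mod2 <- load_model(path)
  expect_identical(mod2$params, mod$params)
  rec <- make_record(3, 2, cfg, seed = 16)
  expect_identical(model_forward(rec, mod2)$hazards,
                   model_forward(rec, mod)$hazards)
  bad <- readRDS(path); bad$format_version <- 99L
  saveRDS(bad, path)
  expect_error(load_model(path), "version")
})
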