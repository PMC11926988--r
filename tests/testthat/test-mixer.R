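test_that("channel split halves the channels and re-concatenates to the input", {
  x <- matrix(rnorm(32), 4, 8)
  sp <- channel_split(x)
  expect_equal(dim(sp$F1), c(4, 4))
  expect_equal(cbind(sp$F1, sp$F2), x)
  sp2 <- channel_split(matrix(1:4, 2, 2))
  expect_equal(ncol(sp2$F1), 1L)
  expect_error(channel_split(matrix(0, 2, 7)), "even")
})

test_that("a single attention group makes the generated kernel equal the tap bank", {
  set.seed(3)
  p <- mambasurv:::idconv_init(8, A = 1, M = 3, r = 4)
  x <- matrix(rnorm(48), 6, 8)
  W <- idconv_weights(x, p)
  expect_equal(W, matrix(p$Q[1, , ], 8, 3))
})

test_that("softmax weights across attention groups sum to one for every slot", {
  set.seed(4)
  p <- mambasurv:::idconv_init(8, A = 3, M = 3, r = 2)
  x <- matrix(rnorm(80), 10, 8)
  wd <- idconv_weights(x, p, detail = TRUE)
  expect_equal(colSums(wd$Gm), rep(1, 8 * 3), tolerance = 1e-6)
})

test_that("hand-set group logits reproduce the two-way softmax combination", {
  # one channel, one tap, two groups with logits (1, -1)
  p <- list(W1 = matrix(0, 1, 1), b1 = 0,
            W2 = matrix(0, 1, 2), b2 = c(1, -1),
            Q = array(c(2, 10), c(2, 1, 1)))
  w1 <- exp(1) / (exp(1) + exp(-1))   # 0.8808
  W <- idconv_weights(matrix(rnorm(5), 5, 1), p)
  expect_equal(W[1, 1], w1 * 2 + (1 - w1) * 10, tolerance = 1e-12)
  expect_equal(w1, 0.8808, tolerance = 1e-4)
})

test_that("an identity tap kernel makes idconv the identity", {
  Q <- array(0, c(1, 4, 3)); Q[1, , 2] <- 1   # center tap only
  p <- list(W1 = matrix(rnorm(4), 4, 1), b1 = 0,
            W2 = matrix(rnorm(4), 1, 4), b2 = rnorm(4), Q = Q)
  x <- matrix(rnorm(28), 7, 4)
  expect_equal(idconv(x, p), x)
})

test_that("constant input is scaled by the kernel tap sum on interior tokens", {
  set.seed(5)
  Q <- array(rnorm(12), c(1, 4, 3))
  p <- list(W1 = matrix(0, 4, 1), b1 = 0, W2 = matrix(0, 1, 4),
            b2 = rep(0, 4), Q = Q)
  x <- matrix(2, 9, 4)
  y <- idconv(x, p)
  s <- rowSums(matrix(Q[1, , ], 4, 3))
  for (t in 2:8) expect_equal(y[t, ], 2 * s, ignore_attr = TRUE)
})

test_that("idconv equals a naive per-channel convolution oracle", {
  set.seed(6)
  p <- mambasurv:::idconv_init(8, A = 2, M = 3, r = 4)
  x <- matrix(rnorm(64), 8, 8)
  W <- idconv_weights(x, p)
  expect_lt(max(abs(idconv(x, p) - naive_depthwise_conv(x, W))), 1e-6)
})

test_that("kernel generation is input-dependent", {
  set.seed(7)
  p <- mambasurv:::idconv_init(8, A = 2, M = 3, r = 4)
  a <- matrix(rnorm(48), 6, 8)
  b <- matrix(rnorm(48), 6, 8)
  expect_gt(max(abs(idconv_weights(a, p) - idconv_weights(b, p))), 1e-8)
})

test_that("squeezed token enhancer with a zeroed branch is the identity", {
  p0 <- list(W_dw = matrix(0, 8, 3), b_dw = rep(0, 8),
             W1 = matrix(0, 8, 2), b1 = rep(0, 2),
             W2 = matrix(0, 2, 8), b2 = rep(0, 8))
  x <- matrix(rnorm(40), 5, 8)
  expect_equal(ste(x, p0), x)
  expect_equal(ste(matrix(0, 5, 8), p0), matrix(0, 5, 8))
})

test_that("ste output minus input equals the directly composed branch", {
  set.seed(8)
  p <- mambasurv:::ste_init(8, r_ste = 4)
  x <- matrix(rnorm(48), 6, 8)
  branch <- naive_depthwise_conv(x, p$W_dw)
  branch <- sweep(branch, 2, p$b_dw, "+")
  branch <- sweep(branch %*% p$W1, 2, p$b1, "+")
  branch <- sweep(branch %*% p$W2, 2, p$b2, "+")
  expect_lt(max(abs(ste(x, p) - x - branch)), 1e-6)
})

test_that("the mixer preserves shape across token counts and widths", {
  cfgs <- expand.grid(L = c(1, 4, 33), C = c(8, 256))
  for (i in seq_len(nrow(cfgs))) {
    C <- cfgs$C[i]; L <- cfgs$L[i]
    set.seed(C + L)
    p <- mambasurv:::mixer_init(C, n_state = 4)
    x <- matrix(rnorm(L * C), L, C)
    y <- cm_mixer_forward(x, p, list(use_bimamba = TRUE, use_idconv = TRUE,
                                     use_ste = TRUE, n_state = 4))
    expect_equal(dim(y), c(L, C))
  }
})

test_that("all stages toggled off make the mixer an identity map", {
  set.seed(9)
  p <- mambasurv:::mixer_init(8, n_state = 4)
  x <- matrix(rnorm(40), 5, 8)
  y <- cm_mixer_forward(x, p, list(use_bimamba = FALSE, use_idconv = FALSE,
                                   use_ste = FALSE, n_state = 4))
  expect_equal(y, x)
})

test_that("the mixer equals the manual composition of its three stages", {
  set.seed(10)
  p <- mambasurv:::mixer_init(8, n_state = 4)
  x <- matrix(rnorm(56), 7, 8)
  y <- cm_mixer_forward(x, p, list(use_bimamba = TRUE, use_idconv = TRUE,
                                   use_ste = TRUE, n_state = 4))
  sp <- channel_split(x)
  manual <- ste(cbind(bimamba_block(sp$F1, p$bimamba, 4),
                      idconv(sp$F2, p$idconv)), p$ste)
  expect_equal(y, manual)
})
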