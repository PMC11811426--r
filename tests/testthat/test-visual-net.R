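test_that("stem stride arithmetic preserves time and quarters space", {
  m <- tsnet_init(toy_tsnet_cfg(), seed = 1)
  x <- rand_clip_batch(1, 1, 8, 64, 64)
  fv <- tsnet_stem(m, x)
  expect_equal(dim(fv), c(1, 4, 8, 16, 16))
  expect_error(tsnet_stem(m, rand_clip_batch(1, 1, 4, 16, 16)), "at least 32")
})

test_that("zero input with zero biases gives a zero stem output", {
  m <- tsnet_init(toy_tsnet_cfg(), seed = 2)
  x <- array(0, c(1, 1, 4, 32, 32))
  expect_equal(max(abs(tsnet_stem(m, x))), 0)
})

test_that("forward passes are deterministic in evaluation mode", {
  m <- tsnet_init(toy_tsnet_cfg(), seed = 3)
  x <- rand_clip_batch(2)
  f1 <- tsnet_forward(m, x)
  f2 <- tsnet_forward(m, x)
  expect_identical(f1$F_V, f2$F_V)
  expect_identical(f1$logits, f2$logits)

  # two identical clips in one batch give identical feature rows
  xx <- x
  xx[2, , , , ] <- xx[1, , , , ]
  f3 <- tsnet_forward(m, xx)
  expect_equal(f3$F_V[1, ], f3$F_V[2, ], tolerance = 1e-12)
})

test_that("temporal attention collapses to 0.5 gating at zero parameters", {
  x <- rand_clip_batch(2, 4, 3, 6, 6)
  pars <- list(W1 = matrix(0, 4, 2), b1 = rep(0, 2),
               W2 = matrix(0, 2, 4), b2 = rep(0, 4))
  r <- temporal_attention(x, pars)
  expect_equal(r$W_t, matrix(0.5, 2, 4))
  expect_equal(r$F_t, 0.5 * x)
})

test_that("temporal attention matches a pencil computation on a toy tensor", {
  set.seed(8)
  x <- array(rnorm(1 * 2 * 2 * 2 * 2), c(1, 2, 2, 2, 2))
  W1 <- matrix(c(0.3, -0.2, 0.1, 0.5), 2, 2)
  b1 <- c(0.05, -0.1)
  W2 <- matrix(c(-0.4, 0.2, 0.6, -0.1), 2, 2)
  b2 <- c(0.2, 0.3)
  r <- temporal_attention(x, list(W1 = W1, b1 = b1, W2 = W2, b2 = b2))
  avg <- c(mean(x[1, 1, , , ]), mean(x[1, 2, , , ]))
  mx <- c(max(x[1, 1, , , ]), max(x[1, 2, , , ]))
  mlp <- function(z) pmax(z %*% W1 + rbind(b1), 0) %*% W2 + rbind(b2)
  wt <- 1 / (1 + exp(-(mlp(rbind(avg)) + mlp(rbind(mx)))))
  expect_equal(r$W_t, wt, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(r$F_t[1, 1, , , ], x[1, 1, , , ] * wt[1], tolerance = 1e-12)
  expect_equal(r$F_t[1, 2, , , ], x[1, 2, , , ] * wt[2], tolerance = 1e-12)

  # constant input per channel: both pools agree, logits double one branch
  xc <- array(rep(c(1.5, -0.7), each = 1), c(1, 2, 2, 2, 2))
  for (ch in 1:2) xc[1, ch, , , ] <- c(1.5, -0.7)[ch]
  rc <- temporal_attention(xc, list(W1 = W1, b1 = b1, W2 = W2, b2 = b2))
  wt_c <- 1 / (1 + exp(-2 * mlp(rbind(c(1.5, -0.7)))))
  expect_equal(rc$W_t, wt_c, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("spatial attention collapses to 0.5 gating and keeps shapes", {
  x <- rand_clip_batch(2, 3, 2, 5, 5)
  pars <- list(W = array(0, c(1, 2, 1, 3, 3)), b = 0)
  r <- spatial_attention(x, pars)
  expect_equal(dim(r$W_s), c(2, 1, 2, 5, 5))
  expect_true(all(r$W_s == 0.5))
  expect_equal(r$F_s, 0.5 * x)
})

test_that("spatial attention has the closed form on a single-pixel map", {
  x <- array(c(2, -1, 0.5), c(1, 3, 1, 1, 1))
  w_avg <- 0.7; w_max <- -0.3; b <- 0.1
  W <- array(c(w_avg, w_max), c(1, 2, 1, 1, 1))
  r <- spatial_attention(x, list(W = W, b = b))
  ws <- 1 / (1 + exp(-(w_avg * mean(x) + w_max * max(x) + b)))
  expect_equal(as.vector(r$W_s), ws, tolerance = 1e-12)
  expect_equal(r$F_s, x * ws, tolerance = 1e-12)
})

test_that("TSAM is the sum of the two gated maps and the identity at zero", {
  set.seed(9)
  x <- array(rnorm(2 * 4 * 4 * 6 * 6), c(2, 4, 4, 6, 6))
  tam0 <- list(W1 = matrix(0, 4, 2), b1 = rep(0, 2),
               W2 = matrix(0, 2, 4), b2 = rep(0, 4))
  sam0 <- list(W = array(0, c(1, 2, 1, 3, 3)), b = 0)
  expect_equal(tsam(x, tam0, sam0), x)          # 0.5 x + 0.5 x exactly
  expect_equal(tsam(array(0, dim(x)), tam0, sam0), array(0, dim(x)))

  tamr <- list(W1 = matrix(rnorm(8, sd = 0.3), 4, 2), b1 = rnorm(2, sd = 0.1),
               W2 = matrix(rnorm(8, sd = 0.3), 2, 4), b2 = rnorm(4, sd = 0.1))
  samr <- list(W = array(rnorm(18, sd = 0.3), c(1, 2, 1, 3, 3)), b = 0.05)
  recomposed <- temporal_attention(x, tamr)$F_t + spatial_attention(x, samr)$F_s
  expect_equal(tsam(x, tamr, samr), recomposed, tolerance = 1e-12)
})

test_that("attention weights stay strictly inside (0, 1)", {
  m <- tsnet_init(toy_tsnet_cfg(), seed = 10)
  x <- rand_clip_batch(1, 1, 4, 32, 32, sd = 1)
  fv <- tsnet_stem(m, x)
  p <- m$params
  ta <- mmdepnet:::tam_fwd(fv, p, "s1.b1.a1.tam")
  sa <- mmdepnet:::sam_fwd(fv, p, "s1.b1.a1.sam", k = m$cfg$sam_kernel)
  expect_true(all(ta$W_t > 0 & ta$W_t < 1))
  expect_true(all(sa$W_s > 0 & sa$W_s < 1))
})

test_that("zeroed attention parameters reproduce the attention-free backbone", {
  cfg <- toy_tsnet_cfg()
  m <- tsnet_init(cfg, seed = 11)
  for (nm in attention_param_names(m)) m$params[[nm]][] <- 0
  m_plain <- m
  m_plain$cfg$use_tsam <- FALSE
  x <- rand_clip_batch(2)
  f_attn <- tsnet_forward(m, x)
  f_plain <- tsnet_forward(m_plain, x)
  expect_identical(f_attn$logits, f_plain$logits)
  expect_identical(f_attn$F_V, f_plain$F_V)
})

test_that("attention module counts match the depth naming", {
  expect_equal(count_attention_modules(tsnet_init(toy_tsnet_cfg(), seed = 1)), 32)
  m64 <- tsnet_init(toy_tsnet_cfg(depth = "tsnet64"), seed = 1)
  expect_equal(count_attention_modules(m64), 64)
  expect_equal(m64$cfg$blocks_per_stage, c(3L, 4L, 6L, 3L))
})

test_that("configuration invariants are enforced", {
  expect_error(tsnet_config(sam_kernel = 4), "odd")
  expect_error(tsnet_config(dropout = 0.2), "dropout")
  expect_error(tsnet_config(base_channels = 6, attention_reduction = 4),
               "divide")
})

test_that("non-finite activations are reported with the stage name", {
  m <- tsnet_init(toy_tsnet_cfg(), seed = 12)
  x <- rand_clip_batch(1)
  x[1, 1, 1, 1, 1] <- NaN
  expect_error(tsnet_forward(m, x), "stem")
})

test_that("one optimisation step on a toy batch decreases the loss", {
  m <- tsnet_init(toy_tsnet_cfg(), seed = 13)
  x <- rand_clip_batch(2)
  lab <- c(0, 1); ph <- c(3, 20)
  loss_of <- function(mm) {
    fw <- tsnet_forward(mm, x)
    joint_loss(fw$logits, fw$phq8, lab, ph)$loss
  }
  g <- mmdepnet:::new_grad_env()
  fw <- tsnet_forward(m, x, grads = g)
  jl <- joint_loss(fw$logits, fw$phq8, lab, ph)
  fw$bwd(dlogits = jl$dlogits, dphq8 = jl$dphq8)
  upd <- mmdepnet:::adamw_step(m$params, mmdepnet:::grads_as_list(g),
                               mmdepnet:::adamw_init(m$params), lr = 1e-3)
  m2 <- m
  m2$params <- upd$params
  expect_lt(loss_of(m2), jl$loss)
})
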