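# Network architecture: shape contract, attention arithmetic, determinism,
# parameter counts, and gradient correctness against finite differences.

test_that("adaptive attention kernel matches the sizing rule", {
  expect_identical(eca_kernel_size(12), 3L)
  expect_identical(eca_kernel_size(2), 1L)
  expect_identical(eca_kernel_size(256), 5L)
  # brute force: nearest odd integer to (log2 C + b)/gamma, ties upward
  for (C in 1:1024) {
    val <- (log2(C) + 1) / 2
    cands <- seq(1, 13, by = 2)
    d <- abs(cands - val)
    best <- cands[d == min(d)]
    expect_identical(eca_kernel_size(C), as.integer(max(best)))
  }
  expect_error(eca_kernel_size(0), class = "amanet_config_error")
})

test_that("default configuration reproduces the published shape chain", {
  cfg <- model_config()
  sh <- stage_shapes(cfg)
  expect_equal(sh$ms_out, c(8L, 12L, 500L))
  expect_equal(sh$st_out, c(16L, 1L, 125L))
  expect_equal(sh$eca_out, c(16L, 1L, 125L))
  expect_equal(sh$dsf_out, c(16L, 1L, 15L))
  expect_equal(sh$flat, 240L)
  expect_equal(cfg$fc_width, 32L)
  expect_equal(sh$logits, 4L)
})

test_that("forward passes realize the declared shapes over a config grid", {
  grid <- list(c(2L, 2L, 500L), c(12L, 4L, 500L), c(6L, 3L, 499L),
               c(22L, 4L, 128L))
  for (g in grid) {
    cfg <- model_config(in_channels = g[1], n_classes = g[2], in_samples = g[3])
    m <- build_model(cfg)
    sh <- stage_shapes(cfg)
    x <- array(rnorm(3 * g[1] * g[3]), c(3, g[1], g[3]))
    h <- ms_block_forward(m, x)
    expect_equal(dim(h), c(3L, sh$ms_out))
    st <- st_block_forward(m, h)
    expect_equal(dim(st), c(3L, sh$st_out))
    q <- dsf_block_forward(m, st)
    expect_equal(dim(q), c(3L, sh$dsf_out))
    lg <- model_forward(m, x)
    expect_equal(dim(lg), c(3L, g[2]))
  }
  # T1 = 499 pools to 124 after the first stage
  cfg499 <- model_config(in_channels = 6L, n_classes = 3L, in_samples = 499L)
  expect_equal(stage_shapes(cfg499)$st_out[3], 124L)
})

test_that("the 4-d batch layout and binary montage are accepted", {
  cfg <- model_config(in_channels = 2L, n_classes = 2L)
  m <- build_model(cfg)
  x4 <- array(rnorm(5 * 1 * 2 * 500), c(5, 1, 2, 500))
  lg <- model_forward(m, x4)
  expect_equal(dim(lg), c(5L, 2L))
  expect_error(model_forward(m, array(0, c(5, 3, 500))),
               class = "amanet_dim_error")
})

test_that("initialization and eval-mode forward are deterministic", {
  cfg <- tiny_model_config(seed = 21L)
  m1 <- build_model(cfg); m2 <- build_model(cfg)
  expect_identical(amanet:::flatten_params(m1$params),
                   amanet:::flatten_params(m2$params))
  x <- array(rnorm(4 * 3 * 64), c(4, 3, 64))
  expect_identical(model_forward(m1, x), model_forward(m1, x))
  # permuting the batch permutes the logits identically
  perm <- c(3, 1, 4, 2)
  expect_equal(model_forward(m1, x[perm, , ]), model_forward(m1, x)[perm, ],
               tolerance = 1e-12)
})

test_that("parameter counts follow closed forms and ignore the seed", {
  m <- build_model(model_config())
  expect_identical(length(m$params$fc1$W) + length(m$params$fc1$b),
                   (240L + 1L) * 32L)        # = 7712
  # a lone (1,8) temporal convolution, 1 -> 8 channels with bias
  expect_identical(length(m$params$ms$branches[[1]]$W) +
                     length(m$params$ms$branches[[1]]$b), 72L)
  total1 <- count_parameters(m)$total
  total2 <- count_parameters(build_model(model_config(seed = 999L)))$total
  expect_identical(total1, total2)
  expect_identical(total1, sum(vapply(unlist(m$params, recursive = TRUE,
                                             use.names = FALSE),
                                      length, integer(1))))
})

test_that("zero input flows to zero logits with zero-initialized biases", {
  m <- build_model(model_config(in_channels = 4L, n_classes = 4L,
                                in_samples = 256L))
  lg <- model_forward(m, array(0, c(2, 4, 256)))
  expect_equal(max(abs(lg)), 0, tolerance = 1e-12)
  p <- exp(lg[1, ]) / sum(exp(lg[1, ]))
  expect_equal(p, rep(0.25, 4))
})

test_that("global average pooling is the per-channel mean", {
  x <- array(0, c(1, 2, 2)); x[1, , ] <- c(1, 2, 3, 4)
  expect_equal(global_avg_pool(x), 2.5)
  expect_equal(global_avg_pool(array(7, c(3, 5, 2))), rep(7, 3))
  expect_equal(global_avg_pool(array(0, c(4, 2, 2))), rep(0, 4))
  expect_error(global_avg_pool(1:3), class = "amanet_dim_error")
})

test_that("attention gates are sigmoidal, bounded, and symmetric", {
  # zero input: gates sigmoid(0) = 0.5, output zero
  x0 <- array(0, c(8, 1, 20))
  y0 <- eca_forward(x0, 3, weights = rnorm(3))
  expect_true(all(y0 == 0))
  expect_equal(attr(y0, "gates"), rep(0.5, 8))
  # identity tap: gate_c = sigmoid(z_c) exactly
  set.seed(2)
  x <- array(rnorm(6 * 1 * 10), c(6, 1, 10))
  y <- eca_forward(x, 3)                       # identity-tap default weights
  z <- apply(x, 1, mean)
  expect_equal(attr(y, "gates"), 1 / (1 + exp(-z)))
  expect_equal(y[, 1, ], x[, 1, ] * attr(y, "gates"), ignore_attr = TRUE)
  # equal descriptors + circular padding: all gates equal
  xc <- array(rep(rnorm(10), each = 6), c(6, 1, 10))
  yc <- eca_forward(xc, 3, weights = rnorm(3), padding = "circular")
  expect_equal(diff(range(attr(yc, "gates"))), 0, tolerance = 1e-12)
  # gates strictly inside (0,1) for any finite input
  yr <- eca_forward(array(rnorm(6 * 30) * 10, c(6, 1, 30)), 5,
                    weights = rnorm(5))
  expect_true(all(attr(yr, "gates") > 0 & attr(yr, "gates") < 1))
  expect_error(eca_forward(x, 4), class = "amanet_config_error")
})

test_that("sum-fused equal branches triple a single branch on an impulse", {
  cfg_sum <- tiny_model_config(ms_kernels = c(5L, 5L, 5L), ms_fusion = "sum",
                               in_channels = 2L, n_classes = 2L)
  m <- build_model(cfg_sum)
  Wpos <- abs(m$params$ms$branches[[1]]$W)
  for (i in 1:3) m$params$ms$branches[[i]]$W <- Wpos
  cfg_one <- tiny_model_config(ms_kernels = c(5L, 5L, 5L),
                               use_multiscale = FALSE,
                               in_channels = 2L, n_classes = 2L)
  m1 <- build_model(cfg_one)
  m1$params$ms$branches[[1]]$W <- Wpos
  x <- array(0, c(1, 2, 64)); x[1, 1, 32] <- 1
  h3 <- ms_block_forward(m, x)
  h1 <- ms_block_forward(m1, x)
  # BN in eval mode on a fresh model scales by 1/sqrt(1+eps); ELU is identity
  # on the non-negative response, so the fused output is 3x the single branch
  expect_equal(h3, 3 * h1, tolerance = 1e-6)
})

test_that("degenerate fusion block reduces to plain average pooling", {
  cfg <- tiny_model_config(in_channels = 2L, n_classes = 2L, K2 = 5L)
  m <- build_model(cfg)
  Cf <- cfg$F1 * cfg$D
  m$params$dsf$Wd <- matrix(0, Cf, 5); m$params$dsf$Wd[, 3] <- 1  # center tap
  m$params$dsf$Wp <- diag(cfg$F2)[, seq_len(Cf)]
  m$params$dsf$bd <- rep(0, Cf); m$params$dsf$bp <- rep(0, cfg$F2)
  set.seed(3)
  x <- abs(array(rnorm(2 * Cf * 16), c(2, Cf, 1, 16)))   # positive: ELU inert
  q <- dsf_block_forward(m, x)
  pooled <- array(0, dim = dim(q))
  for (n in 1:2) for (c in seq_len(Cf)) for (l in seq_len(dim(q)[4]))
    pooled[n, c, 1, l] <- mean(x[n, c, 1, ((l - 1) * 8 + 1):(l * 8)])
  expect_equal(q, pooled, tolerance = 1e-4)   # up to the BN eps factor
})

test_that("classifier head validates input and maps to logits", {
  m <- build_model(model_config())
  flat <- matrix(rnorm(3 * 240), 3, 240)
  lg <- classifier_forward(m, flat)
  expect_equal(dim(lg), c(3L, 4L))
  expect_error(classifier_forward(m, matrix(0, 3, 239)),
               class = "amanet_dim_error")
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  set.seed(4)
  x <- array(rnorm(6 * 3 * 64), c(6, 3, 64))
  y <- sample(1:3, 6, replace = TRUE)
  res <- amanet:::amanet_pass(m, x, y = y, training = TRUE)
  g <- amanet:::flatten_params(res$grads)
  set.seed(9)
  idx <- sample(length(g), 50)
  num <- fd_gradient(m, x, y, idx)
  rel <- abs(num - g[idx]) / pmax(abs(num), abs(g[idx]), 1e-4)
  expect_lt(max(rel), 1e-4)
})

test_that("gradients are exact for every ablated architecture", {
  set.seed(4)
  x <- array(rnorm(6 * 3 * 64), c(6, 3, 64))
  y <- sample(1:3, 6, replace = TRUE)
  variants <- list(list(use_st_block = FALSE),
                   list(use_dsf_block = FALSE),
                   list(use_multiscale = FALSE),
                   list(use_eca = FALSE),
                   list(ms_fusion = "sum"),
                   list(eca_padding = "circular"),
                   list(eca_mode = "adaptive"))
  for (v in variants) {
    m <- build_model(do.call(tiny_model_config, v))
    res <- amanet:::amanet_pass(m, x, y = y, training = TRUE)
    g <- amanet:::flatten_params(res$grads)
    set.seed(10)
    idx <- sample(length(g), 25)
    num <- fd_gradient(m, x, y, idx)
    rel <- abs(num - g[idx]) / pmax(abs(num), abs(g[idx]), 1e-4)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("invalid model configurations are rejected", {
  expect_error(model_config(eca_k = 4L), class = "amanet_config_error")
  expect_error(model_config(in_samples = 16L), class = "amanet_config_error")
  expect_error(model_config(dropout = 1), class = "amanet_config_error")
  expect_error(model_config(K1 = 30L), class = "amanet_config_error")
  expect_error(model_config(use_dsf_block = FALSE, F2 = 20L),
               class = "amanet_config_error")
  expect_error(model_config(ms_kernels = c(8L, 16L)),
               class = "amanet_config_error")
})
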