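# Augmentation block: sliding windows, CSP (with analytic and brute-force
# oracles), amplitude scaling, and the fit-on-train / apply-on-test contract.

test_that("sliding_window matches the closed-form count and start offsets", {
  trial <- matrix(seq_len(3 * 1000), nrow = 3)
  w <- sliding_window(trial, 500, 125)
  expect_equal(dim(w)[1], 5L)
  expect_equal(attr(w, "starts"), c(0, 125, 250, 375, 500))

  one <- sliding_window(trial[, 1:500], 500, 125)
  expect_equal(dim(one)[1], 1L)
  expect_equal(one[1, , ], trial[, 1:500])

  tri <- sliding_window(matrix(1:12, nrow = 1), 4, 3)
  expect_equal(dim(tri)[1], 3L)
  expect_equal(attr(tri, "starts"), c(0, 3, 6))

  # property sweep against the closed form, windows verbatim from the input
  for (Tn in c(17L, 50L, 128L)) for (ws in c(5L, 16L)) for (st in c(1L, 5L, 16L)) {
    if (st > ws || ws > Tn) next
    tr <- matrix(rnorm(2 * Tn), nrow = 2)
    out <- sliding_window(tr, ws, st)
    expect_equal(dim(out)[1], (Tn - ws) %/% st + 1L)
    expect_equal(out[dim(out)[1], , ],
                 tr[, (attr(out, "starts")[dim(out)[1]] + 1):(attr(out, "starts")[dim(out)[1]] + ws)])
  }

  expect_error(sliding_window(trial, 1001, 10), class = "amanet_dim_error")
  expect_error(sliding_window(trial, 1001, 10), "1001")
  expect_error(sliding_window(trial, 1001, 10), "1000")
})

test_that("csp_fit reproduces the analytic two-channel solution", {
  fx <- make_diag_cov_windows(scales_a = c(2, 1), scales_b = c(1, 2))
  bank <- csp_fit(fx$windows, fx$labels, 2)
  # trace-normalized covariances are diag(.8,.2) and diag(.2,.8)
  expect_equal(bank$eigenvalues, c(0.8, 0.2), tolerance = 1e-6)
  expect_gte(cosine(bank$filters[1, ], c(1, 0)), 0.999)
  expect_gte(cosine(bank$filters[2, ], c(0, 1)), 0.999)
  expect_equal(bank$class_of_filter, c(0L, 1L))
  # sign convention: dominant coefficient positive
  expect_true(all(apply(bank$filters, 1, function(r) r[which.max(abs(r))] > 0)))
})

test_that("identical class distributions give eigenvalues near one half", {
  set.seed(1)
  ep <- array(rnorm(40 * 3 * 80), c(40, 3, 80))
  bank <- csp_fit(ep, rep(0:1, each = 20), 2)
  expect_true(all(abs(bank$eigenvalues - 0.5) < 0.1))
})

test_that("four-class one-vs-rest fit with six pairs yields 12 filters", {
  ts <- generate_trialset(make_separable_spec(22, "hard",
                                              n_trials_per_class = 6L, seed = 2L))
  ep <- amanet:::window_trialset(ts, aug_config())
  bank <- csp_fit(ep$data, ep$labels, 12)
  expect_equal(nrow(bank$filters), 12L)
  expect_equal(ncol(bank$filters), 22L)
  expect_equal(as.integer(table(bank$class_of_filter)), rep(3L, 4))
})

test_that("binary CSP jointly diagonalizes and eigenvalue pairs sum to one", {
  set.seed(4)
  A <- matrix(rnorm(16), 4); B <- matrix(rnorm(16), 4)
  ep <- array(0, c(20, 4, 120))
  for (i in 1:10) ep[i, , ] <- A %*% matrix(rnorm(4 * 120), 4)
  for (i in 11:20) ep[i, , ] <- B %*% matrix(rnorm(4 * 120), 4)
  labels <- rep(0:1, each = 10)
  bank <- csp_fit(ep, labels, 4)
  # composite covariance from the same estimator the fit used
  S1 <- amanet:::class_mean_cov(ep, 1:10)
  S2 <- amanet:::class_mean_cov(ep, 11:20)
  # sign fixing changes rows only by -1, which leaves W S W' diagonal identity
  WSW <- bank$filters %*% (S1 + S2) %*% t(bank$filters)
  expect_equal(WSW, diag(4), tolerance = 1e-6)
  # per-filter: the class-0 and class-1 variance ratios sum to one, and the
  # class-0 ratio is exactly the stored generalized eigenvalue
  for (i in seq_len(nrow(bank$filters))) {
    w <- bank$filters[i, ]
    r1 <- drop(w %*% S1 %*% w) / drop(w %*% (S1 + S2) %*% w)
    r2 <- drop(w %*% S2 %*% w) / drop(w %*% (S1 + S2) %*% w)
    expect_equal(r1 + r2, 1, tolerance = 1e-12)
    expect_equal(r1, bank$eigenvalues[i], tolerance = 1e-6)
  }
})

test_that("fitted filters match a dense grid-search oracle on two channels", {
  set.seed(8)
  A <- matrix(c(1.5, 0.4, 0.2, 0.7), 2); B <- matrix(c(0.6, -0.3, 0.5, 1.2), 2)
  ep <- array(0, c(30, 2, 200))
  for (i in 1:15) ep[i, , ] <- A %*% matrix(rnorm(400), 2)
  for (i in 16:30) ep[i, , ] <- B %*% matrix(rnorm(400), 2)
  bank <- csp_fit(ep, rep(0:1, each = 15), 2)
  S1 <- amanet:::class_mean_cov(ep, 1:15)
  S2 <- amanet:::class_mean_cov(ep, 16:30)
  oracle <- csp_grid_oracle(S1, S2)
  expect_gte(cosine(bank$filters[1, ], oracle$w), 0.999)
  ratio <- drop(bank$filters[1, ] %*% S1 %*% bank$filters[1, ]) /
    drop(bank$filters[1, ] %*% (S1 + S2) %*% bank$filters[1, ])
  expect_gte(ratio, oracle$ratio - 1e-6)
})

test_that("csp_fit rejects degenerate inputs", {
  ep <- array(rnorm(4 * 2 * 30), c(4, 2, 30))
  expect_error(csp_fit(ep, c(0, 0, 0, 0), 2), class = "amanet_data_error")
  expect_error(csp_fit(ep, c(0, 0, 0, 1), 2), class = "amanet_data_error")
  expect_error(csp_fit(ep, c(0, 0, 1, 1), 4), class = "amanet_config_error")
  expect_error(csp_fit(ep, c(0, 0, 1, 1), 1), class = "amanet_config_error")
})

test_that("csp_apply is the plain linear projection", {
  fx <- make_diag_cov_windows(c(2, 1), c(1, 2))
  bank <- csp_fit(fx$windows, fx$labels, 2)
  w <- matrix(rnorm(2 * 50), 2)
  expect_equal(csp_apply(bank, w), bank$filters %*% w)
  expect_true(all(csp_apply(bank, matrix(0, 2, 50)) == 0))
  # identity bank
  id_bank <- structure(list(filters = diag(2), eigenvalues = c(0.5, 0.5),
                            class_of_filter = c(0L, 1L), n_source_channels = 2L),
                       class = "csp_bank")
  expect_equal(csp_apply(id_bank, w), w)
  expect_error(csp_apply(bank, matrix(0, 3, 50)), class = "amanet_dim_error")
  # projected variance ratio on class-0 windows ~ 4:1
  proj <- csp_apply(bank, fx$windows[1, , ])
  expect_equal(stats::var(proj[1, ]) / stats::var(proj[2, ]), 4, tolerance = 0.05)
})

test_that("amplitude scaling is exact and bounded", {
  w <- matrix(sin(seq(0, 4 * pi, length.out = 100)), 1)
  expect_identical(amplitude_scale(w, 1), w)
  expect_equal(max(abs(amplitude_scale(w, 0.9))), 0.9 * max(abs(w)))
  expect_error(amplitude_scale(w, 0), class = "amanet_scale_error")
  expect_error(amplitude_scale(w, -1), class = "amanet_scale_error")
  cfg <- aug_config()
  betas <- amanet:::with_seed(1L, amanet:::draw_betas(1e4, cfg))
  expect_true(all(betas >= 0.9 & betas <= 1.1))
  cfg_tn <- aug_config(beta_distribution = "truncated-normal")
  betas_tn <- amanet:::with_seed(1L, amanet:::draw_betas(1e4, cfg_tn))
  expect_true(all(betas_tn >= 0.9 & betas_tn <= 1.1))
})

test_that("augment windows, fits on train only, and scales train only", {
  ts <- tiny_easy_trialset(n_per_class = 20L)   # 40 trials, T = 1000
  tr_idx <- c(1:15, 21:35); te_idx <- setdiff(1:40, tr_idx)
  tr <- amanet:::subset_trials(ts, tr_idx)
  te <- amanet:::subset_trials(ts, te_idx)
  cfg <- aug_config(n_pairs = 1L, seed = 9L)
  aug <- augment(tr, te, cfg)
  expect_equal(dim(aug$train$data), c(150L, 2L, 500L))   # 30 trials x 5 windows
  expect_equal(dim(aug$test$data), c(50L, 2L, 500L))
  # windows of one trial share label and source id
  expect_true(all(tapply(aug$train$labels, aug$train$source_trial,
                         function(l) length(unique(l)) == 1)))
  # test windows are the unscaled CSP projections
  te_raw <- amanet:::window_trialset(te, cfg)
  expect_equal(aug$test$data, csp_apply(aug$bank, te_raw$data))
  # train windows are the projections times per-window factors in [0.9, 1.1]
  tr_raw <- csp_apply(aug$bank, amanet:::window_trialset(tr, cfg)$data)
  ratio <- aug$train$data / tr_raw
  per_window <- apply(ratio, 1, function(m) diff(range(m)))
  expect_true(all(per_window < 1e-9))
  expect_true(all(ratio >= 0.9 - 1e-9 & ratio <= 1.1 + 1e-9))
  # determinism
  aug2 <- augment(tr, te, cfg)
  expect_identical(aug$train$data, aug2$train$data)
  expect_identical(aug$bank$filters, aug2$bank$filters)
})

test_that("augment flags a test class missing from training", {
  ts <- tiny_easy_trialset(n_per_class = 6L)
  tr <- amanet:::subset_trials(ts, 1:6)        # class 0 only
  te <- amanet:::subset_trials(ts, 7:12)       # class 1 only
  expect_warning(
    expect_error(augment(tr, te, aug_config(n_pairs = 1L)),
                 class = "amanet_data_error"),  # CSP needs 2 classes in train
    "absent")
  # without CSP the pipeline proceeds with a warning only
  expect_warning(aug <- augment(tr, te, aug_config(use_csp = FALSE)), "absent")
  expect_equal(dim(aug$train$data)[2], 6L)
})
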