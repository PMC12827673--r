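# Metrics, fold mechanics, ablation presets and the sweep harness.
# Training-heavy end-to-end behavior lives in test-acceptance.R; runs here
# use one or two epochs purely to exercise the plumbing.

test_that("confusion_matrix counts truth by prediction", {
  expect_equal(confusion_matrix(c(0, 0, 1, 1), c(0, 0, 1, 1), 2),
               matrix(c(2L, 0L, 0L, 2L), 2, byrow = TRUE))
  expect_equal(confusion_matrix(c(0, 0, 1, 1), c(0, 0, 0, 0), 2),
               matrix(c(2L, 0L, 2L, 0L), 2, byrow = TRUE))
  expect_equal(confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2),
               matrix(c(1L, 1L, 0L, 2L), 2, byrow = TRUE))
  expect_error(confusion_matrix(c(0, 2), c(0, 0), 2), class = "amanet_data_error")
  expect_error(confusion_matrix(c(0, 1), c(0), 2), class = "amanet_dim_error")
})

test_that("cohen_kappa follows the chance-corrected formula", {
  expect_equal(cohen_kappa(diag(c(10, 20, 30))), 1)
  expect_equal(cohen_kappa(matrix(c(40, 10, 20, 30), 2, byrow = TRUE)), 0.4)
  expect_equal(cohen_kappa(matrix(c(50, 0, 50, 0), 2, byrow = TRUE)), 0)
  expect_error(cohen_kappa(matrix(c(-1, 0, 0, 1), 2)), class = "amanet_data_error")
  expect_error(cohen_kappa(matrix(0, 2, 2)), class = "amanet_data_error")
  # invariance under simultaneous row/column permutation
  set.seed(6)
  for (i in 1:20) {
    cm <- matrix(rpois(16, 8), 4)
    p <- sample(4)
    expect_equal(cohen_kappa(cm[p, p]), cohen_kappa(cm))
  }
})

test_that("stratified folds partition trials and respect class balance", {
  labels <- rep(0:3, each = 25)
  assign <- amanet:::stratified_folds(labels, 10L, 1234L)
  expect_equal(sort(unique(assign)), 1:10)
  for (f in 1:10) {
    idx <- which(assign == f)
    # 25 trials per class dealt round-robin: 2 or 3 per class per fold
    counts <- as.integer(table(factor(labels[idx], levels = 0:3)))
    expect_true(all(counts %in% 2:3))
    expect_equal(sum(counts), length(idx))
  }
  expect_equal(length(assign), 100L)
  expect_identical(assign, amanet:::stratified_folds(labels, 10L, 1234L))
  expect_false(identical(assign, amanet:::stratified_folds(labels, 10L, 99L)))
  expect_error(amanet:::stratified_folds(rep(0:1, each = 3), 10L, 1L),
               class = "amanet_data_error")
})

test_that("cross_validate partitions cleanly and aggregates fold metrics", {
  ts <- tiny_easy_trialset(n_per_class = 6L, n_channels = 4L)
  acfg <- aug_config(n_pairs = 1L, seed = 1L)
  mcfg <- model_config(in_channels = 2L, n_classes = 2L, F1 = 4L, F2 = 8L,
                       fc_width = 8L, seed = 5L)
  tcfg <- train_config(epochs = 2L, folds = 2L, seed = 77L)
  rep1 <- cross_validate(ts, acfg, mcfg, tcfg)
  expect_length(rep1$folds, 2L)
  vals <- sort(unlist(lapply(rep1$folds, `[[`, "val_trials")))
  expect_identical(vals, 1:12)                    # disjoint and exhaustive
  expect_equal(rep1$mean_accuracy,
               mean(vapply(rep1$folds, `[[`, numeric(1), "window_accuracy")))
  expect_equal(rep1$mean_kappa,
               mean(vapply(rep1$folds, `[[`, numeric(1), "kappa")))
  # confusion row sums equal the validation window counts per class
  for (f in rep1$folds)
    expect_equal(sum(f$confusion), 6L * 5L)       # 6 val trials x 5 windows
  # leakage audit: CSP fingerprint excludes validation trials by construction
  expect_false(any(is.na(vapply(rep1$folds, `[[`, character(1), "bank_hash"))))
})

test_that("train_fold errors on empty splits and is fully seeded", {
  ts <- tiny_easy_trialset(n_per_class = 4L, n_channels = 4L)
  aug <- augment(ts, ts, aug_config(n_pairs = 1L))
  mcfg <- model_config(in_channels = 2L, n_classes = 2L, F1 = 2L, F2 = 4L,
                       fc_width = 4L, seed = 2L)
  tcfg <- train_config(epochs = 2L, seed = 11L)
  f1 <- train_fold(aug$train, aug$test, mcfg, tcfg)
  f2 <- train_fold(aug$train, aug$test, mcfg, tcfg)
  expect_identical(f1$loss_curve, f2$loss_curve)
  expect_identical(f1$confusion, f2$confusion)
  empty <- epoch_set(array(0, c(0, 2, 500)), integer(0), integer(0), 250)
  expect_error(train_fold(empty, aug$test, mcfg, tcfg),
               class = "amanet_data_error")
})

test_that("ablation presets map to the published variants", {
  am <- ablation_variant("AMANet")
  expect_true(all(unlist(am$spec[c("use_csp", "use_eca", "use_multiscale",
                                   "use_st_block", "use_dsf_block",
                                   "use_augment_scaling", "expand_windows")])))
  amn <- ablation_variant("AMNet")
  expect_true(amn$spec$use_csp); expect_false(amn$spec$use_eca)
  expect_true(amn$spec$expand_windows)
  wma <- ablation_variant("WMANet")
  expect_true(wma$spec$use_eca); expect_false(wma$spec$use_csp)
  wm <- ablation_variant("WMNet")
  expect_false(wm$spec$use_csp); expect_false(wm$spec$use_eca)
  cm <- ablation_variant("CMNet")
  expect_true(cm$spec$use_csp); expect_false(cm$spec$expand_windows)
  expect_false(cm$spec$use_augment_scaling)
  nms <- ablation_variant("no-multiscale")
  expect_false(nms$spec$use_multiscale)
  expect_error(ablation_variant("FooNet"), class = "amanet_config_error")
  expect_error(ablation_variant("FooNet"), "WMANet")
})

test_that("apply_ablation reverts channels when CSP is off", {
  mcfg <- model_config()
  acfg <- aug_config()
  p <- apply_ablation(ablation_variant("WMNet"), mcfg, acfg, raw_channels = 22L)
  expect_equal(p$mcfg$in_channels, 22L)
  expect_false(p$acfg$use_csp)
  expect_error(apply_ablation(ablation_variant("WMNet"), mcfg, acfg),
               class = "amanet_config_error")
  # CMNet: one centred window, no scaling, CSP retained
  p2 <- apply_ablation(ablation_variant("CMNet"), mcfg, acfg, raw_channels = 22L)
  expect_false(p2$acfg$expand_windows)
  expect_true(p2$acfg$use_csp)
})

test_that("the sweep harness crosses grids and reports window counts", {
  ts <- tiny_easy_trialset(n_per_class = 4L, n_channels = 4L)
  acfg <- aug_config(n_pairs = 1L, seed = 1L)
  mcfg <- model_config(in_channels = 2L, n_classes = 2L, F1 = 2L, F2 = 4L,
                       fc_width = 4L, seed = 5L)
  tcfg <- train_config(epochs = 1L, folds = 2L, seed = 3L)
  tab <- run_sweep(list(window_size = c(500L), stride = c(125L, 250L)),
                   ts, acfg, mcfg, tcfg)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$n_windows, c(5L, 3L))       # closed-form counts, T=1000
  expect_true(all(c("mean_acc", "sd_acc", "mean_kappa") %in% names(tab)))
  expect_error(run_sweep(list(bogus = 1), ts, acfg, mcfg, tcfg),
               class = "amanet_config_error")
})

test_that("attention 'none' equals the no-attention model, extensions register", {
  ts <- tiny_easy_trialset(n_per_class = 4L, n_channels = 4L)
  acfg <- aug_config(n_pairs = 1L, seed = 1L)
  mcfg <- model_config(in_channels = 2L, n_classes = 2L, F1 = 2L, F2 = 4L,
                       fc_width = 4L, seed = 5L)
  tcfg <- train_config(epochs = 1L, folds = 2L, seed = 3L)
  tab <- run_sweep(list(attention = c("none")), ts, acfg, mcfg, tcfg)
  mcfg_off <- model_config(in_channels = 2L, n_classes = 2L, F1 = 2L, F2 = 4L,
                           fc_width = 4L, use_eca = FALSE, seed = 5L)
  direct <- cross_validate(ts, acfg, mcfg_off, tcfg)
  expect_identical(tab$mean_acc, direct$mean_accuracy)
  expect_error(run_sweep(list(attention = c("se")), ts, acfg, mcfg, tcfg),
               class = "amanet_config_error")
  register_attention("se", function(m) { m$use_eca <- FALSE; m })
  tab_se <- run_sweep(list(attention = c("se")), ts, acfg, mcfg, tcfg)
  expect_identical(tab_se$mean_acc, direct$mean_accuracy)
})

test_that("paired permutation utility returns sane p-values", {
  set.seed(1)
  a <- rnorm(12, 3); b <- rnorm(12, 0)
  expect_lt(paired_permutation_test(a, b, 2000L), 0.05)
  expect_gt(paired_permutation_test(a, a + rnorm(12, 0, 1e-3), 2000L), 0.1)
})
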