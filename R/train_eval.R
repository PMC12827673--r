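# Training protocol, metrics, leakage-safe cross-validation, ablation presets
# and the parameter-sweep harness.

#' Training configuration
#'
#' Defaults mirror the reference protocol: Adam, learning rate 0.001,
#' batch size 32, 300 epochs, dropout 0.3, seed 1234, 10 folds, no early
#' stopping. Metrics are reported at the final epoch.
#'
#' @param lr learning rate.
#' @param batch_size mini-batch size.
#' @param epochs training epochs (no early stopping).
#' @param folds cross-validation folds.
#' @param seed integer master seed for fold assignment, batching and dropout.
#' @param report_best report metrics from the best validation epoch instead
#'   of the final one (off by default; evaluating every epoch is slower).
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, batch_size = 32L, epochs = 300L,
                         folds = 10L, seed = 1234L, report_best = FALSE) {
  if (!is.numeric(lr) || lr <= 0)
    amanet_abort("amanet_config_error", "lr must be positive")
  if (!is_count(epochs))
    amanet_abort("amanet_config_error", "epochs must be >= 1")
  if (!is_count(folds, 2L))
    amanet_abort("amanet_config_error", "folds must be >= 2")
  if (!is_count(batch_size))
    amanet_abort("amanet_config_error", "batch_size must be >= 1")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 seed = as.integer(seed), report_best = isTRUE(report_best)),
            class = "train_config")
}

#' Confusion matrix of predicted against true labels
#'
#' @param true_labels,predicted_labels equal-length integer vectors of class
#'   ids in `0 .. n_classes-1`.
#' @param n_classes number of classes K.
#' @return `K x K` integer matrix; entry `(i, j)` counts true class `i-1`
#'   predicted as class `j-1`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes) {
  if (length(true_labels) != length(predicted_labels))
    amanet_abort("amanet_dim_error", "label vectors must have equal length")
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  if (any(true_labels < 0 | true_labels >= n_classes) ||
      any(predicted_labels < 0 | predicted_labels >= n_classes))
    amanet_abort("amanet_data_error", sprintf(
      "labels must lie in 0 .. %d", n_classes - 1L))
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true_labels)) {
    cm[true_labels[i] + 1L, predicted_labels[i] + 1L] <-
      cm[true_labels[i] + 1L, predicted_labels[i] + 1L] + 1L
  }
  cm
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace / total` and chance agreement
#' `p_e = sum_i row_i * col_i / total^2`. Returns 0 when `p_e = 1` and
#' `p_o = p_e` (degenerate single-cell case).
#'
#' @param confusion `K x K` matrix of non-negative counts.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0))
    amanet_abort("amanet_data_error", "confusion counts must be non-negative")
  total <- sum(confusion)
  if (total <= 0)
    amanet_abort("amanet_data_error", "confusion matrix must contain counts")
  po <- sum(diag(confusion)) / total
  pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    if (abs(po - pe) < .Machine$double.eps^0.5) return(0)
    return(sign(po - pe))
  }
  (po - pe) / (1 - pe)
}

# evaluate a model on an epoch set: window accuracy, trial majority vote,
# kappa and confusion matrix (all window-level except trial_accuracy)
evaluate_epochs <- function(model, epochs, batch = 256L) {
  n <- dim(epochs$data)[1]
  K <- model$cfg$n_classes
  preds <- integer(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    lg <- model_forward(model, epochs$data[i:j, , , drop = FALSE])
    preds[i:j] <- max.col(lg, ties.method = "first") - 1L
    i <- j + 1L
  }
  cm <- confusion_matrix(epochs$labels, preds, K)
  # trial-level majority vote; ties resolved toward the lowest class id
  trials <- unique(epochs$source_trial)
  hit <- 0L
  for (tr in trials) {
    idx <- which(epochs$source_trial == tr)
    tab <- tabulate(preds[idx] + 1L, nbins = K)
    vote <- which.max(tab) - 1L
    if (vote == epochs$labels[idx[1]]) hit <- hit + 1L
  }
  list(window_accuracy = sum(diag(cm)) / sum(cm),
       trial_accuracy = hit / length(trials),
       kappa = cohen_kappa(cm), confusion = cm, predictions = preds)
}

#' Train the network on one training/validation split
#'
#' Mini-batch Adam with softmax cross-entropy computed from the raw logits;
#' no early stopping; metrics reported at the final epoch. Fully seeded: the
#' same inputs and seed reproduce the loss curve bit for bit.
#'
#' @param train_epochs,val_epochs [epoch_set()] objects; their source-trial
#'   ids must be disjoint.
#' @param mcfg a [model_config()].
#' @param tcfg a [train_config()].
#' @param fold_id identifier stored in the result.
#' @return a `fold_result` list: `fold_id`, `window_accuracy`,
#'   `trial_accuracy` (majority vote over a trial's windows), `kappa`,
#'   `confusion` (window-level counts) and `loss_curve`.
#' @export
train_fold <- function(train_epochs, val_epochs, mcfg, tcfg, fold_id = 1L) {
  if (dim(train_epochs$data)[1] < 1 || dim(val_epochs$data)[1] < 1)
    amanet_abort("amanet_data_error", "empty training or validation split")
  model <- build_model(mcfg)
  theta <- flatten_params(model$params)
  opt <- adam_init(length(theta))
  n <- dim(train_epochs$data)[1]
  loss_curve <- numeric(tcfg$epochs)
  labels1 <- train_epochs$labels + 1L
  per_epoch <- attr(train_epochs, "scale_per_epoch")

  with_seed(tcfg$seed + 7L * fold_id, {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      data_ep <- train_epochs$data
      if (!is.null(per_epoch)) {
        cfg_beta <- aug_config(beta_low = per_epoch$beta_low,
                               beta_high = per_epoch$beta_high,
                               beta_distribution = per_epoch$beta_distribution)
        data_ep <- data_ep * draw_betas(n, cfg_beta)
      }
      ep_loss <- 0; nb <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(i + tcfg$batch_size - 1L, n)
        idx <- ord[i:j]
        model$params <- unflatten_params(theta, model$params)
        res <- amanet_pass(model, data_ep[idx, , , drop = FALSE],
                           y = labels1[idx], training = TRUE)
        if (!is.finite(res$loss))
          amanet_abort("amanet_numeric_error", sprintf(
            "non-finite loss at epoch %d; lower the learning rate", ep))
        model$state <- res$state
        g <- flatten_params(res$grads)
        st <- adam_step(theta, g, opt, lr = tcfg$lr)
        theta <- st$theta; opt <- st$state
        ep_loss <- ep_loss + res$loss; nb <- nb + 1L
        i <- j + 1L
      }
      loss_curve[ep] <- ep_loss / nb
    }
  })
  model$params <- unflatten_params(theta, model$params)
  ev <- evaluate_epochs(model, val_epochs)
  structure(list(fold_id = fold_id,
                 window_accuracy = ev$window_accuracy,
                 trial_accuracy = ev$trial_accuracy,
                 kappa = ev$kappa, confusion = ev$confusion,
                 loss_curve = loss_curve, model = model),
            class = "fold_result")
}

# stratified trial-level fold assignment (round-robin after a seeded shuffle)
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_seed(seed, {
    for (k in unique(labels)) {
      idx <- which(labels == k)
      if (length(idx) < folds)
        amanet_abort("amanet_data_error", sprintf(
          "class %d has %d trials; %d folds need at least %d per class",
          k, length(idx), folds, folds))
      idx <- sample(idx)
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

subset_trials <- function(ts, idx) {
  raw_trialset(ts$data[idx, , , drop = FALSE], ts$labels[idx], ts$sfreq,
               ts$channel_names)
}

#' Stratified trial-level k-fold cross-validation
#'
#' Trials (never windows) are dealt into stratified folds, so all windows of
#' a trial stay on one side of every split and the CSP bank is fitted on the
#' training folds only. Each fold's bank fingerprint is checked against the
#' validation trial ids (leakage audit) before training.
#'
#' @param trials a [raw_trialset()].
#' @param acfg an [aug_config()].
#' @param mcfg a [model_config()].
#' @param tcfg a [train_config()].
#' @return a `cv_report` list with per-fold `fold_result`s and aggregate
#'   mean/sd accuracy and kappa.
#' @export
cross_validate <- function(trials, acfg, mcfg, tcfg) {
  assign <- stratified_folds(trials$labels, tcfg$folds, tcfg$seed)
  folds <- vector("list", tcfg$folds)
  for (fold in seq_len(tcfg$folds)) {
    val_idx <- which(assign == fold)
    tr_idx <- which(assign != fold)
    aug <- augment(subset_trials(trials, tr_idx), subset_trials(trials, val_idx),
                   acfg)
    # leakage audit: the bank must have been fitted on training trials only
    if (!is.null(aug$bank)) {
      fit_src <- tr_idx[attr(aug$bank, "fit_trial_ids")]
      if (length(intersect(fit_src, val_idx)) > 0)
        amanet_abort("amanet_leakage_error",
                     "CSP bank was fitted on validation trials")
    }
    mcfg_fold <- mcfg
    mcfg_fold$seed <- mcfg$seed + fold
    folds[[fold]] <- train_fold(aug$train, aug$test, mcfg_fold, tcfg,
                                fold_id = fold)
    folds[[fold]]$val_trials <- val_idx
    folds[[fold]]$bank_hash <- if (is.null(aug$bank)) NA_character_ else
      attr(aug$bank, "fit_hash")
  }
  acc <- vapply(folds, `[[`, numeric(1), "window_accuracy")
  kap <- vapply(folds, `[[`, numeric(1), "kappa")
  tac <- vapply(folds, `[[`, numeric(1), "trial_accuracy")
  structure(list(
    folds = folds,
    mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
    mean_kappa = mean(kap), sd_kappa = stats::sd(kap),
    mean_trial_accuracy = mean(tac),
    fold_assignment = assign,
    split_level = "trial",
    n_folds = tcfg$folds
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d folds (trial-level, stratified)\n", x$n_folds))
  cat(sprintf("  window accuracy: %.4f +/- %.4f\n", x$mean_accuracy, x$sd_accuracy))
  cat(sprintf("  trial accuracy : %.4f\n", x$mean_trial_accuracy))
  cat(sprintf("  kappa          : %.4f +/- %.4f\n", x$mean_kappa, x$sd_kappa))
  invisible(x)
}

#' Named ablation variants
#'
#' The five architecture variants: `WMNet` (windowing only: no CSP, no
#' attention), `WMANet` (attention without CSP), `CMNet` (CSP without window
#' expansion or scaling), `AMNet` (CSP plus augmentation, no attention) and
#' `AMANet` (everything). Module-level toggles are exposed as `no-multiscale`,
#' `no-attention`, `no-augment`, `no-st`, `no-dsf` (a disabled block is
#' replaced by a shape-preserving pass-through; the multi-scale block by its
#' middle single-kernel branch).
#'
#' @param name one of the labels above.
#' @return list with `spec` (logical flags and the name), `model` (named list
#'   of [model_config()] overrides) and `aug` (overrides for [aug_config()]).
#' @export
ablation_variant <- function(name) {
  presets <- list(
    WMNet   = list(use_csp = FALSE, use_eca = FALSE, expand = TRUE,  scaling = TRUE),
    WMANet  = list(use_csp = FALSE, use_eca = TRUE,  expand = TRUE,  scaling = TRUE),
    CMNet   = list(use_csp = TRUE,  use_eca = TRUE,  expand = FALSE, scaling = FALSE),
    AMNet   = list(use_csp = TRUE,  use_eca = FALSE, expand = TRUE,  scaling = TRUE),
    AMANet  = list(use_csp = TRUE,  use_eca = TRUE,  expand = TRUE,  scaling = TRUE),
    `no-multiscale` = list(use_multiscale = FALSE),
    `no-attention`  = list(use_eca = FALSE),
    `no-augment`    = list(expand = FALSE, scaling = FALSE),
    `no-st`         = list(use_st_block = FALSE),
    `no-dsf`        = list(use_dsf_block = FALSE)
  )
  if (!name %in% names(presets))
    amanet_abort("amanet_config_error", sprintf(
      "unknown ablation '%s'; valid names: %s", name,
      paste(names(presets), collapse = ", ")))
  pr <- presets[[name]]
  spec <- list(name = name,
               use_augment_scaling = pr$scaling %||% TRUE,
               use_csp = pr$use_csp %||% TRUE,
               use_multiscale = pr$use_multiscale %||% TRUE,
               use_eca = pr$use_eca %||% TRUE,
               use_st_block = pr$use_st_block %||% TRUE,
               use_dsf_block = pr$use_dsf_block %||% TRUE,
               expand_windows = pr$expand %||% TRUE)
  model <- list(use_multiscale = spec$use_multiscale, use_eca = spec$use_eca,
                use_st_block = spec$use_st_block,
                use_dsf_block = spec$use_dsf_block)
  aug <- list(use_csp = spec$use_csp, expand_windows = spec$expand_windows)
  list(spec = spec, model = model, aug = aug)
}

#' Apply ablation overrides to a configuration pair
#'
#' When CSP is disabled the network's input channel count reverts to the raw
#' montage size, which the caller must supply.
#'
#' @param variant an [ablation_variant()] result.
#' @param mcfg a [model_config()].
#' @param acfg an [aug_config()].
#' @param raw_channels raw channel count used when CSP is off.
#' @return list with patched `mcfg` and `acfg`.
#' @export
apply_ablation <- function(variant, mcfg, acfg, raw_channels = NULL) {
  m <- as.list(mcfg); a <- as.list(acfg)
  for (nm in names(variant$model)) m[[nm]] <- variant$model[[nm]]
  for (nm in names(variant$aug)) a[[nm]] <- variant$aug[[nm]]
  if (!a$use_csp) {
    if (is.null(raw_channels))
      amanet_abort("amanet_config_error",
                   "raw_channels is required when CSP is disabled")
    m$in_channels <- as.integer(raw_channels)
  }
  list(mcfg = do.call(model_config, m[names(formals(model_config))]),
       acfg = do.call(aug_config, a[names(formals(aug_config))]))
}

# attention plug-in registry: sweep cells other than {eca, none} must be
# registered extensions
.attention_registry <- new.env(parent = emptyenv())

#' Register an attention mechanism for the sweep harness
#'
#' @param name label used in sweep grids.
#' @param patch function `(mcfg) -> mcfg` applied before building the model.
#' @export
register_attention <- function(name, patch) {
  if (!is.function(patch))
    amanet_abort("amanet_config_error", "patch must be a function")
  assign(name, patch, envir = .attention_registry)
  invisible(name)
}

resolve_attention <- function(name, mcfg) {
  if (name == "eca") { mcfg$use_eca <- TRUE; return(mcfg) }
  if (name == "none") { mcfg$use_eca <- FALSE; return(mcfg) }
  if (exists(name, envir = .attention_registry)) {
    return(get(name, envir = .attention_registry)(mcfg))
  }
  amanet_abort("amanet_config_error", sprintf(
    "attention '%s' is not registered; built-ins are 'eca' and 'none'", name))
}

#' Run a parameter sweep
#'
#' Crosses the supplied grid, patches the base configurations per cell, runs
#' [cross_validate()] on each and returns a tidy table. Supported keys:
#' `ms_kernels` (list of triplets), `attention` (`"eca"`, `"none"` or a
#' registered extension), `window_size`, `stride`, `F1`, `F2`, `K1`, `K2`,
#' `fc`.
#'
#' @param grid named list of parameter value vectors/lists.
#' @param trials a [raw_trialset()].
#' @param acfg,mcfg,tcfg base configurations.
#' @return data.frame with one row per cell: the grid values plus
#'   `mean_acc`, `sd_acc` and `mean_kappa`.
#' @export
run_sweep <- function(grid, trials, acfg, mcfg, tcfg) {
  allowed <- c("ms_kernels", "attention", "window_size", "stride",
               "F1", "F2", "K1", "K2", "fc")
  bad <- setdiff(names(grid), allowed)
  if (length(bad) > 0)
    amanet_abort("amanet_config_error", sprintf(
      "unknown grid key(s): %s (allowed: %s)",
      paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  cells <- expand.grid(lapply(grid, seq_along))
  rows <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    m <- as.list(mcfg); a <- as.list(acfg)
    lab <- list()
    for (key in names(grid)) {
      val <- grid[[key]][[cells[r, key]]]
      lab[[key]] <- if (length(val) > 1) paste(val, collapse = "-") else val
      if (key == "ms_kernels") m$ms_kernels <- val
      else if (key == "attention") NULL        # applied after model_config
      else if (key == "window_size") { a$window_size <- val; m$in_samples <- val }
      else if (key == "stride") a$stride <- val
      else if (key == "fc") m$fc_width <- val
      else m[[key]] <- val
    }
    mc <- do.call(model_config, m[names(formals(model_config))])
    if ("attention" %in% names(grid))
      mc <- resolve_attention(lab$attention, mc)
    ac <- do.call(aug_config, a[names(formals(aug_config))])
    rep <- cross_validate(trials, ac, mc, tcfg)
    n_windows <- (dim(trials$data)[3] - ac$window_size) %/% ac$stride + 1L
    rows[[r]] <- data.frame(lab, n_windows = n_windows,
                            mean_acc = rep$mean_accuracy,
                            sd_acc = rep$sd_accuracy,
                            mean_kappa = rep$mean_kappa,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Paired permutation test on per-fold accuracies (utility stub)
#'
#' Sign-flip permutation test for the mean difference of paired scores.
#' Provided as a convenience; no claims are made about the reference
#' protocol's significance procedure.
#'
#' @param a,b equal-length numeric vectors of paired scores.
#' @param n_perm number of sign permutations.
#' @param seed RNG seed.
#' @return two-sided p-value.
#' @export
paired_permutation_test <- function(a, b, n_perm = 10000L, seed = 1L) {
  if (length(a) != length(b))
    amanet_abort("amanet_dim_error", "a and b must have equal length")
  d <- a - b
  obs <- mean(d)
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      flip <- sample(c(-1, 1), length(d), replace = TRUE)
      if (abs(mean(flip * d)) >= abs(obs)) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
}
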