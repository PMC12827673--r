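# Data-augmentation block: sliding-window segmentation, CSP spatial filtering
# (generalized eigendecomposition of class covariances), and amplitude-scaling
# augmentation, with a strict fit-on-train / apply-on-test contract.

#' Augmentation configuration
#'
#' @param window_size sliding-window length T1 in samples (default 500).
#' @param stride window stride in samples (default 125). Note: at trial length
#'   1000 the (500, 125) pair yields exactly five overlapping sub-windows.
#' @param n_pairs number of CSP filter pairs to retain; the projected channel
#'   count is `C1 = 2 * n_pairs` (12 for the four-class default, 2 for the
#'   binary montage with `n_pairs = 1`).
#' @param beta_low,beta_high bounds of the amplitude scaling factor beta
#'   (default 0.9 and 1.1, i.e. 90--110% of the original amplitude).
#' @param beta_distribution `"uniform"` on `[beta_low, beta_high]` or
#'   `"truncated-normal"` (mean 1, sd `(beta_high - beta_low)/6`, clipped).
#' @param scale_train_only apply amplitude scaling to training windows only
#'   (default `TRUE`); test windows are never perturbed.
#' @param scale_per_epoch if `TRUE` the scaling factors are resampled every
#'   training epoch instead of being frozen at augmentation time.
#' @param use_csp fit and apply CSP spatial filters (default `TRUE`); disabled
#'   by the no-CSP ablation variants, in which case windows keep their raw
#'   channel dimension.
#' @param expand_windows if `FALSE` only one centred window per trial is cut
#'   and no scaling is applied (the "no data augmentation" ablation).
#' @param ridge relative diagonal loading added to the composite covariance
#'   before the eigendecomposition, for rank safety.
#' @param seed integer seed driving the scaling draws.
#' @return an object of class `aug_config`.
#' @export
aug_config <- function(window_size = 500L, stride = 125L, n_pairs = 6L,
                       beta_low = 0.9, beta_high = 1.1,
                       beta_distribution = c("uniform", "truncated-normal"),
                       scale_train_only = TRUE, scale_per_epoch = FALSE,
                       use_csp = TRUE, expand_windows = TRUE,
                       ridge = 1e-8, seed = 1L) {
  beta_distribution <- match.arg(beta_distribution)
  if (!is_count(window_size) || !is_count(stride))
    amanet_abort("amanet_config_error", "window_size and stride must be positive integers")
  if (stride > window_size)
    amanet_abort("amanet_config_error", sprintf(
      "stride (%d) must not exceed window_size (%d)", stride, window_size))
  if (!(beta_low <= 1 && 1 <= beta_high))
    amanet_abort("amanet_config_error", "scaling bounds must satisfy beta_low <= 1 <= beta_high")
  if (!is_count(n_pairs))
    amanet_abort("amanet_config_error", "n_pairs must be a positive integer")
  structure(list(
    window_size = as.integer(window_size), stride = as.integer(stride),
    n_pairs = as.integer(n_pairs), beta_low = beta_low, beta_high = beta_high,
    beta_distribution = beta_distribution,
    scale_train_only = isTRUE(scale_train_only),
    scale_per_epoch = isTRUE(scale_per_epoch),
    use_csp = isTRUE(use_csp), expand_windows = isTRUE(expand_windows),
    ridge = ridge, seed = as.integer(seed)
  ), class = "aug_config")
}

#' Segment one trial into overlapping sliding windows
#'
#' Windows start at offsets `0, stride, 2*stride, ...`; only complete windows
#' are emitted, so the count is `floor((T - window_size)/stride) + 1`.
#'
#' @param trial `channels x samples` matrix.
#' @param window_size window length in samples.
#' @param stride hop between window starts in samples.
#' @return array `n_windows x channels x window_size`, with the zero-based
#'   start offsets in attribute `"starts"`.
#' @export
sliding_window <- function(trial, window_size, stride) {
  trial <- as.matrix(trial)
  Tn <- ncol(trial)
  if (window_size > Tn)
    amanet_abort("amanet_dim_error", sprintf(
      "window_size (%d) exceeds trial length (%d)", window_size, Tn))
  if (stride < 1)
    amanet_abort("amanet_config_error", "stride must be >= 1")
  nw <- (Tn - window_size) %/% stride + 1L
  starts <- (seq_len(nw) - 1L) * stride
  out <- array(0, dim = c(nw, nrow(trial), window_size))
  for (i in seq_len(nw)) out[i, , ] <- trial[, (starts[i] + 1):(starts[i] + window_size)]
  attr(out, "starts") <- starts
  out
}

# per-window spatial covariance, normalized by its trace
window_cov <- function(w) {
  S <- tcrossprod(w)
  S / sum(diag(S))
}

class_mean_cov <- function(epochs, idx) {
  C <- dim(epochs)[2]
  S <- matrix(0, C, C)
  for (i in idx) S <- S + window_cov(epochs[i, , ])
  S / length(idx)
}

# Solve the two-matrix CSP problem Sa w = lambda (Sa + Sb) w by whitening.
# Returns filters (rows, eigenvalue-descending) and eigenvalues in [0, 1].
csp_pairwise <- function(Sa, Sb, ridge) {
  Sc <- Sa + Sb
  Sc <- Sc + diag(ridge * mean(diag(Sc)), nrow(Sc))
  ec <- eigen(Sc, symmetric = TRUE)
  if (min(ec$values) <= 0)
    amanet_abort("amanet_numeric_error", paste(
      "composite covariance is singular; increase the ridge term",
      "(aug_config(ridge = ...)) or supply more/longer windows"))
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)   # whitener: P Sc P' = I
  S1 <- P %*% Sa %*% t(P)
  S1 <- (S1 + t(S1)) / 2
  e1 <- eigen(S1, symmetric = TRUE)                  # descending eigenvalues
  W <- t(e1$vectors) %*% P                           # rows are spatial filters
  list(W = W, lambda = e1$values)
}

fix_filter_signs <- function(W) {
  for (r in seq_len(nrow(W))) {
    j <- which.max(abs(W[r, ]))
    if (W[r, j] < 0) W[r, ] <- -W[r, ]
  }
  W
}

#' Fit a CSP spatial filter bank
#'
#' For two classes the per-class trace-normalized average covariances
#' `S1, S2` define the generalized eigenproblem `S1 w = lambda (S1 + S2) w`;
#' the `n_components/2` filters with the largest and smallest eigenvalues
#' (the discriminative "pairs") are retained. For more than two classes a
#' one-vs-rest decomposition is used: for each class the
#' `n_components/n_classes` eigenvectors with the largest eigenvalue of the
#' class-vs-rest problem are kept (variance-maximizing for that class).
#'
#' @param epochs `windows x channels x samples` array.
#' @param labels integer class ids, one per window.
#' @param n_components total number of spatial filters C1 (even for binary;
#'   a multiple of the class count otherwise).
#' @param ridge relative diagonal loading for rank safety (default 1e-8).
#' @return an object of class `csp_bank` with elements `filters`
#'   (`C1 x C` projection matrix, each row sign-fixed so its
#'   largest-magnitude coefficient is positive), `eigenvalues`,
#'   `class_of_filter` (provenance class id per row) and `n_source_channels`.
#' @export
csp_fit <- function(epochs, labels, n_components, ridge = 1e-8) {
  if (length(dim(epochs)) != 3L)
    amanet_abort("amanet_dim_error", "epochs must be a windows x channels x samples array")
  labels <- as.integer(labels)
  if (length(labels) != dim(epochs)[1])
    amanet_abort("amanet_dim_error", "labels length must equal the number of windows")
  C <- dim(epochs)[2]
  classes <- sort(unique(labels))
  K <- length(classes)
  if (K < 2L)
    amanet_abort("amanet_data_error", "csp_fit needs at least two classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L))
    amanet_abort("amanet_data_error", sprintf(
      "class %s has fewer than 2 windows", names(counts)[which.min(counts)]))
  if (n_components > C)
    amanet_abort("amanet_config_error", sprintf(
      "n_components (%d) cannot exceed channel count (%d)", n_components, C))
  covs <- lapply(classes, function(k) class_mean_cov(epochs, which(labels == k)))

  if (K == 2L) {
    if (n_components %% 2L != 0L)
      amanet_abort("amanet_config_error", "n_components must be even for two classes")
    sol <- csp_pairwise(covs[[1]], covs[[2]], ridge)
    half <- n_components %/% 2L
    take <- c(seq_len(half), nrow(sol$W) - rev(seq_len(half)) + 1L)
    W <- sol$W[take, , drop = FALSE]
    lambda <- sol$lambda[take]
    cls <- rep(classes, each = half)
  } else {
    if (n_components %% K != 0L)
      amanet_abort("amanet_config_error", sprintf(
        "n_components (%d) must be a multiple of the class count (%d)", n_components, K))
    per <- n_components %/% K
    W <- NULL; lambda <- c(); cls <- c()
    for (ki in seq_len(K)) {
      Srest <- Reduce(`+`, covs[-ki]) / (K - 1)
      sol <- csp_pairwise(covs[[ki]], Srest, ridge)
      W <- rbind(W, sol$W[seq_len(per), , drop = FALSE])
      lambda <- c(lambda, sol$lambda[seq_len(per)])
      cls <- c(cls, rep(classes[ki], per))
    }
  }
  structure(list(
    filters = fix_filter_signs(W), eigenvalues = lambda,
    class_of_filter = cls, n_source_channels = C
  ), class = "csp_bank")
}

#' Apply a CSP filter bank to a window
#'
#' @param bank a [csp_fit()] result.
#' @param window `channels x samples` matrix (or `windows x channels x samples`
#'   array, projected window-wise).
#' @return the projected `C1 x samples` matrix (or array).
#' @export
csp_apply <- function(bank, window) {
  if (!inherits(bank, "csp_bank"))
    amanet_abort("amanet_config_error", "bank must be a csp_bank")
  if (length(dim(window)) == 3L) {
    out <- array(0, dim = c(dim(window)[1], nrow(bank$filters), dim(window)[3]))
    for (i in seq_len(dim(window)[1])) out[i, , ] <- csp_apply(bank, window[i, , ])
    return(out)
  }
  window <- as.matrix(window)
  if (nrow(window) != bank$n_source_channels)
    amanet_abort("amanet_dim_error", sprintf(
      "window has %d channels but the bank was fitted on %d",
      nrow(window), bank$n_source_channels))
  bank$filters %*% window
}

#' Scale a window's amplitude by a factor beta
#'
#' Pure element-wise multiplication: the time-frequency structure is
#' unchanged (scaling commutes with linear filtering).
#'
#' @param window numeric matrix or array.
#' @param beta positive scalar scaling factor.
#' @return the scaled window.
#' @export
amplitude_scale <- function(window, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    amanet_abort("amanet_scale_error", "beta must be a positive finite scalar")
  window * beta
}

draw_betas <- function(n, cfg) {
  if (cfg$beta_distribution == "uniform") {
    stats::runif(n, cfg$beta_low, cfg$beta_high)
  } else {
    sd <- (cfg$beta_high - cfg$beta_low) / 6
    pmin(pmax(stats::rnorm(n, mean = 1, sd = sd), cfg$beta_low), cfg$beta_high)
  }
}

#' Construct a window-level epoch set
#'
#' @param data `windows x channels x samples` array.
#' @param labels per-window class ids.
#' @param source_trial per-window id of the originating trial.
#' @param sfreq sampling rate in Hz.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, source_trial, sfreq) {
  if (length(dim(data)) != 3L)
    amanet_abort("amanet_dim_error", "data must be a windows x channels x samples array")
  if (length(labels) != dim(data)[1] || length(source_trial) != dim(data)[1])
    amanet_abort("amanet_dim_error", "labels and source_trial must have one entry per window")
  structure(list(data = data, labels = as.integer(labels),
                 source_trial = as.integer(source_trial), sfreq = sfreq),
            class = "epoch_set")
}

window_trialset <- function(trials, cfg) {
  d <- dim(trials$data)
  Tn <- d[3]
  if (cfg$expand_windows) {
    nw <- (Tn - cfg$window_size) %/% cfg$stride + 1L
    starts <- (seq_len(nw) - 1L) * cfg$stride
  } else {
    nw <- 1L
    starts <- (Tn - cfg$window_size) %/% 2L     # one centred window
  }
  out <- array(0, dim = c(d[1] * nw, d[2], cfg$window_size))
  labels <- integer(d[1] * nw); src <- integer(d[1] * nw)
  j <- 1L
  for (i in seq_len(d[1])) {
    for (s in starts) {
      out[j, , ] <- trials$data[i, , (s + 1):(s + cfg$window_size)]
      labels[j] <- trials$labels[i]; src[j] <- i
      j <- j + 1L
    }
  }
  epoch_set(out, labels, src, trials$sfreq)
}

#' Run the full augmentation block on a train/test split
#'
#' Slides windows over both sets, fits the CSP bank strictly on the training
#' windows, projects both sets through it, and applies amplitude-scaling
#' augmentation to the training windows only (under the default
#' `scale_train_only = TRUE`). The returned bank carries a leakage-audit
#' fingerprint of the trial indices it was fitted on.
#'
#' @param train,test [raw_trialset()] objects sharing channel count, trial
#'   length and sampling rate.
#' @param cfg an [aug_config()].
#' @return list with elements `train` and `test` ([epoch_set()]s) and `bank`
#'   (the fitted [csp_fit()] bank, or `NULL` when `cfg$use_csp` is `FALSE`).
#' @export
augment <- function(train, test, cfg) {
  if (!inherits(train, "raw_trialset") || !inherits(test, "raw_trialset"))
    amanet_abort("amanet_config_error", "train and test must be raw_trialset objects")
  if (!identical(dim(train$data)[2:3], dim(test$data)[2:3]) ||
      !isTRUE(all.equal(train$sfreq, test$sfreq)))
    amanet_abort("amanet_dim_error", "train and test must share channels, samples and sfreq")
  if (cfg$window_size > dim(train$data)[3])
    amanet_abort("amanet_dim_error", sprintf(
      "window_size (%d) exceeds trial length (%d)", cfg$window_size, dim(train$data)[3]))
  missing_cls <- setdiff(unique(test$labels), unique(train$labels))
  if (length(missing_cls) > 0)
    warning(sprintf("test-set class(es) %s absent from training set; filters applied anyway",
                    paste(missing_cls, collapse = ", ")))

  tr <- window_trialset(train, cfg)
  te <- window_trialset(test, cfg)

  bank <- NULL
  if (cfg$use_csp) {
    C1 <- 2L * cfg$n_pairs
    bank <- csp_fit(tr$data, tr$labels, C1, ridge = cfg$ridge)
    tr$data <- csp_apply(bank, tr$data)
    te$data <- csp_apply(bank, te$data)
    attr(bank, "fit_trial_ids") <- sort(unique(tr$source_trial))
    attr(bank, "fit_hash") <- fingerprint(sort(unique(tr$source_trial)))
  }

  if (cfg$expand_windows) {
    if (cfg$scale_per_epoch) {
      # defer: training loop resamples the factors each epoch
      attr(tr, "scale_per_epoch") <- list(
        beta_low = cfg$beta_low, beta_high = cfg$beta_high,
        beta_distribution = cfg$beta_distribution, seed = cfg$seed)
    } else {
      betas <- with_seed(cfg$seed, draw_betas(dim(tr$data)[1], cfg))
      tr$data <- tr$data * betas            # recycles over the first dim
      if (!cfg$scale_train_only) {
        betas_te <- with_seed(cfg$seed + 1L, draw_betas(dim(te$data)[1], cfg))
        te$data <- te$data * betas_te
      }
    }
  }
  list(train = tr, test = te, bank = bank)
}
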