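# The network: multi-scale temporal block -> spatial/temporal refinement block
# -> efficient channel attention -> depthwise separable fusion -> classifier.
# Built on the engine in nn.R; the whole forward/backward pipeline is explicit
# so gradients can be checked against finite differences.

#' Model configuration
#'
#' Defaults follow the compact configuration for four-class decoding:
#' `F1 = 8` temporal filters per branch, spatial multiplier `D = 2`,
#' `F2 = 16` pointwise filters, multi-scale kernels `(8, 16, 24)`,
#' `K1 = 64` (the refinement block's temporal kernel is `K1/4`), `K2 = 32`
#' (depthwise fusion kernel), pooling factors 4 and 8, a 32-unit hidden
#' layer (`= 2 * F2`) and dropout 0.3.
#'
#' @param in_channels spatial channels entering the network (C1; 12 after CSP
#'   with six filter pairs, 2 for the binary montage).
#' @param in_samples window length T1 in samples (default 500).
#' @param n_classes number of output classes.
#' @param F1 temporal filters per multi-scale branch.
#' @param D spatial filter multiplier of the refinement block.
#' @param F2 pointwise fusion filters (equal to `F1 * D` in the default
#'   configuration; required to match when the fusion block is disabled).
#' @param ms_kernels integer triplet of multi-scale kernel lengths.
#' @param K1 base temporal kernel parameter; the refinement block convolves
#'   with `K1 / 4` taps.
#' @param K2 depthwise fusion kernel length.
#' @param pool1,pool2 average-pooling factors after the refinement and fusion
#'   blocks (4 and 8: the temporal axis shrinks 32-fold overall).
#' @param eca_mode `"fixed"` uses `eca_k` taps; `"adaptive"` computes the
#'   kernel from the channel count via [eca_kernel_size()].
#' @param eca_k fixed attention kernel size (odd; default 3).
#' @param eca_gamma,eca_b adaptive sizing constants (defaults 2 and 1).
#' @param eca_padding `"zero"` (default) or `"circular"` padding of the
#'   channel axis in the attention convolution.
#' @param fc_width hidden width of the classifier (default 32).
#' @param dropout dropout probability in `[0, 1)`.
#' @param ms_fusion `"pointwise"` (concatenate the three branches and project
#'   back to F1 channels with a learned 1x1 convolution) or `"sum"`.
#' @param use_multiscale,use_eca,use_st_block,use_dsf_block ablation switches;
#'   a disabled block is replaced by a shape-preserving pass-through (or a
#'   single-kernel branch for the multi-scale block).
#' @param seed integer seed for deterministic weight initialization.
#' @return an object of class `model_config`.
#' @export
model_config <- function(in_channels = 12L, in_samples = 500L, n_classes = 4L,
                         F1 = 8L, D = 2L, F2 = 16L,
                         ms_kernels = c(8L, 16L, 24L), K1 = 64L, K2 = 32L,
                         pool1 = 4L, pool2 = 8L,
                         eca_mode = c("fixed", "adaptive"), eca_k = 3L,
                         eca_gamma = 2, eca_b = 1,
                         eca_padding = c("zero", "circular"),
                         fc_width = 32L, dropout = 0.3,
                         ms_fusion = c("pointwise", "sum"),
                         use_multiscale = TRUE, use_eca = TRUE,
                         use_st_block = TRUE, use_dsf_block = TRUE,
                         seed = 1L) {
  eca_mode <- match.arg(eca_mode)
  ms_fusion <- match.arg(ms_fusion)
  eca_padding <- match.arg(eca_padding)
  for (nm in c("in_channels", "in_samples", "n_classes", "F1", "D", "F2",
               "K1", "K2", "pool1", "pool2", "fc_width")) {
    v <- get(nm)
    if (!is_count(v))
      amanet_abort("amanet_config_error", sprintf("%s must be a positive integer", nm))
  }
  if (length(ms_kernels) != 3L || any(ms_kernels < 1))
    amanet_abort("amanet_config_error", "ms_kernels must be three kernel lengths >= 1")
  if (K1 %% 4 != 0)
    amanet_abort("amanet_config_error", "K1 must be divisible by 4")
  if (eca_k %% 2 == 0)
    amanet_abort("amanet_config_error", "eca_k must be odd")
  if (dropout < 0 || dropout >= 1)
    amanet_abort("amanet_config_error", "dropout must lie in [0, 1)")
  if ((in_samples %/% pool1) %/% pool2 < 1)
    amanet_abort("amanet_config_error", sprintf(
      "in_samples = %d is too short for the pooling chain (factor %d)",
      in_samples, pool1 * pool2))
  if (!use_dsf_block && F2 != F1 * D)
    amanet_abort("amanet_config_error",
                 "disabling the fusion block requires F2 == F1 * D")
  structure(list(
    in_channels = as.integer(in_channels), in_samples = as.integer(in_samples),
    n_classes = as.integer(n_classes), F1 = as.integer(F1), D = as.integer(D),
    F2 = as.integer(F2), ms_kernels = as.integer(ms_kernels),
    K1 = as.integer(K1), K2 = as.integer(K2),
    pool1 = as.integer(pool1), pool2 = as.integer(pool2),
    eca_mode = eca_mode, eca_k = as.integer(eca_k),
    eca_gamma = eca_gamma, eca_b = eca_b, eca_padding = eca_padding,
    fc_width = as.integer(fc_width), dropout = dropout, ms_fusion = ms_fusion,
    use_multiscale = isTRUE(use_multiscale), use_eca = isTRUE(use_eca),
    use_st_block = isTRUE(use_st_block), use_dsf_block = isTRUE(use_dsf_block),
    seed = as.integer(seed)
  ), class = "model_config")
}

#' Adaptive attention kernel size
#'
#' Evaluates `(log2(C) + b) / gamma` and returns the nearest odd integer
#' (ties round upward, never below 1). Pure function of the channel count.
#'
#' @param n_channels channel count C (>= 1).
#' @param gamma,b sizing constants (defaults 2 and 1).
#' @return an odd integer kernel size.
#' @export
eca_kernel_size <- function(n_channels, gamma = 2, b = 1) {
  if (!is_count(n_channels))
    amanet_abort("amanet_config_error", "n_channels must be a positive integer")
  val <- (log2(n_channels) + b) / gamma
  lo <- 2 * floor((val - 1) / 2) + 1          # largest odd <= val (odd grid)
  hi <- lo + 2
  k <- if ((val - lo) < (hi - val)) lo else hi  # tie -> round up
  max(1L, as.integer(k))
}

#' Stage output shapes implied by a configuration
#'
#' Derivable from the configuration alone; pooling uses floor division, so
#' the default 500-sample window shrinks 500 -> 125 -> 15.
#'
#' @param cfg a [model_config()].
#' @return list with `ms_out`, `st_out`, `eca_out`, `dsf_out`, `flat`, `logits`.
#' @export
stage_shapes <- function(cfg) {
  L1 <- cfg$in_samples %/% cfg$pool1
  L2 <- L1 %/% cfg$pool2
  Cf <- cfg$F1 * cfg$D
  Cout <- if (cfg$use_dsf_block) cfg$F2 else Cf
  list(ms_out = c(cfg$F1, cfg$in_channels, cfg$in_samples),
       st_out = c(Cf, 1L, L1), eca_out = c(Cf, 1L, L1),
       dsf_out = c(Cout, 1L, L2), flat = Cout * L2, logits = cfg$n_classes)
}

uconv <- function(dims, fan_in) {
  lim <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

#' Build a model with deterministically initialized weights
#'
#' Layer order: multi-scale block -> fusion -> refinement (ST) block ->
#' channel attention -> depthwise separable fusion -> classifier, with batch
#' normalization after every convolution and ELU activations throughout
#' (the attention gate uses a sigmoid). Weights use a fan-in uniform scheme
#' drawn from a stream seeded by `cfg$seed`; biases start at zero.
#'
#' @param cfg a [model_config()].
#' @return an object of class `amanet_model` with elements `cfg`, `params`
#'   (trainable weights), `state` (batch-norm running statistics) and
#'   `shapes` ([stage_shapes()]).
#' @export
build_model <- function(cfg) {
  if (!inherits(cfg, "model_config"))
    amanet_abort("amanet_config_error", "cfg must be a model_config")
  Cf <- cfg$F1 * cfg$D
  kt <- cfg$K1 %/% 4L
  sh <- stage_shapes(cfg)
  bn_par <- function(C) list(gamma = rep(1, C), beta = rep(0, C))
  bn_st <- function(C) list(mean = rep(0, C), var = rep(1, C))
  params <- list(); state <- list()
  with_seed(cfg$seed, {
    if (cfg$use_multiscale) {
      params$ms <- list(branches = list(), bn = list())
      state$ms <- list(bn = list())
      for (i in 1:3) {
        k <- cfg$ms_kernels[i]
        params$ms$branches[[i]] <- list(W = uconv(c(cfg$F1, 1, k), k),
                                        b = rep(0, cfg$F1))
        params$ms$bn[[i]] <- bn_par(cfg$F1)
        state$ms$bn[[i]] <- bn_st(cfg$F1)
      }
      if (cfg$ms_fusion == "pointwise") {
        params$ms$fuse <- list(W = uconv(c(cfg$F1, 3 * cfg$F1), 3 * cfg$F1),
                               b = rep(0, cfg$F1))
        params$ms$fuse_bn <- bn_par(cfg$F1)
        state$ms$fuse_bn <- bn_st(cfg$F1)
      }
    } else {
      k <- cfg$ms_kernels[2]                 # single-kernel replacement
      params$ms <- list(branches = list(list(W = uconv(c(cfg$F1, 1, k), k),
                                             b = rep(0, cfg$F1))),
                        bn = list(bn_par(cfg$F1)))
      state$ms <- list(bn = list(bn_st(cfg$F1)))
    }
    if (cfg$use_st_block) {
      params$st <- list(
        Wsp = uconv(c(cfg$D, cfg$in_channels, cfg$F1), cfg$in_channels),
        bsp = matrix(0, cfg$D, cfg$F1),
        bn1 = bn_par(Cf),
        Wt = uconv(c(Cf, Cf, kt), Cf * kt), bt = rep(0, Cf),
        bn2 = bn_par(Cf))
      state$st <- list(bn1 = bn_st(Cf), bn2 = bn_st(Cf))
    }
    if (cfg$use_eca) {
      k_eca <- if (cfg$eca_mode == "adaptive") {
        eca_kernel_size(Cf, cfg$eca_gamma, cfg$eca_b)
      } else cfg$eca_k
      params$eca <- list(w = as.numeric(uconv(c(k_eca), k_eca)))
    }
    if (cfg$use_dsf_block) {
      params$dsf <- list(Wd = uconv(c(Cf, cfg$K2), cfg$K2), bd = rep(0, Cf),
                         Wp = uconv(c(cfg$F2, Cf), Cf), bp = rep(0, cfg$F2),
                         bn = bn_par(cfg$F2))
      state$dsf <- list(bn = bn_st(cfg$F2))
    }
    params$fc1 <- list(W = uconv(c(cfg$fc_width, sh$flat), sh$flat),
                       b = rep(0, cfg$fc_width))
    params$fc2 <- list(W = uconv(c(cfg$n_classes, cfg$fc_width), cfg$fc_width),
                       b = rep(0, cfg$n_classes))
  })
  structure(list(cfg = cfg, params = params, state = state, shapes = sh),
            class = "amanet_model")
}

#' @export
print.amanet_model <- function(x, ...) {
  sh <- x$shapes
  cat("amanet_model\n")
  cat(sprintf("  input : (1, %d, %d)\n", x$cfg$in_channels, x$cfg$in_samples))
  cat(sprintf("  ms    : (%s)\n", paste(sh$ms_out, collapse = ", ")))
  cat(sprintf("  st    : (%s)\n", paste(sh$st_out, collapse = ", ")))
  cat(sprintf("  eca   : (%s)\n", paste(sh$eca_out, collapse = ", ")))
  cat(sprintf("  dsf   : (%s)\n", paste(sh$dsf_out, collapse = ", ")))
  cat(sprintf("  flat  : %d -> %d -> %d\n", sh$flat, x$cfg$fc_width, sh$logits))
  pc <- count_parameters(x)
  cat(sprintf("  parameters: %d (%s)\n", pc$total,
              paste(sprintf("%s %d", names(pc$by_stage), unlist(pc$by_stage)),
                    collapse = ", ")))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model an [build_model()] result.
#' @return list with `total` and a per-stage `by_stage` breakdown. The count
#'   is a pure function of the architecture (identical across seeds).
#' @export
count_parameters <- function(model) {
  if (!inherits(model, "amanet_model"))
    amanet_abort("amanet_config_error", "model must be an amanet_model")
  by_stage <- lapply(model$params, function(p) length(unlist(p)))
  # merge the two classifier layers into one entry
  stages <- list()
  for (nm in names(by_stage)) {
    key <- if (nm %in% c("fc1", "fc2")) "classifier" else nm
    stages[[key]] <- (stages[[key]] %||% 0L) + by_stage[[nm]]
  }
  list(total = sum(unlist(by_stage)), by_stage = stages)
}

#' Global average pooling
#'
#' Collapses all non-channel dimensions of a channel-first array to a single
#' mean per channel (per sample when a batch axis is present as the last
#' dimension of a `(C, H, W)` stage tensor this is the plain mean).
#'
#' @param x channel-first numeric array `(C, ...)` with at least one element
#'   per channel.
#' @return numeric vector of per-channel means.
#' @export
global_avg_pool <- function(x) {
  if (is.null(dim(x)) || prod(dim(x)[-1]) < 1)
    amanet_abort("amanet_dim_error", "x must be a channel-first array with non-empty spatial extent")
  rowMeans(matrix(x, nrow = dim(x)[1]))
}

# ---------------------------------------------------------------------------
# flatten / unflatten parameter trees

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(node) {
    if (is.list(node)) return(lapply(node, walk))
    n <- length(node)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    dim(out) <- dim(node)
    out
  }
  walk(skeleton)
}

# zero-filled gradient tree matching a parameter tree
zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else array(0, dim = dim(p) %||% length(p))
}

# ---------------------------------------------------------------------------
# full forward (+ optional backward) pass
#
# x: (N, C1, T1) user layout; y: optional 1-based labels enabling backward.

amanet_pass <- function(model, x, y = NULL, training = FALSE) {
  cfg <- model$cfg; p <- model$params; s <- model$state
  C1 <- cfg$in_channels; T1 <- cfg$in_samples
  Cf <- cfg$F1 * cfg$D
  if (length(dim(x)) == 4L) {                 # accept (N, 1, C1, T1)
    if (dim(x)[2] != 1L)
      amanet_abort("amanet_dim_error", "4-d input must have a singleton second axis")
    dim(x) <- dim(x)[-2]
  }
  if (length(dim(x)) != 3L || dim(x)[2] != C1 || dim(x)[3] != T1)
    amanet_abort("amanet_dim_error", sprintf(
      "input must be N x %d x %d, got %s", C1, T1,
      paste(dim(x), collapse = " x ")))
  N <- dim(x)[1]
  grads <- if (!is.null(y)) zero_like(p) else NULL
  caches <- list()
  stages <- list()

  ## ---- multi-scale temporal block --------------------------------------
  xc <- aperm(x, c(2, 3, 1))                       # (C1, T1, N)
  xm <- aperm(xc, c(2, 1, 3))                      # (T1, C1, N)
  dim(xm) <- c(1, T1, C1 * N)
  nb <- length(p$ms$branches)
  br <- vector("list", nb)
  for (i in seq_len(nb)) {
    cv <- conv_time_fwd(xm, p$ms$branches[[i]]$W, p$ms$branches[[i]]$b)
    bn <- bn_elu_fwd(cv$y, p$ms$bn[[i]], s$ms$bn[[i]], training)
    s$ms$bn[[i]]$mean <- bn$rmean; s$ms$bn[[i]]$var <- bn$rvar
    br[[i]] <- list(cv = cv, bn = bn)
  }
  if (nb == 3L && cfg$ms_fusion == "pointwise") {
    yc <- array(0, dim = c(3 * cfg$F1, T1, C1 * N))
    for (i in 1:3) yc[((i - 1) * cfg$F1 + 1):(i * cfg$F1), , ] <- br[[i]]$bn$y
    ycm <- matrix(yc, 3 * cfg$F1, T1 * C1 * N)
    yfm <- p$ms$fuse$W %*% ycm + p$ms$fuse$b
    dim(yfm) <- c(cfg$F1, T1, C1 * N)
    fbn <- bn_elu_fwd(yfm, p$ms$fuse_bn, s$ms$fuse_bn, training)
    s$ms$fuse_bn$mean <- fbn$rmean; s$ms$fuse_bn$var <- fbn$rvar
    h <- fbn$y
    caches$ms <- list(br = br, ycm = ycm, fbn = fbn)
  } else if (nb == 3L) {                            # sum fusion
    h <- br[[1]]$bn$y + br[[2]]$bn$y + br[[3]]$bn$y
    caches$ms <- list(br = br)
  } else {
    h <- br[[1]]$bn$y
    caches$ms <- list(br = br)
  }
  stages$ms_out <- c(cfg$F1, C1, T1)

  ## ---- spatial / temporal refinement block -----------------------------
  h4 <- h; dim(h4) <- c(cfg$F1, T1, C1, N)
  if (cfg$use_st_block) {
    zarr <- array(0, dim = c(cfg$D, cfg$F1, T1, N))
    ap_list <- vector("list", cfg$F1)
    for (f in seq_len(cfg$F1)) {
      hf <- h4[f, , , , drop = FALSE]
      dim(hf) <- c(T1, C1, N)
      ap <- aperm(hf, c(2, 1, 3))                        # (C1, T1, N)
      dim(ap) <- c(C1, T1 * N)
      ap_list[[f]] <- ap
      zf <- p$st$Wsp[, , f, drop = FALSE]
      dim(zf) <- c(cfg$D, C1)
      zz <- zf %*% ap + p$st$bsp[, f]
      dim(zz) <- c(cfg$D, T1, N)
      zarr[, f, , ] <- zz
    }
    dim(zarr) <- c(Cf, T1, N)
    bn1 <- bn_elu_fwd(zarr, p$st$bn1, s$st$bn1, training)
    s$st$bn1$mean <- bn1$rmean; s$st$bn1$var <- bn1$rvar
    tc <- conv_time_fwd(bn1$y, p$st$Wt, p$st$bt)
    bn2 <- bn_elu_fwd(tc$y, p$st$bn2, s$st$bn2, training)
    s$st$bn2$mean <- bn2$rmean; s$st$bn2$var <- bn2$rvar
    pl <- avgpool_fwd(bn2$y, cfg$pool1)
    dp <- dropout_fwd(pl$y, cfg$dropout, training)
    g <- dp$y
    caches$st <- list(ap_list = ap_list, bn1 = bn1, tc = tc,
                      bn2 = bn2, pl = pl, dp = dp)
  } else {
    # pass-through: average over the spatial axis, duplicate channels D-fold
    hp <- aperm(h4, c(3, 1, 2, 4))                  # (C1, F1, T1, N)
    hm <- colMeans(hp)                              # (F1, T1, N)
    z <- hm[rep(seq_len(cfg$F1), each = cfg$D), , , drop = FALSE]
    pl <- avgpool_fwd(z, cfg$pool1)
    g <- pl$y
    caches$st <- list(pl = pl)
  }
  L1 <- dim(g)[2]
  stages$st_out <- c(Cf, 1L, L1)

  ## ---- efficient channel attention --------------------------------------
  if (cfg$use_eca) {
    ec <- eca_fwd(g, p$eca$w, circular = cfg$eca_padding == "circular")
    g <- ec$y
    caches$eca <- ec
  }
  stages$eca_out <- c(Cf, 1L, L1)

  ## ---- depthwise separable fusion block ---------------------------------
  if (cfg$use_dsf_block) {
    if (L1 < cfg$pool2)
      amanet_abort("amanet_config_error", sprintf(
        "temporal length %d shorter than pooling factor %d", L1, cfg$pool2))
    dw <- conv_dw_fwd(g, p$dsf$Wd, p$dsf$bd)
    dwm <- matrix(dw$y, Cf, L1 * N)
    pwm <- p$dsf$Wp %*% dwm + p$dsf$bp
    dim(pwm) <- c(cfg$F2, L1, N)
    bn <- bn_elu_fwd(pwm, p$dsf$bn, s$dsf$bn, training)
    s$dsf$bn$mean <- bn$rmean; s$dsf$bn$var <- bn$rvar
    pl2 <- avgpool_fwd(bn$y, cfg$pool2)
    dp2 <- dropout_fwd(pl2$y, cfg$dropout, training)
    q <- dp2$y
    caches$dsf <- list(dw = dw, dwm = dwm, bn = bn,
                       pl2 = pl2, dp2 = dp2)
  } else {
    pl2 <- avgpool_fwd(g, cfg$pool2)
    q <- pl2$y
    caches$dsf <- list(pl2 = pl2)
  }
  L2 <- dim(q)[2]
  Cout <- dim(q)[1]
  stages$dsf_out <- c(Cout, 1L, L2)

  ## ---- classifier --------------------------------------------------------
  flat <- q; dim(flat) <- c(Cout * L2, N)
  f1 <- dense_fwd(flat, p$fc1$W, p$fc1$b)
  a3 <- elu_fwd(f1$y)
  dp3 <- dropout_fwd(a3$y, cfg$dropout, training)
  logits <- p$fc2$W %*% dp3$y + p$fc2$b
  stages$flat <- Cout * L2
  stages$logits <- cfg$n_classes

  out <- list(logits = logits, state = s, stages = stages)
  if (is.null(y)) return(out)

  ## ---- backward ----------------------------------------------------------
  sm <- softmax_xent(logits, y)
  out$loss <- sm$loss
  d2 <- dense_bwd(sm$dlogits, dp3$y, p$fc2$W)
  grads$fc2$W <- d2$dW; grads$fc2$b <- d2$db
  dd <- dropout_bwd(d2$dx, dp3$cache)
  da3 <- elu_bwd(dd, a3$cache)
  d1 <- dense_bwd(da3, flat, p$fc1$W)
  grads$fc1$W <- d1$dW; grads$fc1$b <- d1$db
  dq <- d1$dx; dim(dq) <- c(Cout, L2, N)

  if (cfg$use_dsf_block) {
    cc <- caches$dsf
    dpl2 <- dropout_bwd(dq, cc$dp2$cache)
    dac <- avgpool_bwd(dpl2, cc$pl2$cache)
    bb <- bn_elu_bwd(dac, cc$bn$cache)
    grads$dsf$bn$gamma <- bb$dgamma; grads$dsf$bn$beta <- bb$dbeta
    dpwm <- matrix(bb$dx, cfg$F2, L1 * N)
    grads$dsf$Wp <- tcrossprod(dpwm, cc$dwm)
    grads$dsf$bp <- rowSums(dpwm)
    ddwm <- crossprod(p$dsf$Wp, dpwm)
    dim(ddwm) <- c(Cf, L1, N)
    db <- conv_dw_bwd(ddwm, cc$dw$x, p$dsf$Wd)
    grads$dsf$Wd <- db$dW; grads$dsf$bd <- db$db
    dg <- db$dx
  } else {
    dg <- avgpool_bwd(dq, caches$dsf$pl2$cache)
  }

  if (cfg$use_eca) {
    eb <- eca_bwd(dg, caches$eca$cache)
    grads$eca$w <- eb$dw
    dg <- eb$dx
  }

  if (cfg$use_st_block) {
    cc <- caches$st
    dpl <- dropout_bwd(dg, cc$dp$cache)
    da2 <- avgpool_bwd(dpl, cc$pl$cache)
    b2 <- bn_elu_bwd(da2, cc$bn2$cache)
    grads$st$bn2$gamma <- b2$dgamma; grads$st$bn2$beta <- b2$dbeta
    tcb <- conv_time_bwd(b2$dx, cc$tc$x, p$st$Wt)
    grads$st$Wt <- tcb$dW; grads$st$bt <- tcb$db
    b1 <- bn_elu_bwd(tcb$dx, cc$bn1$cache)
    grads$st$bn1$gamma <- b1$dgamma; grads$st$bn1$beta <- b1$dbeta
    dz <- b1$dx; dim(dz) <- c(cfg$D, cfg$F1, T1, N)
    dh4 <- array(0, dim = c(cfg$F1, T1, C1, N))
    for (f in seq_len(cfg$F1)) {
      dzf <- dz[, f, , , drop = FALSE]
      dim(dzf) <- c(cfg$D, T1 * N)
      wf <- p$st$Wsp[, , f, drop = FALSE]; dim(wf) <- c(cfg$D, C1)
      grads$st$Wsp[, , f] <- tcrossprod(dzf, caches$st$ap_list[[f]])
      grads$st$bsp[, f] <- rowSums(dzf)
      dap <- crossprod(wf, dzf)
      dim(dap) <- c(C1, T1, N)
      dh4[f, , , ] <- aperm(dap, c(2, 1, 3))
    }
    dh <- dh4
  } else {
    dzfull <- avgpool_bwd(dg, caches$st$pl$cache)   # (Cf, T1, N)
    dzr <- dzfull; dim(dzr) <- c(cfg$D, cfg$F1, T1, N)
    dhm <- colSums(dzr)                             # sum over D -> (F1, T1, N)
    dh4 <- array(0, dim = c(cfg$F1, T1, C1, N))
    for (c1 in seq_len(C1)) dh4[, , c1, ] <- dhm / C1
    dh <- dh4
  }
  dim(dh) <- c(cfg$F1, T1, C1 * N)

  cc <- caches$ms
  if (nb == 3L && cfg$ms_fusion == "pointwise") {
    fb <- bn_elu_bwd(dh, cc$fbn$cache)
    grads$ms$fuse_bn$gamma <- fb$dgamma; grads$ms$fuse_bn$beta <- fb$dbeta
    dyfm <- matrix(fb$dx, cfg$F1, T1 * C1 * N)
    grads$ms$fuse$W <- tcrossprod(dyfm, cc$ycm)
    grads$ms$fuse$b <- rowSums(dyfm)
    dyc <- crossprod(p$ms$fuse$W, dyfm)
    dim(dyc) <- c(3 * cfg$F1, T1, C1 * N)
    dbr <- lapply(1:3, function(i)
      dyc[((i - 1) * cfg$F1 + 1):(i * cfg$F1), , , drop = FALSE])
  } else if (nb == 3L) {
    dbr <- list(dh, dh, dh)
  } else {
    dbr <- list(dh)
  }
  for (i in seq_len(nb)) {
    bb <- bn_elu_bwd(dbr[[i]], cc$br[[i]]$bn$cache)
    grads$ms$bn[[i]]$gamma <- bb$dgamma; grads$ms$bn[[i]]$beta <- bb$dbeta
    cb <- conv_time_bwd(bb$dx, cc$br[[i]]$cv$x, p$ms$branches[[i]]$W)
    grads$ms$branches[[i]]$W <- cb$dW
    grads$ms$branches[[i]]$b <- cb$db
  }

  out$grads <- grads
  out
}

#' Forward pass of the full network
#'
#' Deterministic in evaluation mode (dropout off, batch normalization using
#' running statistics); per-sample independent, so permuting the batch
#' permutes the logits identically.
#'
#' @param model an [build_model()] result.
#' @param x batch array `N x C1 x T1` (a singleton second axis
#'   `N x 1 x C1 x T1` is also accepted).
#' @param training use batch statistics and dropout (default `FALSE`). The
#'   training path is only meaningful inside the optimizer loop, where the
#'   caller manages the RNG and running statistics.
#' @return `N x n_classes` matrix of raw logits.
#' @export
model_forward <- function(model, x, training = FALSE) {
  t(amanet_pass(model, x, training = training)$logits)
}

#' Forward pass of the multi-scale temporal block only
#'
#' @param model an [build_model()] result.
#' @param x batch array `N x C1 x T1`.
#' @return array `N x F1 x C1 x T1` (evaluation mode).
#' @export
ms_block_forward <- function(model, x) {
  forward_to_stage(model, x, "ms")
}

# internal: run the eval-mode pipeline, capturing one intermediate stage in
# user layout. Duplicates a slice of amanet_pass on purpose: the staged API
# is for inspection/testing and must not disturb the training path.
forward_to_stage <- function(model, x, stage) {
  cfg <- model$cfg
  N <- dim(x)[1]
  res <- amanet_pass_stages(model, x)
  switch(stage,
         ms = res$ms, st = res$st, eca = res$eca, dsf = res$dsf)
}

amanet_pass_stages <- function(model, x) {
  # eval-mode pass that materializes user-layout stage tensors
  cfg <- model$cfg
  C1 <- cfg$in_channels; T1 <- cfg$in_samples; Cf <- cfg$F1 * cfg$D
  N <- dim(x)[1]
  # reuse the fused pass for logits/shapes, then recompute stage outputs by
  # running the same internals with stage capture
  env <- new.env()
  res <- amanet_pass_capture(model, x, env)
  list(ms = env$ms, st = env$st, eca = env$eca, dsf = env$dsf,
       logits = t(res$logits))
}

amanet_pass_capture <- function(model, x, env) {
  # thin wrapper: amanet_pass already computes everything; we re-derive the
  # user-layout stage tensors from a duplicated eval pass
  cfg <- model$cfg; p <- model$params; s <- model$state
  C1 <- cfg$in_channels; T1 <- cfg$in_samples; Cf <- cfg$F1 * cfg$D
  if (length(dim(x)) == 4L) dim(x) <- dim(x)[-2]
  N <- dim(x)[1]
  xc <- aperm(x, c(2, 3, 1))
  xm <- aperm(xc, c(2, 1, 3)); dim(xm) <- c(1, T1, C1 * N)
  nb <- length(p$ms$branches)
  acts <- vector("list", nb)
  for (i in seq_len(nb)) {
    cv <- conv_time_fwd(xm, p$ms$branches[[i]]$W, p$ms$branches[[i]]$b)
    acts[[i]] <- bn_elu_fwd(cv$y, p$ms$bn[[i]], s$ms$bn[[i]], FALSE)$y
  }
  if (nb == 3L && cfg$ms_fusion == "pointwise") {
    yc <- array(0, dim = c(3 * cfg$F1, T1, C1 * N))
    for (i in 1:3) yc[((i - 1) * cfg$F1 + 1):(i * cfg$F1), , ] <- acts[[i]]
    ycm <- matrix(yc, 3 * cfg$F1, T1 * C1 * N)
    yfm <- p$ms$fuse$W %*% ycm + p$ms$fuse$b
    dim(yfm) <- c(cfg$F1, T1, C1 * N)
    h <- bn_elu_fwd(yfm, p$ms$fuse_bn, s$ms$fuse_bn, FALSE)$y
  } else if (nb == 3L) {
    h <- acts[[1]] + acts[[2]] + acts[[3]]
  } else {
    h <- acts[[1]]
  }
  h4 <- h; dim(h4) <- c(cfg$F1, T1, C1, N)
  env$ms <- aperm(h4, c(4, 1, 3, 2))               # (N, F1, C1, T1)

  if (cfg$use_st_block) {
    zarr <- array(0, dim = c(cfg$D, cfg$F1, T1, N))
    for (f in seq_len(cfg$F1)) {
      hf <- h4[f, , , , drop = FALSE]; dim(hf) <- c(T1, C1, N)
      ap <- aperm(hf, c(2, 1, 3)); dim(ap) <- c(C1, T1 * N)
      wf <- p$st$Wsp[, , f, drop = FALSE]; dim(wf) <- c(cfg$D, C1)
      zz <- wf %*% ap + p$st$bsp[, f]; dim(zz) <- c(cfg$D, T1, N)
      zarr[, f, , ] <- zz
    }
    dim(zarr) <- c(Cf, T1, N)
    a1 <- bn_elu_fwd(zarr, p$st$bn1, s$st$bn1, FALSE)$y
    tc <- conv_time_fwd(a1, p$st$Wt, p$st$bt)
    a2 <- bn_elu_fwd(tc$y, p$st$bn2, s$st$bn2, FALSE)$y
    g <- avgpool_fwd(a2, cfg$pool1)$y
  } else {
    hp <- aperm(h4, c(3, 1, 2, 4))
    hm <- colMeans(hp)
    z <- hm[rep(seq_len(cfg$F1), each = cfg$D), , , drop = FALSE]
    g <- avgpool_fwd(z, cfg$pool1)$y
  }
  L1 <- dim(g)[2]
  env$st <- aperm(array(g, dim = c(Cf, 1, L1, N)), c(4, 1, 2, 3))

  if (cfg$use_eca) g <- eca_fwd(g, p$eca$w,
                                circular = cfg$eca_padding == "circular")$y
  env$eca <- aperm(array(g, dim = c(Cf, 1, L1, N)), c(4, 1, 2, 3))

  if (cfg$use_dsf_block) {
    dw <- conv_dw_fwd(g, p$dsf$Wd, p$dsf$bd)
    dwm <- matrix(dw$y, Cf, L1 * N)
    pwm <- p$dsf$Wp %*% dwm + p$dsf$bp
    dim(pwm) <- c(cfg$F2, L1, N)
    ac <- bn_elu_fwd(pwm, p$dsf$bn, s$dsf$bn, FALSE)$y
    q <- avgpool_fwd(ac, cfg$pool2)$y
  } else {
    q <- avgpool_fwd(g, cfg$pool2)$y
  }
  L2 <- dim(q)[2]; Cout <- dim(q)[1]
  env$dsf <- aperm(array(q, dim = c(Cout, 1, L2, N)), c(4, 1, 2, 3))

  flat <- q; dim(flat) <- c(Cout * L2, N)
  a3 <- elu_fwd(p$fc1$W %*% flat + p$fc1$b)$y
  logits <- p$fc2$W %*% a3 + p$fc2$b
  list(logits = logits)
}

#' Forward pass of the spatial/temporal refinement block only
#'
#' @param model an [build_model()] result.
#' @param x array `N x F1 x C1 x T1` as produced by [ms_block_forward()].
#' @return array `N x F1*D x 1 x floor(T1/4)` (evaluation mode).
#' @export
st_block_forward <- function(model, x) {
  cfg <- model$cfg
  if (!identical(dim(x)[2:4],
                 as.integer(c(cfg$F1, cfg$in_channels, cfg$in_samples))))
    amanet_abort("amanet_dim_error", sprintf(
      "expected N x %d x %d x %d input", cfg$F1, cfg$in_channels, cfg$in_samples))
  # run from the captured multi-scale output through the refinement block
  p <- model$params; s <- model$state
  N <- dim(x)[1]; C1 <- cfg$in_channels; T1 <- cfg$in_samples
  Cf <- cfg$F1 * cfg$D
  h4 <- aperm(x, c(2, 4, 3, 1))                    # (F1, T1, C1, N)
  zarr <- array(0, dim = c(cfg$D, cfg$F1, T1, N))
  for (f in seq_len(cfg$F1)) {
    hf <- h4[f, , , , drop = FALSE]; dim(hf) <- c(T1, C1, N)
    ap <- aperm(hf, c(2, 1, 3)); dim(ap) <- c(C1, T1 * N)
    wf <- p$st$Wsp[, , f, drop = FALSE]; dim(wf) <- c(cfg$D, C1)
    zz <- wf %*% ap + p$st$bsp[, f]; dim(zz) <- c(cfg$D, T1, N)
    zarr[, f, , ] <- zz
  }
  dim(zarr) <- c(Cf, T1, N)
  a1 <- bn_elu_fwd(zarr, p$st$bn1, s$st$bn1, FALSE)$y
  tc <- conv_time_fwd(a1, p$st$Wt, p$st$bt)
  a2 <- bn_elu_fwd(tc$y, p$st$bn2, s$st$bn2, FALSE)$y
  g <- avgpool_fwd(a2, cfg$pool1)$y
  aperm(array(g, dim = c(Cf, 1, dim(g)[2], N)), c(4, 1, 2, 3))
}

#' Efficient channel attention as a standalone operation
#'
#' Global average pooling collapses each channel to a scalar descriptor, a
#' k-tap one-dimensional convolution runs across the channel axis (no bias),
#' and a sigmoid produces per-channel gates in (0, 1) that rescale the input.
#'
#' @param x array `C x 1 x L` (single sample) or `N x C x 1 x L` (batch).
#' @param kernel odd kernel size.
#' @param weights optional k-tap kernel; defaults to a centred identity tap.
#' @param padding `"zero"` or `"circular"` channel-axis padding.
#' @return array of the same shape as `x`, with attribute `"gates"` holding
#'   the channel weights.
#' @export
eca_forward <- function(x, kernel, weights = NULL,
                        padding = c("zero", "circular")) {
  padding <- match.arg(padding)
  if (kernel %% 2 == 0)
    amanet_abort("amanet_config_error", "kernel must be odd")
  if (is.null(weights)) {
    weights <- numeric(kernel)
    weights[(kernel + 1) %/% 2] <- 1
  }
  if (length(weights) != kernel)
    amanet_abort("amanet_config_error", "weights must have `kernel` taps")
  single <- length(dim(x)) == 3L
  if (single) {
    xb <- array(x, dim = c(1, dim(x)))
  } else xb <- x
  d <- dim(xb)                                      # (N, C, 1, L)
  xi <- aperm(xb, c(2, 4, 1, 3))                    # (C, L, N, 1)
  dim(xi) <- d[c(2, 4, 1)]
  res <- eca_fwd(xi, weights, circular = padding == "circular")
  y <- aperm(array(res$y, dim = c(d[2], d[4], d[1], 1)), c(3, 1, 4, 2))
  gates <- t(res$cache$s)                           # (N, C)
  if (single) {
    y <- array(y, dim = dim(x))
    gates <- gates[1, ]
  }
  attr(y, "gates") <- gates
  y
}

#' Forward pass of the depthwise separable fusion block only
#'
#' @param model an [build_model()] result.
#' @param x array `N x F1*D x 1 x L`.
#' @return array `N x F2 x 1 x floor(L/8)` (evaluation mode).
#' @export
dsf_block_forward <- function(model, x) {
  cfg <- model$cfg; p <- model$params; s <- model$state
  Cf <- cfg$F1 * cfg$D
  if (dim(x)[2] != Cf)
    amanet_abort("amanet_dim_error", sprintf("expected %d channels", Cf))
  N <- dim(x)[1]; L <- dim(x)[4]
  if (L < cfg$pool2)
    amanet_abort("amanet_config_error", sprintf(
      "temporal length %d shorter than pooling factor %d", L, cfg$pool2))
  g <- aperm(x, c(2, 4, 1, 3)); dim(g) <- c(Cf, L, N)
  dw <- conv_dw_fwd(g, p$dsf$Wd, p$dsf$bd)
  dwm <- matrix(dw$y, Cf, L * N)
  pwm <- p$dsf$Wp %*% dwm + p$dsf$bp
  dim(pwm) <- c(cfg$F2, L, N)
  ac <- bn_elu_fwd(pwm, p$dsf$bn, s$dsf$bn, FALSE)$y
  q <- avgpool_fwd(ac, cfg$pool2)$y
  aperm(array(q, dim = c(cfg$F2, 1, dim(q)[2], N)), c(4, 1, 2, 3))
}

#' Classifier head only
#'
#' Dense layer to the hidden width, ELU, (dropout during training), dense
#' layer to the class logits. Loss is softmax cross-entropy computed from the
#' raw logits in one numerically stable step.
#'
#' @param model an [build_model()] result.
#' @param flat `N x flat` matrix of flattened features.
#' @return `N x n_classes` matrix of raw logits.
#' @export
classifier_forward <- function(model, flat) {
  cfg <- model$cfg; p <- model$params
  flat <- as.matrix(flat)
  if (ncol(flat) != model$shapes$flat)
    amanet_abort("amanet_dim_error", sprintf(
      "flat length %d does not match expected %d", ncol(flat), model$shapes$flat))
  a3 <- elu_fwd(p$fc1$W %*% t(flat) + p$fc1$b)$y
  t(p$fc2$W %*% a3 + p$fc2$b)
}
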