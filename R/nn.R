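# Minimal reverse-mode neural-network engine in base R.
#
# All layers operate on channel-first arrays. The generic layout is
# (channels, length, batch): slicing along `length` and reshaping to a
# (channels, length*batch) matrix turns every convolution into a short sum of
# BLAS matrix products, which is what makes CPU training viable without an
# external framework.
#
# "Same" padding convention: a kernel of k taps is padded floor(k/2) on the
# left and k - 1 - floor(k/2) on the right, so output length equals input
# length for both odd and even k (for even k this equals padding k/2 on both
# sides and cropping the trailing extra sample).

conv_pad <- function(x, k) {
  # x: (C, L, M) -> zero padded (C, L + k - 1, M)
  d <- dim(x)
  pl <- k %/% 2
  xp <- array(0, dim = c(d[1], d[2] + k - 1L, d[3]))
  xp[, (pl + 1):(pl + d[2]), ] <- x
  xp
}

#' @noRd
conv_time_fwd <- function(x, W, b = NULL) {
  # x: (Cin, L, M); W: (Cout, Cin, k); y: (Cout, L, M). Compiled kernel.
  y <- conv_time_fwd_cpp(x, W, if (is.null(b)) numeric(0) else b)
  list(y = y, x = x)
}

conv_time_bwd <- function(dy, x, W, dims_x = NULL, with_bias = TRUE) {
  res <- conv_time_bwd_cpp(dy, x, W)
  if (!with_bias) res$db <- NULL
  res
}

#' @noRd
conv_dw_fwd <- function(x, W, b = NULL) {
  # depthwise temporal conv; x: (C, L, M); W: (C, k)
  y <- conv_dw_fwd_cpp(x, W, if (is.null(b)) numeric(0) else b)
  list(y = y, x = x)
}

conv_dw_bwd <- function(dy, x, W, dims_x = NULL) {
  conv_dw_bwd_cpp(dy, x, W)
}

#' @noRd
bn_fwd <- function(x, gamma, beta, rmean, rvar, training,
                   momentum = 0.1, eps = 1e-5) {
  # x: (C, L, M) cube; statistics over all non-channel elements
  res <- bn_fwd_cpp(x, gamma, beta, rmean, rvar, training, eps)
  if (training) {
    M <- prod(dim(x)[-1])
    vu <- if (M > 1) res$var * M / (M - 1) else res$var
    rmean <- (1 - momentum) * rmean + momentum * drop(res$mu)
    rvar <- (1 - momentum) * rvar + momentum * drop(vu)
  }
  list(y = res$y,
       cache = list(xhat = res$xhat, istd = drop(res$istd), gamma = gamma,
                    training = training),
       rmean = rmean, rvar = rvar)
}

bn_bwd <- function(dy, cache) {
  res <- bn_bwd_cpp(dy, cache$xhat, cache$istd, cache$gamma, cache$training)
  list(dx = res$dx, dgamma = drop(res$dgamma), dbeta = drop(res$dbeta))
}

#' @noRd
elu_fwd <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) dim(x) <- c(d, 1L)       # kernels take (C, L, M) cubes
  y <- elu_fwd_cpp(x)
  dim(y) <- d
  list(y = y, cache = list(y = y))
}

elu_bwd <- function(dy, cache) {
  d <- dim(dy)
  y <- cache$y
  if (length(d) == 2L) { dim(dy) <- c(d, 1L); dim(y) <- c(d, 1L) }
  dx <- elu_bwd_cpp(dy, y)
  dim(dx) <- d
  dx
}

#' @noRd
avgpool_fwd <- function(x, p) {
  # x: (C, L, M) -> (C, floor(L/p), M)
  d <- dim(x)
  if (d[2] %/% p < 1)
    amanet_abort("amanet_config_error", sprintf(
      "temporal length %d too short for pooling factor %d", d[2], p))
  y <- avgpool_fwd_cpp(x, p)
  list(y = y, cache = list(dims = d, p = p))
}

avgpool_bwd <- function(dy, cache) {
  avgpool_bwd_cpp(dy, cache$p, cache$dims[2])
}

#' @noRd
dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, cache = NULL))
  mask <- array(stats::runif(length(x)) >= p, dim = dim(x)) / (1 - p)
  list(y = x * mask, cache = mask)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

#' @noRd
dense_fwd <- function(x, W, b) {
  # x: (Din, N)
  list(y = W %*% x + b, cache = x)
}

dense_bwd <- function(dy, x, W) {
  list(dx = crossprod(W, dy), dW = tcrossprod(dy, x), db = rowSums(dy))
}

# pad a (C, N) channel descriptor along the channel axis
eca_pad <- function(z, k, circular) {
  pl <- k %/% 2; pr <- k - 1L - pl
  C <- nrow(z)
  if (circular) {
    top <- if (pl > 0) z[(C - pl + 1):C, , drop = FALSE] else z[0, , drop = FALSE]
    bot <- if (pr > 0) z[seq_len(pr), , drop = FALSE] else z[0, , drop = FALSE]
    rbind(top, z, bot)
  } else {
    rbind(matrix(0, pl, ncol(z)), z, matrix(0, pr, ncol(z)))
  }
}

#' @noRd
eca_fwd <- function(x, w, circular = FALSE) {
  # x: (C, L, N); w: k-tap channel kernel (no bias, per the original ECA design)
  d <- dim(x); C <- d[1]; L <- d[2]; N <- d[3]
  k <- length(w)
  z <- colMeans(aperm(x, c(2, 1, 3)))               # (C, N) channel descriptor
  dim(z) <- c(C, N)
  zp <- eca_pad(z, k, circular)
  a <- matrix(0, C, N)
  for (j in seq_len(k)) a <- a + w[j] * zp[j:(j + C - 1L), , drop = FALSE]
  s <- sigmoid(a)
  sE <- aperm(array(s, dim = c(C, N, L)), c(1, 3, 2))
  list(y = x * sE, cache = list(x = x, zp = zp, s = s, sE = sE, w = w,
                                circular = circular, dims = d))
}

eca_bwd <- function(dy, cache) {
  d <- cache$dims; C <- d[1]; L <- d[2]; N <- d[3]
  k <- length(cache$w)
  s <- cache$s
  ds <- colSums(aperm(dy * cache$x, c(2, 1, 3)))    # (C, N)
  dim(ds) <- c(C, N)
  da <- ds * s * (1 - s)
  dw <- numeric(k)
  dzp <- matrix(0, nrow(cache$zp), N)
  for (j in seq_len(k)) {
    rows <- j:(j + C - 1L)
    dw[j] <- sum(cache$zp[rows, , drop = FALSE] * da)
    dzp[rows, ] <- dzp[rows, , drop = FALSE] + cache$w[j] * da
  }
  pl <- k %/% 2; pr <- k - 1L - pl
  dz <- dzp[(pl + 1):(pl + C), , drop = FALSE]
  if (cache$circular) {
    if (pl > 0) {
      src <- ((C - pl + 1):C - 1L) %% C + 1L
      for (i in seq_len(pl)) dz[src[i], ] <- dz[src[i], ] + dzp[i, ]
    }
    if (pr > 0) {
      for (i in seq_len(pr)) dz[i, ] <- dz[i, ] + dzp[pl + C + i, ]
    }
  }
  dzE <- aperm(array(dz / L, dim = c(C, N, L)), c(1, 3, 2))
  list(dx = dy * cache$sE + dzE, dw = dw)
}

#' Softmax cross-entropy from raw logits
#'
#' Numerically stable log-softmax + negative log-likelihood in one step;
#' the model never materializes softmax probabilities during training.
#'
#' @noRd
softmax_xent <- function(logits, y) {
  # logits: (K, N); y: 1-based class index per column
  N <- ncol(logits)
  m <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, m))
  Z <- colSums(ex)
  logp <- sweep(logits, 2, m + log(Z))
  idx <- cbind(y, seq_len(N))
  loss <- -mean(logp[idx])
  probs <- sweep(ex, 2, Z, "/")
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / N
  list(loss = loss, probs = probs, dlogits = dlogits)
}

# ---------------------------------------------------------------------------
# Adam on a flat parameter vector

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

#' Fused batch-norm + ELU (the pairing used after every convolution)
#' @noRd
bn_elu_fwd <- function(x, bnp, bns, training, momentum = 0.1, eps = 1e-5) {
  res <- bn_elu_fwd_cpp(x, bnp$gamma, bnp$beta, bns$mean, bns$var, training, eps)
  rmean <- bns$mean; rvar <- bns$var
  if (training) {
    M <- prod(dim(x)[-1])
    vu <- if (M > 1) drop(res$var) * M / (M - 1) else drop(res$var)
    rmean <- (1 - momentum) * rmean + momentum * drop(res$mu)
    rvar <- (1 - momentum) * rvar + momentum * vu
  }
  list(y = res$y,
       cache = list(y = res$y, xhat = res$xhat, istd = drop(res$istd),
                    gamma = bnp$gamma, training = training),
       rmean = rmean, rvar = rvar)
}

bn_elu_bwd <- function(dy, cache) {
  res <- bn_elu_bwd_cpp(dy, cache$y, cache$xhat, cache$istd, cache$gamma,
                        cache$training)
  list(dx = res$dx, dgamma = drop(res$dgamma), dbeta = drop(res$dbeta))
}
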