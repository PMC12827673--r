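# Synthetic motor-imagery EEG with known class structure.
#
# Each class k is defined by a band-limited oscillation (an amplitude-modulated
# sinusoid: carrier at the band center, AM at half the bandwidth so the energy
# spreads over [f0 - bw/2, f0 + bw/2]) projected through a class-specific unit
# spatial pattern, plus broadband noise. This emulates the mu/beta rhythm
# structure that spatial filtering and band-power features exploit in real
# motor-imagery EEG, while keeping closed-form oracles (band power per channel)
# available for testing.

#' Specification of a synthetic motor-imagery data set
#'
#' @param n_channels number of EEG channels (C), >= 2.
#' @param sfreq sampling rate in Hz.
#' @param n_samples samples per trial (T).
#' @param n_trials_per_class trials generated for every class.
#' @param n_classes number of classes, >= 2.
#' @param class_bands list with one `c(center_hz, bandwidth_hz, amplitude)`
#'   triplet per class; amplitudes must be >= 0.
#' @param mixing `n_classes x n_channels` matrix of unit-norm spatial patterns
#'   (one row per class).
#' @param noise_sd standard deviation of the additive broadband noise.
#' @param pink if `TRUE` the noise is 1/f-shaped instead of white. White is
#'   the default so band-power oracles stay simple.
#' @param seed integer seed; identical spec + seed gives bit-identical data.
#'
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_channels, sfreq, n_samples, n_trials_per_class,
                           n_classes, class_bands, mixing, noise_sd = 1,
                           pink = FALSE, seed = 1L) {
  if (!is_count(n_channels, 2L))
    amanet_abort("amanet_spec_error", "n_channels must be an integer >= 2")
  if (!is_count(n_classes, 2L))
    amanet_abort("amanet_spec_error", "n_classes must be an integer >= 2")
  if (!is_count(n_samples, 1L) || !is_count(n_trials_per_class, 1L))
    amanet_abort("amanet_spec_error", "n_samples and n_trials_per_class must be positive integers")
  if (!is.numeric(sfreq) || sfreq <= 0)
    amanet_abort("amanet_spec_error", "sfreq must be a positive sampling rate in Hz")
  if (!is.list(class_bands) || length(class_bands) != n_classes)
    amanet_abort("amanet_config_error", sprintf(
      "class_bands must be a list of %d (center, bandwidth, amplitude) triplets", n_classes))
  for (b in class_bands) {
    if (length(b) != 3L || any(!is.finite(b)) || b[3] < 0)
      amanet_abort("amanet_config_error",
                   "each class band must be c(center_hz, bandwidth_hz, amplitude) with amplitude >= 0")
  }
  mixing <- as.matrix(mixing)
  if (nrow(mixing) != n_classes)
    amanet_abort("amanet_config_error", sprintf(
      "mixing must have one row per class (%d rows), got %d", n_classes, nrow(mixing)))
  if (ncol(mixing) != n_channels)
    amanet_abort("amanet_config_error", sprintf(
      "mixing rows must have length n_channels = %d, got %d", n_channels, ncol(mixing)))
  nrm <- sqrt(rowSums(mixing^2))
  if (any(abs(nrm - 1) > 1e-6))
    amanet_abort("amanet_spec_error", "mixing vectors must have unit Euclidean norm")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    amanet_abort("amanet_spec_error", "noise_sd must be >= 0")
  structure(list(
    n_channels = as.integer(n_channels), sfreq = sfreq,
    n_samples = as.integer(n_samples),
    n_trials_per_class = as.integer(n_trials_per_class),
    n_classes = as.integer(n_classes),
    class_bands = class_bands, mixing = mixing,
    noise_sd = noise_sd, pink = isTRUE(pink), seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Construct a labeled set of epoched EEG trials
#'
#' @param data numeric array `trials x channels x samples`.
#' @param labels integer class ids in `0 .. n_classes-1`, one per trial.
#' @param sfreq sampling rate in Hz.
#' @param channel_names optional character vector of channel names.
#'
#' @return an object of class `raw_trialset`.
#' @export
raw_trialset <- function(data, labels, sfreq, channel_names = NULL) {
  if (length(dim(data)) != 3L)
    amanet_abort("amanet_dim_error", "data must be a trials x channels x samples array")
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1])
    amanet_abort("amanet_dim_error", sprintf(
      "length(labels) = %d does not match number of trials = %d",
      length(labels), dim(data)[1]))
  if (any(labels < 0))
    amanet_abort("amanet_data_error", "labels must be non-negative class ids")
  if (!is.null(channel_names) && length(channel_names) != dim(data)[2])
    amanet_abort("amanet_dim_error", "channel_names length must equal channel count")
  structure(list(data = data, labels = labels, sfreq = sfreq,
                 channel_names = channel_names),
            class = "raw_trialset")
}

#' @export
print.raw_trialset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("raw_trialset: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  cat("class counts:", paste(sprintf("%d:%d", as.integer(names(table(x$labels))),
                                     as.integer(table(x$labels))), collapse = "  "), "\n")
  invisible(x)
}

#' Generate synthetic motor-imagery trials from a specification
#'
#' Every trial of class k is `mixing[k, ] %o% oscillation_k(t) + noise`, where
#' the oscillation is an amplitude-modulated sinusoid with a random phase per
#' trial and the noise is white (or optionally 1/f-shaped) Gaussian. All
#' randomness flows through one seeded stream; the caller's RNG state is left
#' untouched.
#'
#' @param spec a [synthetic_spec()].
#' @return a [raw_trialset()] with exact class balance
#'   (`n_classes * n_trials_per_class` trials, class-blocked order).
#' @export
generate_trialset <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    amanet_abort("amanet_spec_error", "spec must be a synthetic_spec object")
  C <- spec$n_channels; Tn <- spec$n_samples; K <- spec$n_classes
  m <- spec$n_trials_per_class
  n <- K * m
  tt <- (seq_len(Tn) - 1) / spec$sfreq
  X <- array(0, dim = c(n, C, Tn))
  labels <- rep(seq_len(K) - 1L, each = m)
  with_seed(spec$seed, {
    for (i in seq_len(n)) {
      k <- labels[i] + 1L
      band <- spec$class_bands[[k]]
      f0 <- band[1]; bw <- band[2]; amp <- band[3]
      ph1 <- stats::runif(1, 0, 2 * pi)
      ph2 <- stats::runif(1, 0, 2 * pi)
      env <- 1 + 0.5 * sin(2 * pi * (bw / 2) * tt + ph2)
      src <- amp * env * sin(2 * pi * f0 * tt + ph1)
      trial <- outer(spec$mixing[k, ], src)
      if (spec$noise_sd > 0) {
        noise <- matrix(stats::rnorm(C * Tn, sd = spec$noise_sd), C, Tn)
        if (spec$pink) noise <- pink_shape(noise)
        trial <- trial + noise
      }
      X[i, , ] <- trial
    }
  })
  raw_trialset(X, labels, spec$sfreq)
}

# Shape white rows into approximately 1/f amplitude spectra, preserving the
# per-row standard deviation. Rough but adequate for robustness checks; real
# EEG noise modeling is out of scope.
pink_shape <- function(noise) {
  Tn <- ncol(noise)
  f <- c(1, seq_len(Tn - 1))        # avoid DC blow-up
  scale <- 1 / sqrt(f)
  out <- t(apply(noise, 1, function(row) {
    sp <- stats::fft(row) * scale
    Re(stats::fft(sp, inverse = TRUE)) / Tn
  }))
  sweep(out, 1, apply(out, 1, stats::sd) / apply(noise, 1, stats::sd), "/")
}

#' Canonical synthetic problems used by the test and acceptance suites
#'
#' `"easy"` is a two-class problem with orthogonal unit mixing vectors
#' (classes expressed on different channels) and high SNR; `"hard"` is a
#' four-class problem whose mixing vectors have pairwise cosine similarity
#' exactly 0.5 and whose rhythms sit in overlapping mu/beta bands at low SNR.
#'
#' @param n_channels number of channels, >= 2 (>= 4 for `"hard"`).
#' @param difficulty `"easy"` or `"hard"`.
#' @param n_trials_per_class trials per class (default 40).
#' @param seed integer seed.
#' @return a [synthetic_spec()].
#' @export
make_separable_spec <- function(n_channels, difficulty = c("easy", "hard"),
                                n_trials_per_class = 40L, seed = 1L) {
  difficulty <- match.arg(difficulty)
  if (!is_count(n_channels, 2L))
    amanet_abort("amanet_spec_error", "n_channels must be an integer >= 2")
  if (difficulty == "easy") {
    mixing <- matrix(0, 2, n_channels)
    mixing[1, 1] <- 1
    mixing[2, 2] <- 1
    synthetic_spec(
      n_channels = n_channels, sfreq = 250, n_samples = 1000L,
      n_trials_per_class = n_trials_per_class, n_classes = 2L,
      class_bands = list(c(10, 2, 2), c(10, 2, 2)),
      mixing = mixing, noise_sd = 0.4, seed = seed)
  } else {
    if (n_channels < 4L)
      amanet_abort("amanet_spec_error", "hard difficulty needs n_channels >= 4")
    # four unit vectors with pairwise inner product exactly 0.5, from the
    # Cholesky factor of G = 0.5 + 0.5 I, zero-padded to n_channels
    G <- matrix(0.5, 4, 4); diag(G) <- 1
    V <- chol(G)                      # columns give the vectors in R^4
    mixing <- matrix(0, 4, n_channels)
    mixing[, 1:4] <- t(V)
    synthetic_spec(
      n_channels = n_channels, sfreq = 250, n_samples = 1000L,
      n_trials_per_class = n_trials_per_class, n_classes = 4L,
      class_bands = list(c(9, 2, 1), c(11, 2, 1), c(19, 3, 1), c(23, 3, 1)),
      mixing = mixing, noise_sd = 1.5, seed = seed)
  }
}
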