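# Shared fixtures and independent oracles for the test suite.
# Oracles here are deliberately naive (periodogram sums, dense grid searches,
# finite differences) so they stay independent of the implementation paths
# they check.

# periodogram band power of one signal, inclusive band [f_lo, f_hi] Hz
band_power_oracle <- function(x, sfreq, f_lo, f_hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1) * sfreq / n
  sum(sp[freq >= f_lo & freq <= f_hi & freq <= sfreq / 2])
}

# brute-force two-channel CSP: maximize w' S1 w / w' (S1 + S2) w over a dense
# grid of unit vectors
csp_grid_oracle <- function(S1, S2, n_grid = 20000L) {
  theta <- seq(0, pi, length.out = n_grid)
  best <- -Inf; wbest <- NULL
  for (th in theta) {
    w <- c(cos(th), sin(th))
    r <- drop(w %*% S1 %*% w) / drop(w %*% (S1 + S2) %*% w)
    if (r > best) { best <- r; wbest <- w }
  }
  list(w = wbest, ratio = best)
}

cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# deterministic windows with exact diagonal per-class covariance structure:
# orthogonal unit-power sin/cos rows scaled per channel
make_diag_cov_windows <- function(scales_a, scales_b, T1 = 100L, reps = 2L) {
  t <- seq_len(T1)
  s <- sqrt(2) * sin(2 * pi * 4 * t / T1)
  cc <- sqrt(2) * cos(2 * pi * 4 * t / T1)
  base <- rbind(s, cc)
  wins <- array(0, dim = c(2L * reps, 2L, T1))
  for (r in seq_len(reps)) {
    wins[r, , ] <- base * scales_a
    wins[reps + r, , ] <- base * scales_b
  }
  list(windows = wins, labels = rep(c(0L, 1L), each = reps))
}

tiny_easy_trialset <- function(n_per_class = 8L, seed = 5L, n_channels = 6L) {
  generate_trialset(make_separable_spec(n_channels, "easy",
                                        n_trials_per_class = n_per_class,
                                        seed = seed))
}

tiny_model_config <- function(...) {
  defaults <- list(in_channels = 3L, in_samples = 64L, n_classes = 3L,
                   F1 = 2L, D = 2L, F2 = 4L, ms_kernels = c(3L, 5L, 7L),
                   K1 = 8L, K2 = 4L, fc_width = 5L, dropout = 0, seed = 3L)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

# central finite-difference gradient of the training loss for selected
# parameter indices
fd_gradient <- function(model, x, y, idx, h = 1e-5) {
  theta <- amanet:::flatten_params(model$params)
  vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    mp <- model; mp$params <- amanet:::unflatten_params(tp, model$params)
    lp <- amanet:::amanet_pass(mp, x, y = y, training = TRUE)$loss
    tm <- theta; tm[i] <- tm[i] - h
    mm <- model; mm$params <- amanet:::unflatten_params(tm, model$params)
    lm <- amanet:::amanet_pass(mm, x, y = y, training = TRUE)$loss
    (lp - lm) / (2 * h)
  }, numeric(1))
}
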