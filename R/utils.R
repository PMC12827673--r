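# Internal helpers: classed errors, seeded evaluation, small numerics.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed package error
#'
#' All user-facing validation failures are raised as conditions inheriting
#' from `amanet_error` plus a specific subclass, so callers and tests can
#' match on error type rather than message wording.
#'
#' @param class character subclass, e.g. `"amanet_dim_error"`.
#' @param msg message string.
#' @param call. included for symmetry with [stop()].
#' @keywords internal
#' @noRd
amanet_abort <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "amanet_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that library calls never disturb the
#' caller's random stream. Every stochastic operation in the package draws
#' through this gate.
#'
#' @param seed integer seed (must be < 2^31).
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    amanet_abort("amanet_config_error", "seed must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# numerically safe logistic
sigmoid <- function(x) 1 / (1 + exp(-x))

elu <- function(x) ifelse(x > 0, x, expm1(x))

# derivative expressed through the output y = elu(x): y + 1 for x <= 0
elu_grad_from_y <- function(x, y) ifelse(x > 0, 1, y + 1)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

# stable content fingerprint used in leakage audits (no external digest dep);
# a simple polynomial hash in double arithmetic is collision-safe enough here
fingerprint <- function(x) {
  raw <- as.integer(serialize(x, connection = NULL, version = 2))
  h <- 0
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @keywords internal
#' @useDynLib amanet, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"
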