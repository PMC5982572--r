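# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded draws inside the package do
#' not perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# One master seed expands into independent substreams (schedule, amplitudes,
# latencies, noise, ...) so changing e.g. the noise stream leaves the
# schedule untouched.  Kept strictly below 2^31 - 1.
substream <- function(seed, k) {
  s <- (as.numeric(seed) %% 1048573) + 1
  as.integer((s * 2654435 + as.numeric(k) * 40503) %% 2147483647)
}

# validate a single positive scalar
check_scalar <- function(x, name, positive = TRUE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("'%s' must be > 0 (got %g)", name, x)
  if (integer && x != round(x)) stopf("'%s' must be an integer (got %g)", name, x)
  invisible(x)
}
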