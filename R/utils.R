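# Internal helpers shared across modules.

#' Clamp to non-negative values
#'
#' The ramp \eqn{\lceil z \rceil = \max(0, z)} used by the saturating growth
#' and capacity terms of the case-study models.
#'
#' @param z Numeric vector.
#' @return `pmax(z, 0)`.
#' @export
clamp <- function(z) pmax(z, 0)

# Relative deviation with a floor in the denominator so near-zero values do
# not blow up: |u - v| / max(|u|, |v|, eps).
rel_dev <- function(u, v, eps = 1e-12) {
  abs(u - v) / pmax(abs(u), abs(v), eps)
}

# Evaluate a function catching errors and non-finite results; returns
# list(ok, value, message).
safe_eval <- function(expr) {
  out <- tryCatch(
    list(ok = TRUE, value = expr, message = NA_character_),
    error = function(e) list(ok = FALSE, value = NA_real_,
                             message = conditionMessage(e))
  )
  if (out$ok && (length(out$value) != 1L || !is.finite(out$value))) {
    out$ok <- FALSE
    out$message <- "non-finite value"
  }
  out
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards (so library calls never disturb user RNG flow).
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
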