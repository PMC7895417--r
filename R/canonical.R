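# Canonical form of (state, parameters) pairs and power sums.
#
# Two communities are indistinguishable to every impact function exactly when
# they share a canonical form: drop populations with zero abundance or zero
# parameters, lump populations with *identical* parameters by summing their
# abundances, and sort by parameter value. Lumping uses exact equality only —
# clone consistency is defined for identical parameters; near-ties are the
# numerical checker's business, not canonicalization's.

#' Canonicalize a community
#'
#' Reduces `(x, a)` to its canonical form. For scalar parameters (m = 1) this
#' is the ordered sequence of distinct non-zero parameter values with the
#' summed abundance carried by each. For m > 1, populations are lumped only
#' when their full parameter tuples are identical, and tuples are ordered
#' lexicographically (rows with any zero tuple are dropped, matching the
#' "parameter zero means no impact" convention).
#'
#' @param state Abundance vector.
#' @param params A [parameter_table()] or numeric vector/matrix.
#' @return An object of class `canonical_form` with fields `values` (for
#'   m = 1 a numeric vector; for m > 1 a matrix with one row per lumped
#'   class), `masses` (summed abundances, all > 0), `n` (original size) and
#'   `s` (reduced size).
#' @examples
#' canonicalize(c(2, 3, 3), c(0.5, -1, -1))  # values (-1, 0.5), masses (6, 2)
#' @export
canonicalize <- function(state, params) {
  sp <- check_state_params(state, params)
  a <- sp$params$a
  x <- sp$x
  n <- length(x)
  keep <- x > 0 & rowSums(a != 0) > 0
  a <- a[keep, , drop = FALSE]
  x <- x[keep]
  if (nrow(a) == 0L) {
    return(structure(list(values = numeric(0), masses = numeric(0),
                          n = n, s = 0L), class = "canonical_form"))
  }
  # exact-equality grouping: 17 significant digits round-trip doubles
  key <- apply(a, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\r"))
  groups <- split(seq_along(x), key)
  reps <- vapply(groups, `[`, integer(1), 1L)
  vals <- a[reps, , drop = FALSE]
  masses <- vapply(groups, function(i) sum(x[i]), numeric(1))
  ord <- do.call(order, lapply(seq_len(ncol(vals)), function(j) vals[, j]))
  vals <- vals[ord, , drop = FALSE]
  dimnames(vals) <- NULL
  masses <- unname(masses[ord])
  values <- if (ncol(vals) == 1L) drop(vals) else vals
  structure(list(values = values, masses = masses, n = n,
                 s = length(masses)), class = "canonical_form")
}

#' @export
print.canonical_form <- function(x, ...) {
  cat(sprintf("<canonical_form: n = %d -> s = %d>\n", x$n, x$s))
  if (x$s > 0L) print(cbind(value = x$values, mass = x$masses))
  invisible(x)
}

#' Zero-pad a canonical form back to an n-vector pair
#'
#' Maps a canonical form back to full-length `(x, a)` with `n - s` trailing
#' zeros, so canonical and original communities can be fed to the same
#' impact function.
#'
#' @param cf A `canonical_form`.
#' @param n Target length (defaults to the original size).
#' @return List with elements `x` and `a`.
#' @export
canonical_state <- function(cf, n = cf$n) {
  stopifnot(inherits(cf, "canonical_form"), n >= cf$s)
  m <- if (is.matrix(cf$values)) ncol(cf$values) else 1L
  a <- matrix(0, nrow = n, ncol = m)
  x <- numeric(n)
  if (cf$s > 0L) {
    a[seq_len(cf$s), ] <- cf$values
    x[seq_len(cf$s)] <- cf$masses
  }
  list(x = x, a = if (m == 1L) drop(a) else a)
}

#' Power sums of parameters weighted by abundance
#'
#' Returns \eqn{\sum_i a_i^p x_i} for \eqn{p = 1, \dots, p_{\max}} (scalar
#' parameters). These moments characterize the canonical form: two
#' communities with equal power sums for all p are indistinguishable to
#' every impact function, and canonicalization preserves every power sum
#' exactly because lumping merely re-brackets a finite sum at equal `a`.
#'
#' @param state Abundance vector.
#' @param params Scalar parameter vector (or single-column table).
#' @param p_max Highest power, >= 1.
#' @return Numeric vector of length `p_max`.
#' @export
power_sums <- function(state, params, p_max) {
  sp <- check_state_params(state, params)
  if (sp$params$m != 1L) {
    stop("power sums are defined for scalar parameters (m = 1)",
         call. = FALSE)
  }
  stopifnot(p_max >= 1L)
  a <- drop(sp$params$a)
  vapply(seq_len(p_max), function(p) sum(a^p * sp$x), numeric(1))
}
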