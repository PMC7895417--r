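# Community states and parameter tables.

#' Community state
#'
#' A community state is the vector of abundances \eqn{x = (x_1, \dots, x_n)}
#' of all populations in the ecosystem. Abundances are non-negative and may
#' be raw counts per volume or normalized.
#'
#' @param x Numeric vector, all entries >= 0, length >= 1.
#' @return A numeric vector of class `community_state`.
#' @export
community_state <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 1L) stop("a community needs at least one population",
                           call. = FALSE)
  if (anyNA(x) || any(x < 0)) {
    stop("abundances must be non-negative and non-missing", call. = FALSE)
  }
  structure(x, class = "community_state")
}

#' Per-population parameter table
#'
#' Holds the n x m matrix of first-order parameters (one row per population,
#' one column per parameter) and, optionally, named n x n matrices of
#' second-order (pairwise) parameters \eqn{a_{ij}}.
#'
#' @param a Numeric matrix (n x m) or vector (treated as n x 1). Column names
#'   are kept as parameter labels.
#' @param pairwise Optional named list of square n x n numeric matrices.
#' @return An object of class `parameter_table` with elements `a`, `pairwise`,
#'   `n`, `m`.
#' @examples
#' pt <- parameter_table(c(0.5, -1))
#' pt$n
#' @export
parameter_table <- function(a, pairwise = NULL) {
  if (is.vector(a) && is.numeric(a)) a <- matrix(a, ncol = 1L)
  if (!is.matrix(a) || !is.numeric(a)) {
    stop("`a` must be a numeric matrix or vector", call. = FALSE)
  }
  if (ncol(a) < 1L) stop("need at least one parameter column", call. = FALSE)
  if (is.null(colnames(a))) colnames(a) <- paste0("a", seq_len(ncol(a)))
  n <- nrow(a)
  if (!is.null(pairwise)) {
    if (!is.list(pairwise) || is.null(names(pairwise)) ||
        any(names(pairwise) == "")) {
      stop("`pairwise` must be a named list of matrices", call. = FALSE)
    }
    for (nm in names(pairwise)) {
      p <- pairwise[[nm]]
      if (!is.matrix(p) || nrow(p) != n || ncol(p) != n) {
        stop(sprintf("pairwise matrix '%s' must be %d x %d", nm, n, n),
             call. = FALSE)
      }
    }
  }
  structure(list(a = a, pairwise = pairwise, n = n, m = ncol(a)),
            class = "parameter_table")
}

#' @export
print.parameter_table <- function(x, ...) {
  cat(sprintf("<parameter_table: %d populations, %d parameter column%s", x$n,
              x$m, if (x$m == 1L) "" else "s"))
  if (length(x$pairwise)) {
    cat(sprintf(", pairwise: %s", paste(names(x$pairwise), collapse = ", ")))
  }
  cat(">\n")
  print(x$a, ...)
  invisible(x)
}

check_state_params <- function(x, params) {
  if (!inherits(params, "parameter_table")) params <- parameter_table(params)
  x <- as.numeric(x)
  if (length(x) != params$n) {
    stop(sprintf("state has %d populations but parameter table has %d rows",
                 length(x), params$n), call. = FALSE)
  }
  list(x = x, params = params)
}

#' Read / write parameter tables as delimited text
#'
#' First-order tables are written with a header row of parameter labels and
#' one row per population (populations are order-preserving and 1-based).
#' Pairwise matrices live in separate square files without headers.
#'
#' @param path File path.
#' @param sep Field separator; the reader auto-detects `,` vs tab.
#' @return `read_parameter_table` returns a `parameter_table`;
#'   `write_parameter_table` returns `path` invisibly.
#' @export
read_parameter_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  parameter_table(as.matrix(df))
}

#' @rdname read_parameter_table
#' @param params A `parameter_table`.
#' @export
write_parameter_table <- function(params, path, sep = ",") {
  utils::write.table(params$a, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname read_parameter_table
#' @export
read_pairwise_matrix <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("pairwise matrix file must be square",
                               call. = FALSE)
  m
}

#' @rdname read_parameter_table
#' @param m A square numeric matrix.
#' @export
write_pairwise_matrix <- function(m, path, sep = ",") {
  utils::write.table(m, path, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
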