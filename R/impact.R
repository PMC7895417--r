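# Impact functions and the expression algebra built from them.
#
# An impact function phi(x, a) describes the impact of a community on some
# feature of the ecosystem (a growth rate, a niche, a resource, ...). Every
# clone-consistent impact function can be generated from "basic" impact
# functions
#
#   (x, a) -> sum_i zeta(a_ik) x_i          (first order)
#   (x, a) -> sum_ij zeta(a_ij) x_i x_j     (second order)
#
# with zeta(0) = 0, via sums, products, scalar multiples, composition with
# arbitrary combining functions chi, and limits. Expression trees over these
# leaves are therefore consistent *by construction*; arbitrary black boxes
# are not, and must be probed numerically (see check_impact_criteria).

.ZETA_ZERO_TOL <- 1e-12

new_impact_node <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "impact_expression")
}

#' Leaves and nodes of impact expressions
#'
#' Constructors for the expression-tree dialect:
#' * `ie_basic(column, zeta, zeta_args)` — a basic impact function
#'   \eqn{\sum_i \zeta(a_{ik}) x_i} over parameter column `k`.
#' * `ie_pairwise(name, zeta, zeta_args)` — a second-order building block
#'   \eqn{\sum_{ij} \zeta(a_{ij}) x_i x_j} over the named pairwise matrix.
#' * `ie_const(value)` — a constant leaf.
#' * `ie_sum(...)`, `ie_product(...)` — n-ary sum / product nodes.
#' * `ie_scale(factor, child)` — scalar multiple.
#' * `ie_apply(fn, ..., args)` — apply the registered transform `fn` (the
#'   combining function \eqn{\chi}) to the child expressions.
#' * `ie_blackbox(f, label)` — an opaque leaf `f(x, params)`; evaluable but
#'   structurally uncertifiable.
#'
#' @param column Parameter column index (or name) `k`.
#' @param zeta,zeta_args Registered transform name and its argument list;
#'   `zeta` must satisfy `zeta(0) = 0`.
#' @param name Name of a pairwise matrix in the parameter table.
#' @param value Constant value.
#' @param factor Scalar multiplier.
#' @param child,... Child expressions.
#' @param fn Registered transform name for the combining function.
#' @param args Argument list for `fn`.
#' @param f A function `(x, params) -> numeric(1)`.
#' @param label Display label for a black-box leaf.
#' @return An object of class `impact_expression`.
#' @examples
#' # pollination--grazing impact on a plant population:
#' e <- ie_sum(
#'   ie_scale(1, ie_apply("holling2", ie_basic(2))),
#'   ie_scale(-1, ie_basic(1))
#' )
#' certify_structure(e)
#' @export
ie_basic <- function(column, zeta = "identity", zeta_args = list()) {
  new_impact_node("basic", column = column, zeta = zeta,
                  zeta_args = zeta_args)
}

#' @rdname ie_basic
#' @export
ie_pairwise <- function(name, zeta = "identity", zeta_args = list()) {
  new_impact_node("pairwise", name = name, zeta = zeta,
                  zeta_args = zeta_args)
}

#' @rdname ie_basic
#' @export
ie_const <- function(value) {
  stopifnot_scalar(value, "value")
  new_impact_node("const", value = value)
}

#' @rdname ie_basic
#' @export
ie_sum <- function(...) new_impact_node("sum", children = list(...))

#' @rdname ie_basic
#' @export
ie_product <- function(...) new_impact_node("product", children = list(...))

#' @rdname ie_basic
#' @export
ie_scale <- function(factor, child) {
  stopifnot_scalar(factor, "factor")
  new_impact_node("scale", factor = factor, children = list(child))
}

#' @rdname ie_basic
#' @export
ie_apply <- function(fn, ..., args = list()) {
  new_impact_node("apply", fn = fn, args = args, children = list(...))
}

#' @rdname ie_basic
#' @export
ie_blackbox <- function(f, label = "blackbox") {
  stopifnot(is.function(f))
  new_impact_node("blackbox", f = f, label = label)
}

#' Evaluate a basic impact function
#'
#' Computes \eqn{\sum_i \zeta(a_{ik}) x_i} for parameter column `k`. Errors if
#' the column is missing or if the declared transform violates
#' \eqn{\zeta(0) = 0} (within `1e-12`).
#'
#' @param b An `impact_expression` of kind `basic` (see [ie_basic()]).
#' @param state Abundance vector (or [community_state()]).
#' @param params A [parameter_table()] (or numeric vector/matrix).
#' @return A single number.
#' @examples
#' eval_basic(ie_basic(1), c(1, 2), parameter_table(c(0.5, -1)))  # -1.5
#' @export
eval_basic <- function(b, state, params) {
  sp <- check_state_params(state, params)
  k <- b$column
  if (is.character(k)) k <- match(k, colnames(sp$params$a))
  if (is.na(k) || k < 1L || k > sp$params$m) {
    stop("parameter column out of range", call. = FALSE)
  }
  zeta <- get_transform(b$zeta, b$zeta_args)
  if (abs(zeta(0)) > .ZETA_ZERO_TOL) {
    stop(sprintf("transform '%s' is not a valid zeta: zeta(0) != 0", b$zeta),
         call. = FALSE)
  }
  sum(zeta(sp$params$a[, k]) * sp$x)
}

#' Evaluate a second-order (pairwise) impact function
#'
#' Computes \eqn{\sum_i \sum_j \zeta(a_{ij}) x_i x_j} for the named pairwise
#' matrix, i.e. `t(x) %*% zeta(A) %*% x`.
#'
#' @inheritParams eval_basic
#' @param p An `impact_expression` of kind `pairwise`.
#' @return A single number.
#' @export
eval_pairwise <- function(p, state, params) {
  sp <- check_state_params(state, params)
  A <- sp$params$pairwise[[p$name]]
  if (is.null(A)) {
    stop(sprintf("pairwise matrix '%s' not found in parameter table", p$name),
         call. = FALSE)
  }
  zeta <- get_transform(p$zeta, p$zeta_args)
  if (abs(zeta(0)) > .ZETA_ZERO_TOL) {
    stop(sprintf("transform '%s' is not a valid zeta: zeta(0) != 0", p$zeta),
         call. = FALSE)
  }
  drop(crossprod(sp$x, zeta(A) %*% sp$x))
}

#' Evaluate an impact expression tree
#'
#' Recursive evaluation; domain errors of a combining function (e.g. log of a
#' negative intermediate) are reported together with the offending node kind.
#'
#' @inheritParams eval_basic
#' @param e An `impact_expression`.
#' @return A single number.
#' @export
eval_expression <- function(e, state, params) {
  stopifnot(inherits(e, "impact_expression"))
  switch(e$kind,
    const = e$value,
    basic = eval_basic(e, state, params),
    pairwise = eval_pairwise(e, state, params),
    blackbox = e$f(as.numeric(state),
                   if (inherits(params, "parameter_table")) params
                   else parameter_table(params)),
    sum = sum(vapply(e$children, eval_expression, numeric(1), state, params)),
    product = prod(vapply(e$children, eval_expression, numeric(1), state,
                          params)),
    scale = e$factor * eval_expression(e$children[[1L]], state, params),
    apply = {
      vals <- vapply(e$children, eval_expression, numeric(1), state, params)
      chi <- get_transform(e$fn, e$args)
      out <- do.call(chi, as.list(vals))
      if (length(out) != 1L || !is.finite(out)) {
        stop(sprintf("combining function '%s' returned a non-finite value",
                     e$fn), call. = FALSE)
      }
      out
    },
    stop(sprintf("malformed expression node of kind '%s'", e$kind),
         call. = FALSE)
  )
}

#' @export
print.impact_expression <- function(x, ...) {
  fmt <- function(e) {
    switch(e$kind,
      const = format(e$value),
      basic = sprintf("basic[k=%s, zeta=%s]", e$column, e$zeta),
      pairwise = sprintf("pairwise[%s, zeta=%s]", e$name, e$zeta),
      blackbox = sprintf("blackbox[%s]", e$label),
      sum = paste0("(", paste(vapply(e$children, fmt, ""), collapse = " + "),
                   ")"),
      product = paste0("(", paste(vapply(e$children, fmt, ""),
                                  collapse = " * "), ")"),
      scale = sprintf("%s*%s", format(e$factor), fmt(e$children[[1L]])),
      apply = sprintf("%s(%s)", e$fn,
                      paste(vapply(e$children, fmt, ""), collapse = ", "))
    )
  }
  cat("<impact_expression> ", fmt(x), "\n", sep = "")
  invisible(x)
}

#' Structurally certify an expression as clone-consistent
#'
#' Walks the tree: if every leaf is a basic impact function, a pairwise
#' building block, or a constant, the expression lies in the generated algebra
#' of impact functions and is consistent by construction. Trees containing
#' black-box leaves are `"undecidable"` — structure alone can never prove
#' inconsistency, only the numerical checker can falsify it.
#'
#' @param e An `impact_expression`.
#' @return An object of class `structure_verdict` with fields `verdict`
#'   (`"consistent-by-construction"` or `"undecidable"`) and `blackboxes`
#'   (labels of opaque leaves found).
#' @export
certify_structure <- function(e) {
  if (!inherits(e, "impact_expression")) {
    stop("not an impact expression", call. = FALSE)
  }
  boxes <- character(0)
  walk <- function(node) {
    if (!inherits(node, "impact_expression") || is.null(node$kind)) {
      stop("malformed expression tree", call. = FALSE)
    }
    switch(node$kind,
      const = , basic = , pairwise = NULL,
      blackbox = boxes <<- c(boxes, node$label),
      sum = , product = , scale = , apply =
        lapply(node$children, walk),
      stop(sprintf("malformed expression node of kind '%s'", node$kind),
           call. = FALSE)
    )
    invisible(NULL)
  }
  walk(e)
  verdict <- if (length(boxes)) "undecidable" else "consistent-by-construction"
  structure(list(verdict = verdict, blackboxes = unique(boxes)),
            class = "structure_verdict")
}

#' @export
print.structure_verdict <- function(x, ...) {
  cat("<structure_verdict> ", x$verdict, "\n", sep = "")
  if (length(x$blackboxes)) {
    cat("  opaque leaves: ", paste(x$blackboxes, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

# -- JSON (de)serialization of expression trees ------------------------------

expression_to_list <- function(e) {
  stopifnot(inherits(e, "impact_expression"))
  if (e$kind == "blackbox") {
    stop("black-box leaves cannot be serialized", call. = FALSE)
  }
  out <- switch(e$kind,
    const = list(kind = "const", value = e$value),
    basic = list(kind = "basic", column = e$column, zeta = e$zeta,
                 zeta_args = e$zeta_args),
    pairwise = list(kind = "pairwise", name = e$name, zeta = e$zeta,
                    zeta_args = e$zeta_args),
    scale = list(kind = "scale", factor = e$factor,
                 children = lapply(e$children, expression_to_list)),
    apply = list(kind = "apply", fn = e$fn, args = e$args,
                 children = lapply(e$children, expression_to_list)),
    list(kind = e$kind, children = lapply(e$children, expression_to_list))
  )
  out
}

expression_from_list <- function(lst) {
  kids <- function() lapply(lst$children, expression_from_list)
  switch(lst$kind,
    const = ie_const(lst$value),
    basic = ie_basic(lst$column, lst$zeta %||% "identity",
                     as.list(lst$zeta_args %||% list())),
    pairwise = ie_pairwise(lst$name, lst$zeta %||% "identity",
                           as.list(lst$zeta_args %||% list())),
    sum = do.call(ie_sum, kids()),
    product = do.call(ie_product, kids()),
    scale = ie_scale(lst$factor, expression_from_list(lst$children[[1L]])),
    apply = do.call(ie_apply, c(kids(), list(fn = lst$fn,
                                             args = as.list(lst$args %||%
                                                              list())))),
    stop(sprintf("unknown node kind '%s' in config", lst$kind), call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write impact expressions as JSON configs
#'
#' The config dialect mirrors the constructors: node kinds are `sum`,
#' `product`, `scale`, `apply`, `basic`, `pairwise` and `const`; transforms
#' are referenced by registry name. Black-box leaves cannot round-trip.
#'
#' @param e An `impact_expression`.
#' @param path File path.
#' @return `read_expression` returns an `impact_expression`.
#' @export
write_expression <- function(e, path) {
  jsonlite::write_json(expression_to_list(e), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  expression_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}
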