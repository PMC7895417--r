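# Registry of named scalar transforms.
#
# Three roles share the registry:
#   * zeta  -- parameter transforms inside basic impact functions; these must
#              satisfy zeta(0) = 0 so that a zero parameter means "no impact".
#   * chi   -- combining functions wrapped around impact functions
#              (unconstrained).
#   * eta   -- per-factor transforms of the product-form ensemble models;
#              conventionally eta(0) = 1 so absent interactions are neutral.
#
# Registry names serialize to expression-tree configs, which is why
# transforms are addressed by name + argument list rather than by closure.

.transform_registry <- new.env(parent = emptyenv())

#' Register a named scalar transform
#'
#' Transforms are function factories: `fn` receives the arguments stored in an
#' expression node (e.g. the exponent `p` of a power transform) and the data
#' argument `z` first. All built-in transforms are vectorized in `z`.
#'
#' @param name Registry key.
#' @param fn A function `function(z, ...)`.
#' @param overwrite Overwrite an existing entry?
#' @return `name`, invisibly.
#' @examples
#' register_transform("half", function(z) z / 2, overwrite = TRUE)
#' get_transform("half")(4)
#' @export
register_transform <- function(name, fn, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (!overwrite && exists(name, envir = .transform_registry)) {
    stop(sprintf("transform '%s' is already registered", name), call. = FALSE)
  }
  assign(name, fn, envir = .transform_registry)
  invisible(name)
}

#' Look up a registered transform
#'
#' @param name Registry key.
#' @param args Named list of extra arguments baked into the returned closure
#'   (e.g. `list(p = 2)` for a power transform).
#' @return A function of one numeric argument.
#' @export
get_transform <- function(name, args = list()) {
  if (!exists(name, envir = .transform_registry)) {
    stop(sprintf("unknown transform '%s'", name), call. = FALSE)
  }
  fn <- get(name, envir = .transform_registry)
  if (length(args) == 0L) return(fn)
  function(z) do.call(fn, c(list(z), args))
}

#' List registered transform names
#' @return Character vector.
#' @export
list_transforms <- function() sort(ls(envir = .transform_registry))

# Built-ins. Registered at load time (see .onLoad).
.register_builtin_transforms <- function() {
  reg <- function(name, fn) register_transform(name, fn, overwrite = TRUE)
  reg("identity", function(z) z)
  reg("power", function(z, p = 2) z^p)
  reg("scale", function(z, a = 1) a * z)
  reg("affine", function(z, a = 1, b = 0) a * z + b)
  reg("clamp", function(z) pmax(z, 0))
  reg("exp", function(z) exp(z))
  reg("log", function(z) log(z))
  reg("one_plus", function(z) 1 + z)
  # Holling type-II saturation z / (h + z); the continuous extension of
  # 1 / (1 + z^-1) at z = 0 (value 0, i.e. no pollination without insects).
  reg("holling2", function(z, h = 1) z / (h + z))
  # One unique-interaction summand a*x_i/(h + x_i) expressed as a combining
  # function of the basic impact w = a*x_i: w/(h + w/a).
  reg("holling2_scaled", function(z, h = 1, a = 1) z / (h + z / a))
  # Capacity transform sigma(z) = 1 - clamp(z)^q of the saturating
  # carrying-capacity factor; sigma(0) = 1 (empty niche), sigma(1) = 0 (full).
  reg("capacity_saturation", function(z, q = 10) 1 - pmax(z, 0)^q)
  # Gaussian bump, eta(0) = 1; a bounded nonlinearity for ensemble factors.
  reg("gauss", function(z) exp(-z^2))
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  .register_builtin_transforms()
}
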