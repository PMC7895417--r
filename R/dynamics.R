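# Population models of the mandated form R_j = x_j * phi_j(x, a), their
# simulation in continuous or discrete time, and fixed-point computation.
#
# The factor x_j is structural: extinction is absorbing by construction, and
# the per-capita rate phi_j is the impact function through which the rest of
# the community acts on population j.

#' Construct a population model
#'
#' A model couples `n` populations through per-capita rate functions
#' \eqn{\phi_j}: in continuous time \eqn{\dot x_j = x_j \phi_j(x)}, in
#' discrete time \eqn{x_j(t+1) = x_j(t) + x_j(t)\phi_j(x(t))}.
#'
#' @param n Number of populations.
#' @param phi Vectorized per-capita rate: `function(x) -> numeric(n)`.
#' @param tables Named list of parameter objects the model was built from:
#'   `vectors` (named list of length-n numerics) and `matrices` (named list
#'   of n x n matrices). Used by the generic clone-split rule.
#' @param rebuild `function(vectors, matrices) -> population_model`; used to
#'   reconstruct the model after a clone split. If `NULL` the model cannot be
#'   split.
#' @param phi_exprs Optional list of `n` [impact expression][ie_basic()]
#'   trees mirroring `phi` (plus `expr_params`, a function
#'   `function(j) -> parameter_table` supplying each tree's parameters).
#'   When present and free of black boxes, the model is certifiable as
#'   consistent by construction.
#' @param expr_params See `phi_exprs`.
#' @param time_mode `"continuous"` (ODE) or `"discrete"` (map).
#' @param frozen Integer indices whose abundance is held constant (their
#'   derivative is zeroed; used e.g. to represent a conditioned-medium
#'   footprint). Indexing of the remaining populations is unaffected.
#' @param domain `"nonneg"` or `"positive"` (models involving `log(x_i)`
#'   require strictly positive abundances).
#' @param family Short family label (`"glv"`, `"log"`, ...).
#' @param split Optional custom split rule `function(model, j) -> model`
#'   overriding the generic table-duplication rule.
#' @return An object of class `population_model`.
#' @export
population_model <- function(n, phi, tables = list(), rebuild = NULL,
                             phi_exprs = NULL, expr_params = NULL,
                             time_mode = c("continuous", "discrete"),
                             frozen = integer(0),
                             domain = c("nonneg", "positive"),
                             family = "custom", split = NULL) {
  stopifnot(is.function(phi), n >= 1L)
  structure(list(n = as.integer(n), phi = phi, tables = tables,
                 rebuild = rebuild, phi_exprs = phi_exprs,
                 expr_params = expr_params,
                 time_mode = match.arg(time_mode),
                 frozen = as.integer(frozen),
                 domain = match.arg(domain), family = family,
                 split = split),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model '%s': n = %d, %s time%s>\n", x$family, x$n,
              x$time_mode,
              if (length(x$frozen))
                paste0(", frozen: ", paste(x$frozen, collapse = ","))
              else ""))
  invisible(x)
}

#' Right-hand side of a population model
#'
#' Returns \eqn{(x_j \phi_j(x))_j} with frozen populations zeroed. Expression
#' or domain errors are propagated with the population index when it can be
#' identified.
#'
#' @param model A [population_model()].
#' @param state Abundance vector of length `n`.
#' @return Numeric vector of length `n`.
#' @export
rhs <- function(model, state) {
  x <- as.numeric(state)
  if (length(x) != model$n) {
    stop(sprintf("state length %d but model has %d populations", length(x),
                 model$n), call. = FALSE)
  }
  if (model$domain == "positive" && any(x <= 0)) {
    stop("model domain requires strictly positive abundances (log terms)",
         call. = FALSE)
  }
  r <- x * model$phi(x)
  if (length(model$frozen)) r[model$frozen] <- 0
  r
}

#' Simulate a population model
#'
#' Continuous mode integrates with an adaptive Dormand-Prince 5(4) method and
#' samples the solution on `t_grid`; discrete mode iterates the map
#' \eqn{x(t+1) = x(t) + R(x(t))} over integer steps. Frozen populations stay
#' constant throughout.
#'
#' @param model A [population_model()].
#' @param x0 Initial abundances (>= 0; strictly positive for log-domain
#'   models).
#' @param t_grid Ascending output times (integers for discrete mode).
#' @param solver_opts List with `rtol` (default `1e-10`), `atol` (`1e-12`)
#'   and `max_step` (`Inf`). Tolerances are deliberately tight so that
#'   integration error never masquerades as clone inconsistency.
#' @return An object of class `trajectory`: `times`, `abundances`
#'   (times x n matrix) and solver metadata.
#' @export
simulate_model <- function(model, x0, t_grid,
                           solver_opts = list()) {
  opts <- utils::modifyList(list(rtol = 1e-10, atol = 1e-12, max_step = Inf,
                                 max_steps = 5e6, blowup = 1e8),
                            solver_opts)
  x0 <- as.numeric(x0)
  if (length(x0) != model$n) stop("x0 has wrong length", call. = FALSE)
  if (any(x0 < 0)) stop("x0 must be non-negative", call. = FALSE)
  if (length(t_grid) < 2L) stop("t_grid must have at least two times",
                                call. = FALSE)
  if (model$time_mode == "discrete") {
    steps <- as.integer(round(t_grid))
    if (any(steps != t_grid)) stop("discrete mode needs integer steps",
                                   call. = FALSE)
    n_iter <- max(steps)
    X <- matrix(NA_real_, length(steps), model$n)
    x <- x0
    for (t in 0:n_iter) {
      hit <- which(steps == t)
      if (length(hit)) X[hit, ] <- rep(x, each = length(hit))
      if (t < n_iter) x <- x + rhs(model, x)
    }
    return(structure(list(times = steps, abundances = X, method = "map",
                          rtol = NA_real_, atol = NA_real_),
                     class = "trajectory"))
  }
  f <- function(t, y) rhs(model, y)
  X <- ode_dopri5(f, x0, t_grid, rtol = opts$rtol, atol = opts$atol,
                  max_step = opts$max_step, max_steps = opts$max_steps,
                  blowup = opts$blowup)
  structure(list(times = t_grid, abundances = X, method = "dopri5",
                 rtol = opts$rtol, atol = opts$atol),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d times in [%g, %g], %d populations, %s>\n",
              length(x$times), min(x$times), max(x$times),
              ncol(x$abundances), x$method))
  invisible(x)
}

#' Tidy a trajectory
#'
#' @param x A `trajectory`.
#' @param row.names,optional Unused (S3 signature).
#' @param wide If `TRUE`, one column per population; otherwise long format
#'   `(time, population, abundance)`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.trajectory <- function(x, row.names = NULL, optional = FALSE,
                                     wide = FALSE, ...) {
  n <- ncol(x$abundances)
  if (wide) {
    df <- data.frame(time = x$times, x$abundances)
    names(df) <- c("time", paste0("x", seq_len(n)))
    return(df)
  }
  data.frame(time = rep(x$times, n),
             population = rep(seq_len(n), each = length(x$times)),
             abundance = as.vector(x$abundances))
}

#' Interior fixed point of a linear interaction system
#'
#' Solves \eqn{0 = 1 + B x} for the interaction matrix `B` (caller's
#' convention: diagonal `-1`, so a population maximally competes with
#' itself). This characterizes the interior fixed points of both the
#' existing and the new conditioned-medium case-study models.
#'
#' @param b Square interaction matrix.
#' @return An object of class `fixed_point` (fields `x`, `residual`,
#'   `classification`).
#' @export
interior_fixed_point_linear <- function(b) {
  stopifnot(is.matrix(b), nrow(b) == ncol(b))
  if (kappa(b, exact = FALSE) > 1e12) {
    stop("interaction matrix is singular or ill-conditioned", call. = FALSE)
  }
  x <- solve(b, rep(-1, nrow(b)))
  structure(list(x = x, residual = max(abs(1 + b %*% x)),
                 classification = "interior-linear"),
            class = "fixed_point")
}

#' Refine a fixed point by damped Newton iteration
#'
#' Root-finds `R(x) = 0` restricted to the support of the initial guess
#' (entries of `x_guess` that are zero stay zero: extinction is absorbing).
#' The Jacobian is obtained by central finite differences.
#'
#' @param model A [population_model()].
#' @param x_guess Non-negative starting point.
#' @param tol Residual tolerance (max-norm), default `1e-10`.
#' @param max_iter Maximum Newton iterations.
#' @return A `fixed_point` with classification `"numeric"` (or `"boundary"`
#'   when the support is empty or partial).
#' @export
refine_fixed_point <- function(model, x_guess, tol = 1e-10, max_iter = 100L) {
  x <- as.numeric(x_guess)
  if (any(x < 0)) stop("x_guess must be non-negative", call. = FALSE)
  supp <- which(x > 0)
  cls <- if (length(supp) == model$n) "numeric" else "boundary"
  if (length(supp) == 0L) {
    return(structure(list(x = x, residual = 0, classification = "boundary"),
                     class = "fixed_point"))
  }
  res_fn <- function(xs) {
    full <- numeric(model$n)
    full[supp] <- xs
    rhs(model, full)[supp]
  }
  xs <- x[supp]
  r <- res_fn(xs)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) <= tol) break
    J <- numeric_jacobian(res_fn, xs)
    step <- tryCatch(solve(J, -r), error = function(e) {
      stop("singular Jacobian in fixed-point refinement", call. = FALSE)
    })
    lambda <- 1
    repeat {
      cand <- xs + lambda * step
      if (model$domain == "positive") cand <- pmax(cand, 1e-12)
      rc <- tryCatch(res_fn(cand), error = function(e) NULL)
      if (!is.null(rc) && all(is.finite(rc)) &&
          (max(abs(rc)) < max(abs(r)) || lambda < 1e-4)) {
        xs <- cand
        r <- rc
        break
      }
      lambda <- lambda / 2
      if (lambda < 1e-8) stop("fixed-point refinement stalled",
                              call. = FALSE)
    }
  }
  if (max(abs(r)) > tol) {
    stop(sprintf("fixed-point refinement did not reach residual %g in %d iterations",
                 tol, max_iter), call. = FALSE)
  }
  full <- numeric(model$n)
  full[supp] <- xs
  structure(list(x = full, residual = max(abs(r)), classification = cls),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("<fixed_point (%s), residual %.3g>\n", x$classification,
              x$residual))
  print(x$x)
  invisible(x)
}

numeric_jacobian <- function(f, x, h_rel = 1e-7) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- h_rel * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# -- qualitative classification ---------------------------------------------

# Local maxima of a series with a simple prominence measure: peak height
# minus the higher of the two flanking minima (up to the nearest higher
# point or the boundary).
local_maxima_prominence <- function(y) {
  n <- length(y)
  if (n < 3L) return(numeric(0))
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  proms <- vapply(idx, function(i) {
    l <- i; while (l > 1L && y[l - 1L] <= y[i]) l <- l - 1L
    r <- i; while (r < n && y[r + 1L] <= y[i]) r <- r + 1L
    left_min <- min(y[l:i]); right_min <- min(y[i:r])
    y[i] - max(left_min, right_min)
  }, numeric(1))
  proms
}

#' Classify a trajectory as converged or oscillating
#'
#' `"converged"`: the final distance to `x_star` is below `conv_dist` and
#' the distance envelope over the last 20 percent of the horizon is
#' non-increasing (successive local maxima of the distance decrease).
#' `"oscillating"`: the first series has at least three local maxima with
#' prominence above `min_prominence`. Otherwise `"indeterminate"`.
#'
#' @param times Time grid.
#' @param X Matrix of series (rows = times); for aggregate classification
#'   pass the summed clone series.
#' @param x_star Reference fixed point matching `ncol(X)`.
#' @param conv_dist Convergence distance threshold (Euclidean), default
#'   `1e-3`.
#' @param min_prominence Prominence threshold for counting oscillation
#'   peaks, default `0.05`.
#' @return List with `label`, `final_distance`, `n_peaks`.
#' @export
classify_dynamics <- function(times, X, x_star, conv_dist = 1e-3,
                              min_prominence = 0.05) {
  X <- as.matrix(X)
  d <- sqrt(rowSums((X - matrix(x_star, nrow(X), ncol(X),
                                byrow = TRUE))^2))
  final_d <- d[length(d)]
  tail_idx <- which(times >= times[1] + 0.8 * (max(times) - times[1]))
  tail_d <- d[tail_idx]
  tail_peaks <- tail_d[which(diff(sign(diff(tail_d))) < 0) + 1L]
  envelope_ok <- length(tail_peaks) < 2L || all(diff(tail_peaks) <= 0)
  proms <- local_maxima_prominence(X[, 1L])
  n_peaks <- sum(proms > min_prominence)
  label <- if (final_d < conv_dist && envelope_ok) {
    "converged"
  } else if (n_peaks >= 3L) {
    "oscillating"
  } else {
    "indeterminate"
  }
  list(label = label, final_distance = final_d, n_peaks = n_peaks)
}
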