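# Adaptive explicit Runge-Kutta integration, Dormand-Prince 5(4).
#
# No ODE package is assumed; the integrator is self-contained. Steps are
# clipped to land exactly on the requested output times, so trajectories are
# solver-grid independent. Error control is the usual mixed absolute/relative
# scaled RMS norm with PI step-size control and FSAL reuse.

# Butcher tableau (Dormand & Prince 1980).
.DP_C <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
.DP_A <- matrix(0, 7, 7)
.DP_A[2, 1] <- 1 / 5
.DP_A[3, 1:2] <- c(3 / 40, 9 / 40)
.DP_A[4, 1:3] <- c(44 / 45, -56 / 15, 32 / 9)
.DP_A[5, 1:4] <- c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729)
.DP_A[6, 1:5] <- c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176,
                   -5103 / 18656)
.DP_A[7, 1:6] <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
.DP_B5 <- .DP_A[7, ]                       # 5th-order solution weights
.DP_B4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)            # embedded 4th-order weights
.DP_E <- .DP_B5 - .DP_B4

#' Integrate an ODE with the Dormand-Prince 5(4) method
#'
#' @param f Right-hand side `function(t, y) -> numeric`.
#' @param y0 Initial state.
#' @param times Strictly increasing output times; `times[1]` is the initial
#'   time.
#' @param rtol,atol Relative / absolute error tolerances.
#' @param max_step Maximum step size (useful for non-smooth right-hand
#'   sides such as clamped growth terms).
#' @param max_steps Safety cap on accepted + rejected steps.
#' @param blowup Magnitude at which the solution is declared divergent
#'   (finite-time blowup guard); integration then fails with an
#'   `ode_failure` carrying the last valid state.
#' @return Matrix `length(times) x length(y0)` of states at `times`.
#' @keywords internal
#' @export
ode_dopri5 <- function(f, y0, times, rtol = 1e-10, atol = 1e-12,
                       max_step = Inf, max_steps = 5e6, blowup = 1e8) {
  ny <- length(y0)
  nt <- length(times)
  if (nt < 2L || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing with at least two entries",
         call. = FALSE)
  }
  out <- matrix(NA_real_, nt, ny)
  out[1L, ] <- y0
  t <- times[1L]
  y <- as.numeric(y0)
  k <- matrix(0, 7, ny)
  k[1, ] <- f(t, y)
  # initial step heuristic
  sc <- atol + rtol * abs(y)
  d0 <- sqrt(mean((y / sc)^2))
  d1 <- sqrt(mean((k[1, ] / sc)^2))
  h <- if (d1 > 1e-10) 0.01 * d0 / d1 else 1e-6
  h <- min(h, times[nt] - t, max_step)
  if (h <= 0 || !is.finite(h)) h <- 1e-6
  i_out <- 2L
  n_steps <- 0L
  err_prev <- 1
  while (i_out <= nt) {
    if (n_steps >= max_steps) {
      stop(structure(class = c("ode_failure", "error", "condition"),
                     list(message = sprintf(
                       "step limit reached at t = %.6g", t),
                       call = NULL, t = t, y = y)))
    }
    hit_output <- FALSE
    if (t + h >= times[i_out] - 1e-14 * max(1, abs(times[i_out]))) {
      h <- times[i_out] - t
      hit_output <- TRUE
    }
    if (h < 1e-14 * max(1, abs(t))) {
      stop(structure(class = c("ode_failure", "error", "condition"),
                     list(message = sprintf(
                       "step size underflow at t = %.6g", t),
                       call = NULL, t = t, y = y)))
    }
    for (s in 2:7) {
      ys <- y + h * drop(.DP_A[s, 1:(s - 1)] %*% k[1:(s - 1), , drop = FALSE])
      k[s, ] <- f(t + .DP_C[s] * h, ys)
    }
    y5 <- y + h * drop(.DP_B5 %*% k)
    err_vec <- h * drop(.DP_E %*% k)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean((err_vec / sc)^2))
    n_steps <- n_steps + 1L
    if (!is.finite(err)) err <- 2
    if (err <= 1) {                       # accept
      if (max(abs(y5)) > blowup) {
        stop(structure(class = c("ode_failure", "error", "condition"),
                       list(message = sprintf(
                         "solution diverged (|y| > %g) at t = %.6g",
                         blowup, t), call = NULL, t = t, y = y)))
      }
      t <- t + h
      y <- y5
      k[1, ] <- k[7, ]                    # FSAL
      if (hit_output) {
        while (i_out <= nt &&
               abs(times[i_out] - t) <= 1e-12 * max(1, abs(t))) {
          out[i_out, ] <- y
          i_out <- i_out + 1L
        }
      }
      # PI controller (orders 5/4): exponents 0.7/5 and 0.4/5
      fac <- 0.9 * err^-0.14 * err_prev^0.08
      err_prev <- max(err, 1e-10)
      h <- h * min(5, max(0.2, fac))
    } else {                              # reject
      h <- h * max(0.2, 0.9 * err^-0.2)
    }
    h <- min(h, max_step)
  }
  out
}
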