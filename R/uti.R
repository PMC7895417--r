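# Case study: semi-empirical models for microbial communities measured via
# conditioned-medium experiments (strains from polymicrobial urinary-tract
# infections).
#
# The experiment: each strain j grows alone in fresh medium, yielding an
# exponential growth rate g_j and a carrying capacity c_j (abundances are
# normalized so c_j = 1). For each strain k, medium containing a fraction v
# of strain k's spent supernatant is prepared; the growth rate g_jk and
# capacity c_jk of strain j in that medium quantify how k affects j. Under
# the footprint assumption (a population's abundance doubles as its
# footprint of consumed/produced substances), conditioning by strain k is
# represented in a model by freezing x_k at v * c_k.

#' Conditioned-medium dataset
#'
#' @param g Monoculture growth rates (1/time), all > 0.
#' @param g_pair Matrix of conditioned growth rates `g_jk` (row = focal
#'   strain j, column = conditioning strain k).
#' @param c_pair Matrix of conditioned carrying capacities `c_jk`; the
#'   diagonal must equal `1 - v` (a strain in its own conditioned medium
#'   can only fill the unconditioned fraction of its niche).
#' @param v Conditioning fraction, strictly between 0 and 1 (default 0.4).
#' @param c Monoculture capacities; must all be 1 (normalization).
#' @return An object of class `cm_dataset`.
#' @export
cm_dataset <- function(g, g_pair, c_pair, v = 0.4, c = rep(1, length(g))) {
  n <- length(g)
  stopifnot(is.matrix(g_pair), is.matrix(c_pair),
            all(dim(g_pair) == n), all(dim(c_pair) == n))
  if (v <= 0 || v >= 1) stop("v must lie strictly between 0 and 1",
                             call. = FALSE)
  if (any(g <= 0)) stop("growth rates must be positive", call. = FALSE)
  if (any(abs(c - 1) > 1e-9)) {
    stop("monoculture capacities must be normalized to 1", call. = FALSE)
  }
  if (any(abs(diag(c_pair) - (1 - v)) > 1e-9)) {
    stop("diagonal of c_pair must equal 1 - v (self-conditioning)",
         call. = FALSE)
  }
  structure(list(g = g, c = c, g_pair = g_pair, c_pair = c_pair, v = v,
                 n = n), class = "cm_dataset")
}

#' @export
print.cm_dataset <- function(x, ...) {
  cat(sprintf("<cm_dataset: %d strains, v = %g>\n", x$n, x$v))
  cat("g:", signif(x$g, 4), "\n")
  invisible(x)
}

#' Clone-split a conditioned-medium dataset
#'
#' Duplicates strain `j`'s rows and columns in both pairwise matrices. The
#' clone block entries come from the diagonal (`g_jj`, `c_jj = 1 - v`):
#' a strain and its clone condition each other exactly as the strain
#' conditions itself.
#'
#' @param d A [cm_dataset()].
#' @param j Strain index.
#' @return A `cm_dataset` with `n + 1` strains (clone appended).
#' @export
split_cm_dataset <- function(d, j) {
  idx <- c(seq_len(d$n), j)
  cm_dataset(g = d$g[idx], g_pair = d$g_pair[idx, idx],
             c_pair = d$c_pair[idx, idx], v = d$v)
}

# -- existing model ----------------------------------------------------------

#' Interaction parameters of the existing conditioned-medium model
#'
#' `a_ji = g_ji / g_j - 1` (growth modification) and
#' `b_ji = c_ji - 1` if `c_ji >= 1`, else `(c_ji - 1) / v` (capacity
#' modification). Diagonals are set to 0 in `a` (unused: the model's sums
#' exclude i = j) and to -1 in `b` (the fixed-point convention).
#'
#' @param d A [cm_dataset()].
#' @return List with matrices `a` and `b`.
#' @export
derive_existing_params <- function(d) {
  if (any(d$g == 0)) stop("a_ji undefined for g_j = 0", call. = FALSE)
  a <- sweep(d$g_pair, 1L, d$g, "/") - 1
  b <- ifelse(d$c_pair >= 1, d$c_pair - 1, (d$c_pair - 1) / d$v)
  diag(a) <- 0
  diag(b) <- -1
  list(a = a, b = b)
}

#' The existing (clone-inconsistent) conditioned-medium model
#'
#' Verhulst growth with both the rate and the capacity modified by
#' interaction terms:
#' \deqn{\dot x_j = x_j g_j \lceil 1 + \sum_{i \ne j} a_{ji} x_i \rceil
#'   \Big(1 - \frac{x_j}{\lceil 1 + \sum_{i \ne j} b_{ji} x_i \rceil}\Big)}
#' with \eqn{\lceil z \rceil = \max(0, z)} (the modified capacity enters as
#' the denominator of the logistic crowding ratio; a fully depleted
#' capacity makes the crowding penalty arbitrarily large). Both sums are
#' incomplete (they exclude i = j) and the crowding ratio carries the bare
#' abundance `x_j` inside the impact position, so neither term is an impact
#' function: the model must violate criterion I4 and is clone-inconsistent.
#' Its interior fixed points, however, satisfy
#' \eqn{x_j = 1 + \sum_{i \ne j} b_{ji} x_i}, i.e. the clone-consistent
#' linear system `0 = 1 + b x` with `b_jj = -1` (see
#' [interior_fixed_point_linear()]), so fixed-point based conclusions
#' survive the inconsistency; transients do not.
#'
#' Splitting this model duplicates the *dataset* rows/columns (see
#' [split_cm_dataset()]) and rebuilds, mirroring how a clone strain would
#' enter the experiment.
#'
#' @param d A [cm_dataset()].
#' @return A [population_model()] (black-box rate; structurally
#'   uncertifiable).
#' @export
make_existing_model <- function(d) {
  par <- derive_existing_params(d)
  A0 <- par$a
  B0 <- par$b
  diag(A0) <- 0
  diag(B0) <- 0          # the model's sums exclude i = j
  g <- d$g
  population_model(
    n = d$n,
    phi = function(x) {
      grow <- clamp(1 + drop(A0 %*% x))
      # clamped modified capacity; the floor only guards the division when
      # interactions wipe the capacity out entirely
      cap <- 1 - x / pmax(clamp(1 + drop(B0 %*% x)), 1e-12)
      g * grow * cap
    },
    tables = list(vectors = list(g = g), matrices = list(a = A0, b = B0)),
    rebuild = NULL,
    family = "uti_existing",
    split = function(model, j) make_existing_model(split_cm_dataset(d, j)))
}

# -- new model ---------------------------------------------------------------

#' Derive the new model's parameters from a dataset
#'
#' Niche coefficients are fixed by the conditioned capacities,
#' \eqn{s_{jk} = (1 - c_{jk}) / v} (so \eqn{s_{jj} = 1} follows from
#' \eqn{c_{jj} = 1 - v}). Growth coefficients under the `"full"` variant are
#' \deqn{r_{jk} = \frac{1}{v}\Big(\frac{g_{jk}}{\varsigma(1 - c_{jk})} -
#'   g_j\Big), \qquad \varsigma(z) = 1 - \lceil z \rceil^q,}
#' which is singular as \eqn{c_{jk} \to 0}; the `"approx"` variant replaces
#' \eqn{\varsigma(1 - c_{jk})} by its sharp-saturation limit 1, giving
#' \eqn{r_{jk} = (g_{jk} - g_j)/v} — well-behaved everywhere at the price of
#' a small, exactly quantifiable residual in the conditioned-growth
#' constraint.
#'
#' @param d A [cm_dataset()].
#' @param q Saturation exponent (> 0), default 10.
#' @param variant `"approx"` (default) or `"full"`.
#' @return An object of class `uti_new_params`: matrices `r`, `s`, plus
#'   `q`, `variant`, `v`, `g`.
#' @export
derive_new_params <- function(d, q = 10, variant = c("approx", "full")) {
  variant <- match.arg(variant)
  stopifnot(q > 0)
  s <- (1 - d$c_pair) / d$v
  if (variant == "full") {
    bad <- which(d$c_pair <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "full variant is singular at c_jk <= 0 (first offender j = %d, k = %d)",
        bad[1, 1], bad[1, 2]), call. = FALSE)
    }
    low <- which(d$c_pair < 0.05 & d$c_pair > 0, arr.ind = TRUE)
    if (nrow(low)) {
      warning(sprintf(
        "c_jk < 0.05 at (j = %d, k = %d): growth coefficient blows up",
        low[1, 1], low[1, 2]), call. = FALSE)
    }
    sig <- 1 - clamp(1 - d$c_pair)^q
    r <- sweep(d$g_pair / sig, 1L, d$g, "-") / d$v
  } else {
    r <- sweep(d$g_pair, 1L, d$g, "-") / d$v
  }
  structure(list(r = r, s = s, q = q, variant = variant, v = d$v, g = d$g),
            class = "uti_new_params")
}

#' The new clone-consistent conditioned-medium model
#'
#' \deqn{\dot x_j = x_j \Big\lceil g_j + \sum_{i=1}^n r_{ji} x_i \Big\rceil
#'   \cdot \Big\lceil 1 - \Big\lceil \sum_{i=1}^n s_{ji} x_i
#'   \Big\rceil^q \Big\rceil}
#' Both factors are (clamped transforms of) complete linear combinations —
#' impact functions — so the model is consistent by construction. Both
#' clamped factors are non-negative: populations never decline (the
#' footprint of a strain cannot be undone; add dilution for declines).
#'
#' @param p A [derive_new_params()] result (or any list with `r`, `s`, `q`).
#' @param g Monoculture growth rates; defaults to `p$g`.
#' @return A [population_model()] certified consistent-by-construction.
#' @export
make_new_model <- function(p, g = p$g) {
  r <- p$r
  s <- p$s
  q <- p$q
  n <- length(g)
  stopifnot(all(dim(r) == n), all(dim(s) == n))
  build <- function(vectors, matrices) {
    gg <- vectors$g
    rr <- matrices$r
    ss <- matrices$s
    nn <- length(gg)
    population_model(
      n = nn,
      phi = function(x) {
        grow <- clamp(gg + drop(rr %*% x))
        cap <- clamp(1 - clamp(drop(ss %*% x))^q)
        grow * cap
      },
      tables = list(vectors = list(g = gg), matrices = list(r = rr, s = ss)),
      rebuild = build,
      phi_exprs = lapply(seq_len(nn), function(j) {
        ie_product(
          ie_apply("clamp", ie_sum(ie_const(gg[j]), ie_basic(1L))),
          ie_apply("clamp",
                   ie_apply("capacity_saturation", ie_basic(2L),
                            args = list(q = q))))
      }),
      expr_params = function(j) parameter_table(cbind(r = rr[j, ],
                                                      s = ss[j, ])),
      family = "uti_new")
  }
  build(list(g = g), list(r = r, s = s))
}

#' Check a model against the experimental constraints
#'
#' Every conditioned-medium model should reproduce the four measured
#' observables. Because models here have the structure
#' \eqn{R_j = x_j \phi_j}, the two growth-rate constraints (derivatives at
#' \eqn{x_j = 0}) are evaluated exactly as \eqn{\phi_j} — no finite
#' differencing:
#' * growth rate: \eqn{\phi_j(\vec 0) - g_j}
#' * carrying capacity: \eqn{R_j} at \eqn{x_j = 1}, all others 0
#' * conditioned growth rate: \eqn{\phi_j(x_k = v, x_j = 0) - g_{jk}}
#' * conditioned capacity: \eqn{R_j} at \eqn{(x_j = c_{jk},\; x_k = v)}
#'
#' Diagonal (self-conditioning) entries are evaluated on a clone-augmented
#' system: the strain's footprint is a frozen clone at abundance `v`.
#'
#' @param model A [population_model()] built from `d`.
#' @param d The [cm_dataset()].
#' @return An object of class `constraint_residuals` with fields `growth`,
#'   `capacity` (vectors) and `conditioned_growth`, `conditioned_capacity`
#'   (matrices).
#' @export
validate_constraints <- function(model, d) {
  n <- d$n
  stopifnot(model$n == n)
  phi0 <- model$phi(rep(0, n))
  growth <- phi0 - d$g
  capacity <- vapply(seq_len(n), function(j) {
    x <- rep(0, n); x[j] <- 1
    rhs(model, x)[j]
  }, numeric(1))
  cg <- matrix(NA_real_, n, n)
  cc <- matrix(NA_real_, n, n)
  splits <- lapply(seq_len(n), function(j) split_model(model, j))
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j != k) {
        x <- rep(0, n); x[k] <- d$v
        cg[j, k] <- model$phi(x)[j] - d$g_pair[j, k]
        x[j] <- d$c_pair[j, k]
        cc[j, k] <- rhs(model, x)[j]
      } else {
        m2 <- splits[[j]]
        x <- rep(0, n + 1L); x[n + 1L] <- d$v
        cg[j, j] <- m2$phi(x)[j] - d$g_pair[j, j]
        x[j] <- d$c_pair[j, j]
        cc[j, j] <- rhs(m2, x)[j]
      }
    }
  }
  structure(list(growth = growth, capacity = capacity,
                 conditioned_growth = cg, conditioned_capacity = cc),
            class = "constraint_residuals")
}

#' @export
print.constraint_residuals <- function(x, ...) {
  cat("<constraint_residuals> max |residual|:\n")
  cat(sprintf("  growth rate:            %.3e\n", max(abs(x$growth))))
  cat(sprintf("  carrying capacity:      %.3e\n", max(abs(x$capacity))))
  cat(sprintf("  conditioned growth:     %.3e\n",
              max(abs(x$conditioned_growth))))
  cat(sprintf("  conditioned capacity:   %.3e\n",
              max(abs(x$conditioned_capacity))))
  invisible(x)
}

# -- synthetic experiment ----------------------------------------------------

#' Generate a ground-truth community for the synthetic experiment
#'
#' Draws a random community in the new model's form: growth rates
#' `g ~ U[0.5, 1.5]`, niche coefficients `s` with unit diagonal and
#' off-diagonals from `U[-0.5, 1.2]`, growth-interaction coefficients `r`
#' with zero diagonal and off-diagonals from `U[-0.5, 0.5]`; off-diagonal
#' entries are independently zeroed so that each is nonzero with
#' probability `sparsity`. Regeneration with the same seed is bit-exact.
#'
#' @param n Number of strains (keep <= 8 for desk-scale runtimes).
#' @param seed RNG seed.
#' @param sparsity Probability that an off-diagonal interaction is nonzero.
#' @param q Saturation exponent of the truth model.
#' @param v Conditioning fraction.
#' @return An object of class `synthetic_truth`: the truth
#'   [population_model()] plus its parameter tables.
#' @export
synthetic_truth <- function(n = 4L, seed = 1L, sparsity = 0.5, q = 10,
                            v = 0.4) {
  with_seed(seed, {
    g <- stats::runif(n, 0.5, 1.5)
    mask_s <- matrix(stats::runif(n * n) < sparsity, n, n)
    s <- matrix(stats::runif(n * n, -0.5, 1.2), n, n)
    s[!mask_s] <- 0
    diag(s) <- 1
    mask_r <- matrix(stats::runif(n * n) < sparsity, n, n)
    r <- matrix(stats::runif(n * n, -0.5, 0.5), n, n)
    r[!mask_r] <- 0
    diag(r) <- 0
  })
  params <- structure(list(r = r, s = s, q = q, variant = "truth", v = v,
                           g = g), class = "uti_new_params")
  structure(list(model = make_new_model(params), r = r, s = s, g = g,
                 q = q, v = v, seed = seed, n = n),
            class = "synthetic_truth")
}

# Integrate one focal strain (others absent or frozen) to its plateau.
# Plateau: |dx_j/dt| / x_j < ptol, checked after chunks of the horizon.
plateau_abundance <- function(model, j, x_init, horizon = 1000,
                              ptol = 1e-10, chunk = 25, solver_opts = list()) {
  x <- x_init
  t_done <- 0
  while (t_done < horizon) {
    t_next <- min(t_done + chunk, horizon)
    traj <- simulate_model(model, x, seq(t_done, t_next, length.out = 11L),
                           solver_opts)
    x <- traj$abundances[nrow(traj$abundances), ]
    t_done <- t_next
    dx <- rhs(model, x)
    if (abs(dx[j]) / max(x[j], 1e-30) < ptol) return(x[j])
  }
  stop(sprintf("strain %d did not reach a plateau within the horizon", j),
       call. = FALSE)
}

#' Run the synthetic conditioned-medium experiment
#'
#' Emulates the laboratory protocol on a ground-truth model:
#' * `g_j` — the initial per-capita growth rate, read off exactly as
#'   \eqn{\phi_j} at \eqn{x = 0} (models have the form
#'   \eqn{R_j = x_j \phi_j}, so no regression on log-abundances is needed);
#' * `c_j` — the monoculture plateau (then abundances are renormalized so
#'   that `c_j = 1`);
#' * `g_jk` — \eqn{\phi_j} at \eqn{x_j = 0} with strain k's footprint
#'   frozen at `v * c_k` (freezing, not deletion: the conditioning strain's
#'   cells are removed but its footprint persists);
#' * `c_jk` — the plateau of strain j integrated with strain k frozen at
#'   `v * c_k`, in units of `c_j`;
#' * diagonal entries: `g_jj` from a clone-augmented system (the strain's
#'   own footprint frozen at `v * c_j`), and `c_jj = 1 - v` by the
#'   self-conditioning convention.
#'
#' @param truth A [synthetic_truth()] (or any list with a `model` of the
#'   right structure and `v`).
#' @param v Conditioning fraction (default from `truth`).
#' @param horizon Maximum cultivation time per plateau (model time units;
#'   the lab's 48 h is wall-clock, not model time).
#' @param x0 Inoculum abundance for each cultivation.
#' @param ptol Plateau tolerance on the per-capita rate.
#' @return A [cm_dataset()].
#' @export
simulate_experiment <- function(truth, v = truth$v, horizon = 1000,
                                x0 = 0.01, ptol = 1e-10) {
  model <- truth$model
  n <- model$n
  g <- model$phi(rep(0, n))
  c_raw <- vapply(seq_len(n), function(j) {
    xi <- rep(0, n); xi[j] <- x0
    plateau_abundance(model, j, xi, horizon, ptol)
  }, numeric(1))
  g_pair <- matrix(NA_real_, n, n)
  c_pair <- matrix(NA_real_, n, n)
  for (k in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j != k) {
        x <- rep(0, n)
        x[k] <- v * c_raw[k]
        g_pair[j, k] <- model$phi(x)[j]
        frozen_model <- model
        frozen_model$frozen <- k
        x[j] <- x0 * c_raw[j]
        c_pair[j, k] <- plateau_abundance(frozen_model, j, x, horizon,
                                          ptol) / c_raw[j]
      } else {
        m2 <- split_model(model, j)
        x <- rep(0, n + 1L)
        x[n + 1L] <- v * c_raw[j]
        g_pair[j, j] <- m2$phi(x)[j]
        c_pair[j, j] <- 1 - v
      }
    }
  }
  cm_dataset(g = g, g_pair = g_pair, c_pair = c_pair, v = v)
}

#' End-to-end parameter recovery on synthetic data
#'
#' Generates a ground-truth community, runs the synthetic conditioned-medium
#' experiment, derives the new model's parameters from the resulting
#' dataset, and compares them with the truth. Niche coefficients `s` are
#' recovered exactly (to plateau tolerance). Under the `"approx"` variant
#' the growth coefficients carry the known saturation residual: entrywise,
#' \deqn{\hat r_{jk} - r_{jk} = -\,\frac{g_{jk} (1 - c_{jk})^q}
#'   {v\,(1 - (1 - c_{jk})^q)},}
#' whose magnitude bounds the recovery error (`r_bound`).
#'
#' @param seed RNG seed for the truth.
#' @param n Number of strains (<= 8 recommended).
#' @param sparsity Probability that an off-diagonal interaction is nonzero.
#' @param q Saturation exponent.
#' @param v Conditioning fraction.
#' @param variant Parameter-derivation variant, `"approx"` or `"full"`.
#' @return An object of class `recovery_report` with `s_error`, `r_error`,
#'   `r_bound`, plus the `truth`, `dataset` and `recovered` parameters.
#' @export
recover_parameters <- function(seed = 1L, n = 4L, sparsity = 0.5, q = 10,
                               v = 0.4, variant = "approx") {
  truth <- synthetic_truth(n = n, seed = seed, sparsity = sparsity, q = q,
                           v = v)
  d <- simulate_experiment(truth)
  rec <- derive_new_params(d, q = q, variant = variant)
  z <- clamp(1 - d$c_pair)^q
  r_bound <- max(abs(d$g_pair) * z / (v * (1 - z)))
  structure(list(
    s_error = max(abs(rec$s - truth$s)),
    r_error = max(abs(rec$r - truth$r)),
    r_bound = if (variant == "approx") r_bound else NA_real_,
    variant = variant, seed = seed, n = n, sparsity = sparsity,
    truth = truth, dataset = d, recovered = rec),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report: n = %d, seed = %d, variant = %s>\n", x$n, x$seed,
    x$variant))
  cat(sprintf("  max |s_hat - s| = %.3e\n", x$s_error))
  cat(sprintf("  max |r_hat - r| = %.3e", x$r_error))
  if (is.finite(x$r_bound)) cat(sprintf("  (closed-form bound %.3e)",
                                        x$r_bound))
  cat("\n")
  invisible(x)
}

# -- dataset I/O -------------------------------------------------------------

#' Read / write conditioned-medium datasets as delimited text
#'
#' Four files in `dir`: `g.csv`, `c.csv` (one value per line), `g_pair.csv`,
#' `c_pair.csv` (square, row = focal strain j, column = conditioning strain
#' k), plus `config.json` holding `v`.
#'
#' @param d A [cm_dataset()].
#' @param dir Directory.
#' @return `read_cm_dataset` returns a `cm_dataset`.
#' @export
write_cm_dataset <- function(d, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(d$g, file.path(dir, "g.csv"), row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(d$c, file.path(dir, "c.csv"), row.names = FALSE,
                     col.names = FALSE)
  write_pairwise_matrix(d$g_pair, file.path(dir, "g_pair.csv"))
  write_pairwise_matrix(d$c_pair, file.path(dir, "c_pair.csv"))
  jsonlite::write_json(list(v = d$v, n = d$n), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cm_dataset
#' @export
read_cm_dataset <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  cm_dataset(g = scan(file.path(dir, "g.csv"), quiet = TRUE),
             g_pair = read_pairwise_matrix(file.path(dir, "g_pair.csv")),
             c_pair = read_pairwise_matrix(file.path(dir, "c_pair.csv")),
             v = cfg$v,
             c = scan(file.path(dir, "c.csv"), quiet = TRUE))
}
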