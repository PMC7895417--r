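# Numerical falsification of the impact-function criteria I1-I4 on black-box
# terms, structural certification, and the whole-model clone-split test.
#
# The four criteria, as numeric probe transformations:
#   I1 (commutativity)  swap a random index pair (x_i, a_i) <-> (x_j, a_j)
#   I2 (absent population) set x_1 = 0 and re-randomize a_1
#   I3 (zero parameters)   set a_1 = 0 and re-randomize x_1
#   I4 (clone consistency) force a_1 = a_2 and move a random amount
#                          z in [-x_1, x_2] between x_1 and x_2
# A consistent term's value is invariant under each transformation; the
# checker can falsify consistency (with a concrete witness probe) but can
# never prove it -- that is what structural certification is for.

#' Probe configuration for the numerical checker
#'
#' @param n_probes Number of random probes (default 100).
#' @param seed RNG seed; probes are fully reproducible.
#' @param abundance_sampler `function(n) -> n abundances` (default uniform on
#'   \[0, 2\]).
#' @param parameter_sampler `function(k) -> k parameter values` (default
#'   uniform on \[-1, 1\]).
#' @param tie_fraction Share of probes whose *base* community already
#'   contains a duplicated parameter row. I4 always constructs its own tie:
#'   random real parameters almost never coincide, so ties must be built,
#'   not sampled.
#' @param tolerance Relative deviation above which a criterion fails
#'   (default `1e-6`; ODE tolerances in the model-level test are far
#'   tighter, so integration error never masquerades as inconsistency).
#' @return An object of class `probe_config`.
#' @export
probe_config <- function(n_probes = 100L, seed = 1L,
                         abundance_sampler = function(n) stats::runif(n, 0, 2),
                         parameter_sampler = function(k) stats::runif(k, -1, 1),
                         tie_fraction = 0.25, tolerance = 1e-6) {
  stopifnot(n_probes >= 1L, tie_fraction >= 0, tie_fraction <= 1,
            tolerance > 0)
  structure(list(n_probes = as.integer(n_probes), seed = as.integer(seed),
                 abundance_sampler = abundance_sampler,
                 parameter_sampler = parameter_sampler,
                 tie_fraction = tie_fraction, tolerance = tolerance),
            class = "probe_config")
}

new_witness <- function(criterion, probe, probe2, v1, v2) {
  structure(list(criterion = criterion, probe = probe, transformed = probe2,
                 value = v1, value_transformed = v2,
                 abs_deviation = abs(v1 - v2),
                 rel_deviation = rel_dev(v1, v2)),
            class = "witness")
}

#' @export
print.witness <- function(x, ...) {
  cat(sprintf("<witness %s: %.6g vs %.6g (rel dev %.3g)>\n", x$criterion,
              x$value, x$value_transformed, x$rel_deviation))
  invisible(x)
}

sample_probe <- function(cfg, n, m, pairwise_names, tie) {
  x <- cfg$abundance_sampler(n)
  a <- matrix(cfg$parameter_sampler(n * m), n, m)
  P <- NULL
  if (length(pairwise_names)) {
    P <- lapply(pairwise_names, function(nm) {
      matrix(cfg$parameter_sampler(n * n), n, n)
    })
    names(P) <- pairwise_names
  }
  if (tie && n >= 2L) {
    ij <- sample.int(n, 2L)
    a[ij[2L], ] <- a[ij[1L], ]
    if (!is.null(P)) P <- lapply(P, clone_pairwise, i = ij[1L], j = ij[2L])
  }
  list(x = x, a = a, P = P)
}

# Make rows/cols i and j of a pairwise matrix clone-equivalent: equal rows,
# equal columns, and the 2 x 2 clone block constant at the original (i, i)
# entry.
clone_pairwise <- function(M, i, j) {
  orig <- M
  M[j, ] <- orig[i, ]
  M[, j] <- orig[, i]
  M[c(i, j), c(i, j)] <- orig[i, i]
  M
}

swap_pairwise <- function(M, i, j) {
  perm <- seq_len(nrow(M))
  perm[c(i, j)] <- c(j, i)
  M[perm, perm]
}

probe_table <- function(p) parameter_table(p$a, p$P)

eval_probe <- function(f, p) safe_eval(f(p$x, probe_table(p)))

#' Numerically test the impact-function criteria on a black-box term
#'
#' Runs `cfg$n_probes` seeded random probes through each of the four
#' criterion transformations and reports the worst relative deviation per
#' criterion, with a concrete witness. Evaluation failures (domain errors,
#' non-finite values) at a probe are counted as skipped evaluations; a
#' criterion whose every probe fails to evaluate is reported `"skipped"`.
#'
#' @param f Black-box term `function(x, params) -> numeric(1)`, where
#'   `params` is a [parameter_table()] carrying the n x m matrix (and any
#'   pairwise matrices).
#' @param n Number of populations to probe with (>= 2).
#' @param m Number of first-order parameter columns.
#' @param cfg A [probe_config()].
#' @param pairwise_names Names of pairwise matrices to sample (empty for
#'   first-order terms).
#' @return A `consistency_report`.
#' @examples
#' glv_term <- function(x, pt) sum(pt$a[, 1] * x)
#' rep <- check_impact_criteria(glv_term, n = 3, cfg = probe_config(25))
#' all(rep$results$verdict == "pass")
#' @export
check_impact_criteria <- function(f, n, m = 1L, cfg = probe_config(),
                                  pairwise_names = character(0)) {
  stopifnot(n >= 2L)
  crits <- c("I1", "I2", "I3", "I4")
  worst <- stats::setNames(rep(-Inf, 4), crits)
  witness <- stats::setNames(vector("list", 4), crits)
  n_ok <- stats::setNames(integer(4), crits)
  n_skip <- stats::setNames(integer(4), crits)
  with_seed(cfg$seed, {
    for (probe_i in seq_len(cfg$n_probes)) {
      tie <- stats::runif(1) < cfg$tie_fraction
      base <- sample_probe(cfg, n, m, pairwise_names, tie)
      for (crit in crits) {
        pair <- transform_probe(base, crit, cfg)
        r1 <- eval_probe(f, pair[[1L]])
        r2 <- eval_probe(f, pair[[2L]])
        if (!r1$ok || !r2$ok) {
          n_skip[crit] <- n_skip[crit] + 1L
          next
        }
        n_ok[crit] <- n_ok[crit] + 1L
        dev <- rel_dev(r1$value, r2$value)
        if (dev > worst[crit]) {
          worst[crit] <- dev
          witness[[crit]] <- new_witness(crit, pair[[1L]], pair[[2L]],
                                         r1$value, r2$value)
        }
      }
    }
  })
  verdict <- ifelse(n_ok == 0L, "skipped",
                    ifelse(worst > cfg$tolerance, "fail", "pass"))
  new_consistency_report(crits, verdict, worst, witness, n_ok, n_skip, cfg)
}

# Returns list(original probe, transformed probe) for one criterion.
transform_probe <- function(p, criterion, cfg) {
  n <- length(p$x)
  m <- ncol(p$a)
  q <- p
  switch(criterion,
    I1 = {
      ij <- sample.int(n, 2L)
      i <- ij[1L]; j <- ij[2L]
      q$x[c(i, j)] <- p$x[c(j, i)]
      q$a[c(i, j), ] <- p$a[c(j, i), ]
      if (!is.null(q$P)) q$P <- lapply(q$P, swap_pairwise, i = i, j = j)
    },
    I2 = {
      p$x[1L] <- 0
      q <- p
      q$a[1L, ] <- cfg$parameter_sampler(m)
      if (!is.null(q$P)) {
        for (nm in names(q$P)) {
          q$P[[nm]][1L, ] <- cfg$parameter_sampler(n)
          q$P[[nm]][, 1L] <- cfg$parameter_sampler(n)
        }
      }
    },
    I3 = {
      p$a[1L, ] <- 0
      if (!is.null(p$P)) {
        for (nm in names(p$P)) {
          p$P[[nm]][1L, ] <- 0
          p$P[[nm]][, 1L] <- 0
        }
      }
      q <- p
      q$x[1L] <- cfg$abundance_sampler(1L)
    },
    I4 = {
      p$a[2L, ] <- p$a[1L, ]
      if (!is.null(p$P)) p$P <- lapply(p$P, clone_pairwise, i = 1L, j = 2L)
      q <- p
      z <- stats::runif(1L, -p$x[1L], p$x[2L])
      q$x[1L] <- p$x[1L] + z
      q$x[2L] <- p$x[2L] - z
    }
  )
  list(p, q)
}

new_consistency_report <- function(criteria, verdict, worst, witnesses,
                                   n_ok, n_skip, cfg) {
  worst[!is.finite(worst)] <- NA_real_
  structure(list(
    results = data.frame(criterion = criteria, verdict = verdict,
                         worst_deviation = unname(worst),
                         n_evaluated = unname(n_ok),
                         n_skipped = unname(n_skip),
                         stringsAsFactors = FALSE, row.names = NULL),
    witnesses = witnesses, seed = cfg$seed, n_probes = cfg$n_probes,
    tolerance = cfg$tolerance),
    class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report: %d probes, seed %d, tolerance %g>\n",
              x$n_probes, x$seed, x$tolerance))
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Overall verdict of a consistency report
#'
#' @param report A `consistency_report`.
#' @return `TRUE` when no criterion failed.
#' @export
is_consistent <- function(report) {
  !any(report$results$verdict == "fail")
}

#' Serialize a consistency report to JSON
#'
#' Witness probes (state, parameters, transformed counterparts and values)
#' are embedded so a failure can be reproduced independently.
#'
#' @param report A `consistency_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_consistency_report <- function(report, path) {
  wit <- lapply(report$witnesses, function(w) {
    if (is.null(w)) return(NULL)
    list(criterion = w$criterion,
         x = w$probe$x, a = w$probe$a,
         x_transformed = w$transformed$x, a_transformed = w$transformed$a,
         value = w$value, value_transformed = w$value_transformed,
         abs_deviation = w$abs_deviation, rel_deviation = w$rel_deviation)
  })
  jsonlite::write_json(
    list(results = report$results, witnesses = wit, seed = report$seed,
         n_probes = report$n_probes, tolerance = report$tolerance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

# -- clone splitting ---------------------------------------------------------

#' Split one population into two clones
#'
#' Operates on a `(state, parameter table)` pair: population `j` is split
#' into clones carrying fractions `theta` and `1 - theta` of its abundance;
#' its parameter row is duplicated, and every pairwise matrix gets row and
#' column `j` duplicated, which makes all four clone-block entries equal to
#' the original `a_jj`.
#'
#' @param state Abundance vector.
#' @param params A [parameter_table()].
#' @param j Population index to split.
#' @param theta Fraction of abundance assigned to the first clone,
#'   strictly between 0 and 1.
#' @return List with the enlarged `state` (length n + 1; the new clone is
#'   appended) and `params`.
#' @export
split_population <- function(state, params, j, theta = 0.5) {
  sp <- check_state_params(state, params)
  n <- sp$params$n
  if (j < 1L || j > n) stop("population index out of range", call. = FALSE)
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)",
                                     call. = FALSE)
  x2 <- c(sp$x, (1 - theta) * sp$x[j])
  x2[j] <- theta * sp$x[j]
  idx <- c(seq_len(n), j)
  a2 <- sp$params$a[idx, , drop = FALSE]
  P2 <- if (is.null(sp$params$pairwise)) NULL else
    lapply(sp$params$pairwise, function(M) M[idx, idx])
  list(state = x2, params = parameter_table(a2, P2))
}

#' Split a population model into a clone system
#'
#' Applies the clone-split rule to the model's parameter tables (duplicate
#' vector entry `j`; duplicate row and column `j` of every matrix) and
#' rebuilds the model at size n + 1. Model families with their own split
#' semantics (e.g. dataset-backed case-study models) override this via their
#' `split` field.
#'
#' @param model A [population_model()].
#' @param j Population index to split (must not be frozen).
#' @return A `population_model` with `n + 1` populations; the clone is
#'   appended as index `n + 1`.
#' @export
split_model <- function(model, j) {
  if (j < 1L || j > model$n) stop("population index out of range",
                                  call. = FALSE)
  if (j %in% model$frozen) stop("cannot split a frozen population",
                                call. = FALSE)
  if (is.function(model$split)) return(model$split(model, j))
  if (is.null(model$rebuild)) {
    stop(sprintf("model family '%s' does not support clone splitting",
                 model$family), call. = FALSE)
  }
  idx <- c(seq_len(model$n), j)
  vecs <- lapply(model$tables$vectors, function(v) v[idx])
  mats <- lapply(model$tables$matrices, function(M) M[idx, idx])
  m2 <- model$rebuild(vecs, mats)
  m2$frozen <- model$frozen
  m2
}

#' Whole-model clone-split test
#'
#' For each random probe state and each (non-frozen) population `j`, the
#' model is compared against its clone-split counterpart in two ways:
#' instantaneous right-hand sides at t = 0 (the clones' summed growth must
#' equal the original population's growth, and every other population's
#' growth must be unchanged), and trajectories over the horizon sampled on a
#' fixed grid of `n_grid` points (the clones' summed abundance must track
#' the original). The worst relative deviation over probes, populations,
#' grid times and components decides the verdict.
#'
#' @param model A [population_model()] that supports splitting.
#' @param cfg A [probe_config()]; the model-level default is 10 probes.
#' @param horizon Integration horizon for trajectory comparison.
#' @param theta Clone abundance fraction.
#' @param n_grid Number of comparison grid points (fixed grid, so verdicts
#'   are independent of solver-internal steps).
#' @param solver_opts Passed to [simulate_model()].
#' @return A `consistency_report` with the single criterion
#'   `"model-split"`.
#' @export
check_model_consistency <- function(model, cfg = probe_config(n_probes = 10L),
                                    horizon = 10, theta = 0.5,
                                    n_grid = 101L, solver_opts = list()) {
  worst <- -Inf
  wit <- NULL
  n_ok <- 0L
  n_skip <- 0L
  # bounded step budget: a grossly inconsistent split system can be stiff
  # enough to stall an explicit method; its RHS deviation at t = 0 already
  # witnesses the inconsistency, so the trajectory comparison may bail out
  solver_opts <- utils::modifyList(list(max_steps = 5e3), solver_opts)
  t_grid <- seq(0, horizon, length.out = n_grid)
  split_js <- setdiff(seq_len(model$n), model$frozen)
  with_seed(cfg$seed, {
    for (probe_i in seq_len(cfg$n_probes)) {
      x0 <- cfg$abundance_sampler(model$n)
      if (model$domain == "positive") x0 <- pmax(x0, 1e-3)
      res <- tryCatch({
        r0 <- rhs(model, x0)
        X0 <- tryCatch(
          simulate_model(model, x0, t_grid, solver_opts)$abundances,
          error = function(e) NULL)
        list(r0 = r0, X0 = X0)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_skip <- n_skip + 1L
        next
      }
      for (j in split_js) {
        dev_j <- tryCatch({
          m2 <- split_model(model, j)
          x02 <- c(x0, (1 - theta) * x0[j])
          x02[j] <- theta * x0[j]
          r2 <- rhs(m2, x02)
          agg_r <- r2[seq_len(model$n)]
          agg_r[j] <- r2[j] + r2[model$n + 1L]
          dev_rhs <- max(rel_dev(agg_r, res$r0))
          # the trajectory comparison may fail (e.g. divergence of the
          # split system); the instantaneous comparison still stands
          dev_traj <- if (is.null(res$X0)) NA_real_ else tryCatch({
            traj2 <- simulate_model(m2, x02, t_grid, solver_opts)
            A <- traj2$abundances[, seq_len(model$n), drop = FALSE]
            A[, j] <- A[, j] + traj2$abundances[, model$n + 1L]
            max(rel_dev(A, res$X0))
          }, error = function(e) NA_real_)
          list(dev = max(dev_rhs, dev_traj, na.rm = TRUE),
               detail = list(x0 = x0, j = j, theta = theta,
                             rhs_original = res$r0, rhs_split = r2,
                             dev_rhs = dev_rhs, dev_traj = dev_traj))
        }, error = function(e) e)
        if (inherits(dev_j, "error")) {
          n_skip <- n_skip + 1L
          next
        }
        n_ok <- n_ok + 1L
        if (dev_j$dev > worst) {
          worst <- dev_j$dev
          d <- dev_j$detail
          agg <- d$rhs_split[seq_len(model$n)]
          agg[d$j] <- d$rhs_split[d$j] + d$rhs_split[model$n + 1L]
          wit <- new_witness("model-split",
                             list(x = d$x0, a = NULL,
                                  info = d[c("j", "theta", "dev_rhs",
                                             "dev_traj")]),
                             list(x = c(d$x0[-d$j], theta * d$x0[d$j],
                                        (1 - theta) * d$x0[d$j]), a = NULL),
                             d$rhs_original[d$j], agg[d$j])
          wit$rel_deviation <- dev_j$dev
        }
      }
    }
  })
  verdict <- if (n_ok == 0L) "skipped" else
    if (worst > cfg$tolerance) "fail" else "pass"
  new_consistency_report("model-split", verdict,
                         stats::setNames(worst, "model-split"),
                         stats::setNames(list(wit), "model-split"),
                         stats::setNames(n_ok, "model-split"),
                         stats::setNames(n_skip, "model-split"), cfg)
}

#' Certify a whole model as consistent by construction
#'
#' A model whose every per-capita rate is given as an impact-expression tree
#' free of black-box leaves has the mandated form \eqn{x_j \phi_j(x, a)}
#' with \eqn{\phi_j} in the generated algebra, and is therefore
#' clone-consistent by construction. Models carrying opaque rate functions
#' are `"undecidable"` (use [check_model_consistency()] to falsify).
#'
#' @param model A [population_model()].
#' @return A `structure_verdict`.
#' @export
certify_model <- function(model) {
  if (is.null(model$phi_exprs)) {
    return(structure(list(verdict = "undecidable",
                          blackboxes = sprintf("phi[%s]", model$family)),
                     class = "structure_verdict"))
  }
  verdicts <- lapply(model$phi_exprs, certify_structure)
  boxes <- unique(unlist(lapply(verdicts, `[[`, "blackboxes")))
  verdict <- if (length(boxes)) "undecidable" else
    "consistent-by-construction"
  structure(list(verdict = verdict, blackboxes = boxes),
            class = "structure_verdict")
}
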