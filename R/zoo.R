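# Ready-made model constructors: generalized Lotka-Volterra, the logarithmic
# predator-prey model (a deliberately clone-inconsistent example), the
# pollination-grazing toy community, the unique-interactions demonstration
# terms, and a sampler for sparse product-form ensemble models.

#' Generalized Lotka-Volterra model
#'
#' \eqn{\dot x_j = g_j x_j (c_j + \sum_i a_{ji} x_i)} with diagonal
#' \eqn{a_{jj} = -1} by default (a population maximally competes with
#' itself). Built from a single basic impact function, hence certified
#' clone-consistent by construction. With n = 1 this reduces to the logistic
#' (Verhulst) model with fixed point `c`.
#'
#' @param g Growth rates (1/time), length n.
#' @param c Capacities, length n (recycled).
#' @param A Interaction matrix `a_ji` (row = focal population); defaults to
#'   `-diag(n)`.
#' @return A [population_model()].
#' @examples
#' m <- make_glv(g = 1, c = 1)       # logistic, fixed point 1
#' rhs(m, 0.5)                       # 0.25
#' @export
make_glv <- function(g, c = rep(1, length(g)), A = NULL) {
  n <- length(g)
  c <- rep_len(c, n)
  if (is.null(A)) A <- -diag(n)
  stopifnot(is.matrix(A), nrow(A) == n, ncol(A) == n)
  build <- function(vectors, matrices) {
    gg <- vectors$g; cc <- vectors$c; AA <- matrices$A
    nn <- length(gg)
    population_model(
      n = nn,
      phi = function(x) gg * (cc + drop(AA %*% x)),
      tables = list(vectors = list(g = gg, c = cc),
                    matrices = list(A = AA)),
      rebuild = build,
      phi_exprs = lapply(seq_len(nn), function(j) {
        ie_scale(gg[j], ie_sum(ie_const(cc[j]), ie_basic(1L)))
      }),
      expr_params = function(j) parameter_table(AA[j, ]),
      family = "glv")
  }
  build(list(g = g, c = c), list(A = A))
}

#' Logarithmic predator-prey model (clone-inconsistent example)
#'
#' \eqn{\dot x_j = x_j (a_j + \sum_i b_{ji} \log x_i)}. The logarithm of an
#' abundance is not additive (\eqn{\log y + \log z \neq \log(y+z)}), so the
#' interaction sum is not an impact function and the model is
#' clone-inconsistent: splitting a population changes the dynamics
#' qualitatively (see [predator_prey_fixture()]). Defined for strictly positive
#' abundances only.
#'
#' @param a Per-population rates, length n.
#' @param b Interaction matrix (row = focal population).
#' @return A [population_model()] (no structural certificate; the rate is a
#'   black box for the certifier).
#' @export
make_log_model <- function(a, b) {
  n <- length(a)
  stopifnot(is.matrix(b), nrow(b) == n, ncol(b) == n)
  build <- function(vectors, matrices) {
    aa <- vectors$a; bb <- matrices$b
    population_model(
      n = length(aa),
      phi = function(x) aa + drop(bb %*% log(x)),
      tables = list(vectors = list(a = aa), matrices = list(b = bb)),
      rebuild = build,
      domain = "positive",
      family = "log")
  }
  build(list(a = a), list(b = b))
}

#' Predator-prey fixture for the clone-split demonstration
#'
#' The two-population logarithmic model with prey/predator parameters
#' `a = (0.3, -0.3)`, `b = ((0.5, -1.0), (0.8, -0.5))` and initial state
#' `(2, 6)`, together with its clone-split counterpart in which the predator
#' population is divided into two identical sub-populations with half the
#' initial abundance each. The unsplit system oscillates indefinitely; the
#' split system spirals onto a fixed point — the two simulations describe
#' the same scenario yet disagree, which is the inconsistency this package
#' detects.
#'
#' @return List with `unsplit` / `split` (each `model` + `x0`).
#' @export
predator_prey_fixture <- function() {
  a <- c(0.3, -0.3)
  b <- matrix(c(0.5, -1.0,
                0.8, -0.5), 2, 2, byrow = TRUE)
  unsplit <- make_log_model(a, b)
  split <- split_model(unsplit, 2L)
  list(unsplit = list(model = unsplit, x0 = c(2, 6)),
       split = list(model = split, x0 = c(2, 3, 3)))
}

#' Pollination-grazing community model
#'
#' A community of flowering plants and insect populations. The per-capita
#' rate of a plant is
#' \deqn{\phi = g_{\max} \frac{\sum_i b_i x_i}{1 + \sum_i b_i x_i}
#'       - \sum_i a_i x_i,}
#' i.e. a Holling type-II saturating pollination benefit minus a linear
#' grazing loss — both impact functions, so the model is consistent by
#' construction. Insects follow fixed per-capita baseline rates. Plants are
#' distinguished from insects only by having zero grazing and pollination
#' rates themselves.
#'
#' @param g_max Maximum plant growth rate at saturating pollination.
#' @param a Grazing rates (>= 0), length n; must be zero for plants.
#' @param b Pollination contributions (>= 0), length n; zero for plants.
#' @param is_plant Logical length n marking plant populations.
#' @param baseline Insect per-capita rates (default 0), length n.
#' @return A [population_model()].
#' @export
make_pollination_grazing <- function(g_max, a, b,
                                     is_plant = c(TRUE,
                                                  rep(FALSE,
                                                      length(a) - 1L)),
                                     baseline = rep(0, length(a))) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0), g_max > 0)
  if (any(a[is_plant] != 0) || any(b[is_plant] != 0)) {
    stop("plant populations must have zero grazing and pollination rates",
         call. = FALSE)
  }
  build <- function(vectors, matrices) {
    aa <- vectors$a; bb <- vectors$b
    plant <- vectors$is_plant > 0
    base <- vectors$baseline
    gmax <- vectors$g_max
    nn <- length(aa)
    h2 <- get_transform("holling2")
    population_model(
      n = nn,
      phi = function(x) {
        poll <- h2(sum(bb * x))
        graz <- sum(aa * x)
        ifelse(plant, gmax * poll - graz, base)
      },
      tables = list(vectors = list(a = aa, b = bb,
                                   is_plant = as.numeric(plant),
                                   baseline = base, g_max = gmax),
                    matrices = list()),
      rebuild = build,
      phi_exprs = lapply(seq_len(nn), function(j) {
        if (plant[j]) {
          ie_sum(ie_scale(gmax[j], ie_apply("holling2", ie_basic(2L))),
                 ie_scale(-1, ie_basic(1L)))
        } else {
          ie_const(base[j])
        }
      }),
      expr_params = function(j) parameter_table(cbind(a = aa, b = bb)),
      family = "pollination_grazing")
  }
  build(list(a = a, b = b, is_plant = as.numeric(is_plant),
             baseline = baseline, g_max = rep(g_max, length(a))),
        list())
}

#' Demonstration terms from the unique-interactions and niche settings
#'
#' Returns three community-impact terms used to illustrate how assumptions
#' interact with clone consistency:
#' * `mutualism` — the saturating multi-interaction sum
#'   \eqn{\sum_i a_i x_i / (h + x_i)} as a black box. It is *not* an impact
#'   function (the saturation applies per abundance, not to a linear
#'   combination) and fails criterion I4.
#' * `unique` — one summand of the same sum under the unique-interaction
#'   assumption (only one parameter nonzero). As an expression
#'   \eqn{\chi(\sum_i b_i x_i)} with \eqn{\chi(w) = w / (h + w / s)} it is
#'   consistent by construction.
#' * `niche` — the expanded niche term \eqn{u - \sum_i a_i x_i}; the naive
#'   `u - x_j` becomes an impact function once the exclusive-niche
#'   occupancies (`a_jj = 1`, `a_ji = 0` otherwise) are made explicit.
#'
#' @param h Half-saturation constant (> 0).
#' @param u Total niche size.
#' @param strength Interaction strength baked into the `unique` summand's
#'   combining function.
#' @return List with elements `mutualism` (a `function(x, params)`),
#'   `unique` and `niche` (impact expressions).
#' @export
make_uim_terms <- function(h = 1, u = 1, strength = 1) {
  if (h <= 0) stop("half-saturation constant must be positive",
                   call. = FALSE)
  list(
    mutualism = function(x, params) {
      a <- if (inherits(params, "parameter_table")) params$a[, 1L] else params
      sum(a * x / (h + x))
    },
    unique = ie_apply("holling2_scaled", ie_basic(1L),
                      args = list(h = h, a = strength)),
    niche = ie_sum(ie_const(u), ie_scale(-1, ie_basic(1L)))
  )
}

#' Sample a sparse product-form ensemble model
#'
#' Draws a random model of the general form
#' \deqn{\dot x_j = x_j\, g_j \prod_{k=1}^m \eta_k\Big(\sum_i a_{jik}
#'   x_i\Big),}
#' the shape this framework suggests for theoretical-ecology ensembles: `m`
#' interaction mechanisms, each a basic impact function wrapped in a
#' transform \eqn{\eta_k} normalized to \eqn{\eta_k(0) = 1} so that absent
#' interactions are neutral under the product. Coefficients are sampled from
#' a sparse distribution (most populations take part in few mechanisms):
#' each entry is nonzero with probability `sparsity`; off-diagonal values
#' are drawn uniformly from `coef_range` and diagonal entries of the first
#' mechanism are set to -1 (self-limitation) when drawn. The default
#' `coef_range` is non-positive (competitive), which keeps trajectories
#' bounded on the checker's probe horizon.
#'
#' @param n Number of populations.
#' @param m Number of interaction mechanisms (basic impact functions).
#' @param sparsity Probability that a coefficient is nonzero.
#' @param g Growth rates; default drawn uniformly from \[0.5, 1.5\].
#' @param eta Registry names of the per-mechanism transforms (recycled to
#'   length m); must satisfy `eta(0) = 1`.
#' @param coef_range Range of the off-diagonal coefficient distribution.
#' @param seed RNG seed; the same seed reproduces the coefficient tables
#'   bit-exactly.
#' @return A [population_model()] (consistent by construction).
#' @export
sample_general_model <- function(n, m = 2L, sparsity = 0.5, g = NULL,
                                 eta = c("one_plus", "gauss"),
                                 coef_range = c(-0.5, 0), seed = 1L) {
  stopifnot(m >= 1L, sparsity >= 0, sparsity <= 1)
  eta <- rep_len(eta, m)
  for (nm in eta) {
    e0 <- get_transform(nm)(0)
    if (abs(e0 - 1) > 1e-12) {
      stop(sprintf("eta transform '%s' violates eta(0) = 1", nm),
           call. = FALSE)
    }
  }
  with_seed(seed, {
    if (is.null(g)) g <- stats::runif(n, 0.5, 1.5)
    mats <- lapply(seq_len(m), function(k) {
      mask <- matrix(stats::runif(n * n) < sparsity, n, n)
      M <- matrix(stats::runif(n * n, coef_range[1], coef_range[2]), n, n)
      M[!mask] <- 0
      if (k == 1L) diag(M) <- ifelse(diag(mask), -1, 0)
      M
    })
  })
  names(mats) <- paste0("A", seq_len(m))
  build <- function(vectors, matrices) {
    gg <- vectors$g
    MM <- matrices
    nn <- length(gg)
    etas <- lapply(eta, get_transform)
    population_model(
      n = nn,
      phi = function(x) {
        out <- gg
        for (k in seq_len(m)) out <- out * etas[[k]](drop(MM[[k]] %*% x))
        out
      },
      tables = list(vectors = list(g = gg), matrices = MM),
      rebuild = build,
      phi_exprs = lapply(seq_len(nn), function(j) {
        factors <- lapply(seq_len(m), function(k) {
          ie_apply(eta[k], ie_basic(k))
        })
        ie_scale(gg[j], do.call(ie_product, factors))
      }),
      expr_params = function(j) {
        parameter_table(do.call(cbind, lapply(MM, function(M) M[j, ])))
      },
      family = "ensemble")
  }
  build(list(g = g), mats)
}
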