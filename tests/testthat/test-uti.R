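# The conditioned-medium case study: datasets, both models, constraint
# validation, the synthetic experiment and parameter recovery.

test_that("dataset constructor enforces the normalization conventions", {
  d <- inhibitory_dataset()
  expect_equal(d$c, rep(1, 3))
  expect_equal(diag(d$c_pair), rep(0.6, 3))
  expect_error(cm_dataset(g = c(1, -1), g_pair = diag(2) + 1,
                          c_pair = matrix(0.6, 2, 2)), "positive")
  expect_error(cm_dataset(g = c(1, 1), g_pair = diag(2) + 1,
                          c_pair = matrix(0.5, 2, 2)), "1 - v")
  expect_error(cm_dataset(g = 1, g_pair = matrix(1), c_pair = matrix(0.6),
                          v = 1.2), "strictly between")
  expect_error(cm_dataset(g = c(1, 1), g_pair = diag(2) + 1,
                          c_pair = matrix(c(0.6, 1, 1, 0.6), 2),
                          c = c(1, 2)), "normalized")
})

test_that("existing-model parameters follow the case-split rule", {
  d <- inhibitory_dataset()
  p <- derive_existing_params(d)
  expect_equal(p$a[1, 2], d$g_pair[1, 2] / d$g[1] - 1)
  # all off-diagonal capacities < 1 here: b_ji = (c_ji - 1)/v
  expect_equal(p$b[1, 2], (d$c_pair[1, 2] - 1) / d$v)
  expect_equal(diag(p$b), rep(-1, 3))
  # promotion branch: c_ji >= 1 uses c_ji - 1 without the 1/v factor
  d2 <- d; d2$c_pair[1, 2] <- 1.2
  p2 <- derive_existing_params(d2)
  expect_equal(p2$b[1, 2], 0.2)
})

test_that("existing model reduces to Verhulst for a monoculture", {
  d1 <- cm_dataset(g = 1, g_pair = matrix(1.1), c_pair = matrix(0.6))
  m <- make_existing_model(d1)
  x <- seq(0.1, 0.9, by = 0.2)
  for (xi in x) expect_equal(rhs(m, xi), xi * (1 - xi))
  fp <- refine_fixed_point(m, 0.5)
  expect_equal(fp$x, 1, tolerance = 1e-10)
})

test_that("existing model's interior fixed point solves the linear system", {
  d <- inhibitory_dataset()
  m <- make_existing_model(d)
  b <- derive_existing_params(d)$b
  fp <- interior_fixed_point_linear(b)
  expect_true(all(fp$x > 0))
  expect_equal(max(abs(rhs(m, fp$x))), 0, tolerance = 1e-12)
})

test_that("new-model parameter derivation matches the closed forms", {
  d <- inhibitory_dataset()
  p <- derive_new_params(d)
  # s_jk = (1 - c_jk)/v; c_jk = 0.6, v = 0.4 -> 1
  expect_equal(p$s, (1 - d$c_pair) / 0.4)
  expect_equal(diag(p$s), rep(1, 3))   # from c_jj = 1 - v
  # approx variant: r_jk = (g_jk - g_j)/v; g_j = 1, g_jk = 1.2 -> 0.5
  d2 <- d; d2$g_pair[1, 2] <- 1.2
  expect_equal(derive_new_params(d2)$r[1, 2], (1.2 - 1) / 0.4)
  # full variant divides by the saturation factor
  pf <- derive_new_params(d, variant = "full")
  sig <- 1 - pmax(1 - d$c_pair, 0)^10
  expect_equal(pf$r, (d$g_pair / sig - matrix(d$g, 3, 3)) / 0.4)
  # singularity guard names the offending entry
  d3 <- d; d3$c_pair[2, 1] <- 0
  expect_error(derive_new_params(d3, variant = "full"), "j = 2, k = 1")
  d4 <- d; d4$c_pair[2, 1] <- 0.01
  expect_warning(derive_new_params(d4, variant = "full"), "blows up")
})

test_that("new model: monoculture equilibrium, non-negativity, structure", {
  d <- inhibitory_dataset()
  m <- make_new_model(derive_new_params(d))
  # at x_j = 1 alone the niche is exactly full: RHS = 0
  for (j in 1:3) {
    x <- rep(0, 3); x[j] <- 1
    expect_equal(rhs(m, x)[j], 0)
  }
  # populations never decline: both clamped factors are non-negative
  set.seed(8)
  for (i in 1:50) expect_true(all(rhs(m, runif(3, 0, 3)) >= 0))
  expect_equal(certify_model(m)$verdict, "consistent-by-construction")
})

test_that("new model passes, existing model fails, the clone-split test", {
  d <- inhibitory_dataset()
  mn <- make_new_model(derive_new_params(d))
  rep_n <- check_model_consistency(mn, probe_config(n_probes = 3, seed = 2),
                                   horizon = 10)
  expect_equal(rep_n$results$verdict, "pass")
  expect_lt(rep_n$results$worst_deviation, 1e-8)
  me <- make_existing_model(d)
  rep_e <- check_model_consistency(me, probe_config(n_probes = 3, seed = 2),
                                   horizon = 10)
  expect_equal(rep_e$results$verdict, "fail")
})

test_that("constraint residuals: approx closed form, full variant exact", {
  d <- inhibitory_dataset()
  res <- validate_constraints(make_new_model(derive_new_params(d)), d)
  expect_equal(res$growth, rep(0, 3))
  expect_equal(res$capacity, rep(0, 3))
  expect_equal(max(abs(res$conditioned_capacity)), 0, tolerance = 1e-12)
  # conditioned growth residual is -g_jk (1 - c_jk)^q, entrywise exactly
  expect_equal(res$conditioned_growth,
               -d$g_pair * pmax(1 - d$c_pair, 0)^10, tolerance = 1e-12)
  resf <- validate_constraints(
    make_new_model(derive_new_params(d, variant = "full")), d)
  expect_equal(max(abs(resf$conditioned_growth)), 0, tolerance = 1e-12)
  expect_equal(max(abs(resf$conditioned_capacity)), 0, tolerance = 1e-12)
  # existing model meets the monoculture capacity constraint trivially
  rese <- validate_constraints(make_existing_model(d), d)
  expect_equal(rese$capacity, rep(0, 3))
})

test_that("synthetic truth is seeded and the experiment deterministic", {
  t1 <- synthetic_truth(n = 3, seed = 5)
  t2 <- synthetic_truth(n = 3, seed = 5)
  expect_identical(t1$r, t2$r)
  expect_identical(t1$s, t2$s)
  expect_identical(t1$g, t2$g)
  d1 <- simulate_experiment(t1)
  d2 <- simulate_experiment(t2)
  expect_identical(d1$g_pair, d2$g_pair)
  expect_identical(d1$c_pair, d2$c_pair)
  expect_equal(diag(d1$c_pair), rep(0.6, 3))
})

test_that("independent strains are unaffected by conditioning", {
  truth <- synthetic_truth(n = 3, seed = 4, sparsity = 0)
  d <- simulate_experiment(truth)
  off <- row(d$c_pair) != col(d$c_pair)
  expect_equal(d$c_pair[off], rep(1, 6), tolerance = 1e-8)
  expect_equal(d$g_pair[off], matrix(d$g, 3, 3)[off], tolerance = 1e-10)
  # exact recovery needs the full variant: the approx variant's diagonal
  # necessarily carries the saturation residual -g_j v^q / v
  rec <- recover_parameters(seed = 4, n = 3, sparsity = 0, variant = "full")
  expect_lt(rec$s_error, 1e-6)
  expect_lt(rec$r_error, 1e-6)
  rec_a <- recover_parameters(seed = 4, n = 3, sparsity = 0)
  z <- pmax(1 - rec_a$dataset$c_pair, 0)^10
  expect_lte(rec_a$r_error,
             max(abs(rec_a$dataset$g_pair) * z / (0.4 * (1 - z))) + 1e-9)
})

test_that("parameter recovery is exact for s and bounded for r", {
  rec <- recover_parameters(seed = 1, n = 4, sparsity = 0.5)
  expect_lt(rec$s_error, 1e-6)
  expect_lte(rec$r_error, rec$r_bound * (1 + 1e-9) + 1e-9)
  # the approx residual is known in closed form, entrywise
  z <- pmax(1 - rec$dataset$c_pair, 0)^10
  expect_equal(rec$recovered$r - rec$truth$r,
               -rec$dataset$g_pair * z / (0.4 * (1 - z)),
               tolerance = 1e-7)
})

test_that("clone-splitting the dataset preserves new-model dynamics only", {
  # mild inhibition keeps the existing model's crowding ratio integrable,
  # so the comparison is about consistency, not stiffness
  v <- 0.4
  d <- cm_dataset(g = c(1.0, 0.8, 1.2),
                  g_pair = matrix(c(0.6, 1.15, 0.9,
                                    0.7, 0.48, 0.95,
                                    1.3, 1.1, 0.72), 3, 3, byrow = TRUE),
                  c_pair = matrix(c(1 - v, 0.90, 0.85,
                                    0.88, 1 - v, 0.92,
                                    0.86, 0.94, 1 - v), 3, 3, byrow = TRUE))
  d2 <- split_cm_dataset(d, 2)
  expect_equal(d2$g_pair[2, 4], d$g_pair[2, 2])
  expect_equal(d2$c_pair[4, 4], 1 - d$v)
  t_grid <- seq(0, 10, length.out = 51)
  x0 <- c(0.2, 0.3, 0.25)
  x0s <- c(0.2, 0.15, 0.25, 0.15)
  mn <- make_new_model(derive_new_params(d))
  mn2 <- make_new_model(derive_new_params(d2))
  A <- simulate_model(mn, x0, t_grid)$abundances
  B <- simulate_model(mn2, x0s, t_grid)$abundances
  B_agg <- cbind(B[, 1], B[, 2] + B[, 4], B[, 3])
  expect_lt(max(abs(A - B_agg)), 1e-8)
  me <- make_existing_model(d)
  me2 <- make_existing_model(d2)
  Ae <- simulate_model(me, x0, t_grid)$abundances
  Be <- simulate_model(me2, x0s, t_grid)$abundances
  Be_agg <- cbind(Be[, 1], Be[, 2] + Be[, 4], Be[, 3])
  expect_gt(max(abs(Ae - Be_agg)), 1e-3)
})

test_that("weakening inhibition never lowers the conditioned plateau", {
  # two strains; sweep c_12 upward (strain 2 inhibits strain 1 less and
  # less) and watch strain 1's pairwise plateau
  plateaus <- vapply(c(0.3, 0.5, 0.7, 0.9, 1.05), function(c12) {
    v <- 0.4
    d <- cm_dataset(g = c(1, 1),
                    g_pair = matrix(c(1 - v, 1, 1, 1 - v), 2) + 0.9,
                    c_pair = matrix(c(1 - v, c12, 0.8, 1 - v), 2,
                                    byrow = TRUE))
    m <- make_new_model(derive_new_params(d))
    m$frozen <- 2L
    clonecon:::plateau_abundance(m, 1L, c(0.01, v), horizon = 500,
                                 ptol = 1e-10)
  }, numeric(1))
  expect_true(all(diff(plateaus) >= -1e-9))
})

test_that("datasets round-trip through the four delimited files", {
  d <- inhibitory_dataset()
  dir <- withr::local_tempdir()
  write_cm_dataset(d, dir)
  expect_true(all(file.exists(file.path(dir, c("g.csv", "c.csv",
                                               "g_pair.csv", "c_pair.csv",
                                               "config.json")))))
  d2 <- read_cm_dataset(dir)
  expect_equal(d2$g, d$g)
  expect_equal(d2$g_pair, d$g_pair)
  expect_equal(d2$c_pair, d$c_pair)
  expect_equal(d2$v, d$v)
})
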