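# Impact-function evaluation, canonical form, power sums, and the algebraic
# invariants behind clone equivalence.

test_that("eval_basic computes transformed linear combinations", {
  pt <- parameter_table(c(0.5, -1))
  expect_equal(eval_basic(ie_basic(1), c(1, 2), pt), -1.5)
  # zero parameters force a zero value whatever the (valid) transform
  pt0 <- parameter_table(rep(0, 4))
  for (z in list(list("identity", list()), list("power", list(p = 3)),
                 list("clamp", list()))) {
    expect_equal(eval_basic(ie_basic(1, z[[1]], z[[2]]),
                            runif(4, 0, 5), pt0), 0)
  }
  # lumping oracle: evaluation on the canonicalized community is identical
  x <- c(2, 3, 3); a <- c(0.5, -1, -1)
  cf <- canonicalize(x, a)
  padded <- canonical_state(cf)
  expect_equal(eval_basic(ie_basic(1), x, parameter_table(a)), -5)
  expect_equal(eval_basic(ie_basic(1), padded$x, parameter_table(padded$a)),
               -5)
})

test_that("eval_basic rejects bad columns and invalid transforms", {
  pt <- parameter_table(c(1, 2))
  expect_error(eval_basic(ie_basic(3), c(1, 1), pt), "out of range")
  # one_plus has zeta(0) = 1, not a parameter transform
  expect_error(eval_basic(ie_basic(1, "one_plus"), c(1, 1), pt),
               "zeta\\(0\\)")
})

test_that("eval_pairwise computes the double sum over a_ij", {
  pt <- parameter_table(c(0, 0), list(P = matrix(c(0, 1, 1, 0), 2)))
  expect_equal(eval_pairwise(ie_pairwise("P"), c(1, 1), pt), 2)
  # all-zero matrix: zero independent of x
  pt0 <- parameter_table(c(0, 0, 0), list(P = matrix(0, 3, 3)))
  expect_equal(eval_pairwise(ie_pairwise("P"), runif(3), pt0), 0)
  # only the (1,1) term survives when x = (2, 0)
  A <- matrix(c(3, 7, -4, 2), 2)
  pt2 <- parameter_table(c(0, 0), list(P = A))
  expect_equal(eval_pairwise(ie_pairwise("P"), c(2, 0), pt2), 12)
  expect_error(eval_pairwise(ie_pairwise("missing"), c(1, 1), pt2),
               "not found")
})

test_that("eval_expression handles composition, constants and saturation", {
  # Holling type-II pollination factor at summed contribution 1 -> 1/2
  e <- ie_apply("holling2", ie_basic(1))
  expect_equal(eval_expression(e, c(1, 1), parameter_table(c(0.5, 0.5))),
               0.5)
  # saturation: factor tends to 1 for large summed contribution
  expect_equal(eval_expression(e, c(1e8, 1), parameter_table(c(1, 1))), 1,
               tolerance = 1e-6)
  # constant-leaf-only tree ignores state and parameters
  e2 <- ie_sum(ie_const(2), ie_scale(3, ie_const(1)))
  expect_equal(eval_expression(e2, runif(3), parameter_table(runif(3))), 5)
})

test_that("canonicalize drops zero rows and lumps exact ties, ascending", {
  cf <- canonicalize(c(2, 3, 3), c(0.5, -1, -1))
  expect_equal(cf$values, c(-1, 0.5))
  expect_equal(cf$masses, c(6, 2))
  expect_equal(cf$s, 2L)
  # zero abundance dropped
  cf2 <- canonicalize(c(0, 5), c(7, 2))
  expect_equal(cf2$values, 2)
  expect_equal(cf2$masses, 5)
  # zero parameter dropped ("no impact" convention)
  cf3 <- canonicalize(c(4, 5), c(0, 2))
  expect_equal(cf3$values, 2)
  expect_equal(cf3$masses, 5)
  # near-ties are NOT lumped: exact equality only
  cf4 <- canonicalize(c(1, 1), c(0.5, 0.5 + 1e-14))
  expect_equal(cf4$s, 2L)
})

test_that("canonicalize for m > 1 lumps identical tuples lexicographically", {
  a <- rbind(c(1, 2), c(0, 3), c(1, 2), c(-1, 5))
  cf <- canonicalize(c(1, 2, 3, 4), parameter_table(a))
  expect_equal(cf$s, 3L)
  expect_equal(cf$values[1, ], c(-1, 5))   # lexicographic order
  expect_equal(cf$masses[cf$values[, 1] == 1 & cf$values[, 2] == 2], 4)
  # zero-padding round trip keeps length n
  st <- canonical_state(cf)
  expect_length(st$x, 4L)
  # row 2 has a1 = 0 but a2 != 0, so it is kept: total mass is preserved
  expect_equal(sum(st$x), 10)
})

test_that("power sums match hand values and are preserved by lumping", {
  expect_equal(power_sums(c(1, 1), c(1, 1), 2), c(2, 2))
  expect_equal(power_sums(c(2, 0), c(3, 9), 1), 6)
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    # draw parameters from a small pool to force lumpable ties
    a <- sample(c(-1, 0, 0.5, 2), n, replace = TRUE)
    x <- runif(n, 0, 3) * rbinom(n, 1, 0.8)
    cf <- canonicalize(x, a)
    st <- canonical_state(cf)
    expect_equal(power_sums(x, a, 2 * n + 1),
                 power_sums(st$x, st$a, 2 * n + 1), tolerance = 1e-13)
  }
})

test_that("equal power sums imply equal canonical form (small n)", {
  # finite surrogate of the moment-determinacy lemma: redistribute masses
  # within tied parameter groups and permute; power sums and canonical
  # forms must both be unchanged, and differing configurations must differ
  # in some power sum
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(2:4, 1)
    a <- sample(c(-2, -0.5, 1, 3), n, replace = TRUE)
    x <- runif(n, 0.1, 2)
    # second configuration: permute and redistribute within equal-a groups
    perm <- sample(n)
    a2 <- a[perm]; x2 <- x[perm]
    for (val in unique(a2)) {
      idx <- which(a2 == val)
      if (length(idx) > 1) {
        w <- runif(length(idx)); w <- w / sum(w)
        x2[idx] <- sum(x2[idx]) * w
      }
    }
    p1 <- power_sums(x, a, 2 * n + 1)
    p2 <- power_sums(x2, a2, 2 * n + 1)
    expect_equal(p1, p2, tolerance = 1e-12)
    cf1 <- canonicalize(x, a); cf2 <- canonicalize(x2, a2)
    expect_equal(cf1$values, cf2$values)
    expect_equal(cf1$masses, cf2$masses, tolerance = 1e-12)
    # a genuinely different community differs in some power sum
    x3 <- x; x3[1] <- x3[1] + 0.5
    p3 <- power_sums(x3, a, 2 * n + 1)
    expect_gt(max(abs(p3 - p1)), 1e-9)
  }
})

test_that("expression evaluation is invariant under canonicalization", {
  # single-column expressions cannot tell a community from its canonical
  # form (the lumping lemma), to float accuracy
  set.seed(11)
  for (rep in 1:60) {
    e <- rand_basic_expr(1L, depth = 2L)
    n <- sample(3:6, 1)
    a <- sample(c(-1, -0.25, 0, 0.5, 1.5), n, replace = TRUE)
    x <- runif(n, 0, 2) * rbinom(n, 1, 0.85)
    st <- canonical_state(canonicalize(x, a))
    v1 <- eval_expression(e, x, parameter_table(a))
    v2 <- eval_expression(e, st$x, parameter_table(st$a))
    expect_equal(v1, v2, tolerance = 1e-12)
  }
})

test_that("eval_basic is linear in the abundance argument", {
  set.seed(3)
  pt <- parameter_table(runif(5, -1, 1))
  b <- ie_basic(1, "power", list(p = 2))
  for (rep in 1:20) {
    x <- runif(5); y <- runif(5)
    expect_equal(eval_basic(b, x + y, pt),
                 eval_basic(b, x, pt) + eval_basic(b, y, pt),
                 tolerance = 1e-12)
  }
})

test_that("expression JSON configs round-trip", {
  e <- ie_sum(ie_scale(0.5, ie_apply("holling2", ie_basic(2), args = list())),
              ie_product(ie_const(2), ie_basic(1, "power", list(p = 2))),
              ie_pairwise("P", "clamp"))
  path <- withr::local_tempfile(fileext = ".json")
  write_expression(e, path)
  e2 <- read_expression(path)
  pt <- parameter_table(cbind(runif(3), runif(3)),
                        list(P = matrix(runif(9), 3)))
  x <- runif(3)
  expect_equal(eval_expression(e2, x, pt), eval_expression(e, x, pt))
  expect_equal(certify_structure(e2)$verdict, "consistent-by-construction")
  expect_error(write_expression(ie_blackbox(function(x, p) 0), path),
               "serialized")
})

test_that("community_state and parameter_table validate their invariants", {
  expect_error(community_state(numeric(0)), "at least one")
  expect_error(community_state(c(1, -1)), "non-negative")
  expect_error(parameter_table(matrix(1, 2, 2),
                               list(P = matrix(1, 3, 3))), "2 x 2")
  expect_error(eval_basic(ie_basic(1), c(1, 2, 3), parameter_table(c(1, 2))),
               "3 populations")
})

test_that("parameter tables round-trip through delimited text", {
  pt <- parameter_table(cbind(growth = c(0.3, -0.3), cap = c(1, 2)))
  dir <- withr::local_tempdir()
  write_parameter_table(pt, file.path(dir, "params.csv"))
  pt2 <- read_parameter_table(file.path(dir, "params.csv"))
  expect_equal(pt2$a, pt$a)
  M <- matrix(c(0.5, -1, 0.8, -0.5), 2, byrow = TRUE)
  write_pairwise_matrix(M, file.path(dir, "b.csv"))
  expect_equal(read_pairwise_matrix(file.path(dir, "b.csv")), M)
})
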