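# Shared fixtures and generators, all built in code at test time.

# Random impact expression over basic leaves of a single parameter column.
# Transforms are chosen tame (bounded or low-order) so that float equality
# at 1e-12 relative is a fair ask for the lumping-invariance property.
rand_basic_expr <- function(column = 1L, depth = 2L) {
  zetas <- list(list("identity", list()),
                list("power", list(p = 2)),
                list("power", list(p = 3)),
                list("clamp", list()))
  chis <- c("gauss", "one_plus")
  leaf <- function() {
    z <- zetas[[sample.int(length(zetas), 1L)]]
    ie_basic(column, z[[1L]], z[[2L]])
  }
  build <- function(d) {
    if (d <= 0L || stats::runif(1) < 0.3) return(leaf())
    switch(sample.int(4L, 1L),
           ie_sum(build(d - 1L), build(d - 1L)),
           ie_product(build(d - 1L), build(d - 1L)),
           ie_scale(stats::runif(1, -2, 2), build(d - 1L)),
           ie_apply(sample(chis, 1L), build(d - 1L)))
  }
  build(depth)
}

# Wrap an expression as a black-box (x, params) term for the criteria
# checker.
expr_fn <- function(e) function(x, params) eval_expression(e, x, params)

# A small hand-built conditioned-medium dataset with all off-diagonal
# conditioned capacities < 1 (pure inhibition), n = 3, v = 0.4.
inhibitory_dataset <- function() {
  v <- 0.4
  g <- c(1.0, 0.8, 1.2)
  g_pair <- matrix(c(0.72, 1.10, 0.95,
                     0.64, 0.48, 0.90,
                     1.30, 1.05, 0.84), 3, 3, byrow = TRUE)
  c_pair <- matrix(c(1 - v, 0.80, 0.55,
                     0.70, 1 - v, 0.90,
                     0.45, 0.85, 1 - v), 3, 3, byrow = TRUE)
  cm_dataset(g = g, g_pair = g_pair, c_pair = c_pair, v = v)
}

# Deterministic 3-species gLV fixture used across tests.
glv_fixture <- function() {
  make_glv(g = c(1, 0.8, 1.2), c = c(1, 1, 1),
           A = matrix(c(-1, -0.2, -0.1,
                        -0.3, -1, -0.2,
                        -0.1, -0.2, -1), 3, 3, byrow = TRUE))
}
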