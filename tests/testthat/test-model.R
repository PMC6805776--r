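test_that("the null system has zero derivatives everywhere", {
  p <- zero_parameters()
  set.seed(1)
  for (i in 1:5)
    expect_equal(unname(hif_rhs(0, random_state(), p)), rep(0, 10))
})

test_that("IL-15 decays at its tabulated first-order rate", {
  p <- hif_parameters()       # a1 = 0
  y <- canonical_state(1)     # primed: y1 = 1
  dy <- hif_rhs(0, y, p)
  expect_equal(unname(dy[["y1"]]), -0.062)
})

test_that("the mTOR balance reproduces a hand-substituted value", {
  p <- hif_parameters()
  y <- canonical_state(1)
  # direct substitution of the published numbers into the mTOR equation:
  # (a3 + k2*y2) * alpha1/(alpha2 + y6) - d3*y3
  by_hand <- (0.037 + 0.307 * 1) * 1.163 / (0.386 + 0.05) - 0.919 * 1
  expect_equal(unname(hif_rhs(0, y, p)[["y3"]]), by_hand, tolerance = 1e-12)
})

test_that("total HIF-1alpha is the sum of the three pools", {
  expect_equal(total_hif(rep(0, 10)), 0)
  expect_equal(total_hif(canonical_state(0)), 1)
  y <- rep(0, 10); y[4] <- 2; y[6] <- 3; y[10] <- 5
  expect_equal(total_hif(y), 10)
  # linear and permutation-insensitive over the three pools
  y2 <- rep(0, 10); y2[4] <- 5; y2[6] <- 2; y2[10] <- 3
  expect_equal(total_hif(y), total_hif(y2))
  expect_equal(total_hif(2 * y), 2 * total_hif(y))
})

test_that("the steady-state constraint has exactly 10 equations", {
  p <- hif_parameters()
  r <- steady_state_residual(canonical_state(0), p)
  expect_length(r, 10)
  expect_equal(unname(steady_state_residual(random_state(),
                                            zero_parameters())),
               rep(0, 10))
})

test_that("the STAT3 equation balances under the d8 = k8 tie", {
  # a8 = 0, y1 = 0 and y3 = y8 = 1 make activation equal decay exactly
  p <- hif_parameters()
  r <- steady_state_residual(canonical_state(0), p)
  expect_equal(unname(r[["y8"]]), 0)
})

test_that("derivatives are non-negative on each axis boundary", {
  # positivity invariance: a component at zero cannot be pushed negative
  set.seed(42)
  for (rep in 1:20) {
    p <- hif_parameters()
    jitter <- stats::runif(length(p$values), 0.5, 1.5)
    p$values <- p$values * jitter
    p$values[c("rho3", "rho4", "rho6", "rho_rapa", "rho_nfkb")] <-
      pmin(p$values[c("rho3", "rho4", "rho6", "rho_rapa", "rho_nfkb")], 1)
    p <- resolve_ties(p)
    y <- random_state()
    j <- sample(10, 1)
    y[j] <- 0
    dy <- hif_rhs(0, y, p)
    expect_gte(dy[[j]], 0)
  }
})

test_that("degenerate Hill input is defined as zero", {
  p <- set_parameters(hif_parameters(), c(xi28 = 0))
  y <- canonical_state(0); y[8] <- 0
  expect_true(all(is.finite(hif_rhs(0, y, p))))
})

test_that("rhs rejects invalid states", {
  p <- hif_parameters()
  y <- canonical_state(0); y[3] <- -0.1
  expect_error(hif_rhs(0, y, p), "negative")
  p_bad <- set_parameters(p, c(alpha2 = 0))
  y2 <- canonical_state(0); y2[6] <- 0
  p_bad$values[["alpha1"]] <- Inf
  expect_error(hif_rhs(0, y2, p_bad), "equation")
})

test_that("consistency solving reaches machine-level equilibrium", {
  eq <- consistent_fixture()
  expect_lte(eq$residual, 1e-8)
  r <- steady_state_residual(eq$state, eq$params)
  expect_lte(max(abs(r)), 1e-8)
  # printed tables are rounded to 3 decimals: adjustments stay below 2%
  expect_lt(max(abs(eq$adjustment)), 0.02)
  # already-consistent parameters are a fixed point
  eq2 <- solve_consistent_equilibrium(eq$params)
  expect_lt(max(abs(eq2$adjustment[c("a2", "a3", "a5", "kalpha", "d10")])),
            1e-6)
})

test_that("the untreated equilibrium persists over 100 h", {
  eq <- consistent_fixture()
  tr <- hif_simulate(eq$params, hif_protocol(horizon = 100),
                     times = c(0, 100), y0 = eq$state)
  drift <- max(abs(tr$states[2, ] - tr$states[1, ]) /
                 pmax(abs(tr$states[1, ]), 1e-8))
  expect_lt(drift, 0.01)
})

test_that("equilibrium_state solves the full ten-equation system", {
  p <- set_parameters(hif_parameters(), c(d4 = 0.7, k6 = 20))
  y <- equilibrium_state(p)
  expect_lte(max(abs(steady_state_residual(y, p))), 1e-9)
  expect_true(all(y >= 0))
})
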