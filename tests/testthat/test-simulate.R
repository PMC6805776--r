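test_that("the null system yields a constant trajectory", {
  p <- zero_parameters()
  set.seed(7)
  y0 <- random_state()
  tr <- hif_simulate(p, hif_protocol(horizon = 10),
                     times = seq(0, 10, by = 1), y0 = y0)
  for (i in seq_along(tr$times))
    expect_equal(unname(tr$states[i, ]), unname(y0), tolerance = 1e-10)
})

test_that("IL-15 follows its closed-form exponential decay", {
  p <- hif_parameters()       # a1 = 0
  eq <- consistent_fixture()
  proto <- protocol_standard(il15_at = 0, horizon = 30)
  tms <- seq(0, 30, by = 0.5)
  tr <- hif_simulate(eq$params, proto, tms, y0 = eq$state)
  expect_equal(tr$states[, 1], exp(-eq$params$values[["d1"]] * tms),
               tolerance = 1e-6)
})

test_that("compiled and pure-R right-hand sides integrate identically", {
  eq <- consistent_fixture()
  proto <- protocol_standard(il15_at = 0, dmog_at = 0, horizon = 20)
  tms <- seq(0, 20, by = 2)
  trC <- hif_simulate(eq$params, proto, tms, y0 = eq$state)
  trR <- hif_simulate(eq$params, proto, tms, y0 = eq$state, engine = "R")
  expect_equal(trC$states, trR$states, tolerance = 1e-8)
})

test_that("two integrator families agree on the observables", {
  eq <- consistent_fixture()
  proto <- protocol_standard(il15_at = 0, dmog_at = 0, horizon = 20)
  tms <- seq(0, 20, by = 2)
  tr1 <- hif_simulate(eq$params, proto, tms, y0 = eq$state)
  tr2 <- hif_simulate(eq$params, proto, tms, y0 = eq$state,
                      method = "ode45")
  m1 <- as.matrix(tr1$observables[-1]); m2 <- as.matrix(tr2$observables[-1])
  expect_lt(max(abs(m1 - m2) / pmax(abs(m1), 1e-8)), 1e-5)
})

test_that("the output grid contains every protocol event time", {
  eq <- consistent_fixture()
  proto <- protocol_standard(il15_at = 3.3, dmog_at = 7.7, horizon = 20)
  tr <- hif_simulate(eq$params, proto, times = seq(0, 20, by = 2),
                     y0 = eq$state)
  expect_true(all(c(3.3, 7.7) %in% tr$times))
  expect_true(all(tr$states >= 0))
  # impulse: y1 jumps by the dose right after its event
  i <- which(tr$times == 3.3)
  expect_lt(tr$states[i, 1], 0.5)        # pre-impulse convention at event
  expect_gt(tr$states[i + 1, 1], 0.5)
})

test_that("zero-efficacy treatments leave the trajectory untouched", {
  eq <- consistent_fixture()
  p0 <- set_parameters(eq$params, c(rho3 = 0, rho4 = 0, rho6 = 0,
                                    rho_rapa = 0, rho_nfkb = 0))
  tms <- seq(0, 20, by = 2)
  treated <- hif_simulate(
    p0, protocol_standard(dmog_at = 0, s3i_at = 0, rapamycin_at = 0,
                          nfkbi_at = 0, horizon = 20),
    tms, y0 = eq$state)
  untreated <- hif_simulate(p0, hif_protocol(horizon = 20), tms,
                            y0 = eq$state)
  expect_equal(treated$states, untreated$states, tolerance = 1e-10)
})

test_that("steady-state diagnostics detect convergence", {
  eq <- consistent_fixture()
  ss <- steady_state_value(eq$params, hif_protocol(horizon = 100),
                           y0 = eq$state)
  expect_true(ss$converged)
  expect_equal(unname(ss$state), unname(eq$state), tolerance = 0.01)
  expect_lt(ss$max_deriv, 1e-6)
})

test_that("an IL-15 impulse relaxes back to the untreated equilibrium", {
  eq <- consistent_fixture()
  # the IL-15 tail (1/d1 ~ 16 h) is still visible at the 100 h snapshot;
  # the convergence diagnostic must say so
  ss100 <- steady_state_value(eq$params,
                              protocol_standard(il15_at = 0, horizon = 100),
                              y0 = eq$state)
  expect_false(ss100$converged)
  # once relaxed, the stimulated endpoint equals the untreated one
  ss0 <- steady_state_value(eq$params, hif_protocol(horizon = 250),
                            y0 = eq$state, t_end = 250)
  ss1 <- steady_state_value(eq$params,
                            protocol_standard(il15_at = 0, horizon = 250),
                            y0 = eq$state, t_end = 250)
  expect_true(ss1$converged)
  expect_equal(ss1$total_hif, ss0$total_hif, tolerance = 0.01)
})

test_that("simulation rejects domain violations", {
  eq <- consistent_fixture()
  expect_error(hif_simulate(eq$params, hif_protocol(horizon = 10),
                            times = seq(0, 20, 1), y0 = eq$state),
               "horizon")
  y_bad <- eq$state; y_bad[2] <- -1
  expect_error(hif_simulate(eq$params, hif_protocol(horizon = 10),
                            times = c(0, 10), y0 = y_bad),
               "non-negative")
})
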