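test_that("a degenerate sweep grid reduces to the baseline steady state", {
  eq <- consistent_fixture()
  sw <- parameter_sweep(eq$params, "a1", list(0), "normoxia", y0 = eq$state)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$TOTAL_HIF, 1, tolerance = 0.01)
})

test_that("stronger continuous IL-15 supply raises HIF-1alpha under DMOG", {
  eq <- consistent_fixture()
  g <- seq(0, 10, length.out = 6)
  swD <- parameter_sweep(eq$params, "a1", g, "dmog", y0 = eq$state)
  expect_true(all(diff(swD$TOTAL_HIF) >= -1e-8))
  expect_true(all(is.finite(swD$TOTAL_HIF)) && all(swD$TOTAL_HIF >= 0))
})

test_that("DMOG amplifies the STAT3 external-regulation response", {
  eq <- consistent_fixture()
  g <- seq(0, 10, length.out = 5)
  sN <- parameter_sweep(eq$params, "a8", g, "normoxia", y0 = eq$state)
  sD <- parameter_sweep(eq$params, "a8", g, "dmog", y0 = eq$state)
  expect_true(all(sD$TOTAL_HIF >= sN$TOTAL_HIF))
})

test_that("2-D sweeps have the full grid product shape", {
  eq <- consistent_fixture()
  sw <- parameter_sweep(eq$params, c("a3", "a8"), list(c(0, 5), c(0, 5, 10)),
                        "normoxia", y0 = eq$state)
  expect_equal(nrow(sw), 6L)
  expect_true(all(is.finite(sw$TOTAL_HIF)))
})

test_that("dose-response is normalized, monotone and non-proportional", {
  eq <- consistent_fixture()
  dr <- dose_response(eq$params, doses = c(0, 0.25, 0.5, 0.75, 1),
                      y0 = eq$state)
  expect_equal(dr$fold_change[[1]], 1)
  expect_true(all(diff(dr$fold_change) > 0))
  # doubling the dose does not double the response
  ratio <- dr$fold_change[[5]] / dr$fold_change[[3]]
  expect_gt(abs(ratio - 2), 0.2)
})

test_that("treatment timing shapes the 12 h response", {
  eq <- consistent_fixture()
  tim <- timing_experiment(eq$params, y0 = eq$state)
  expect_equal(nrow(tim), 9L)
  expect_equal(tim$fold_change[tim$protocol == "untreated"], 1)
  # the maximum is IL-15 priming at 0 h followed by DMOG at 6 h
  expect_equal(tim$protocol[which.max(tim$fold_change)], "il15_0_dmog_6")
  # order of administration matters
  f_dmog_first <- tim$fold_change[tim$protocol == "dmog_0_il15_6"]
  f_il15_first <- tim$fold_change[tim$protocol == "il15_0_dmog_6"]
  expect_gt(abs(f_il15_first - f_dmog_first), 1e-3)
})

test_that("robustness sampling is seeded and degenerate at zero width", {
  eq <- consistent_fixture()
  r0 <- monte_carlo_robustness(eq$params, "a2", width = 0, n = 5, seed = 9,
                               y0 = eq$state)
  expect_equal(r0$relative_spread, 0, tolerance = 1e-10)
  r1 <- monte_carlo_robustness(eq$params, "a3", width = 0.25, n = 20,
                               seed = 11, y0 = eq$state)
  r2 <- monte_carlo_robustness(eq$params, "a3", width = 0.25, n = 20,
                               seed = 11, y0 = eq$state)
  expect_identical(r1$samples, r2$samples)
  expect_length(r1$samples, 20L)
})

test_that("combined IL-15 + DMOG dominates the single treatments past 4 h", {
  eq <- consistent_fixture()
  tms <- seq(0, 30, by = 1)
  hif <- function(proto)
    hif_simulate(eq$params, proto, tms, y0 = eq$state)$observables$TOTAL_HIF
  both <- hif(protocol_standard(il15_at = 0, dmog_at = 0, horizon = 30))
  il15 <- hif(protocol_standard(il15_at = 0, horizon = 30))
  dmog <- hif(protocol_standard(dmog_at = 0, horizon = 30))
  late <- tms > 4
  expect_true(all(both[late] > pmax(il15[late], dmog[late])))
})

test_that("dual transcription-factor blockade abolishes the IL-15 response", {
  eq <- consistent_fixture()
  at12 <- function(proto)
    tail(hif_simulate(eq$params, proto, c(0, 12),
                      y0 = eq$state)$observables$TOTAL_HIF, 1)
  inc_plain <- at12(protocol_standard(il15_at = 0, horizon = 30)) -
    at12(hif_protocol(horizon = 30))
  inc_blocked <- at12(protocol_standard(il15_at = 0, s3i_at = 0,
                                        nfkbi_at = 0, horizon = 30)) -
    at12(protocol_standard(s3i_at = 0, nfkbi_at = 0, horizon = 30))
  expect_lte(abs(inc_blocked), 0.05 * abs(inc_plain))
})

test_that("rapamycin reduces but does not eliminate HIF-1alpha", {
  eq <- consistent_fixture()
  tms <- seq(0, 30, by = 0.5)
  peak <- function(proto)
    max(hif_simulate(eq$params, proto, tms,
                     y0 = eq$state)$observables$TOTAL_HIF)
  p_both <- peak(protocol_standard(il15_at = 0, dmog_at = 0, horizon = 30))
  p_rapa <- peak(protocol_standard(il15_at = 0, dmog_at = 0,
                                   rapamycin_at = 0, horizon = 30))
  expect_lt(p_rapa, p_both)
  expect_gt(p_rapa, 1)    # still well above the untreated baseline
})
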