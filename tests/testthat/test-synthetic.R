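test_that("zero noise reproduces the model observables exactly", {
  eq <- consistent_fixture()
  proto <- protocol_standard(il15_at = 0, horizon = 30)
  pts <- data.frame(time_h = c(2, 6, 12), observable = "TOTAL_HIF")
  ds <- generate_dataset(proto, eq$params, pts, sds = 0.1, noise_sd = 0,
                         y0 = eq$state)
  tr <- hif_simulate(eq$params, proto,
                     times = sort(unique(c(0, pts$time_h))), y0 = eq$state)
  expect_equal(ds$points$value,
               tr$observables$TOTAL_HIF[match(ds$points$time_h, tr$times)],
               tolerance = 1e-9)
  expect_equal(ds$points$sd, rep(0.1, 3))
})

test_that("generation is seed-deterministic", {
  eq <- consistent_fixture()
  proto <- protocol_standard(dmog_at = 0, horizon = 30)
  pts <- data.frame(time_h = c(2, 6), observable = c("STAT3", "AKT"))
  d1 <- generate_dataset(proto, eq$params, pts, seed = 77, y0 = eq$state)
  d2 <- generate_dataset(proto, eq$params, pts, seed = 77, y0 = eq$state)
  d3 <- generate_dataset(proto, eq$params, pts, seed = 78, y0 = eq$state)
  expect_identical(d1$points$value, d2$points$value)
  expect_false(identical(d1$points$value, d3$points$value))
})

test_that("noise has the promised mean, spread and independence", {
  eq <- consistent_fixture()
  proto <- protocol_standard(il15_at = 0, horizon = 30)
  n <- 1e4
  # the same two (time, observable) cells replicated n times
  pts <- data.frame(time_h = rep(c(6, 12), n),
                    observable = "TOTAL_HIF")
  ds <- generate_dataset(proto, eq$params, pts, sds = 0.1, seed = 5,
                         y0 = eq$state)
  tr <- hif_simulate(eq$params, proto, times = c(0, 6, 12), y0 = eq$state)
  truth6 <- tr$observables$TOTAL_HIF[[2]]
  v6 <- ds$points$value[ds$points$time_h == 6]
  v12 <- ds$points$value[ds$points$time_h == 12]
  expect_lt(abs(mean(v6) - truth6), 3 * 0.1 / sqrt(n))
  expect_lt(abs(stats::sd(v6) - 0.1) / 0.1, 0.05)
  # independence across distinct points
  expect_lt(abs(stats::cor(v6, v12)), 0.05)
})

test_that("the default design mirrors the study layout", {
  s <- suite_fixture()
  expect_length(s$calibration, 4L)
  expect_setequal(names(s$calibration),
                  c("il15", "dmog", "il15_dmog_rapa", "il15_dmog_s3i"))
  expect_equal(sum(vapply(s$calibration, function(d) nrow(d$points),
                          integer(1))), 39L)
  expect_s3_class(s$validation, "hif_dataset")
  expect_equal(s$validation$label, "il15_dmog_validation")
  # all measurement times inside the 0-27 h observation window
  all_t <- unlist(lapply(s$calibration, function(d) d$points$time_h))
  expect_true(all(all_t >= 0 & all_t <= 27))
})

test_that("changing the design seed changes values but not shape", {
  a <- generate_calibration_suite(synth_design(seed = 1))
  b <- generate_calibration_suite(synth_design(seed = 2))
  expect_identical(lapply(a$calibration, function(d) dim(d$points)),
                   lapply(b$calibration, function(d) dim(d$points)))
  expect_false(identical(a$calibration[["il15"]]$points$value,
                         b$calibration[["il15"]]$points$value))
})

test_that("fitted synthetic trajectories keep the qualitative ordering", {
  # total HIF-1alpha under the generating parameters: combined treatment
  # above each single arm, inhibitor arms reduced
  eq <- consistent_fixture()
  at12 <- function(proto)
    tail(hif_simulate(eq$params, proto, c(0, 12),
                      y0 = eq$state)$observables$TOTAL_HIF, 1)
  v_both <- at12(protocol_standard(il15_at = 0, dmog_at = 0, horizon = 30))
  v_il15 <- at12(protocol_standard(il15_at = 0, horizon = 30))
  v_dmog <- at12(protocol_standard(dmog_at = 0, horizon = 30))
  v_rapa <- at12(protocol_standard(il15_at = 0, dmog_at = 0,
                                   rapamycin_at = 0, horizon = 30))
  v_s3i <- at12(protocol_standard(il15_at = 0, dmog_at = 0, s3i_at = 0,
                                  horizon = 30))
  expect_gt(v_both, v_il15)
  expect_gt(v_both, v_dmog)
  expect_lt(v_rapa, v_both)
  expect_lt(v_s3i, v_both)
})

test_that("noise-free recovery replicates are unbiased", {
  eq <- consistent_fixture()
  d <- synth_design(eq$params, seed = 31, noise_sd = 0)
  rs <- recovery_study(d, free = c("d1", "k6"), n_replicates = 2,
                       seed = 31)
  expect_equal(nrow(rs$summary), 2L)
  expect_lt(max(rs$summary$rmse_rel), 1e-4)
  expect_equal(rs$n_failed, 0L)
  expect_length(unique(rs$per_replicate$replicate), 2L)
})
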