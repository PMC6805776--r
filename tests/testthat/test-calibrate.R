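test_that("observables start at the normalized reference and sum correctly", {
  eq <- consistent_fixture()
  tr <- hif_simulate(eq$params, hif_protocol(horizon = 10),
                     times = seq(0, 10, by = 1), y0 = eq$state)
  o <- hif_observe(tr, 0)
  expect_equal(unname(o[1, ]), c(1, 1, 1), tolerance = 1e-6)
  expect_equal(tr$observables$TOTAL_HIF,
               tr$states[, 4] + tr$states[, 6] + tr$states[, 10])
  expect_error(hif_observe(tr, 11), "span")
})

test_that("interpolated observables match a re-integration at the query", {
  eq <- consistent_fixture()
  proto <- protocol_standard(il15_at = 0, dmog_at = 0, horizon = 30)
  grid <- seq(0, 30, by = 0.25)
  tr <- hif_simulate(eq$params, proto, grid, y0 = eq$state)
  q <- c(3.1, 10.6, 21.3)
  o <- hif_observe(tr, q)
  trf <- hif_simulate(eq$params, proto, sort(unique(c(grid, q))),
                      y0 = eq$state)
  of <- as.matrix(trf$observables[match(q, trf$times), -1])
  expect_lt(max(abs(o - of) / pmax(abs(of), 1e-8)), 1e-5)
})

test_that("the objective obeys its arithmetic contracts", {
  eq <- consistent_fixture()
  # noise-free data generated at the evaluation parameters: objective ~ 0
  proto <- protocol_standard(il15_at = 0, horizon = 30)
  pts <- data.frame(time_h = c(2, 6, 12), observable = "TOTAL_HIF")
  ds <- generate_dataset(proto, eq$params, pts, sds = 0.1, noise_sd = 0,
                         y0 = eq$state)
  cfg <- pep_config(free = c("d1", "k6"), use_prior = FALSE)
  o <- hif_objective(eq$params, ds, cfg)
  expect_lt(o$value, 1e-8)
  expect_identical(o$prior, 0)
  # doubling every sd divides the data term by 4
  ds_noisy <- ds
  ds_noisy$points$value <- ds$points$value + 0.2
  o1 <- hif_objective(eq$params, ds_noisy, cfg)
  ds2 <- ds_noisy
  ds2$points$sd <- 2 * ds2$points$sd
  o2 <- hif_objective(eq$params, ds2, cfg)
  expect_equal(o2$data, o1$data / 4, tolerance = 1e-10)
  # residual vector bookkeeping: data rows then one prior row per free
  cfg_p <- pep_config(free = c("d1", "k6"))
  expect_length(hif_objective(eq$params, ds, cfg_p)$residuals, 3 + 2)
})

test_that("a single hand-computed residual matches", {
  # null system: trajectory constant, total HIF-1alpha stays 1
  p <- zero_parameters()
  proto <- hif_protocol(horizon = 10)
  ds <- hif_dataset(proto, data.frame(time_h = 5, observable = "TOTAL_HIF",
                                      value = 1.3, sd = 0.2))
  cfg <- pep_config(free = "d1", use_prior = FALSE,
                    init_state = "canonical")
  o <- hif_objective(p, ds, cfg)
  expect_equal(o$residuals[[1]], (1.3 - 1) / 0.2, tolerance = 1e-12)
  expect_equal(o$value, 0.5 * 1.5^2, tolerance = 1e-12)
})

test_that("a fit started at the truth stays there", {
  eq <- consistent_fixture()
  d <- synth_design(eq$params, seed = 21, noise_sd = 0)
  s <- generate_calibration_suite(d)
  free <- c("d1", "k6", "k9")
  fit <- hif_fit(s$calibration[1:2], eq$params, pep_config(free = free))
  expect_lte(fit$iterations, 2)
  expect_equal(unname(fit$estimates), unname(eq$params$values[free]),
               tolerance = 1e-6)
})

test_that("accepted Gauss-Newton steps decrease the objective monotonically", {
  eq <- consistent_fixture()
  s <- suite_fixture()
  free <- c("d1", "k6", "k9")
  start <- set_parameters(eq$params, eq$params$values[free] * 1.3)
  fit <- hif_fit(s$calibration[c("il15", "dmog")], start,
                 pep_config(free = free))
  expect_true(all(diff(fit$history) < 0))
  expect_true(fit$converged)
  expect_true(all(fit$sd >= 0))
})

test_that("reported standard deviations ignore dataset ordering", {
  eq <- consistent_fixture()
  s <- suite_fixture()
  free <- c("d1", "k6")
  cfg <- pep_config(free = free)
  f1 <- hif_fit(s$calibration[c("il15", "dmog")], eq$params, cfg)
  f2 <- hif_fit(s$calibration[c("dmog", "il15")], eq$params, cfg)
  expect_equal(f1$sd, f2$sd, tolerance = 1e-4)
})

test_that("an uninformative free parameter without priors is flagged", {
  eq <- consistent_fixture()
  s <- suite_fixture()
  # no rapamycin in these two experiments: rho_rapa has a zero column
  expect_error(
    hif_fit(s$calibration[c("il15", "dmog")], eq$params,
            pep_config(free = c("d1", "rho_rapa"), use_prior = FALSE)),
    "identifiab")
})

test_that("multiple shooting agrees with single shooting", {
  eq <- consistent_fixture()
  s <- suite_fixture()
  free <- c("d1", "k6", "k9")
  start <- set_parameters(eq$params, eq$params$values[free] * 1.3)
  two <- s$calibration[c("il15", "dmog")]
  fs <- hif_fit(two, start, pep_config(free = free, shooting = "single"))
  fm <- hif_fit(two, start, pep_config(free = free, shooting = "multiple"))
  expect_lt(abs(fm$objective - fs$objective) / fs$objective, 1e-4)
  expect_lt(fm$constraint_norm, 1e-6)
  expect_equal(fm$estimates, fs$estimates, tolerance = 1e-3)
})

test_that("fit methods expose estimates, covariance and predictions", {
  eq <- consistent_fixture()
  s <- suite_fixture()
  fit <- hif_fit(s$calibration[["il15"]], eq$params,
                 pep_config(free = c("d1", "k6")))
  expect_named(coef(fit), c("d1", "k6"))
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  expect_length(residuals(fit), nrow(s$calibration[["il15"]]$points))
  pr <- predict(fit)
  expect_s3_class(pr[[1]], "hif_trajectory")
  expect_output(print(fit), "Gauss-Newton")
  expect_output(print(summary(fit)), "estimate")
})

test_that("dataset CSV files round-trip with their protocols", {
  s <- suite_fixture()
  f <- tempfile(fileext = ".csv")
  write_datasets(s$calibration, f)
  protos <- lapply(s$calibration, function(d) d$protocol)
  back <- read_datasets(f, protos)
  expect_setequal(names(back), names(s$calibration))
  expect_equal(back[["il15"]]$points$value,
               s$calibration[["il15"]]$points$value, tolerance = 1e-10)
  unlink(f)
})
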