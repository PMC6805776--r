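# Synthetic measurement generator.
#
# The calibration data of the original study (four perturbation experiments
# totalling 39 points, plus one held-out validation experiment) are not
# publicly deposited, so the package generates measurements with exactly
# the statistical structure the estimator assumes: normalized observables
# evaluated on the true trajectory plus independent additive zero-mean
# Gaussian noise with known per-point standard deviation.  Negative noisy
# values are kept — normalized densitometry ratios can dip below zero.

#' Synthetic study design
#'
#' The default design emulates the study layout: ground truth is the
#' steady-state-consistent published parameterization; the four calibration
#' experiments are (i) IL-15, (ii) DMOG, (iii) IL-15 + DMOG + rapamycin,
#' (iv) IL-15 + DMOG + S3I-201, and the validation experiment is
#' IL-15 + DMOG.  Measurements lie in the 0--27 h observation window:
#' per experiment total HIF-1alpha at 2, 4, 6, 8, 12 and 27 h and STAT3 and
#' AKT at 1 and 6 h — 40 points, with one AKT point dropped from experiment
#' (iv) to reach the 39 calibration points of the study.  Noise sd is 0.1
#' on the normalized scale for every observable (the order of the error
#' bars on the original blots), configurable per observable.
#'
#' @param params_true ground-truth `hif_parameters`; default the
#'   steady-state-consistent published set.
#' @param sd per-observable noise standard deviation: single number or
#'   named vector over `TOTAL_HIF`, `STAT3`, `AKT`.
#' @param seed integer seed used by [generate_calibration_suite()].
#' @param noise_sd optional noise scale distinct from the recorded
#'   weighting sd (0 gives noise-free data with realistic weights).
#' @return an object of class `hif_synth_design`: list with `params_true`,
#'   `y0` (consistent equilibrium), `experiments` (named list of protocol +
#'   measurement-layout pairs), `sd`, `noise_sd`, `seed`.
#' @export
synth_design <- function(params_true = NULL, sd = 0.1, seed = 1,
                         noise_sd = NULL) {
  if (is.null(params_true)) {
    eq <- solve_consistent_equilibrium()
    params_true <- eq$params
    y0 <- eq$state
  } else {
    y0 <- equilibrium_state(params_true)
  }
  if (length(sd) == 1) sd <- stats::setNames(rep(sd, 3), .observables)
  stopifnot(all(.observables %in% names(sd)), all(sd >= 0))
  layout <- function(drop_akt6 = FALSE) {
    pts <- rbind(
      data.frame(time_h = c(2, 4, 6, 8, 12, 27), observable = "TOTAL_HIF"),
      data.frame(time_h = c(1, 6), observable = "STAT3"),
      data.frame(time_h = c(1, 6), observable = "AKT"))
    if (drop_akt6)
      pts <- pts[!(pts$observable == "AKT" & pts$time_h == 6), ]
    pts
  }
  h <- 30
  experiments <- list(
    il15 = list(protocol = protocol_standard(il15_at = 0, horizon = h),
                layout = layout(), role = "calibration"),
    dmog = list(protocol = protocol_standard(dmog_at = 0, horizon = h),
                layout = layout(), role = "calibration"),
    il15_dmog_rapa = list(
      protocol = protocol_standard(il15_at = 0, dmog_at = 0,
                                   rapamycin_at = 0, horizon = h),
      layout = layout(), role = "calibration"),
    il15_dmog_s3i = list(
      protocol = protocol_standard(il15_at = 0, dmog_at = 0, s3i_at = 0,
                                   horizon = h),
      layout = layout(drop_akt6 = TRUE), role = "calibration"),
    il15_dmog_validation = list(
      protocol = protocol_standard(il15_at = 0, dmog_at = 0, horizon = h),
      layout = rbind(
        data.frame(time_h = c(1, 2, 4, 6, 8, 12, 24, 27),
                   observable = "TOTAL_HIF"),
        data.frame(time_h = c(1, 6, 12), observable = "STAT3"),
        data.frame(time_h = c(1, 6, 12), observable = "AKT")),
      role = "validation"))
  if (!is.null(noise_sd) && length(noise_sd) == 1)
    noise_sd <- stats::setNames(rep(noise_sd, 3), .observables)
  structure(list(params_true = params_true, y0 = y0,
                 experiments = experiments, sd = sd, noise_sd = noise_sd,
                 seed = seed),
            class = "hif_synth_design")
}

#' @export
print.hif_synth_design <- function(x, ...) {
  npts <- vapply(x$experiments, function(e) nrow(e$layout), integer(1))
  roles <- vapply(x$experiments, function(e) e$role, character(1))
  cat("Synthetic study design (seed ", x$seed, "):\n", sep = "")
  for (nm in names(x$experiments))
    cat("  ", nm, ": ", npts[[nm]], " points (", roles[[nm]], ")\n",
        sep = "")
  cat("  calibration points total:", sum(npts[roles == "calibration"]),
      "\n")
  invisible(x)
}

#' Generate one noisy dataset
#'
#' Simulates the true trajectory under `protocol`, evaluates the
#' observables at the measurement times and adds independent zero-mean
#' Gaussian noise with the given standard deviations.  Values are not
#' clipped.
#'
#' @param protocol a `hif_protocol`.
#' @param params_true ground-truth `hif_parameters`.
#' @param points data frame with columns `time_h`, `observable`.
#' @param sds numeric: one sd per point, or a named per-observable vector.
#'   Used both as the noise scale and as the recorded weighting sd, unless
#'   `noise_sd` separates the two.
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @param y0 initial state (default: untreated equilibrium of
#'   `params_true`).
#' @param label dataset label.
#' @param noise_sd optional noise scale overriding `sds` (set 0 for
#'   noise-free data that keep realistic weights).
#' @return a `hif_dataset`.
#' @export
generate_dataset <- function(protocol, params_true, points, sds = 0.1,
                             seed = NULL, y0 = NULL, label = "synthetic",
                             noise_sd = NULL) {
  if (is.null(y0)) y0 <- equilibrium_state(params_true)
  expand <- function(s) {
    if (!is.null(names(s))) unname(s[points$observable])
    else if (length(s) == 1) rep(s, nrow(points))
    else s
  }
  sds <- expand(sds)
  noise_sd <- if (is.null(noise_sd)) sds else expand(noise_sd)
  stopifnot(length(sds) == nrow(points), all(sds >= 0),
            length(noise_sd) == nrow(points), all(noise_sd >= 0))
  tms <- sort(unique(c(0, points$time_h)))
  res <- integrate_segments(params_true, y0, protocol, times = tms)
  obs <- cbind(TOTAL_HIF = total_hif(res$states),
               STAT3 = res$states[, 8], AKT = res$states[, 2])
  g <- obs[cbind(match(points$time_h, res$times),
                 match(points$observable, .observables))]
  if (!is.null(seed)) set.seed(seed)
  noise <- stats::rnorm(nrow(points), 0, 1) * noise_sd
  hif_dataset(protocol,
              data.frame(time_h = points$time_h,
                         observable = points$observable,
                         value = g + noise, sd = pmax(sds, 1e-8)),
              label = label)
}

#' Generate the calibration suite
#'
#' Emits the four calibration datasets (39 points by default) and the
#' held-out validation dataset of the design, with reproducible
#' per-experiment noise derived from the design seed.
#'
#' @param design a [synth_design()].
#' @return list with `calibration` (named list of 4 `hif_dataset`s),
#'   `validation` (one `hif_dataset`), and `design`.
#' @export
generate_calibration_suite <- function(design = synth_design()) {
  stopifnot(inherits(design, "hif_synth_design"))
  set.seed(design$seed)
  subseeds <- sample.int(.Machine$integer.max %/% 2,
                         length(design$experiments))
  out <- mapply(function(e, s, nm) {
    generate_dataset(e$protocol, design$params_true, e$layout,
                     sds = design$sd, seed = s, y0 = design$y0, label = nm,
                     noise_sd = design$noise_sd)
  }, design$experiments, subseeds, names(design$experiments),
  SIMPLIFY = FALSE)
  roles <- vapply(design$experiments, function(e) e$role, character(1))
  list(calibration = out[roles == "calibration"],
       validation = out[[which(roles == "validation")]],
       design = design)
}

#' Parameter-recovery study
#'
#' For each replicate: generate a fresh noisy calibration suite, perturb
#' the starting parameters, fit, and record estimates, reported standard
#' deviations and whether the truth lies inside the `+/- 2 sd` interval.
#'
#' @param design a [synth_design()].
#' @param free character vector of free parameter names (default: the full
#'   published free set).
#' @param n_replicates number of replicates.
#' @param seed integer master seed (controls noise and start perturbation).
#' @param start_factor multiplicative perturbation of the start values
#'   (applied to every free parameter; efficacies are clipped into
#'   `[0, 1]`).
#' @param config optional [pep_config()] template (its `free` is replaced).
#' @return an object of class `hif_recovery`: list with `per_replicate`
#'   (data frame of estimates/sd/coverage), `summary` (per-parameter bias,
#'   relative RMSE and coverage), `n_failed`, `truth`.
#' @export
recovery_study <- function(design = synth_design(), free = NULL,
                           n_replicates = 20, seed = 1,
                           start_factor = 1.5, config = NULL) {
  stopifnot(n_replicates >= 1)
  params_true <- design$params_true
  if (is.null(free)) free <- free_parameters(params_true)
  if (is.null(config)) config <- pep_config()
  config$free <- free
  truth <- params_true$values[free]
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max %/% 2, n_replicates)
  rows <- list(); failures <- 0
  for (r in seq_len(n_replicates)) {
    d <- design; d$seed <- rep_seeds[[r]]
    suite <- generate_calibration_suite(d)
    start <- truth * start_factor
    eff <- is_efficacy(free)
    start[eff] <- pmin(pmax(truth[eff] * start_factor, 0.01), 0.99)
    p_start <- set_parameters(params_true, start)
    fit <- tryCatch(hif_fit(suite$calibration, p_start, config),
                    error = function(e) e)
    if (inherits(fit, "error")) { failures <- failures + 1; next }
    rows[[length(rows) + 1]] <- data.frame(
      replicate = r, parameter = free,
      truth = unname(truth),
      estimate = unname(fit$estimates),
      sd = unname(fit$sd),
      covered = abs(fit$estimates - truth) <= 2 * fit$sd,
      row.names = NULL)
  }
  if (failures > n_replicates / 2)
    stop("more than half of the recovery fits failed (", failures, "/",
         n_replicates, ")")
  per <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per, per$parameter), function(d) {
    data.frame(parameter = d$parameter[[1]], truth = d$truth[[1]],
               bias = mean(d$estimate - d$truth),
               rmse_rel = sqrt(mean((d$estimate / d$truth - 1)^2)),
               coverage = mean(d$covered), row.names = NULL)
  }))
  summ <- summ[match(free, summ$parameter), ]
  rownames(summ) <- NULL
  structure(list(per_replicate = per, summary = summ,
                 n_failed = failures, truth = truth, seed = seed),
            class = "hif_recovery")
}

#' @export
print.hif_recovery <- function(x, ...) {
  cat("Parameter-recovery study:",
      length(unique(x$per_replicate$replicate)), "successful replicates,",
      x$n_failed, "failed\n")
  print(transform(x$summary, bias = signif(bias, 3),
                  rmse_rel = signif(rmse_rel, 3)))
  invisible(x)
}
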