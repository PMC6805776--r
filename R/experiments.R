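# The in-silico experiment battery: external-regulation sweeps, DMOG
# dose-response, treatment-timing comparisons and Monte Carlo robustness.

# condition protocols used throughout the battery
condition_protocol <- function(condition = c("normoxia", "dmog"),
                               horizon = 100, dmog_dose = 1) {
  condition <- match.arg(condition)
  if (condition == "dmog")
    protocol_standard(dmog_at = 0, dmog_dose = dmog_dose, horizon = horizon)
  else hif_protocol(horizon = horizon)
}

#' Steady-state sweep over external-regulation parameters
#'
#' Varies one or two parameters (typically the basal/external activation
#' rates `a1`, `a3`, `a7`, `a8`) over grids and records the 100 h
#' steady-state levels of total HIF-1alpha, STAT3, mTOR and NF-kB under a
#' constant condition.  The swept parameter *is* the perturbation: the
#' initial state stays at the reference equilibrium of `params` and is not
#' re-solved per grid point.
#'
#' @param params a `hif_parameters` object (use the steady-state-consistent
#'   set from [solve_consistent_equilibrium()] for a flat baseline).
#' @param names character vector of one or two parameter names.
#' @param grids list of numeric grids, one per name (a single numeric
#'   vector is accepted for 1-D sweeps).
#' @param condition `"normoxia"` or `"dmog"` (DMOG dose 1 from `t = 0`).
#' @param y0 initial state (default: untreated equilibrium of `params`).
#' @return an object of class `hif_sweep`: data frame with one row per grid
#'   point, the swept values, and columns `TOTAL_HIF`, `STAT3`, `MTOR`,
#'   `NFKB`, `converged`; failed grid points carry `NA` and the reason in
#'   `attr(, "failures")`.
#' @export
parameter_sweep <- function(params, names, grids,
                            condition = c("normoxia", "dmog"), y0 = NULL) {
  condition <- match.arg(condition)
  if (is.numeric(grids)) grids <- list(grids)
  stopifnot(length(names) == length(grids),
            length(names) %in% c(1L, 2L))
  bad <- setdiff(names, base::names(params$values))
  if (length(bad)) stop("unknown parameter(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(y0)) y0 <- equilibrium_state(params)
  pts <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  base::names(pts) <- names
  proto <- condition_protocol(condition)
  res <- data.frame(pts, TOTAL_HIF = NA_real_, STAT3 = NA_real_,
                    MTOR = NA_real_, NFKB = NA_real_, converged = NA)
  failures <- character(0)
  for (i in seq_len(nrow(pts))) {
    p_i <- set_parameters(params, stats::setNames(as.numeric(pts[i, ]),
                                                  names))
    ss <- tryCatch(steady_state_value(p_i, proto, y0 = y0),
                   error = function(e) e)
    if (inherits(ss, "error")) {
      failures <- c(failures, paste0("grid point ", i, ": ",
                                     conditionMessage(ss)))
      next
    }
    res$TOTAL_HIF[i] <- ss$total_hif
    res$STAT3[i] <- ss$state[[8]]
    res$MTOR[i] <- ss$state[[3]]
    res$NFKB[i] <- ss$state[[7]]
    res$converged[i] <- ss$converged
  }
  structure(res, condition = condition, failures = failures,
            class = c("hif_sweep", "data.frame"))
}

#' DMOG dose-response of steady-state total HIF-1alpha
#'
#' For each DMOG dose fraction (1 corresponds to 20 uM) the 100 h
#' steady-state total HIF-1alpha is computed and normalized to the dose-0
#' value.  Cells are IL-15 primed at `t = 0` by default.
#'
#' @param params a `hif_parameters` object.
#' @param doses numeric vector of dose fractions in `[0, 1]`.
#' @param il15_priming logical; apply an IL-15 impulse of 1 at `t = 0`.
#' @param y0 initial state (default: untreated equilibrium).
#' @return data frame with columns `dose`, `total_hif`, `fold_change`.
#' @export
dose_response <- function(params, doses = seq(0, 1, by = 0.1),
                          il15_priming = TRUE, y0 = NULL) {
  stopifnot(all(doses >= 0 & doses <= 1))
  if (is.null(y0)) y0 <- equilibrium_state(params)
  run <- function(dose) {
    proto <- protocol_standard(
      il15_at = if (il15_priming) 0 else NA,
      dmog_at = 0, dmog_dose = dose, horizon = 100)
    steady_state_value(params, proto, y0 = y0)$total_hif
  }
  ref <- run(0)
  vals <- vapply(doses, run, numeric(1))
  data.frame(dose = doses, total_hif = vals, fold_change = vals / ref)
}

#' The nine treatment-timing protocols
#'
#' Protocol library for the treatment-timing comparison over 30 h:
#' untreated; IL-15 at 0; DMOG throughout; DMOG throughout + IL-15 at 0;
#' IL-15 at 6 h; DMOG from 6 h; IL-15 and DMOG at 6 h; DMOG from 0 +
#' IL-15 at 6 h; IL-15 at 0 + DMOG from 6 h.
#'
#' @param horizon protocol length in hours (at least 30).
#' @return named list of `hif_protocol` objects.
#' @export
timing_protocols <- function(horizon = 30) {
  stopifnot(horizon >= 30)
  list(
    untreated       = hif_protocol(horizon = horizon),
    il15_0          = protocol_standard(il15_at = 0, horizon = horizon),
    dmog_0          = protocol_standard(dmog_at = 0, horizon = horizon),
    il15_0_dmog_0   = protocol_standard(il15_at = 0, dmog_at = 0,
                                        horizon = horizon),
    il15_6          = protocol_standard(il15_at = 6, horizon = horizon),
    dmog_6          = protocol_standard(dmog_at = 6, horizon = horizon),
    il15_6_dmog_6   = protocol_standard(il15_at = 6, dmog_at = 6,
                                        horizon = horizon),
    dmog_0_il15_6   = protocol_standard(il15_at = 6, dmog_at = 0,
                                        horizon = horizon),
    il15_0_dmog_6   = protocol_standard(il15_at = 0, dmog_at = 6,
                                        horizon = horizon))
}

#' Treatment-timing experiment
#'
#' Runs each protocol of the timing library and reports total HIF-1alpha at
#' `t = 12` h normalized to the untreated value at the same time.
#'
#' @param params a `hif_parameters` object.
#' @param protocols named list of protocols (default [timing_protocols()]);
#'   each must span at least 30 h.
#' @param at readout time in hours (default 12).
#' @param y0 initial state (default: untreated equilibrium).
#' @return data frame with columns `protocol`, `total_hif`, `fold_change`,
#'   ordered as given.
#' @export
timing_experiment <- function(params, protocols = timing_protocols(),
                              at = 12, y0 = NULL) {
  stopifnot(all(vapply(protocols, function(p) p$horizon, numeric(1)) >= 30))
  if (is.null(y0)) y0 <- equilibrium_state(params)
  vals <- vapply(protocols, function(proto) {
    tr <- hif_simulate(params, proto, times = c(0, at), y0 = y0)
    tr$observables$TOTAL_HIF[[length(tr$times)]]
  }, numeric(1))
  ref <- if ("untreated" %in% names(protocols)) vals[["untreated"]] else {
    tr <- hif_simulate(params, hif_protocol(horizon = 30),
                       times = c(0, at), y0 = y0)
    tr$observables$TOTAL_HIF[[length(tr$times)]]
  }
  data.frame(protocol = names(protocols), total_hif = unname(vals),
             fold_change = unname(vals) / ref)
}

#' Monte Carlo robustness of steady-state total HIF-1alpha
#'
#' Perturbs one element of the system uniformly within `+/- width` of its
#' reference value and measures the spread of 100 h steady-state total
#' HIF-1alpha under the baseline condition of IL-15 stimulation (impulse 1
#' at `t = 0`) plus DMOG (dose 1 from `t = 0`).  `"IL15"` perturbs the
#' initial IL-15 load (extrinsic noise); `"a2"`/`"a3"` perturb the AKT /
#' mTOR basal activation rate (intrinsic noise).
#'
#' @param params a `hif_parameters` object.
#' @param element `"IL15"`, `"a2"` or `"a3"`.
#' @param width half-width of the uniform perturbation as a fraction of the
#'   reference value (default 0.25).
#' @param n number of Monte Carlo samples (default 1000).
#' @param seed integer seed for the sampler.
#' @param y0 initial state (default: untreated equilibrium of `params`).
#' @return an object of class `hif_robustness`: list with `element`,
#'   `width`, `n`, `seed`, `baseline`, `samples` (steady-state total
#'   HIF-1alpha per draw), `relative_spread` (`max |sample - baseline| /
#'   baseline`) and `band` (2.5--97.5 percentiles).
#' @export
monte_carlo_robustness <- function(params, element = c("IL15", "a2", "a3"),
                                   width = 0.25, n = 1000, seed = 1,
                                   y0 = NULL) {
  element <- match.arg(element)
  stopifnot(width >= 0, n >= 1)
  if (is.null(y0)) y0 <- equilibrium_state(params)
  proto <- protocol_standard(dmog_at = 0, horizon = 100)  # DMOG only; IL-15
  y0_base <- y0                                           # enters via y1
  run <- function(il15, p) {
    y <- y0_base; y[1] <- y[1] + il15
    steady_state_value(p, proto, y0 = y)$total_hif
  }
  base_val <- if (element == "IL15") 1 else params$values[[element]]
  baseline <- run(1, params)
  set.seed(seed)
  draws <- stats::runif(n, base_val * (1 - width), base_val * (1 + width))
  samples <- vapply(draws, function(d) {
    if (element == "IL15") run(d, params)
    else run(1, set_parameters(params, stats::setNames(d, element)))
  }, numeric(1))
  spread <- if (baseline == 0) 0 else max(abs(samples - baseline)) / baseline
  structure(list(element = element, width = width, n = n, seed = seed,
                 baseline = baseline, samples = samples,
                 relative_spread = spread,
                 band = stats::quantile(samples, c(0.025, 0.975))),
            class = "hif_robustness")
}

#' @export
print.hif_robustness <- function(x, ...) {
  cat("Monte Carlo robustness:", x$element, "+/-",
      100 * x$width, "% x", x$n, "samples (seed", paste0(x$seed, ")\n"))
  cat("  baseline steady-state total HIF-1a:", signif(x$baseline, 5), "\n")
  cat("  relative spread:", signif(100 * x$relative_spread, 3), "%\n")
  cat("  2.5-97.5% band: [", signif(x$band[[1]], 5), ",",
      signif(x$band[[2]], 5), "]\n")
  invisible(x)
}
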