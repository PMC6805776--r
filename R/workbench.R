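# Scenario presets and input validation: every in-silico experiment of the
# study is reproducible from one call, with tidy CSV results plus a JSON
# metadata sidecar (seed, tolerances, protocol) for bit-reproducible
# reruns.

.scenarios <- c("fit", "validate", "figure4_5", "figure6", "figure7",
                "figure8", "figure9", "figure10", "figure11", "figure12",
                "recovery")

write_meta <- function(out_dir, scenario, seed, extra = list()) {
  meta <- c(list(scenario = scenario, seed = seed,
                 package_version = as.character(
                   utils::packageVersion("hifnk")),
                 rtol = 1e-8, atol = 1e-10), extra)
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run a preset scenario
#'
#' Dispatches to the simulation/calibration machinery with the presets of
#' the study's in-silico experiments and writes tidy CSV results plus a
#' `metadata.json` sidecar into `out_dir`.  Scenarios:
#'
#' * `fit` — calibrate the full free set on a synthetic suite.
#' * `validate` — fitted-model prediction vs the held-out validation
#'   dataset.
#' * `figure4_5` — trajectories of all states under the single- and
#'   double-inhibitor settings, normoxia and DMOG.
#' * `figure6` — IL-15 external-regulation sweep (`a1` from 0 to 10).
#' * `figure7` — mTOR (`a3`) and STAT3 (`a8`) sweeps.
#' * `figure8` — 2-D sweeps `a3` x `a8` and `a7` x `a8`.
#' * `figure9` — 2-D sweep `a1` x `a8`.
#' * `figure10` — Monte Carlo robustness for IL-15, `a2`, `a3`
#'   (n = 1000 each).
#' * `figure11` — DMOG dose-response, doses 0 to 100 percent of 20 uM.
#' * `figure12` — the nine treatment-timing protocols, 12 h fold changes.
#' * `recovery` — parameter-recovery study on a 5-parameter subset.
#'
#' @param scenario one of the scenario ids above.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for every stochastic step.
#' @param params a `hif_parameters`; default the steady-state-consistent
#'   published set.
#' @param n_grid grid resolution for sweep scenarios.
#' @return invisibly, the list of result objects; side effect: CSV/JSON
#'   files in `out_dir`.
#' @export
run_scenario <- function(scenario, out_dir = tempfile("hifnk_"), seed = 1,
                         params = NULL, n_grid = 11) {
  scenario <- match.arg(scenario, .scenarios)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(params)) {
    eq <- solve_consistent_equilibrium()
    params <- eq$params
    y0 <- eq$state
  } else y0 <- equilibrium_state(params)
  put <- function(df, name)
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  res <- switch(
    scenario,
    fit = {
      suite <- generate_calibration_suite(synth_design(params, seed = seed))
      fit <- hif_fit(suite$calibration, params)
      put(data.frame(parameter = names(fit$estimates),
                     estimate = unname(fit$estimates),
                     sd = unname(fit$sd)), "estimates")
      jsonlite::write_json(
        list(objective = fit$objective, data_term = fit$data_term,
             prior_term = fit$prior_term, converged = fit$converged,
             iterations = fit$iterations),
        file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
      fit
    },
    validate = {
      suite <- generate_calibration_suite(synth_design(params, seed = seed))
      fit <- hif_fit(suite$calibration, params)
      v <- suite$validation
      tr <- predict(fit, protocol = v$protocol,
                    times = sort(unique(c(0, v$points$time_h))))
      g <- hif_observe(tr, v$points$time_h)
      pred <- g[cbind(seq_len(nrow(v$points)),
                      match(v$points$observable, .observables))]
      out <- cbind(v$points, predicted = pred)
      put(out, "validation")
      out
    },
    figure4_5 = {
      inhib <- list(none = protocol_standard(il15_at = 0),
                    s3i = protocol_standard(il15_at = 0, s3i_at = 0),
                    rapa = protocol_standard(il15_at = 0, rapamycin_at = 0),
                    nfkbi = protocol_standard(il15_at = 0, nfkbi_at = 0),
                    s3i_rapa = protocol_standard(il15_at = 0, s3i_at = 0,
                                                 rapamycin_at = 0),
                    nfkbi_rapa = protocol_standard(il15_at = 0,
                                                   nfkbi_at = 0,
                                                   rapamycin_at = 0),
                    nfkbi_s3i = protocol_standard(il15_at = 0, nfkbi_at = 0,
                                                  s3i_at = 0))
      rows <- list()
      for (cond in c("normoxia", "dmog")) for (nm in names(inhib)) {
        proto <- inhib[[nm]]
        if (cond == "dmog")
          proto$events <- rbind(proto$events,
                                data.frame(time_h = 0, agent = "DMOG",
                                           dose_fraction = 1))
        proto <- hif_protocol(proto$events, proto$horizon)
        tr <- hif_simulate(params, proto,
                           times = seq(0, 30, length.out = 121), y0 = y0)
        long <- as.data.frame(tr)
        long$condition <- cond; long$setting <- nm
        rows[[length(rows) + 1]] <- long
      }
      out <- do.call(rbind, rows)
      put(out, "trajectories")
      out
    },
    figure6 = {
      grid <- seq(0, 10, length.out = n_grid)
      out <- rbind(
        cbind(condition = "normoxia",
              parameter_sweep(params, "a1", grid, "normoxia", y0 = y0)),
        cbind(condition = "dmog",
              parameter_sweep(params, "a1", grid, "dmog", y0 = y0)))
      put(out, "sweep_a1")
      out
    },
    figure7 = {
      grid <- seq(0, 10, length.out = n_grid)
      out <- do.call(rbind, lapply(c("a3", "a8"), function(pn)
        do.call(rbind, lapply(c("normoxia", "dmog"), function(cond) {
          sw <- parameter_sweep(params, pn, grid, cond, y0 = y0)
          names(sw)[names(sw) == pn] <- "value"
          cbind(parameter = pn, condition = cond, as.data.frame(sw))
        }))))
      put(out, "sweep_a3_a8")
      out
    },
    figure8 = {
      g <- seq(0, 10, length.out = n_grid)
      out <- do.call(rbind, lapply(
        list(c("a3", "a8"), c("a7", "a8")), function(pair)
          do.call(rbind, lapply(c("normoxia", "dmog"), function(cond) {
            sw <- parameter_sweep(params, pair, list(g, g), cond, y0 = y0)
            data.frame(pair = paste(pair, collapse = "x"),
                       condition = cond, x = sw[[1]], y = sw[[2]],
                       sw[c("TOTAL_HIF", "STAT3", "MTOR", "NFKB")])
          }))))
      put(out, "sweep_2d")
      out
    },
    figure9 = {
      g1 <- seq(0, 5, length.out = n_grid)
      g8 <- seq(0, 10, length.out = n_grid)
      out <- do.call(rbind, lapply(c("normoxia", "dmog"), function(cond) {
        sw <- parameter_sweep(params, c("a1", "a8"), list(g1, g8), cond,
                              y0 = y0)
        data.frame(condition = cond, a1 = sw$a1, a8 = sw$a8,
                   sw[c("TOTAL_HIF", "STAT3")])
      }))
      put(out, "sweep_a1_a8")
      out
    },
    figure10 = {
      out <- lapply(c("IL15", "a2", "a3"), function(el)
        monte_carlo_robustness(params, el, width = 0.25, n = 1000,
                               seed = seed, y0 = y0))
      names(out) <- c("IL15", "a2", "a3")
      put(do.call(rbind, lapply(out, function(r)
        data.frame(element = r$element, n = r$n, width = r$width,
                   baseline = r$baseline,
                   relative_spread = r$relative_spread,
                   band_lo = r$band[[1]], band_hi = r$band[[2]]))),
        "robustness")
      put(do.call(rbind, lapply(out, function(r)
        data.frame(element = r$element, sample = seq_len(r$n),
                   total_hif = r$samples))), "robustness_samples")
      out
    },
    figure11 = {
      out <- dose_response(params, doses = seq(0, 1, length.out = n_grid),
                           y0 = y0)
      put(out, "dose_response")
      out
    },
    figure12 = {
      out <- timing_experiment(params, y0 = y0)
      put(out, "timing")
      out
    },
    recovery = {
      out <- recovery_study(synth_design(params, seed = seed),
                            free = c("d1", "k6", "k9", "k3", "kalpha"),
                            n_replicates = 20, seed = seed)
      put(out$summary, "recovery_summary")
      put(out$per_replicate, "recovery_replicates")
      out
    })
  write_meta(out_dir, scenario, seed)
  invisible(res)
}

#' Validate input files
#'
#' Schema and invariant checks for parameter, protocol and dataset files:
#' non-negativity of rates, efficacy ranges, positive measurement sds,
#' event times inside the horizon.  Diagnostics carry row numbers.
#'
#' @param parameter_file,protocol_file,dataset_file file paths (`NULL`
#'   skips a check).
#' @param protocols named list of protocols needed to resolve a dataset
#'   file (defaults to an unbounded untreated protocol per experiment).
#' @return list with `valid` (logical) and `issues` (character vector).
#' @export
validate_inputs <- function(parameter_file = NULL, protocol_file = NULL,
                            dataset_file = NULL, protocols = NULL) {
  issues <- character(0)
  note <- function(...) issues <<- c(issues, paste0(...))
  if (!is.null(parameter_file)) {
    p <- tryCatch(read_parameters(parameter_file), error = function(e) e)
    if (inherits(p, "error")) note("parameters: ", conditionMessage(p))
    else tryCatch(validate_parameters(p),
                  error = function(e) note("parameters: ",
                                           conditionMessage(e)))
  }
  if (!is.null(protocol_file)) {
    pr <- tryCatch(read_protocol(protocol_file), error = function(e) e)
    if (inherits(pr, "error")) note("protocol: ", conditionMessage(pr))
  }
  if (!is.null(dataset_file)) {
    tab <- tryCatch(utils::read.csv(dataset_file), error = function(e) e)
    if (inherits(tab, "error")) {
      note("dataset: ", conditionMessage(tab))
    } else {
      need <- c("experiment", "label", "time_h", "observable", "value",
                "sd")
      miss <- setdiff(need, names(tab))
      if (length(miss)) {
        note("dataset: missing column(s) ", paste(miss, collapse = ", "))
      } else {
        for (i in seq_len(nrow(tab))) {
          if (!is.finite(tab$sd[i]) || tab$sd[i] <= 0)
            note("dataset row ", i, ": sd must be > 0")
          if (!tab$observable[i] %in% .observables)
            note("dataset row ", i, ": unknown observable '",
                 tab$observable[i], "'")
          if (!is.finite(tab$value[i]))
            note("dataset row ", i, ": non-finite value")
          if (!is.finite(tab$time_h[i]) || tab$time_h[i] < 0)
            note("dataset row ", i, ": invalid time")
        }
        if (!is.null(protocols)) {
          ds <- tryCatch(read_datasets(dataset_file, protocols),
                         error = function(e) note("dataset: ",
                                                  conditionMessage(e)))
        }
      }
    }
  }
  list(valid = length(issues) == 0, issues = issues)
}
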