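# Numerical integration of the network under treatment protocols.
#
# Events are handled by restarting the integrator: the protocol partitions
# [0, t_end] into segments on which the treatment scale factors are
# constant; IL-15 events add their dose to y1 at the segment boundary.
# Within a segment the compiled right-hand side is integrated by deSolve
# (default lsoda; the explicit Runge-Kutta pair rk45dp7 serves as the
# independent second integrator family).

# parameter vector handed to the compiled model: kinetics + scale factors
compiled_parms <- function(values, scales) {
  c(values[.kinetic_names], as.numeric(scales))
}

# integrate one protocol over an output grid; core used everywhere
integrate_segments <- function(params, y0, protocol, times,
                               method = "lsoda", rtol = 1e-8, atol = 1e-10,
                               engine = "compiled") {
  params <- resolve_ties(params)
  v <- params$values
  t0 <- times[[1]]; t_end <- times[[length(times)]]
  ev <- protocol$events
  breaks <- sort(unique(c(t0, t_end, ev$time_h[ev$time_h > t0 &
                                               ev$time_h < t_end])))
  grid <- sort(unique(c(times, breaks)))
  y <- as.numeric(y0)
  # IL-15 impulses exactly at the start of the window (earlier impulses are
  # assumed to be reflected in y0 already)
  imp0 <- ev[ev$agent == "IL15" & ev$time_h == t0, , drop = FALSE]
  if (nrow(imp0)) y[1] <- y[1] + sum(imp0$dose_fraction)
  out <- matrix(NA_real_, length(grid), 10,
                dimnames = list(NULL, .state_names))
  out[1, ] <- y
  for (i in seq_len(length(breaks) - 1)) {
    ta <- breaks[[i]]; tb <- breaks[[i + 1]]
    if (ta > t0) {                      # impulses at interior boundaries
      imp <- ev[ev$agent == "IL15" & ev$time_h == ta, , drop = FALSE]
      if (nrow(imp)) y[1] <- y[1] + sum(imp$dose_fraction)
    }
    s <- effective_inputs(params, protocol, ta)
    seg_times <- unique(c(ta, grid[grid > ta & grid <= tb]))
    if (length(seg_times) == 1) seg_times <- c(ta, tb)
    sol <- if (engine == "compiled")
      deSolve::ode(y = y, times = seg_times, func = "hifnk_derivs",
                   parms = compiled_parms(v, s), dllname = "hifnk",
                   initfunc = "hifnk_initmod", method = method,
                   rtol = rtol, atol = atol, maxsteps = 100000)
    else
      deSolve::ode(y = y, times = seg_times,
                   func = function(t, y, p) list(rhs_scaled(y, v, s)),
                   parms = NULL, method = method, rtol = rtol, atol = atol,
                   maxsteps = 100000)
    if (attr(sol, "istate")[1] < 0)
      stop("integration failed on [", ta, ", ", tb, "] h")
    y <- as.numeric(sol[nrow(sol), -1])
    keep <- sol[, 1] %in% grid & sol[, 1] > ta
    out[match(sol[keep, 1], grid), ] <- sol[keep, -1, drop = FALSE]
  }
  worst <- min(out)
  if (worst < -1e-9)
    warning("state fell below -1e-9 (", format(worst),
            "); clipped to zero")
  out[out < 0] <- 0
  list(times = grid, states = out)
}

#' Simulate the network under a treatment protocol
#'
#' Integrates the ten-state system piecewise between protocol events and
#' returns the trajectory together with the three measured observables
#' (total HIF-1alpha, STAT3, AKT).
#'
#' @param params a `hif_parameters` object.
#' @param protocol a `hif_protocol`; IL-15 events act as impulses on `y1`,
#'   the other agents as persistent conditions.
#' @param times output time grid in hours (event times are added
#'   automatically).
#' @param y0 initial state; defaults to the steady-state-consistent
#'   equilibrium for `params` (IL-15 priming comes from the protocol).
#' @param method deSolve integrator: `"lsoda"` (default, stiff-capable
#'   multistep) or `"ode45"` (explicit Runge-Kutta 4(5) family).
#' @param rtol,atol relative / absolute integration tolerances.
#' @param engine `"compiled"` (C right-hand side, default) or `"R"` (pure-R
#'   right-hand side, for cross-checking).
#' @return an object of class `hif_trajectory`: list with `times`, `states`
#'   (matrix, one row per time), `observables` (data frame with columns
#'   `time_h`, `TOTAL_HIF`, `STAT3`, `AKT`) and `protocol`.
#' @examples
#' \donttest{
#' eq <- solve_consistent_equilibrium()
#' tr <- hif_simulate(eq$params,
#'                    protocol_standard(il15_at = 0, dmog_at = 0,
#'                                      horizon = 30),
#'                    times = seq(0, 30, by = 0.5), y0 = eq$state)
#' plot(tr)
#' }
#' @export
hif_simulate <- function(params, protocol = hif_protocol(),
                         times = seq(0, protocol$horizon, length.out = 201),
                         y0 = NULL, method = "lsoda",
                         rtol = 1e-8, atol = 1e-10, engine = "compiled") {
  stopifnot(inherits(params, "hif_parameters"),
            inherits(protocol, "hif_protocol"))
  if (max(times) > protocol$horizon)
    stop("requested times exceed the protocol horizon")
  if (is.null(y0)) y0 <- equilibrium_state(params)
  if (any(y0 < 0)) stop("initial state must be non-negative")
  res <- integrate_segments(params, y0, protocol, times,
                            method = method, rtol = rtol, atol = atol,
                            engine = engine)
  obs <- data.frame(time_h = res$times,
                    TOTAL_HIF = total_hif(res$states),
                    STAT3 = res$states[, 8],
                    AKT = res$states[, 2])
  structure(list(times = res$times, states = res$states,
                 observables = obs, protocol = protocol,
                 method = method, rtol = rtol, atol = atol),
            class = "hif_trajectory")
}

#' @export
print.hif_trajectory <- function(x, ...) {
  cat("hif_trajectory:", length(x$times), "time points over [",
      min(x$times), ",", max(x$times), "] h;",
      nrow(x$protocol$events), "protocol event(s)\n")
  cat("  final observables: total HIF-1a =",
      signif(x$observables$TOTAL_HIF[length(x$times)], 4),
      " STAT3 =", signif(x$observables$STAT3[length(x$times)], 4),
      " AKT =", signif(x$observables$AKT[length(x$times)], 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.hif_trajectory <- function(x, ...) {
  long <- data.frame(
    time_h = rep(x$times, 10),
    variable = rep(.state_names, each = length(x$times)),
    value = as.vector(x$states))
  obs <- data.frame(
    time_h = rep(x$observables$time_h, 3),
    variable = rep(c("TOTAL_HIF", "STAT3", "AKT"),
                   each = length(x$times)),
    value = c(x$observables$TOTAL_HIF, x$observables$STAT3,
              x$observables$AKT))
  rbind(long, obs)
}

#' @export
plot.hif_trajectory <- function(x, which = c("TOTAL_HIF", "STAT3", "AKT"),
                                ...) {
  obs <- x$observables
  cols <- c(TOTAL_HIF = "red3", STAT3 = "blue3", AKT = "black")
  graphics::matplot(obs$time_h, as.matrix(obs[which]), type = "l",
                    lty = 1, col = cols[which], xlab = "time [h]",
                    ylab = "normalized level", ...)
  graphics::legend("topleft", legend = which, col = cols[which],
                   lty = 1, bty = "n")
  invisible(x)
}

#' Steady state under a constant condition
#'
#' Integrates to `t_end` (100 h by default, the operational steady-state
#' snapshot) under a protocol whose persistent treatments are active from
#' `t = 0`, and reports convergence diagnostics: the maximum absolute
#' derivative at the endpoint and whether any component moved by more than
#' 0.1\% over the final 10 h.
#'
#' @param params a `hif_parameters` object.
#' @param protocol a `hif_protocol` holding a constant condition.
#' @param y0 initial state (default: untreated equilibrium).
#' @param t_end snapshot time in hours.
#' @return list with `state` (endpoint), `total_hif`, `max_deriv`,
#'   `converged` (logical) and `max_rel_change_10h`.
#' @export
steady_state_value <- function(params, protocol = hif_protocol(),
                               y0 = NULL, t_end = 100) {
  if (protocol$horizon < t_end)
    protocol$horizon <- t_end
  tr <- hif_simulate(params, protocol, times = c(0, t_end - 10, t_end),
                     y0 = y0)
  y_end <- tr$states[nrow(tr$states), ]
  y_10 <- tr$states[nrow(tr$states) - 1, ]
  # components below 1e-3 on the normalized scale are judged absolutely,
  # otherwise a species decaying exponentially to zero never "converges"
  scale <- pmax(abs(y_end), 1e-3)
  rel <- max(abs(y_end - y_10) / scale)
  s <- effective_inputs(params, protocol, t_end)
  dy <- rhs_scaled(as.numeric(y_end), resolve_ties(params)$values, s)
  list(state = y_end, total_hif = total_hif(y_end),
       max_deriv = max(abs(dy)), converged = rel <= 1e-3,
       max_rel_change_10h = rel)
}
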