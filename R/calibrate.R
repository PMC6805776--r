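# Steady-state-constrained weighted least-squares calibration.
#
# The estimation problem: minimize over the free parameters
#   1/2 sum_{i,j,ex} [(eta_ij - g_i(t_j))/sigma_ij]^2
#   + 1/2 sum_m [(p_m - p0_m)/lambda_m]^2
# subject to the untreated-equilibrium initial condition y0(p) and the
# steady-state ties a1 = 0, d8 = k8.  Solved by a damped generalized
# Gauss-Newton iteration, either with single shooting (the trajectory is a
# function of p alone) or with direct multiple shooting (node states enter
# as unknowns tied by continuity/matching equality constraints).
# Non-negativity is enforced by optimizing rates on a log scale and
# efficacies on a clamped logit scale.

.observables <- c("TOTAL_HIF", "STAT3", "AKT")

#' Construct a measurement dataset
#'
#' One perturbation experiment: a treatment protocol plus noisy normalized
#' measurements with per-point standard deviations.
#'
#' @param protocol a `hif_protocol`.
#' @param points data frame with columns `time_h`, `observable` (one of
#'   `"TOTAL_HIF"`, `"STAT3"`, `"AKT"`), `value` and `sd` (`> 0`).
#' @param label experiment label.
#' @return an object of class `hif_dataset`.
#' @export
hif_dataset <- function(protocol, points, label = "experiment") {
  stopifnot(inherits(protocol, "hif_protocol"),
            is.data.frame(points),
            all(c("time_h", "observable", "value", "sd") %in% names(points)))
  points <- points[c("time_h", "observable", "value", "sd")]
  points$observable <- as.character(points$observable)
  if (!all(points$observable %in% .observables))
    stop("unknown observable(s): ",
         paste(setdiff(points$observable, .observables), collapse = ", "))
  if (any(points$sd <= 0)) stop("all measurement sds must be > 0")
  if (any(!is.finite(points$value))) stop("non-finite measurement value")
  if (any(points$time_h < 0 | points$time_h > protocol$horizon))
    stop("measurement times must lie within the protocol horizon")
  points <- points[order(points$time_h, points$observable), , drop = FALSE]
  rownames(points) <- NULL
  structure(list(protocol = protocol, points = points, label = label),
            class = "hif_dataset")
}

#' @export
print.hif_dataset <- function(x, ...) {
  cat("hif_dataset '", x$label, "': ", nrow(x$points), " points, ",
      nrow(x$protocol$events), " protocol event(s), horizon ",
      x$protocol$horizon, " h\n", sep = "")
  invisible(x)
}

#' Read / write dataset CSV files
#'
#' The CSV dialect has columns `experiment`, `label`, `time_h`,
#' `observable`, `value`, `sd`; one file may hold several experiments.
#' Protocols travel separately (see [read_protocol()]).
#'
#' @param path CSV file path.
#' @param protocols named list of `hif_protocol` objects keyed by the
#'   `experiment` values in the file.
#' @return `read_datasets()` returns a named list of `hif_dataset`s.
#' @export
read_datasets <- function(path, protocols) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment", "label", "time_h", "observable", "value", "sd")
  if (!all(need %in% names(tab)))
    stop("dataset file must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$experiment), function(d) {
    proto <- protocols[[d$experiment[[1]]]]
    if (is.null(proto)) stop("no protocol for experiment '",
                             d$experiment[[1]], "'")
    hif_dataset(proto, d[c("time_h", "observable", "value", "sd")],
                label = d$label[[1]])
  })
  out
}

#' @rdname read_datasets
#' @param datasets named list of `hif_dataset` objects.
#' @export
write_datasets <- function(datasets, path) {
  rows <- lapply(names(datasets), function(nm) {
    d <- datasets[[nm]]
    cbind(experiment = nm, label = d$label, d$points)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Observables of a trajectory at requested times
#'
#' Evaluates total HIF-1alpha, STAT3 and AKT at arbitrary times inside the
#' simulated span by cubic-spline interpolation of the trajectory grid (a
#' dense-output surrogate; on the default grids it agrees with a direct
#' re-integration to well below 1e-5).
#'
#' @param trajectory a `hif_trajectory`.
#' @param times numeric vector of times in hours.
#' @return matrix with one row per time and columns `TOTAL_HIF`, `STAT3`,
#'   `AKT`.
#' @export
hif_observe <- function(trajectory, times) {
  stopifnot(inherits(trajectory, "hif_trajectory"))
  if (any(times < min(trajectory$times) - 1e-12) ||
      any(times > max(trajectory$times) + 1e-12))
    stop("requested times outside the trajectory span")
  obs <- trajectory$observables
  out <- vapply(.observables, function(o)
    stats::spline(obs$time_h, obs[[o]], xout = times, method = "fmm")$y,
    numeric(length(times)))
  if (length(times) == 1) out <- matrix(out, nrow = 1,
                                        dimnames = list(NULL, .observables))
  rownames(out) <- NULL
  out
}

#' Calibration configuration
#'
#' @param free character vector of free parameter names (default: the 25
#'   parameters of the published calibration).
#' @param prior,lambda optional named numeric overrides of the prior values
#'   and Tikhonov scales (`lambda = Inf` switches a prior off; the default,
#'   taken from the parameter object, is `10 * |p0|` — a weak pull).
#' @param use_prior logical; drop the regularization term entirely when
#'   `FALSE`.
#' @param shooting `"single"` or `"multiple"`.
#' @param nodes for multiple shooting: named list of node-time vectors per
#'   dataset label, or `NULL` for the default grid (the measurement times
#'   of each experiment).
#' @param init_state `"equilibrium"` (the initial condition is the untreated
#'   equilibrium re-solved for every parameter iterate) or `"canonical"`
#'   (fixed canonical reference state).
#' @param max_iter Gauss-Newton iteration cap.
#' @param step_tol convergence threshold on `||dp|| / (1 + ||p||)` in the
#'   original parameter scale.
#' @param rtol,atol integrator tolerances used during fitting; tighter than
#'   the simulation defaults so that the line search can resolve objective
#'   differences near the optimum.
#' @return an object of class `pep_config`.
#' @export
pep_config <- function(free = NULL, prior = NULL, lambda = NULL,
                       use_prior = TRUE,
                       shooting = c("single", "multiple"), nodes = NULL,
                       init_state = c("equilibrium", "canonical"),
                       max_iter = 50, step_tol = 1e-8,
                       rtol = 1e-10, atol = 1e-12) {
  structure(list(free = free, prior = prior, lambda = lambda,
                 use_prior = use_prior, shooting = match.arg(shooting),
                 nodes = nodes, init_state = match.arg(init_state),
                 max_iter = max_iter, step_tol = step_tol,
                 rtol = rtol, atol = atol),
            class = "pep_config")
}

# resolve config against a parameter object
resolve_config <- function(config, params) {
  if (is.null(config)) config <- pep_config()
  free <- config$free
  if (is.null(free)) free <- free_parameters(params)
  bad <- setdiff(free, names(params$values))
  if (length(bad)) stop("unknown free parameter(s): ",
                        paste(bad, collapse = ", "))
  if (any(free %in% c("a1", "d8")))
    stop("tied parameters (a1, d8) cannot be free")
  prior <- params$values[free]
  prior[intersect(names(params$prior), free)] <-
    params$prior[intersect(names(params$prior), free)]
  lambda <- 10 * abs(prior)
  lambda[intersect(names(params$lambda), free)] <-
    params$lambda[intersect(names(params$lambda), free)]
  if (!is.null(config$prior)) prior[names(config$prior)] <- config$prior
  if (!is.null(config$lambda)) lambda[names(config$lambda)] <- config$lambda
  lambda[lambda <= 0] <- Inf              # a zero scale means "no prior"
  if (!config$use_prior) lambda[] <- Inf
  config$free <- free; config$prior <- prior; config$lambda <- lambda
  config
}

# --- internal parameter transforms (non-negativity / [0,1] bounds) -------
is_efficacy <- function(nms) nms %in% .efficacy_names

to_internal <- function(p, nms) {
  eff <- is_efficacy(nms)
  th <- numeric(length(p))
  th[!eff] <- log(pmax(p[!eff], 1e-12))
  th[eff] <- stats::qlogis(pmin(pmax(p[eff], 1e-9), 1 - 1e-9))
  th
}

from_internal <- function(th, nms) {
  eff <- is_efficacy(nms)
  p <- numeric(length(th))
  p[!eff] <- exp(th[!eff])
  p[eff] <- stats::plogis(th[eff])
  stats::setNames(p, nms)
}

# dp/dtheta for the delta method
internal_jacobian_scale <- function(p, nms) {
  eff <- is_efficacy(nms)
  out <- p
  out[eff] <- p[eff] * (1 - p[eff])
  out
}

# keep efficacy logits inside the clamped range so a boundary optimum
# (e.g. a fully effective inhibitor) cannot drift to +/- infinity
clamp_internal <- function(th, nms) {
  eff <- is_efficacy(nms)
  lim <- stats::qlogis(1 - 1e-9)
  th[eff] <- pmin(pmax(th[eff], -lim), lim)
  th
}

# damped least-squares Gauss-Newton step.  The absolute Tikhonov term mu
# is tiny: it only regularizes directions whose singular values are
# numerically dead (an efficacy pinned at its clamped bound has a
# vanishing logit-scale column); every informative direction takes the
# plain Gauss-Newton step.
gn_step <- function(J, r, mu = 1e-8) {
  n <- ncol(J)
  Jaug <- rbind(J, diag(sqrt(mu), n))
  step <- qr.coef(qr(Jaug), -c(r, rep(0, n)))
  step[is.na(step)] <- 0
  step
}

# initial condition for a parameter iterate
fit_init_state <- function(params, init_state) {
  if (init_state == "equilibrium") equilibrium_state(params)
  else canonical_state(0)
}

# model observables at the measurement points of one dataset
dataset_predictions <- function(params, dataset, y0, rtol = 1e-10,
                                atol = 1e-12) {
  tms <- sort(unique(c(0, dataset$points$time_h)))
  res <- integrate_segments(params, y0, dataset$protocol,
                            times = tms, rtol = rtol, atol = atol)
  obs <- cbind(TOTAL_HIF = total_hif(res$states),
               STAT3 = res$states[, 8], AKT = res$states[, 2])
  idx <- match(dataset$points$time_h, res$times)
  obs[cbind(idx, match(dataset$points$observable, .observables))]
}

# stacked weighted residual vector: data residuals then prior residuals
stacked_residuals <- function(params, datasets, config) {
  params <- resolve_ties(params)
  y0 <- fit_init_state(params, config$init_state)
  r_data <- unlist(lapply(datasets, function(d) {
    g <- tryCatch(
      dataset_predictions(params, d, y0, rtol = config$rtol,
                          atol = config$atol),
      error = function(e) stop("simulation failed for dataset '", d$label,
                               "': ", conditionMessage(e), call. = FALSE))
    (d$points$value - g) / d$points$sd
  }), use.names = FALSE)
  p <- params$values[config$free]
  active <- is.finite(config$lambda)
  r_prior <- (p[active] - config$prior[active]) / config$lambda[active]
  c(r_data, unname(r_prior))
}

#' Calibration objective
#'
#' Evaluates the weighted least-squares objective with its Tikhonov
#' regularization term and returns the stacked weighted residual vector
#' (data residuals first, prior residuals last).
#'
#' @param params a `hif_parameters` object.
#' @param datasets list of `hif_dataset` objects.
#' @param config a [pep_config()] (default configuration when `NULL`).
#' @return list with `value` (the objective), `data` and `prior` (the two
#'   halves), and `residuals` (the stacked weighted vector).
#' @export
hif_objective <- function(params, datasets, config = NULL) {
  if (inherits(datasets, "hif_dataset")) datasets <- list(datasets)
  config <- resolve_config(config, params)
  r <- stacked_residuals(params, datasets, config)
  nd <- sum(vapply(datasets, function(d) nrow(d$points), integer(1)))
  rd <- r[seq_len(nd)]; rp <- r[-seq_len(nd)]
  list(value = 0.5 * sum(r^2), data = 0.5 * sum(rd^2),
       prior = 0.5 * sum(rp^2), residuals = r)
}

# finite-difference Jacobian of the stacked residuals w.r.t. internal
# theta.  The step is sized against the integration-noise floor of the
# residuals (~1e-7 after weighting), not machine precision: h ~ 1e-3 in
# log/logit scale (a ~0.1% parameter perturbation) keeps the noise part of
# the FD error below ~1e-4 per entry, which is what lets the weak prior
# pull along structurally non-identifiable directions remain visible.
gn_jacobian <- function(theta, r0, params, datasets, config) {
  free <- config$free
  J <- matrix(0, length(r0), length(theta))
  for (j in seq_along(theta)) {
    h <- 1e-3 * max(abs(theta[[j]]), 1)
    th <- theta; th[[j]] <- th[[j]] + h
    pj <- set_parameters(params, from_internal(th, free))
    J[, j] <- (stacked_residuals(pj, datasets, config) - r0) / h
  }
  J
}

fit_single_shooting <- function(params, datasets, config) {
  free <- config$free
  theta <- to_internal(params$values[free], free)
  r <- stacked_residuals(set_parameters(params, from_internal(theta, free)),
                         datasets, config)
  obj <- 0.5 * sum(r^2)
  history <- obj
  converged <- FALSE
  n_data <- sum(vapply(datasets, function(d) nrow(d$points), integer(1)))
  J <- NULL
  for (it in seq_len(config$max_iter)) {
    p_cur <- set_parameters(params, from_internal(theta, free))
    J <- gn_jacobian(theta, r, p_cur, datasets, config)
    if (all(!is.finite(config$lambda)) && qr(J)$rank < length(theta))
      stop("rank-deficient Gauss-Newton system: the free set is not ",
           "locally identifiable with these data; run ",
           "identifiability_screen() to select an estimable subset")
    step <- gn_step(J, r)
    accepted <- FALSE
    for (tk in 2^(0:-10)) {
      th_new <- clamp_internal(theta + tk * step, free)
      r_new <- tryCatch(
        stacked_residuals(set_parameters(params,
                                         from_internal(th_new, free)),
                          datasets, config),
        error = function(e) NULL)
      if (is.null(r_new) || any(!is.finite(r_new))) next
      obj_new <- 0.5 * sum(r_new^2)
      if (obj_new < obj) { accepted <- TRUE; break }
    }
    if (!accepted) { converged <- TRUE; break }   # no descent left
    p_old <- from_internal(theta, free)
    p_new <- from_internal(th_new, free)
    theta <- th_new; r <- r_new; obj <- obj_new
    history <- c(history, obj)
    if (sqrt(sum((p_new - p_old)^2)) / (1 + sqrt(sum(p_new^2))) <
        config$step_tol) { converged <- TRUE; break }
  }
  estimates <- from_internal(theta, free)
  p_fit <- set_parameters(params, estimates)
  # refresh residuals/Jacobian at the solution for the covariance
  r <- stacked_residuals(p_fit, datasets, config)
  J <- gn_jacobian(theta, r, p_fit, datasets, config)
  JtJ <- crossprod(J)
  cov_int <- tryCatch(chol2inv(chol(JtJ)), error = function(e) {
    warning("near-singular Gauss-Newton system at the solution; ",
            "using a pseudo-inverse for the covariance")
    sv <- svd(JtJ)
    keep <- sv$d > max(sv$d) * 1e-12
    sv$v[, keep] %*% (t(sv$u[, keep]) / sv$d[keep])
  })
  scale <- internal_jacobian_scale(estimates, free)
  cov_p <- diag(scale, length(scale)) %*% cov_int %*%
    diag(scale, length(scale))
  dimnames(cov_p) <- list(free, free)
  rd <- r[seq_len(n_data)]; rp <- r[-seq_len(n_data)]
  list(estimates = estimates, sd = sqrt(pmax(diag(cov_p), 0)),
       cov = cov_p, objective = obj,
       data_term = 0.5 * sum(rd^2), prior_term = 0.5 * sum(rp^2),
       history = history, iterations = length(history) - 1,
       converged = converged, constraint_norm = 0,
       params = p_fit, residuals = r)
}

# ---- multiple shooting ---------------------------------------------------

# per-dataset shooting structure: node times (measurement grid by default)
ms_nodes <- function(datasets, config) {
  lapply(datasets, function(d) {
    nd <- config$nodes[[d$label]]
    if (is.null(nd)) nd <- d$points$time_h
    sort(unique(c(0, nd)))
  })
}

# integrate one shooting segment, returning the endpoint state.
# Node states follow the pre-impulse convention, so an IL-15 impulse
# falling exactly on the segment start is applied by integrate_segments.
ms_segment_end <- function(params, y_start, protocol, t_a, t_b,
                           rtol = 1e-10, atol = 1e-12) {
  res <- integrate_segments(params, y_start, protocol, times = c(t_a, t_b),
                            rtol = rtol, atol = atol)
  res$states[nrow(res$states), ]
}

fit_multiple_shooting <- function(params, datasets, config) {
  free <- config$free
  np <- length(free)
  nodes <- ms_nodes(datasets, config)
  # initial node states from the single-shooting trajectory at the start
  y0 <- fit_init_state(params, config$init_state)
  s_list <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]; nd <- nodes[[i]]
    res <- integrate_segments(params, y0, d$protocol, times = nd)
    res$states[match(nd[-1], res$times), , drop = FALSE]  # states at n_1..n_K
  })
  pack_s <- function(sl) unlist(lapply(sl, function(m) as.vector(t(m))))
  unpack_s <- function(sv) {
    out <- list(); off <- 0
    for (i in seq_along(datasets)) {
      K <- length(nodes[[i]]) - 1
      out[[i]] <- matrix(sv[off + seq_len(10 * K)], nrow = K, ncol = 10,
                         byrow = TRUE)
      off <- off + 10 * K
    }
    out
  }
  theta <- c(to_internal(params$values[free], free), pack_s(s_list))
  ns <- length(theta) - np

  eval_all <- function(theta) {
    p <- set_parameters(params, from_internal(theta[seq_len(np)], free))
    sl <- unpack_s(theta[-seq_len(np)])
    y0p <- fit_init_state(p, config$init_state)
    F1 <- c(); F2 <- c()
    for (i in seq_along(datasets)) {
      d <- datasets[[i]]; nd <- nodes[[i]]; S <- pmax(sl[[i]], 0)
      node_state <- function(k)                    # state at node k (0-based)
        if (k == 0) y0p else S[k, ]
      # data residuals: each measurement time is a node
      g <- vapply(seq_len(nrow(d$points)), function(j) {
        k <- match(d$points$time_h[[j]], nd) - 1
        y <- node_state(k)
        switch(d$points$observable[[j]],
               TOTAL_HIF = y[[4]] + y[[6]] + y[[10]],
               STAT3 = y[[8]], AKT = y[[2]])
      }, numeric(1))
      F1 <- c(F1, (d$points$value - g) / d$points$sd)
      # matching conditions
      for (k in seq_len(length(nd) - 1)) {
        xe <- ms_segment_end(p, node_state(k - 1), d$protocol,
                             nd[[k]], nd[[k + 1]],
                             rtol = config$rtol, atol = config$atol)
        F2 <- c(F2, xe - S[k, ])
      }
    }
    pv <- p$values[free]
    active <- is.finite(config$lambda)
    rp <- (pv[active] - config$prior[active]) / config$lambda[active]
    list(F1 = c(F1, unname(rp)), F2 = F2)
  }

  merit <- function(ev) 0.5 * sum(ev$F1^2) + 10 * sqrt(sum(ev$F2^2))
  ev <- eval_all(theta)
  history <- 0.5 * sum(ev$F1^2)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    # finite-difference Jacobians of (F1, F2) w.r.t. all unknowns
    n1 <- length(ev$F1); n2 <- length(ev$F2)
    J1 <- matrix(0, n1, length(theta)); J2 <- matrix(0, n2, length(theta))
    for (j in seq_along(theta)) {
      h <- 1e-3 * max(abs(theta[[j]]), 1)
      th <- theta; th[[j]] <- th[[j]] + h
      evj <- eval_all(th)
      J1[, j] <- (evj$F1 - ev$F1) / h
      J2[, j] <- (evj$F2 - ev$F2) / h
    }
    # null-space solution of the linearized constrained problem
    delta0 <- -crossprod(J2, solve(tcrossprod(J2) +
                                     1e-12 * diag(n2), ev$F2))
    qz <- qr(t(J2))
    Q <- qr.Q(qz, complete = TRUE)
    Z <- Q[, (qz$rank + 1):ncol(Q), drop = FALSE]
    A <- J1 %*% Z
    w <- gn_step(A, as.numeric(ev$F1 + J1 %*% delta0))
    step <- as.numeric(delta0 + Z %*% w)
    m0 <- merit(ev)
    accepted <- FALSE
    for (tk in 2^(0:-10)) {
      th_new <- theta + tk * step
      th_new[seq_len(np)] <- clamp_internal(th_new[seq_len(np)], free)
      ev_new <- tryCatch(eval_all(th_new), error = function(e) NULL)
      if (is.null(ev_new) || any(!is.finite(c(ev_new$F1, ev_new$F2)))) next
      if (merit(ev_new) < m0) { accepted <- TRUE; break }
    }
    if (!accepted) { converged <- TRUE; break }
    p_old <- from_internal(theta[seq_len(np)], free)
    p_new <- from_internal(th_new[seq_len(np)], free)
    theta <- th_new; ev <- ev_new
    history <- c(history, 0.5 * sum(ev$F1^2))
    if (sqrt(sum((p_new - p_old)^2)) / (1 + sqrt(sum(p_new^2))) <
        config$step_tol && max(abs(ev$F2)) < 1e-8) {
      converged <- TRUE; break
    }
  }
  estimates <- from_internal(theta[seq_len(np)], free)
  p_fit <- set_parameters(params, estimates)
  # covariance on the constraint null space at the solution
  n1 <- length(ev$F1); n2 <- length(ev$F2)
  J1 <- matrix(0, n1, length(theta)); J2 <- matrix(0, n2, length(theta))
  for (j in seq_along(theta)) {
    h <- 1e-3 * max(abs(theta[[j]]), 1)
    th <- theta; th[[j]] <- th[[j]] + h
    evj <- eval_all(th)
    J1[, j] <- (evj$F1 - ev$F1) / h
    J2[, j] <- (evj$F2 - ev$F2) / h
  }
  qz <- qr(t(J2)); Q <- qr.Q(qz, complete = TRUE)
  Z <- Q[, (qz$rank + 1):ncol(Q), drop = FALSE]
  A <- J1 %*% Z
  AtA <- crossprod(A)
  cov_z <- tryCatch(chol2inv(chol(AtA)), error = function(e) {
    sv <- svd(AtA); keep <- sv$d > max(sv$d) * 1e-12
    sv$v[, keep] %*% (t(sv$u[, keep]) / sv$d[keep])
  })
  cov_full <- Z %*% cov_z %*% t(Z)
  cov_int <- cov_full[seq_len(np), seq_len(np), drop = FALSE]
  scale <- internal_jacobian_scale(estimates, free)
  cov_p <- diag(scale, np) %*% cov_int %*% diag(scale, np)
  dimnames(cov_p) <- list(free, free)
  nd_total <- sum(vapply(datasets, function(d) nrow(d$points), integer(1)))
  rd <- ev$F1[seq_len(nd_total)]; rp <- ev$F1[-seq_len(nd_total)]
  list(estimates = estimates, sd = sqrt(pmax(diag(cov_p), 0)),
       cov = cov_p, objective = 0.5 * sum(ev$F1^2),
       data_term = 0.5 * sum(rd^2), prior_term = 0.5 * sum(rp^2),
       history = history, iterations = length(history) - 1,
       converged = converged, constraint_norm = max(abs(ev$F2), 0),
       params = p_fit, residuals = ev$F1)
}

#' Fit the network to perturbation-experiment data
#'
#' Solves the multi-experiment weighted least-squares problem with Tikhonov
#' regularization by a damped generalized Gauss-Newton iteration, subject
#' to the steady-state ties (`a1 = 0`, `d8 = k8`) and, by default, the
#' untreated-equilibrium initial condition re-solved at every parameter
#' iterate.  In multiple-shooting mode the states at the shooting nodes are
#' additional unknowns bound by continuity (matching) equality constraints,
#' and the linearized problems are solved on the constraint null space.
#'
#' @param datasets a `hif_dataset` or list of them.
#' @param params starting `hif_parameters` (also supplies priors and
#'   regularization scales); default the published set.
#' @param config a [pep_config()].
#' @return an object of class `hif_fit` with components `estimates`, `sd`
#'   (from the constrained variance-covariance approximation), `cov`,
#'   `objective`, `data_term`, `prior_term`, `history` (objective per
#'   accepted iteration), `converged`, `constraint_norm`, `params` (full
#'   parameter set at the optimum), `datasets` and `config`.  Methods:
#'   `print`, `summary`, `coef`, `vcov`, `predict`, `residuals`, `plot`.
#' @seealso [sensitivity_matrix()], [identifiability_screen()]
#' @export
hif_fit <- function(datasets, params = hif_parameters(), config = NULL) {
  if (inherits(datasets, "hif_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, logical(1), "hif_dataset")))
  params <- resolve_ties(params)
  validate_parameters(params)
  config <- resolve_config(config, params)
  fit <- if (config$shooting == "multiple")
    fit_multiple_shooting(params, datasets, config)
  else fit_single_shooting(params, datasets, config)
  structure(c(fit, list(datasets = datasets, config = config)),
            class = "hif_fit")
}

#' @export
print.hif_fit <- function(x, ...) {
  cat("Constrained Gauss-Newton fit (", x$config$shooting, " shooting)\n",
      sep = "")
  cat("  ", length(x$estimates), " free parameters, ",
      sum(vapply(x$datasets, function(d) nrow(d$points), integer(1))),
      " data points, ", x$iterations, " iterations, ",
      if (x$converged) "converged" else "iteration cap reached", "\n",
      sep = "")
  cat("  objective ", signif(x$objective, 6), " (data ",
      signif(x$data_term, 6), " + prior ", signif(x$prior_term, 6), ")\n",
      sep = "")
  invisible(x)
}

#' @export
coef.hif_fit <- function(object, ...) object$estimates

#' @export
vcov.hif_fit <- function(object, ...) object$cov

#' @export
summary.hif_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$estimates, sd = object$sd,
                    prior = object$config$prior,
                    row.names = names(object$estimates))
  structure(list(table = tab, objective = object$objective,
                 data_term = object$data_term,
                 prior_term = object$prior_term,
                 converged = object$converged,
                 iterations = object$iterations,
                 shooting = object$config$shooting),
            class = "summary.hif_fit")
}

#' @export
print.summary.hif_fit <- function(x, ...) {
  cat("Parameter estimates (", x$shooting, " shooting, ",
      x$iterations, " iterations, ",
      if (x$converged) "converged" else "not converged", ")\n", sep = "")
  print(round(x$table, 5))
  cat("objective:", signif(x$objective, 6), "\n")
  invisible(x)
}

#' @export
residuals.hif_fit <- function(object, ...) {
  nd <- sum(vapply(object$datasets, function(d) nrow(d$points), integer(1)))
  object$residuals[seq_len(nd)]
}

#' Fitted trajectories
#'
#' Simulates the model at the fitted parameters, for each calibration
#' protocol (default) or a new one.
#'
#' @param object a `hif_fit`.
#' @param protocol optional `hif_protocol` replacing the calibration
#'   protocols.
#' @param times output grid in hours.
#' @param ... unused.
#' @return a `hif_trajectory` (single protocol) or named list of them.
#' @export
predict.hif_fit <- function(object, protocol = NULL, times = NULL, ...) {
  p <- object$params
  y0 <- fit_init_state(p, object$config$init_state)
  one <- function(proto) {
    tms <- if (is.null(times)) seq(0, proto$horizon, length.out = 151)
           else times
    hif_simulate(p, proto, times = tms, y0 = y0)
  }
  if (!is.null(protocol)) return(one(protocol))
  out <- lapply(object$datasets, function(d) one(d$protocol))
  names(out) <- vapply(object$datasets, function(d) d$label, character(1))
  out
}

#' @export
plot.hif_fit <- function(x, ...) {
  trs <- predict(x)
  n <- length(trs)
  old <- graphics::par(mfrow = c(ceiling(n / 2), min(n, 2)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  cols <- c(TOTAL_HIF = "red3", STAT3 = "blue3", AKT = "black")
  for (i in seq_along(trs)) {
    d <- x$datasets[[i]]
    plot(trs[[i]], main = d$label)
    for (o in .observables) {
      pts <- d$points[d$points$observable == o, ]
      if (nrow(pts))
        graphics::points(pts$time_h, pts$value, col = cols[[o]], pch = 16)
    }
  }
  invisible(x)
}
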