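# Parameter set for the HIF-1alpha regulatory network.
#
# All rate constants act on normalized (dimensionless) state variables;
# thresholds keep their printed nM values, which is how the published fit
# was performed.  Two parameters are tied by the requirement that untreated
# cells sit at equilibrium: a1 = 0 (no external IL-15 supply) and d8 = k8
# (STAT3 turnover balances its mTOR-driven activation at the reference
# state).

# canonical ordering of the kinetic parameters passed to the compiled
# right-hand side; the five treatment scale factors are appended after these
.kinetic_names <- c(
  "a1", "a2", "a3", "a5", "a7", "a8", "a9", "a11",
  "d1", "d2", "d3", "d4", "d5", "d6", "d7", "d8", "d9", "d10",
  "k1", "k2", "k3", "k4", "k5", "k6", "k7", "k8", "k9", "k10", "k11",
  "k12", "k13", "k14", "k15", "kS", "kalpha",
  "n2", "xi28", "xi4", "xi44", "xi10", "Delta", "phi", "K_O2",
  "alpha1", "alpha2"
)

.efficacy_names <- c("rho3", "rho4", "rho6", "rho_rapa", "rho_nfkb")

.param_names <- c(.kinetic_names, .efficacy_names)

# Table-2 parameters (free in the default calibration); d8 is tied, not free
.free_names <- c(
  "a5", "d1", "d2", "d3", "d4", "d5", "d6", "d7", "d9", "d10",
  "rho3", "rho4", "k3", "k4", "k6", "k7", "k8", "k9", "k13", "k14",
  "kalpha", "xi10", "phi", "alpha1", "alpha2"
)

.published_values <- c(
  # basal/external rates [nM/h] and PHD normoxic equilibrium [nM]
  a1 = 0, a2 = 0.848, a3 = 0.037, a5 = 0.211, a7 = 0, a8 = 0, a9 = 0,
  a11 = 4.17,
  # first-order decay rates [1/h]; d8 tied to k8
  d1 = 0.062, d2 = 0.848, d3 = 0.919, d4 = 0.623, d5 = 0.196,
  d6 = 0.301, d7 = 0.914, d8 = 0.577, d9 = 0.934, d10 = 0.935,
  # activation / catalytic rates
  k1 = 2e-5, k2 = 0.307, k3 = 0.181, k4 = 76.196, k5 = 75.895,
  k6 = 25.001, k7 = 2.903, k8 = 0.577, k9 = 0.753, k10 = 421.353,
  k11 = 0.211, k12 = 0.061, k13 = 12.152, k14 = 16.528, k15 = 0.088,
  kS = 9e-4, kalpha = 1.034,
  # Hill coefficient, thresholds [nM], PHD induction, FIH level, O2 force
  n2 = 2, xi28 = 38.44, xi4 = 15.018, xi44 = 128.022, xi10 = 8.127,
  Delta = 200, phi = 0.829, K_O2 = 0.96,
  # HIF-1 feedback constants on mTOR [nM]
  alpha1 = 1.163, alpha2 = 0.386,
  # inhibitor efficacies, all in [0,1]
  rho3 = 1.0, rho4 = 0.863, rho6 = 0.99, rho_rapa = 1.0, rho_nfkb = 1.0
)

#' Published parameterization of the HIF-1alpha network
#'
#' Builds the full parameter set of the ten-state regulatory network with the
#' published values, role flags and priors.  Basal activation of NF-kB, STAT3
#' and HIF-1alpha mRNA is zero (biological assumption); the IL-15 supply rate
#' `a1` and the STAT3 decay rate `d8` are *tied* by the steady-state
#' requirement on untreated cells (`a1 = 0`, `d8 = k8`) and are never free.
#' The 25 parameters estimated in the original calibration carry role
#' `"free"`; everything else is `"fixed"`.
#'
#' Priors default to the published values themselves with regularization
#' scale `lambda = 10 * |p0|`, i.e. a weak Tikhonov pull used only to
#' stabilize the least-squares problem.
#'
#' @param values optional named numeric vector overriding individual
#'   published values.
#' @return an object of class `hif_parameters`: a list with elements
#'   `values` (named numeric, all 50 symbols), `role` (named character,
#'   `"fixed"`, `"tied"` or `"free"`), `prior` and `lambda` (named numeric,
#'   for the free parameters).
#' @examples
#' p <- hif_parameters()
#' p$values[c("d1", "k4", "rho3")]
#' sum(p$role == "free")
#' @export
hif_parameters <- function(values = NULL) {
  v <- .published_values
  if (!is.null(values)) {
    bad <- setdiff(names(values), names(v))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    v[names(values)] <- values
  }
  role <- stats::setNames(rep("fixed", length(v)), names(v))
  role[.free_names] <- "free"
  role[c("a1", "d8")] <- "tied"
  p <- structure(
    list(values = v, role = role,
         prior  = v[.free_names],
         lambda = 10 * abs(v[.free_names])),
    class = "hif_parameters")
  resolve_ties(p)
}

#' Resolve steady-state parameter ties
#'
#' Enforces the algebraic tie implied by equilibrium of untreated cells,
#' `d8 = k8`; called by every constructor and before every model
#' evaluation.  The companion tie `a1 = 0` is the published *value* of the
#' IL-15 supply rate under the same equilibrium argument: `a1` defaults to
#' 0 and is never a free calibration parameter, but it may be set
#' explicitly (the external-regulation sweeps vary it deliberately), so it
#' is not overwritten here.
#'
#' @param params a `hif_parameters` object.
#' @return the object with ties applied.
#' @export
resolve_ties <- function(params) {
  stopifnot(inherits(params, "hif_parameters"))
  params$values[["d8"]] <- params$values[["k8"]]
  params
}

#' Validate a parameter set
#'
#' Checks non-negativity of all rates and thresholds and the `[0, 1]` range
#' of the inhibitor efficacies.
#'
#' @param params a `hif_parameters` object.
#' @return invisibly `TRUE`; signals an error describing each violated
#'   constraint otherwise.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "hif_parameters"))
  v <- params$values
  probs <- character(0)
  if (anyNA(v) || any(!is.finite(v)))
    probs <- c(probs, "non-finite parameter value")
  neg <- names(v)[v < 0]
  if (length(neg))
    probs <- c(probs, paste0("negative value for: ",
                             paste(neg, collapse = ", ")))
  eff <- v[.efficacy_names]
  out <- .efficacy_names[eff < 0 | eff > 1]
  if (length(out))
    probs <- c(probs, paste0("efficacy outside [0,1]: ",
                             paste(out, collapse = ", ")))
  if (length(probs)) stop(paste(probs, collapse = "; "))
  invisible(TRUE)
}

#' @export
print.hif_parameters <- function(x, ...) {
  cat("HIF-1alpha network parameter set (", length(x$values),
      " parameters)\n", sep = "")
  tab <- table(factor(x$role, levels = c("fixed", "tied", "free")))
  cat("  roles: ", paste(names(tab), tab, sep = " = ", collapse = ", "),
      "\n", sep = "")
  cat("  tied: a1 = 0, d8 = k8\n")
  invisible(x)
}

#' Update parameter values
#'
#' Returns a copy of `params` with the named values replaced and ties
#' re-resolved.
#'
#' @param params a `hif_parameters` object.
#' @param values named numeric vector of replacements.
#' @return the updated `hif_parameters` object.
#' @export
set_parameters <- function(params, values) {
  stopifnot(inherits(params, "hif_parameters"))
  bad <- setdiff(names(values), names(params$values))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  params$values[names(values)] <- values
  resolve_ties(params)
}

#' Names of the free parameters in the default calibration
#'
#' @param params a `hif_parameters` object.
#' @return character vector of parameter names with role `"free"`.
#' @export
free_parameters <- function(params) {
  names(params$role)[params$role == "free"]
}

#' Read / write parameter files
#'
#' Flat key--value YAML (or JSON) documents keyed by the symbol names, with
#' optional `role`, `prior` and `lambda` blocks.  `write_parameters()` emits
#' a document that `read_parameters()` round-trips.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_parameters()` returns a `hif_parameters` object.
#' @export
read_parameters <- function(path) {
  doc <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  p <- hif_parameters(values = unlist(doc$values))
  if (!is.null(doc$role))   p$role[names(doc$role)] <- unlist(doc$role)
  if (!is.null(doc$prior))  p$prior[names(doc$prior)] <- unlist(doc$prior)
  if (!is.null(doc$lambda)) p$lambda[names(doc$lambda)] <- unlist(doc$lambda)
  resolve_ties(p)
}

#' @rdname read_parameters
#' @param params a `hif_parameters` object to serialize.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "hif_parameters"))
  doc <- list(values = as.list(params$values),
              role   = as.list(params$role),
              prior  = as.list(params$prior),
              lambda = as.list(params$lambda))
  if (grepl("\\.json$", path))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(doc, path)
  invisible(path)
}
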