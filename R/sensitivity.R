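# Local sensitivity analysis and collinearity-based identifiability
# screening: which parameters can the measurement layout actually pin down?

#' Sensitivity (Jacobian) matrix of the weighted residuals
#'
#' Forward finite differences of the stacked weighted residual vector with
#' respect to the free parameters, on the original parameter scale
#' (relative step `1e-6`, absolute floor `1e-8`).  Rows are the measurement
#' residuals of all datasets followed by the active prior residuals; the
#' column order is the free-parameter order and is reported.
#'
#' @param params a `hif_parameters` object.
#' @param datasets a `hif_dataset` or list of them.
#' @param config a [pep_config()]; `NULL` for the defaults.
#' @return an object of class `hif_sensitivity`: list with `J` (the
#'   Jacobian, columns named by parameter), `free`, `singular_values` (of
#'   the column-scaled Jacobian, sorted decreasingly), and
#'   `collinearity_index` (reciprocal of the smallest singular value).
#' @export
sensitivity_matrix <- function(params, datasets, config = NULL) {
  if (inherits(datasets, "hif_dataset")) datasets <- list(datasets)
  params <- resolve_ties(params)
  config <- resolve_config(config, params)
  free <- config$free
  r0 <- stacked_residuals(params, datasets, config)
  J <- matrix(0, length(r0), length(free),
              dimnames = list(NULL, free))
  for (j in seq_along(free)) {
    p0 <- params$values[[free[[j]]]]
    h <- max(1e-6 * abs(p0), 1e-8)
    # step backwards when a forward step would leave an efficacy's [0,1]
    if (is_efficacy(free[[j]]) && p0 + h > 1) h <- -h
    pj <- set_parameters(params, stats::setNames(p0 + h, free[[j]]))
    J[, j] <- (stacked_residuals(pj, datasets, config) - r0) / h
  }
  sv <- svd(scale_columns(J))$d
  structure(list(J = J, free = free,
                 singular_values = sort(sv, decreasing = TRUE),
                 collinearity_index = 1 / min(sv)),
            class = "hif_sensitivity")
}

#' @export
print.hif_sensitivity <- function(x, ...) {
  cat("Sensitivity matrix:", nrow(x$J), "residuals x", ncol(x$J),
      "free parameters\n")
  cat("  singular values (column-scaled):",
      paste(signif(x$singular_values, 3), collapse = " "), "\n")
  cat("  collinearity index:", signif(x$collinearity_index, 4), "\n")
  invisible(x)
}

# scale columns to unit Euclidean norm (zero columns left untouched)
scale_columns <- function(J) {
  nrm <- sqrt(colSums(J^2))
  nz <- nrm > 0
  J[, nz] <- sweep(J[, nz, drop = FALSE], 2, nrm[nz], "/")
  J
}

#' Identifiability screen by singular-value thresholding
#'
#' Computes the singular value decomposition of the column-scaled
#' sensitivity matrix and greedily removes parameters while its smallest
#' singular value lies below the threshold: at each pass the parameter with
#' the largest weight in the singular vector of the smallest singular value
#' is fixed at its prior.  Parameters whose residual columns vanish
#' entirely are rejected first.
#'
#' @param x a `hif_sensitivity` (or a plain numeric Jacobian matrix with
#'   named columns).
#' @param threshold minimal acceptable singular value of the column-scaled
#'   Jacobian (default 0.1).
#' @return list with `estimable` and `fix` (character vectors partitioning
#'   the free set), `collinearity_before` and `collinearity_after`
#'   (reciprocal smallest singular values), and `threshold`.
#' @export
identifiability_screen <- function(x, threshold = 0.1) {
  J <- if (inherits(x, "hif_sensitivity")) x$J else as.matrix(x)
  if (is.null(colnames(J)))
    colnames(J) <- paste0("p", seq_len(ncol(J)))
  if (ncol(J) == 0 || nrow(J) == 0) stop("empty sensitivity matrix")
  keep <- colnames(J)
  fix <- character(0)
  # zero columns carry no information at all
  dead <- keep[colSums(J[, keep, drop = FALSE]^2) == 0]
  fix <- c(fix, dead)
  keep <- setdiff(keep, dead)
  ci_before <- {
    sv <- svd(scale_columns(J))$d
    if (min(sv) > 0) 1 / min(sv) else Inf
  }
  repeat {
    if (length(keep) == 0)
      stop("all parameter columns rejected at threshold ", threshold)
    dec <- svd(scale_columns(J[, keep, drop = FALSE]))
    smin <- min(dec$d)
    if (smin >= threshold) break
    vmin <- dec$v[, which.min(dec$d)]
    drop_idx <- which.max(abs(vmin))
    fix <- c(fix, keep[[drop_idx]])
    keep <- keep[-drop_idx]
  }
  ci_after <- 1 / min(svd(scale_columns(J[, keep, drop = FALSE]))$d)
  list(estimable = keep, fix = fix,
       collinearity_before = ci_before,
       collinearity_after = ci_after,
       threshold = threshold)
}
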