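# Treatment protocols and their translation into effective model inputs.
#
# A protocol is an ordered list of events (time, agent, dose fraction).
# IL-15 events are impulses: the dose is added to y1 at the event time
# (primed cells correspond to an IL-15 impulse of 1 at t = 0).  All other
# agents switch a persistent condition on: the most recent dose for an agent
# is the active one, and a dose of 0 switches the agent off.

.agents <- c("IL15", "DMOG", "RAPAMYCIN", "S3I201", "NFKB_INHIBITOR")

#' Construct a treatment protocol
#'
#' @param events a data frame with columns `time_h` (hours, `>= 0`),
#'   `agent` (one of `"IL15"`, `"DMOG"`, `"RAPAMYCIN"`, `"S3I201"`,
#'   `"NFKB_INHIBITOR"`) and `dose_fraction` (in `[0, 1]`; for DMOG a dose
#'   fraction of 1 corresponds to 20 uM).  `NULL` or zero rows means
#'   untreated.
#' @param horizon length of the experiment in hours.
#' @return an object of class `hif_protocol`.
#' @examples
#' # IL-15 priming at t = 0 plus DMOG from t = 6 h
#' hif_protocol(data.frame(time_h = c(0, 6),
#'                         agent = c("IL15", "DMOG"),
#'                         dose_fraction = c(1, 1)), horizon = 30)
#' @export
hif_protocol <- function(events = NULL, horizon = 100) {
  if (is.null(events) || NROW(events) == 0)
    events <- data.frame(time_h = numeric(0), agent = character(0),
                         dose_fraction = numeric(0))
  stopifnot(is.data.frame(events),
            all(c("time_h", "agent", "dose_fraction") %in% names(events)))
  events <- events[c("time_h", "agent", "dose_fraction")]
  events$agent <- as.character(events$agent)
  if (!all(events$agent %in% .agents))
    stop("unknown agent(s): ",
         paste(setdiff(events$agent, .agents), collapse = ", "))
  if (any(events$time_h < 0) || any(events$time_h > horizon))
    stop("event times must lie within [0, horizon]")
  if (any(events$dose_fraction < 0) || any(events$dose_fraction > 1))
    stop("dose fractions must lie in [0, 1]")
  events <- events[order(events$time_h), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, horizon = horizon),
            class = "hif_protocol")
}

#' @export
print.hif_protocol <- function(x, ...) {
  cat("Treatment protocol over", x$horizon, "h\n")
  if (nrow(x$events) == 0) cat("  (untreated)\n") else print(x$events)
  invisible(x)
}

#' Common treatment protocols
#'
#' Convenience constructor for the protocols used throughout: IL-15 priming
#' is an impulse at `il15_at` (dose `il15_dose`), the other agents switch on
#' at the given onset times and stay active.  `NA` onset omits the agent.
#'
#' @param il15_at,dmog_at,rapamycin_at,s3i_at,nfkbi_at onset times in hours
#'   (`NA` = agent not used).
#' @param il15_dose,dmog_dose dose fractions in `[0, 1]`.
#' @param horizon experiment length in hours.
#' @return a `hif_protocol`.
#' @export
protocol_standard <- function(il15_at = NA, dmog_at = NA, rapamycin_at = NA,
                              s3i_at = NA, nfkbi_at = NA,
                              il15_dose = 1, dmog_dose = 1, horizon = 100) {
  on <- c(IL15 = il15_at, DMOG = dmog_at, RAPAMYCIN = rapamycin_at,
          S3I201 = s3i_at, NFKB_INHIBITOR = nfkbi_at)
  dose <- c(IL15 = il15_dose, DMOG = dmog_dose, RAPAMYCIN = 1,
            S3I201 = 1, NFKB_INHIBITOR = 1)
  keep <- !is.na(on)
  ev <- data.frame(time_h = unname(on[keep]), agent = names(on)[keep],
                   dose_fraction = unname(dose[keep]))
  hif_protocol(ev, horizon = horizon)
}

# active (most recent) dose of a persistent agent at time t; IL-15 excluded
active_dose <- function(protocol, agent, t) {
  ev <- protocol$events
  ev <- ev[ev$agent == agent & ev$time_h <= t, , drop = FALSE]
  if (nrow(ev) == 0) return(0)
  ev$dose_fraction[[nrow(ev)]]
}

#' Effective model inputs under a protocol
#'
#' Maps the active treatments at time `t` into the five multiplicative
#' scale factors applied inside the right-hand side:
#' \describe{
#'   \item{hydroxylation_scale}{`1 - rho6 * dose_DMOG(t)`, multiplying the
#'     three oxygen-dependent hydroxylation fluxes (FIH and PHD).  Linear in
#'     the DMOG dose; dose 1 corresponds to 20 uM.}
#'   \item{stat3_il15_scale}{`1 - rho4` while DMOG is active (all-or-nothing),
#'     multiplying the IL-15 -> STAT3 activation term `k6 * y1`.}
#'   \item{stat3_block_scale}{`1 - rho3` while S3I-201 is active, multiplying
#'     the whole STAT3 activation input.}
#'   \item{mtor_block_scale}{`1 - rho_rapa` while rapamycin is active,
#'     multiplying the mTOR activation input `a3 + k2 * y2`.}
#'   \item{nfkb_block_scale}{`1 - rho_nfkb` while the NF-kB inhibitor is
#'     active, multiplying all NF-kB activation inputs.}
#' }
#' All factors equal 1 when no agent is active.
#'
#' @param params a `hif_parameters` object (supplies the efficacies).
#' @param protocol a `hif_protocol`.
#' @param t time in hours, inside `[0, horizon]`.
#' @return named numeric vector of the five scale factors, each in `[0, 1]`.
#' @export
effective_inputs <- function(params, protocol, t) {
  stopifnot(inherits(params, "hif_parameters"),
            inherits(protocol, "hif_protocol"))
  if (t < 0 || t > protocol$horizon)
    stop("time ", t, " outside protocol horizon [0, ", protocol$horizon, "]")
  v <- params$values
  dmog <- active_dose(protocol, "DMOG", t)
  c(hydroxylation_scale = 1 - v[["rho6"]] * dmog,
    stat3_il15_scale = if (dmog > 0) 1 - v[["rho4"]] else 1,
    stat3_block_scale =
      if (active_dose(protocol, "S3I201", t) > 0) 1 - v[["rho3"]] else 1,
    mtor_block_scale =
      if (active_dose(protocol, "RAPAMYCIN", t) > 0) 1 - v[["rho_rapa"]]
      else 1,
    nfkb_block_scale =
      if (active_dose(protocol, "NFKB_INHIBITOR", t) > 0) 1 - v[["rho_nfkb"]]
      else 1)
}

#' Read / write protocol files
#'
#' YAML (or JSON) list of `{time_h, agent, dose_fraction}` records plus a
#' `horizon` field.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return `read_protocol()` returns a `hif_protocol`.
#' @export
read_protocol <- function(path) {
  doc <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  ev <- doc$events
  if (is.list(ev) && !is.data.frame(ev)) {
    # yaml serializes a data frame as a named list of columns, and a list
    # of event records as an unnamed list of rows; accept both
    ev <- if (!is.null(names(ev))) as.data.frame(ev)
          else do.call(rbind, lapply(ev, as.data.frame))
  }
  hif_protocol(ev, horizon = doc$horizon)
}

#' @rdname read_protocol
#' @param protocol a `hif_protocol` to serialize.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "hif_protocol"))
  doc <- list(horizon = protocol$horizon,
              events = protocol$events)
  if (grepl("\\.json$", path))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(doc, path)
  invisible(path)
}
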