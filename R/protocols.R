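# Timed perturbation protocols encoding the in-silico experiments:
# siRNA-style cyclin knockdowns, Emi1 depletion, and Cdk2 inhibition.

#' Construct a perturbation protocol
#'
#' A protocol is an ordered list of instantaneous events applied during a
#' simulation. Each event scales or sets a parameter or a species level at a
#' given time; engines stop and restart the integration (or the stochastic
#' path) at every event time, so parameter values are piecewise constant and
#' the state is continuous across events.
#'
#' @param events data.frame with columns \code{time_h} (>= 0),
#'   \code{action} (one of \code{scale_parameter}, \code{set_parameter},
#'   \code{scale_species}, \code{set_species}), \code{target} (name) and
#'   \code{value} (factor or level, >= 0).
#' @param label free-text protocol label.
#' @return object of class \code{g1s_protocol}.
#' @export
perturbation_protocol <- function(events, label = "") {
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(time_h = numeric(0), action = character(0),
                         target = character(0), value = numeric(0))
  }
  need <- c("time_h", "action", "target", "value")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("protocol events missing column(s): ",
                         paste(miss, collapse = ", "))
  events <- events[need]
  ok <- c("scale_parameter", "set_parameter", "scale_species", "set_species")
  if (!all(events$action %in% ok))
    stop("unknown protocol action(s): ",
         paste(setdiff(events$action, ok), collapse = ", "))
  if (any(events$time_h < 0)) stop("protocol event times must be >= 0")
  if (any(events$value < 0)) stop("protocol factors/values must be >= 0")
  events <- events[order(events$time_h), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, label = label), class = "g1s_protocol")
}

#' @export
print.g1s_protocol <- function(x, ...) {
  cat("Perturbation protocol", if (nzchar(x$label)) paste0("'", x$label, "'"),
      "with", nrow(x$events), "event(s)\n")
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Compose protocols
#'
#' Concatenates the event lists and re-sorts by time. Engines produce
#' identical results for a pre-composed protocol and for the same events
#' supplied separately.
#'
#' @param ... \code{g1s_protocol} objects.
#' @param label label of the composite.
#' @return a \code{g1s_protocol}.
#' @export
compose_protocols <- function(..., label = "composite") {
  ps <- list(...)
  ev <- do.call(rbind, lapply(ps, function(p) p$events))
  perturbation_protocol(ev, label = label)
}

#' CyclinE knockdown protocol
#'
#' siRNA-style depletion acting on the CyclinE mRNA: residual synthesis and
#' accelerated mRNA degradation, both applied at time zero. Defaults are 5
#' percent residual synthesis with a 20-fold increase in mRNA degradation
#' rate.
#'
#' @param residual_synthesis fraction of synthesis remaining, in [0, 1].
#' @param mrna_deg_fold fold increase of mRNA degradation, >= 1.
#' @return a \code{g1s_protocol}.
#' @export
cyclinE_knockdown <- function(residual_synthesis = 0.05, mrna_deg_fold = 20) {
  if (residual_synthesis < 0 || residual_synthesis > 1)
    stop("residual_synthesis must be in [0, 1]")
  if (mrna_deg_fold < 1) stop("mrna_deg_fold must be >= 1")
  perturbation_protocol(data.frame(
    time_h = c(0, 0),
    action = "scale_parameter",
    target = c("ks_me", "kd_me"),
    value = c(residual_synthesis, mrna_deg_fold)),
    label = "cyclinE_knockdown")
}

#' CyclinA knockdown protocol
#'
#' As \code{\link{cyclinE_knockdown}}, acting on the CyclinA mRNA.
#'
#' @inheritParams cyclinE_knockdown
#' @return a \code{g1s_protocol}.
#' @export
cyclinA_knockdown <- function(residual_synthesis = 0.05, mrna_deg_fold = 20) {
  if (residual_synthesis < 0 || residual_synthesis > 1)
    stop("residual_synthesis must be in [0, 1]")
  if (mrna_deg_fold < 1) stop("mrna_deg_fold must be >= 1")
  perturbation_protocol(data.frame(
    time_h = c(0, 0),
    action = "scale_parameter",
    target = c("ks_ma", "kd_ma"),
    value = c(residual_synthesis, mrna_deg_fold)),
    label = "cyclinA_knockdown")
}

#' Emi1 depletion protocol
#'
#' At \code{t_deplete} hours, both the Emi1 level and its synthesis rate are
#' reduced by \code{fraction} (default 90 percent). Applied to an S-phase
#' initial state this reactivates APC/C-Cdh1, collapses CyclinA and Skp2,
#' and lets p27 and CyclinE re-accumulate, transiently resetting the cell to
#' a G1-like state.
#'
#' @param t_deplete depletion time in hours (default 5).
#' @param fraction fraction removed, in [0, 1] (default 0.9).
#' @return a \code{g1s_protocol}.
#' @export
emi1_depletion <- function(t_deplete = 5, fraction = 0.9) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  perturbation_protocol(data.frame(
    time_h = t_deplete,
    action = c("scale_species", "scale_parameter"),
    target = c("emi1", "ks_emi1"),
    value = 1 - fraction),
    label = "emi1_depletion")
}

#' Cdk2 inhibition protocol
#'
#' Models a small-molecule Cdk1/2 inhibitor as a scaling of all
#' Cdk2-catalysed rate constants (p27 T187 phosphorylation, Cdh1
#' phosphorylation, CyclinE phospho-degradation) from \code{t_start}
#' onwards. The drug blocks kinase activity, not cyclin binding, so
#' complexes are left intact.
#'
#' @param t_start inhibition start time in hours.
#' @param efficiency fraction of catalytic activity removed, in [0, 1]
#'   (default 1 = complete inhibition).
#' @return a \code{g1s_protocol}.
#' @export
cdk_inhibition <- function(t_start = 0, efficiency = 1) {
  if (efficiency < 0 || efficiency > 1) stop("efficiency must be in [0, 1]")
  f <- 1 - efficiency
  perturbation_protocol(data.frame(
    time_h = t_start,
    action = "scale_parameter",
    target = c("kphos_p27", "ki_cdh1_cdk2", "kd_e_cdk2"),
    value = f),
    label = "cdk_inhibition")
}

#' S-phase initial state from the control trajectory
#'
#' Samples the deterministic control simulation at the first time after the
#' G1/S transition where total CyclinA exceeds total CyclinE: CyclinA
#' increasing, CyclinE decreasing, p27 low.
#'
#' @param network a \code{g1s_network}.
#' @param params a \code{g1s_parameters}.
#' @param t_end length of the control simulation used (hours).
#' @return named state vector.
#' @export
sphase_arrest_state <- function(network, params, t_end = 20) {
  traj <- simulate_ode(network, params, t_end = t_end)
  g1s <- detect_g1s(traj)
  if (is.na(g1s)) stop("control trajectory shows no G1/S transition")
  cycA <- series(traj, "cyclinA_total")
  cycE <- series(traj, "cyclinE_total")
  i <- which(traj$time > g1s & cycA > cycE)[1]
  if (is.na(i)) stop("CyclinA never exceeds CyclinE after G1/S; extend t_end")
  st <- traj$species[i, ]
  names(st) <- colnames(traj$species)
  st
}
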