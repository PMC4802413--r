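# Deterministic (ODE) engine and in-silico G1/S event detection.

#' Construct a trajectory object
#' @keywords internal
new_trajectory <- function(time, species_mat, params, network, protocol = NULL,
                           engine = "ode", seed = NULL, settings = list()) {
  obs <- list()
  if (all(c("cycE", "cycA") %in% colnames(species_mat)) &&
      all(c("w_e", "w_a") %in% names(params$value)))
    obs$cdk2_activity <- cdk2_activity(species_mat, params)
  for (ob in names(network$observables)) {
    w <- network$observables[[ob]]
    obs[[ob]] <- as.numeric(species_mat[, names(w), drop = FALSE] %*% w)
  }
  structure(list(time = time, species = species_mat, observables = obs,
                 protocol = protocol, engine = engine, seed = seed,
                 settings = settings),
            class = "g1s_trajectory")
}

#' @export
print.g1s_trajectory <- function(x, ...) {
  cat(sprintf("G1/S trajectory (%s engine): %d time points, t in [%g, %g] h\n",
              x$engine, length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' @export
as.data.frame.g1s_trajectory <- function(x, ...) {
  sp <- colnames(x$species)
  long <- data.frame(
    time_h = rep(x$time, times = length(sp)),
    species = rep(sp, each = length(x$time)),
    value = as.vector(x$species))
  for (ob in names(x$observables)) {
    long <- rbind(long, data.frame(time_h = x$time, species = ob,
                                   value = x$observables[[ob]]))
  }
  long
}

#' Extract a time series from a trajectory
#'
#' @param traj a \code{g1s_trajectory}.
#' @param name a species or observable name (e.g. \code{"p27_total"},
#'   \code{"cdk2_activity"}).
#' @return numeric vector aligned with \code{traj$time}.
#' @export
series <- function(traj, name) {
  if (name %in% colnames(traj$species)) return(traj$species[, name])
  if (name %in% names(traj$observables)) return(traj$observables[[name]])
  stop("no species or observable named '", name, "'")
}

#' Default post-mitotic (early G1) state
#'
#' The state of a newborn HeLa cell: p27 absent after cell division, CyclinA
#' degraded by the still-active APC/C-Cdh1, CyclinE low, Emi1 and Skp2 low,
#' mRNAs near steady state, E2F constitutively active.
#'
#' @return named numeric state vector (a.u.).
#' @export
default_postmitotic_state <- function() {
  c(cyclinE_mRNA = 1, cyclinA_mRNA = 1, cycE = 0.01, cycA = 0,
    p27 = 0, p27_cycE = 0, p27_cycA = 0, p27_T187p = 0,
    emi1 = 0.02, skp2 = 0.05, cdh1_active = 1, e2f_active = 1)
}

# split [0, t_end] into protocol segments; returns list of
# (t0, t1, events-at-t0) with events sorted
protocol_segments <- function(protocol, t_end) {
  if (is.null(protocol) || nrow(protocol$events) == 0)
    return(list(list(t0 = 0, t1 = t_end, events = NULL)))
  ev <- protocol$events
  if (any(ev$time_h < 0 | ev$time_h > t_end))
    stop("protocol event time outside [0, t_end]")
  ev <- ev[order(ev$time_h), , drop = FALSE]
  times <- sort(unique(ev$time_h))
  bounds <- unique(c(0, times, t_end))
  segs <- list()
  for (i in seq_len(length(bounds) - 1)) {
    at <- ev[ev$time_h == bounds[i], , drop = FALSE]
    segs[[i]] <- list(t0 = bounds[i], t1 = bounds[i + 1],
                      events = if (nrow(at)) at else NULL)
  }
  # events exactly at t_end still applied (zero-length final segment)
  if (any(ev$time_h == t_end))
    segs[[length(segs) + 1]] <- list(t0 = t_end, t1 = t_end,
                                     events = ev[ev$time_h == t_end, ,
                                                 drop = FALSE])
  segs
}

apply_events <- function(events, state, params) {
  if (is.null(events)) return(list(state = state, params = params))
  for (i in seq_len(nrow(events))) {
    act <- events$action[i]; tg <- events$target[i]; v <- events$value[i]
    if (act %in% c("scale_parameter", "set_parameter")) {
      if (!tg %in% names(params$value))
        stop("protocol targets unknown parameter '", tg, "'")
      params$value[[tg]] <- if (act == "scale_parameter")
        params$value[[tg]] * v else v
    } else if (act %in% c("scale_species", "set_species")) {
      if (!tg %in% names(state))
        stop("protocol targets unknown species '", tg, "'")
      state[[tg]] <- if (act == "scale_species") state[[tg]] * v else v
    } else stop("unknown protocol action '", act, "'")
  }
  list(state = state, params = params)
}

#' Integrate a reaction network deterministically
#'
#' Solves the initial-value problem for any \code{g1s_network} with a
#' stiff-capable integrator (\code{deSolve::lsoda}). Timed protocol events
#' are applied as instantaneous parameter or state changes, with the
#' integration stopped and restarted at each event time (no smoothing).
#' Negative undershoots within the integrator tolerance are clipped to zero
#' in the reported trajectory; larger undershoots raise an error.
#'
#' @param network a \code{g1s_network}.
#' @param params a \code{g1s_parameters}.
#' @param init named nonnegative state vector; defaults to
#'   \code{default_postmitotic_state()} for the core network.
#' @param t_end end time (hours, > 0).
#' @param protocol optional \code{g1s_protocol} of timed events.
#' @param grid_dt output grid spacing in hours (default 0.05).
#' @param rtol,atol relative/absolute integrator tolerances.
#' @return a \code{g1s_trajectory}.
#' @export
simulate_ode <- function(network, params, init = default_postmitotic_state(),
                         t_end = 15, protocol = NULL, grid_dt = 0.05,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(t_end > 0)
  comp <- compiled(network, params)
  init <- state_vector(init, comp$species)
  if (any(init < 0)) stop("initial state has negative species levels")
  tri <- which(comp$stoich != 0, arr.ind = TRUE)
  tri_sp <- as.integer(tri[, 1] - 1L)
  tri_rx <- as.integer(tri[, 2] - 1L)
  tri_coef <- comp$stoich[tri]
  pv_template <- params
  segs <- protocol_segments(protocol, t_end)
  grid <- seq(0, t_end, by = grid_dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  times_all <- numeric(0)
  mat_all <- NULL
  state <- init
  par_now <- pv_template
  for (seg in segs) {
    ae <- apply_events(seg$events, stats::setNames(state, comp$species), par_now)
    state <- state_vector(ae$state, comp$species)
    par_now <- ae$params
    if (seg$t1 <= seg$t0) next
    pv <- unname(par_now$value[comp$param_names])
    rhs <- function(t, y, parms) {
      list(deriv_cpp(comp$ops, comp$args, comp$consts, comp$offsets,
                     tri_rx, tri_sp, tri_coef, comp$n_species, y, parms))
    }
    seg_grid <- grid[grid >= seg$t0 & grid <= seg$t1]
    tms <- sort(unique(c(seg$t0, seg_grid, seg$t1)))
    sol <- deSolve::lsoda(y = state, times = tms, func = rhs, parms = pv,
                          rtol = rtol, atol = atol, maxsteps = 100000)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("ODE integrator failed; last valid time %.4f h",
                   max(sol[, 1])))
    keep <- sol[, 1] %in% seg_grid
    # avoid duplicating the segment boundary point
    if (length(times_all) && any(sol[keep, 1] == times_all[length(times_all)]))
      keep <- keep & sol[, 1] != times_all[length(times_all)]
    times_all <- c(times_all, sol[keep, 1])
    mat_all <- rbind(mat_all, sol[keep, -1, drop = FALSE])
    state <- as.numeric(sol[nrow(sol), -1])
  }
  undershoot <- min(mat_all)
  if (undershoot < -1e3 * atol - 1e-8)
    stop(sprintf("species went negative beyond tolerance (min %.3g)",
                 undershoot))
  mat_all[mat_all < 0] <- 0
  colnames(mat_all) <- comp$species
  new_trajectory(times_all, mat_all, par_now, network, protocol,
                 engine = "ode", seed = NULL,
                 settings = list(grid_dt = grid_dt, rtol = rtol, atol = atol))
}

#' Detect the in-silico G1/S transition time
#'
#' Operational definition: the first time total p27 crosses 50 percent of its
#' running maximum on a downward trajectory and stays below that level for at
#' least \code{persist} hours. Experimentally G1/S is called from the sharp
#' PCNA increase; in the model the two coincide because p27 is degraded
#' immediately prior to S-phase entry.
#'
#' @param traj a \code{g1s_trajectory} (must carry \code{p27_total}).
#' @param persist persistence window in hours rejecting noise-induced
#'   crossings (default 1).
#' @return crossing time in hours, or \code{NA_real_} if no switch occurs.
#' @export
detect_g1s <- function(traj, persist = 1) {
  p <- series(traj, "p27_total")
  tt <- traj$time
  rm <- cummax(p)
  thr <- 0.5 * rm
  below <- p < thr
  cand <- which(below)
  if (!length(cand)) return(NA_real_)
  starts <- cand[c(TRUE, diff(cand) > 1)]
  for (i0 in starts) {
    level <- thr[i0]
    t0 <- tt[i0]
    win <- tt >= t0 & tt <= t0 + persist
    if (all(p[win] < level) && (max(tt) >= t0 + persist || i0 == length(tt))) {
      # linear interpolation of the crossing between i0-1 and i0
      if (i0 > 1 && p[i0 - 1] > level) {
        f <- (p[i0 - 1] - level) / (p[i0 - 1] - p[i0])
        return(tt[i0 - 1] + f * (tt[i0] - tt[i0 - 1]))
      }
      return(t0)
    }
  }
  NA_real_
}

#' Abruptness of the p27 switch
#'
#' Time for total p27 to fall from 80 percent to 20 percent of its maximum,
#' measured after the maximum (linear interpolation between grid points).
#'
#' @param traj a \code{g1s_trajectory}.
#' @return duration in hours, or \code{NA_real_} if p27 never falls below 20
#'   percent of its maximum.
#' @export
switch_abruptness <- function(traj) {
  p <- series(traj, "p27_total")
  tt <- traj$time
  imax <- which.max(p)
  pmax <- p[imax]
  if (pmax <= 0) return(NA_real_)
  cross_down <- function(level) {
    if (imax >= length(p)) return(NA_real_)
    for (i in imax:(length(p) - 1)) {
      if (p[i] >= level && p[i + 1] < level) {
        f <- (p[i] - level) / (p[i] - p[i + 1])
        return(tt[i] + f * (tt[i + 1] - tt[i]))
      }
    }
    NA_real_
  }
  t80 <- if (p[imax] < 0.8 * pmax) tt[imax] else cross_down(0.8 * pmax)
  t20 <- cross_down(0.2 * pmax)
  if (is.na(t80) || is.na(t20)) return(NA_real_)
  t20 - t80
}
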