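# Steady-state analysis: Z-shaped p27 diagrams, saddle-node thresholds,
# hysteresis, and Emi1-dependent threshold curves.
#
# The scanned cyclin enters as a conserved moiety: reactions that change the
# total (synthesis, cyclin degradation) are removed, binding/unbinding and
# p27 exchange remain, and the free form is eliminated through the
# conservation relation free = total - bound. Roots of the reduced
# derivative field are located by damped multi-start Newton iteration with a
# finite-difference Jacobian; stability comes from its eigenvalues. An
# independent forward-relaxation sweep (up-scan/down-scan) serves as an
# oracle for the same thresholds.

moiety_members <- function(scan_species) {
  switch(scan_species,
         cyclinE = c(free = "cycE", bound = "p27_cycE"),
         cyclinA = c(free = "cycA", bound = "p27_cycA"),
         stop("scan_species must be 'cyclinE' or 'cyclinA'"))
}

#' Clamp species of a network
#'
#' Returns a network in which the clamped species are held constant: their
#' stoichiometric entries are removed (their own balance is zero) while they
#' still appear in rate laws as modifiers. The clamped levels themselves are
#' supplied through the initial state of whatever computation consumes the
#' returned network.
#'
#' @param network a \code{g1s_network}.
#' @param clamped character vector of species names to clamp.
#' @return a \code{g1s_network}.
#' @export
clamped_subnetwork <- function(network, clamped) {
  bad <- setdiff(clamped, network$species)
  if (length(bad)) stop("cannot clamp undeclared species: ",
                        paste(bad, collapse = ", "))
  net <- network
  net$.compiled <- NULL
  net$reactions <- lapply(network$reactions, function(rx) {
    rx$stoich <- rx$stoich[!(names(rx$stoich) %in% clamped)]
    rx
  })
  net$reactions <- Filter(function(rx) length(rx$stoich) > 0, net$reactions)
  if (length(net$reactions) == 0)
    stop("clamping removed every reaction; empty network")
  net$clamped <- union(network$clamped, clamped)
  net
}

# network for a conserved-moiety scan: remove reactions changing the scanned
# cyclin total, clamp everything extrinsic to the switch
scan_network <- function(network, scan_species,
                         clamps = c(emi1 = 0.05),
                         keep_dynamic = character()) {
  mem <- moiety_members(scan_species)
  keep <- vapply(network$reactions, function(rx) {
    idx <- intersect(names(rx$stoich), mem)
    length(idx) == 0 || sum(rx$stoich[idx]) == 0
  }, logical(1))
  net <- network
  net$.compiled <- NULL
  net$reactions <- network$reactions[keep]
  other <- moiety_members(setdiff(c("cyclinE", "cyclinA"), scan_species))
  clamp_sp <- setdiff(
    unique(c(names(clamps), other, "cyclinE_mRNA", "cyclinA_mRNA",
             "e2f_active")),
    keep_dynamic)
  net <- clamped_subnetwork(net, clamp_sp)
  attr(net, "scan") <- list(species = scan_species, members = mem,
                            clamps = clamps, other = other)
  net
}

scan_base_state <- function(network, params, total, clamps) {
  st <- stats::setNames(rep(0, length(network$species)), network$species)
  if ("e2f_active" %in% network$species) st[["e2f_active"]] <- 1
  st[names(clamps)] <- clamps
  sc <- attr(network, "scan")
  st[[sc$members[["free"]]]] <- total
  st
}

# reduced residual/assembly closures for root finding
reduced_system <- function(network, params, total, clamps) {
  comp <- compile_network(network, params)
  sc <- attr(network, "scan")
  base <- state_vector(scan_base_state(network, params, total, clamps),
                       comp$species)
  active <- which(rowSums(abs(comp$stoich)) > 0)
  dep <- match(sc$members[["free"]], comp$species)
  bnd <- match(sc$members[["bound"]], comp$species)
  free <- setdiff(active, dep)
  tri <- which(comp$stoich != 0, arr.ind = TRUE)
  tri_sp <- as.integer(tri[, 1] - 1L); tri_rx <- as.integer(tri[, 2] - 1L)
  tri_coef <- comp$stoich[tri]
  pv <- unname(params$value[comp$param_names])
  assemble <- function(y) {
    x <- base
    x[free] <- pmax(y, 0)
    x[bnd] <- min(max(x[bnd], 0), total)
    x[dep] <- total - x[bnd]
    x
  }
  fn <- function(y) {
    x <- assemble(y)
    d <- deriv_cpp(comp$ops, comp$args, comp$consts, comp$offsets,
                   tri_rx, tri_sp, tri_coef, comp$n_species, x, pv)
    d[free]
  }
  list(fn = fn, assemble = assemble, free = free, species = comp$species,
       comp = comp, bound_index = match(bnd, free))
}

num_jacobian <- function(fn, y, h_rel = 1e-7) {
  f0 <- fn(y)
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- h_rel * max(1, abs(y[j]))
    yp <- y; yp[j] <- yp[j] + h
    ym <- y; ym[j] <- max(yp[j] - 2 * h, 0)
    hh <- yp[j] - ym[j]
    J[, j] <- (fn(yp) - fn(ym)) / hh
  }
  J
}

damped_newton <- function(fn, y0, tol = 1e-11, maxit = 80) {
  y <- y0
  f <- fn(y)
  for (it in seq_len(maxit)) {
    if (max(abs(f)) < tol) return(y)
    J <- num_jacobian(fn, y)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      y1 <- pmax(y - lam * step, 0)
      f1 <- fn(y1)
      if (all(is.finite(f1)) &&
          (max(abs(f1)) < max(abs(f)) || max(abs(f1)) < tol)) break
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
    y <- y1; f <- f1
  }
  if (max(abs(f)) < 1e-8) y else NULL
}

# deterministic multi-start grid for the scan system
scan_starts <- function(params, total) {
  cap <- params$value[["ks_p27"]] / params$value[["kd_p27"]]
  p27s <- c(0.002, 0.5 * cap, 1.6 * cap)
  bounds <- unique(pmin(c(0, 0.5, 0.98) * total, total))
  cdh1s <- c(0.02, 0.98)
  starts <- list()
  for (pp in p27s) for (bb in bounds) for (cc in cdh1s)
    starts[[length(starts) + 1]] <- c(p27 = pp, bound = bb, cdh1 = cc)
  starts
}

#' Steady states of a clamped scan system
#'
#' Locates all steady states of the p27 switch at one clamped level of the
#' scanned cyclin total, by damped Newton iteration from a deterministic
#' grid of initial guesses, de-duplicated at an absolute tolerance of 1e-6
#' a.u. Stability is classified from the eigenvalues of the
#' finite-difference Jacobian of the reduced system; eigenvalues with real
#' part within 1e-9 of zero are flagged marginal.
#'
#' @param network a \code{g1s_network} (the canonical G1/S network).
#' @param params a \code{g1s_parameters}.
#' @param total clamped total of the scanned cyclin (a.u.).
#' @param scan_species \code{"cyclinE"} or \code{"cyclinA"}.
#' @param clamps named vector of additional clamped species levels
#'   (default clamps Emi1 low).
#' @return data.frame with one row per steady state: \code{p27_total},
#'   \code{p27_free}, \code{stability} ("stable"/"unstable"), \code{marginal},
#'   plus one column per reduced-system species.
#' @export
steady_states <- function(network, params, total, scan_species = "cyclinE",
                          clamps = c(emi1 = 0.05)) {
  net <- if (is.null(attr(network, "scan")))
    scan_network(network, scan_species, clamps) else network
  rs <- reduced_system(net, params, total, clamps)
  roots <- list()
  for (s0 in scan_starts(params, total)) {
    y0 <- numeric(length(rs$free))
    names(y0) <- rs$species[rs$free]
    y0["p27"] <- s0[["p27"]]
    if (!is.na(rs$bound_index)) y0[rs$bound_index] <- s0[["bound"]]
    if ("cdh1_active" %in% names(y0)) y0["cdh1_active"] <- s0[["cdh1"]]
    if ("skp2" %in% names(y0)) {
      c_ <- s0[["cdh1"]]
      y0["skp2"] <- params$value[["ks_skp2"]] /
        (params$value[["kd_skp2"]] + params$value[["kd_skp2_cdh1"]] * c_)
    }
    y <- damped_newton(rs$fn, y0)
    if (is.null(y)) next
    dup <- any(vapply(roots, function(r) max(abs(r - y)) < 1e-6, logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- y
  }
  # relaxation-seeded starts guarantee at least the stable attractors are
  # found even where the plain Newton grid stalls
  cap <- params$value[["ks_p27"]] / params$value[["kd_p27"]]
  for (branch in c("high", "low")) {
    st <- scan_base_state(net, params, total, clamps)
    st[["p27"]] <- if (branch == "high") 1.5 * cap else 0
    if ("cdh1_active" %in% names(st))
      st[["cdh1_active"]] <- if (branch == "high") 0.99 else 0.02
    if ("skp2" %in% names(st))
      st[["skp2"]] <- if (branch == "high") 0.05 else 1
    tr <- simulate_ode(net, params, init = st, t_end = 120, grid_dt = 30,
                       rtol = 1e-10, atol = 1e-12)
    yr <- tr$species[nrow(tr$species), rs$free]
    y <- damped_newton(rs$fn, yr)
    if (is.null(y) && max(abs(rs$fn(yr))) < 1e-7) y <- yr
    if (!is.null(y) &&
        !any(vapply(roots, function(r) max(abs(r - y)) < 1e-6, logical(1))))
      roots[[length(roots) + 1]] <- y
  }
  if (!length(roots)) stop("steady-state search failed from every start")
  rows <- lapply(roots, function(y) {
    x <- rs$assemble(y)
    names(x) <- rs$species
    J <- num_jacobian(rs$fn, y)
    ev <- eigen(J, only.values = TRUE)$values
    mre <- max(Re(ev))
    data.frame(p27_total = x[["p27"]] + x[["p27_cycE"]] + x[["p27_cycA"]] +
                 x[["p27_T187p"]],
               p27_free = x[["p27"]],
               stability = if (mre < 0) "stable" else "unstable",
               marginal = abs(mre) < 1e-9,
               max_re_eigenvalue = mre,
               t(x))
  })
  out <- do.call(rbind, rows)
  out[order(-out$p27_total), , drop = FALSE]
}

count_stable <- function(ss) sum(ss$stability == "stable")

#' Generic steady-state search for any network
#'
#' Multi-start damped Newton root finding of \code{derivatives = 0} over the
#' dynamic species of an arbitrary network (species without any remaining
#' stoichiometric entry are held at their \code{base_state} level). No
#' conservation handling: intended for clamped subsystems and small test
#' networks; use \code{\link{steady_states}} for the conserved-moiety cyclin
#' scans.
#'
#' @param network a \code{g1s_network}.
#' @param params a \code{g1s_parameters}.
#' @param base_state named state vector supplying clamped/inactive species.
#' @param starts list of named numeric vectors (partial states: named
#'   entries override \code{base_state} for the dynamic species).
#' @return data.frame: one row per distinct root with stability columns and
#'   one column per species.
#' @export
find_steady_states <- function(network, params, base_state, starts) {
  comp <- compile_network(network, params)
  base <- state_vector(base_state, comp$species)
  active <- which(rowSums(abs(comp$stoich)) > 0)
  tri <- which(comp$stoich != 0, arr.ind = TRUE)
  tri_sp <- as.integer(tri[, 1] - 1L); tri_rx <- as.integer(tri[, 2] - 1L)
  tri_coef <- comp$stoich[tri]
  pv <- unname(params$value[comp$param_names])
  fn <- function(y) {
    x <- base
    x[active] <- pmax(y, 0)
    d <- deriv_cpp(comp$ops, comp$args, comp$consts, comp$offsets,
                   tri_rx, tri_sp, tri_coef, comp$n_species, x, pv)
    d[active]
  }
  roots <- list()
  for (s0 in starts) {
    y0 <- base[active]
    names(y0) <- comp$species[active]
    common <- intersect(names(s0), names(y0))
    y0[common] <- s0[common]
    y <- damped_newton(fn, unname(y0))
    if (is.null(y)) next
    if (!any(vapply(roots, function(r) max(abs(r - y)) < 1e-6, logical(1))))
      roots[[length(roots) + 1]] <- y
  }
  if (!length(roots)) stop("steady-state search failed from every start")
  rows <- lapply(roots, function(y) {
    x <- base; x[active] <- y
    names(x) <- comp$species
    J <- num_jacobian(fn, y)
    ev <- eigen(J, only.values = TRUE)$values
    mre <- max(Re(ev))
    data.frame(stability = if (mre < 0) "stable" else "unstable",
               marginal = abs(mre) < 1e-9, max_re_eigenvalue = mre, t(x))
  })
  do.call(rbind, rows)
}

#' One-parameter bifurcation diagram of the p27 switch
#'
#' Scans the clamped total of one cyclin over a grid, records every steady
#' p27 level with its stability, and locates the two saddle-node thresholds
#' by bracketing the change in steady-state count and refining by bisection
#' to a grid-independent precision of 1e-3 a.u. The upper threshold is the
#' cyclin level at which the high-p27 (G1) state disappears; the lower
#' threshold is where the low-p27 (S) state disappears. Upper > lower is
#' hysteresis.
#'
#' @inheritParams steady_states
#' @param grid increasing vector of cyclin totals to scan (a.u.).
#' @return object of class \code{g1s_diagram}: \code{points} (long
#'   data.frame: scan value, p27_total, stability), \code{upper_threshold},
#'   \code{lower_threshold}, \code{scan_species}, \code{clamps}.
#' @export
scan_diagram <- function(network, params, scan_species = "cyclinE",
                         grid = seq(0.01, 1.2, length.out = 60),
                         clamps = c(emi1 = 0.05)) {
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be increasing")
  net <- scan_network(network, scan_species, clamps)
  sslist <- lapply(grid, function(T)
    steady_states(net, params, T, scan_species, clamps))
  pts <- do.call(rbind, Map(function(T, ss) {
    data.frame(scan_value = T, p27_total = ss$p27_total,
               stability = ss$stability)
  }, grid, sslist))
  nst <- vapply(sslist, nrow, 0L)
  count_at <- function(T) nrow(steady_states(net, params, T, scan_species,
                                             clamps))
  bisect_change <- function(lo, hi, n_lo, tol = 1e-3) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (count_at(mid) == n_lo) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  upper <- NA_real_; lower <- NA_real_
  for (i in seq_len(length(grid) - 1)) {
    if (nst[i] != nst[i + 1]) {
      thr <- bisect_change(grid[i], grid[i + 1], nst[i])
      if (nst[i] < nst[i + 1]) lower <- thr else upper <- thr
    }
  }
  structure(list(points = pts, upper_threshold = upper,
                 lower_threshold = lower, grid = grid,
                 scan_species = scan_species, clamps = clamps,
                 n_states = nst),
            class = "g1s_diagram")
}

#' @export
print.g1s_diagram <- function(x, ...) {
  cat(sprintf("p27 steady-state diagram vs clamped %s (%s)\n", x$scan_species,
              paste(names(x$clamps), x$clamps, sep = "=", collapse = ", ")))
  cat(sprintf("saddle-node thresholds: lower %.4f, upper %.4f a.u.\n",
              x$lower_threshold, x$upper_threshold))
  invisible(x)
}

#' Relaxation-sweep threshold oracle
#'
#' Locates the same saddle-node thresholds as \code{\link{scan_diagram}} by
#' an independent route: long forward ODE relaxations of the clamped system
#' from a high-p27 and from a low-p27 start (up-scan / down-scan hysteresis
#' sweeps), with the branch endpoint classified by its final p27 level and
#' the threshold refined by bisection.
#'
#' @inheritParams steady_states
#' @param t_relax relaxation horizon in hours.
#' @param range cyclin-total search interval.
#' @param tol bisection tolerance (a.u.).
#' @return list with \code{upper_threshold} and \code{lower_threshold}.
#' @export
relaxation_thresholds <- function(network, params, scan_species = "cyclinE",
                                  clamps = c(emi1 = 0.05),
                                  range = c(0.01, 2), t_relax = 150,
                                  n_steps = 40, tol = 5e-4) {
  net <- scan_network(network, scan_species, clamps)
  net <- precompile(net, params)
  mem <- moiety_members(scan_species)
  cap <- params$value[["ks_p27"]] / params$value[["kd_p27"]]
  is_high <- function(st) {
    p <- st[["p27"]] + st[["p27_cycE"]] + st[["p27_cycA"]] + st[["p27_T187p"]]
    p > 0.4 * cap
  }
  relax <- function(st, t_end) {
    tr <- simulate_ode(net, params, init = st, t_end = t_end,
                       grid_dt = t_end / 4, rtol = 1e-10, atol = 1e-12)
    stats::setNames(tr$species[nrow(tr$species), ], colnames(tr$species))
  }
  # move the conserved total to `total` while preserving the carried state
  set_total <- function(st, total) {
    st[[mem[["free"]]]] <- st[[mem[["free"]]]] +
      (total - st[[mem[["free"]]]] - st[[mem[["bound"]]]])
    if (st[[mem[["free"]]]] < 0) {
      st[[mem[["bound"]]]] <- max(st[[mem[["bound"]]]] + st[[mem[["free"]]]], 0)
      st[[mem[["free"]]]] <- 0
    }
    st
  }
  sweep_threshold <- function(up) {
    Ts <- seq(range[1], range[2], length.out = n_steps)
    if (!up) Ts <- rev(Ts)
    st <- scan_base_state(net, params, Ts[1], clamps)
    if (up) {                      # start on the high-p27 (G1-like) branch
      st[["p27"]] <- 1.6 * cap; st[["cdh1_active"]] <- 0.99
      st[["skp2"]] <- 0.05
    }                              # down-sweep start is monostable low
    st <- relax(st, 400)
    state_was <- st; T_was <- Ts[1]
    side_was <- is_high(st)
    bracket <- NULL
    for (T in Ts[-1]) {
      st <- relax(set_total(st, T), t_relax)
      if (is_high(st) != side_was) { bracket <- c(T_was, T); break }
      state_was <- st; T_was <- T
    }
    if (is.null(bracket)) return(NA_real_)
    lo <- bracket[1]; hi <- bracket[2]
    while (abs(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      stm <- relax(set_total(state_was, mid), t_relax)
      if (is_high(stm) == side_was) {
        lo <- mid; state_was <- stm
      } else hi <- mid
    }
    (lo + hi) / 2
  }
  list(upper_threshold = sweep_threshold(up = TRUE),
       lower_threshold = sweep_threshold(up = FALSE))
}

#' Emi1-dependent threshold curves and territory map
#'
#' Computes the cyclin inactivation (upper) and reactivation (lower)
#' thresholds of the p27 switch as a function of the clamped Emi1 level,
#' with each (Emi1, cyclin) cell labelled as high-p27, low-p27 or bistable.
#'
#' @inheritParams steady_states
#' @param emi1_grid increasing vector of Emi1 levels (a.u.).
#' @param range cyclin-total search interval for threshold bisection.
#' @return object of class \code{g1s_threshold_curve}: data.frame
#'   \code{thresholds} (emi1, inactivation_threshold, reactivation_threshold)
#'   plus the scan metadata.
#' @export
threshold_vs_emi1 <- function(network, params,
                              scan_species = c("cyclinA", "cyclinE"),
                              emi1_grid = seq(0.02, 1.2, length.out = 40),
                              range = c(0.005, 2)) {
  scan_species <- match.arg(scan_species)
  rows <- lapply(emi1_grid, function(e) {
    net <- scan_network(network, scan_species, clamps = c(emi1 = e))
    count_at <- function(T) {
      ss <- steady_states(net, params, T, scan_species, c(emi1 = e))
      c(n = nrow(ss), stable = count_stable(ss),
        high = max(ss$p27_total), low = min(ss$p27_total))
    }
    lo <- range[1]; hi <- range[2]
    n_lo <- count_at(lo); n_hi <- count_at(hi)
    bisect <- function(f_keep, lo, hi, tol = 1e-3) {
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (f_keep(count_at(mid))) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
    cap <- params$value[["ks_p27"]] / params$value[["kd_p27"]]
    has_high <- function(ct) ct[["high"]] > 0.4 * cap
    has_low <- function(ct) ct[["n"]] > 1 || ct[["high"]] <= 0.4 * cap
    upper <- bisect(has_high, lo, hi)
    lower <- bisect(function(ct) !has_low(ct), lo, hi)
    data.frame(emi1 = e, inactivation_threshold = upper,
               reactivation_threshold = lower)
  })
  thr <- do.call(rbind, rows)
  structure(list(thresholds = thr, scan_species = scan_species,
                 range = range),
            class = "g1s_threshold_curve")
}

#' @export
print.g1s_threshold_curve <- function(x, ...) {
  cat(sprintf("%s thresholds vs Emi1 (%d Emi1 levels)\n", x$scan_species,
              nrow(x$thresholds)))
  print(utils::head(x$thresholds))
  invisible(x)
}

#' Territory label at one point of the (Emi1, cyclin) plane
#'
#' @param curve a \code{g1s_threshold_curve}.
#' @param emi1,cyclin coordinates (a.u.). Emi1 values outside the computed
#'   grid are clamped to its ends.
#' @return \code{"high-p27"}, \code{"bistable"} or \code{"low-p27"}.
#' @export
territory <- function(curve, emi1, cyclin) {
  thr <- curve$thresholds
  e <- pmin(pmax(emi1, min(thr$emi1)), max(thr$emi1))
  up <- stats::approx(thr$emi1, thr$inactivation_threshold, e)$y
  dn <- stats::approx(thr$emi1, thr$reactivation_threshold, e)$y
  ifelse(cyclin >= up, "low-p27",
         ifelse(cyclin <= dn, "high-p27", "bistable"))
}

#' Project a trajectory onto the threshold plane
#'
#' Annotates every time point of a trajectory with its territory in the
#' (Emi1, scanned cyclin) plane and reports the first crossing into the
#' low-p27 territory (the point of no return through the switch).
#'
#' @param traj a \code{g1s_trajectory}.
#' @param curve a \code{g1s_threshold_curve}.
#' @return list: \code{path} data.frame (time_h, emi1, cyclin, territory)
#'   and \code{crossing_time} (first entry into low-p27; NA if never).
#' @export
project_trajectory <- function(traj, curve) {
  cyc <- series(traj, paste0(curve$scan_species, "_total"))
  e <- series(traj, "emi1")
  lab <- territory(curve, e, cyc)
  path <- data.frame(time_h = traj$time, emi1 = e, cyclin = cyc,
                     territory = lab)
  ct <- path$time_h[match("low-p27", lab)]
  list(path = path, crossing_time = if (length(ct)) ct else NA_real_)
}
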