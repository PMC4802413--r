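# Restriction-point extension: pRb control over E2F with E2F autoregulation.
# The core HeLa model is the pRb-null limit (E2F clamped at 1). In cells
# with an intact restriction point and intermediate mitogen input, the
# CyclinE/pRb balance curves intersect in two stable states (Cdk2-high
# proliferation vs Cdk2-low arrest) separated by a saddle.

#' Extended network with pRb control over E2F
#'
#' Adds to the core G1/S network a hypo-phosphorylated pRb pool
#' (\code{rb_hypo}, a fraction of total pRb) and dynamic E2F activity
#' (\code{e2f_active}, fraction of total E2F):
#' pRb is phosphorylated by a lumped mitogen-driven CyclinD-like activity
#' plus Cdk2:Cyclin activity, and dephosphorylated at a constant rate; E2F
#' activates with positive autoregulation and is inactivated basally and by
#' hypo-phosphorylated pRb. The extension's rate laws are qualitative
#' constructions consistent with the known wiring; they are exercised at the
#' property level, not fitted to data.
#'
#' @param params a parameter set containing the extension constants (see
#'   \code{\link{default_rb_parameters}}).
#' @return a validated \code{g1s_network}.
#' @export
build_rb_network <- function(params = default_rb_parameters()) {
  A <- .ACT
  rx <- default_reactions()
  rx <- c(rx, list(
    .rxn("rb_dephosphorylation", c(rb_hypo = 1L),
         "kdp_rb * (1 - rb_hypo)"),
    .rxn("rb_phosphorylation", c(rb_hypo = -1L),
         paste0("(kp_rb_mitogen * mitogen + kp_rb_cdk2 * ", A,
                ") * rb_hypo")),
    .rxn("e2f_activation", c(e2f_active = 1L),
         "(ka_e2f + ka_e2f_auto * e2f_active) * (1 - e2f_active)"),
    .rxn("e2f_inactivation", c(e2f_active = -1L),
         "(ki_e2f + ki_e2f_rb * rb_hypo * rb_hypo) * e2f_active")))
  net <- reaction_network(
    species = c(g1s_species, "rb_hypo"),
    reactions = rx,
    observables = list(
      p27_total = c(p27 = 1, p27_cycE = 1, p27_cycA = 1, p27_T187p = 1),
      cyclinE_total = c(cycE = 1, p27_cycE = 1),
      cyclinA_total = c(cycA = 1, p27_cycA = 1)),
    metadata = "G1/S network extended with pRb-E2F restriction point control",
    unit_interval = c("cdh1_active", "e2f_active", "rb_hypo"))
  rep <- validate(net, params)
  if (length(rep)) stop("invalid extended network:\n  ",
                        paste(rep, collapse = "\n  "))
  net
}

#' Default parameters for the extended model
#'
#' The core defaults plus the restriction-point constants. \code{mitogen}
#' is a dimensionless lumped input scaling CyclinD-like pRb phosphorylation;
#' its default (0.5) sits in the intermediate regime where both fates
#' coexist.
#'
#' @param mitogen mitogen input level (dimensionless).
#' @return a \code{g1s_parameters}.
#' @export
default_rb_parameters <- function(mitogen = 0.5) {
  p <- default_parameters()
  extra <- c(kdp_rb = 1, kp_rb_mitogen = 1.5, kp_rb_cdk2 = 20,
             mitogen = mitogen,
             ka_e2f = 0.1, ka_e2f_auto = 3, ki_e2f = 0.1, ki_e2f_rb = 9)
  unit <- c(kdp_rb = "1/h", kp_rb_mitogen = "1/h", kp_rb_cdk2 = "1/h",
            mitogen = "dimensionless",
            ka_e2f = "1/h", ka_e2f_auto = "1/h", ki_e2f = "1/h",
            ki_e2f_rb = "1/h")
  fit <- stats::setNames(rep(TRUE, length(extra)), names(extra))
  kinetic_parameters(c(p$value, extra), c(p$unit, unit),
                     c(p$fittable, fit))
}

#' Post-mitotic state for the extended model
#'
#' @param cycE0 initial free CyclinE carried over mitosis (a.u.).
#' @param cki0 initial free p27 (a.u.).
#' @param e2f0,rb0 initial E2F-active and hypo-pRb fractions.
#' @return named state vector.
#' @export
rb_postmitotic_state <- function(cycE0 = 0.01, cki0 = 0, e2f0 = 0.5,
                                 rb0 = 0.5) {
  st <- default_postmitotic_state()
  st[["cycE"]] <- cycE0
  st[["p27"]] <- cki0
  st[["e2f_active"]] <- e2f0
  c(st, rb_hypo = rb0)
}

# restriction-point subsystem: CyclinA moiety and Emi1 clamped (early G1),
# CyclinE total conserved when scanned
rp_clamps <- c(emi1 = 0.05)

#' CyclinE / pRb balance curves of the extended model
#'
#' For the restriction-point subsystem (CyclinA absent and Emi1 low, the
#' early-G1 condition), computes the two balance curves of the Fig-style
#' phase plane: the steady CyclinE level reached when hypo-pRb is clamped at
#' each grid value, and the steady hypo-pRb level(s) when the total CyclinE
#' is clamped. The p27/Cdk2 antagonism folds the pRb curve (an inverse-N
#' shape); without CKI it is monotone. Intersection states of the subsystem
#' are reported with stability.
#'
#' @param network the extended network.
#' @param params a \code{g1s_parameters}.
#' @param rb_grid grid of clamped hypo-pRb fractions.
#' @param cycE_grid grid of clamped CyclinE totals (a.u.).
#' @return list: \code{cyclinE_curve} (rb_hypo, cyclinE_total per stable
#'   state), \code{rb_curve} (cyclinE_total, rb_hypo per steady state with
#'   stability), \code{fixed_points} (subsystem fixed points, data.frame).
#' @export
balance_curves <- function(network, params,
                           rb_grid = seq(0.02, 0.98, length.out = 25),
                           cycE_grid = seq(0.02, 1.2, length.out = 25)) {
  # CyclinE balance: clamp rb_hypo, CyclinA moiety and emi1; relax to ss
  cycE_rows <- lapply(rb_grid, function(rb) {
    net <- clamped_subnetwork(network, c("rb_hypo", "cycA", "p27_cycA",
                                         "emi1"))
    st <- rb_postmitotic_state(rb0 = rb)
    st[["emi1"]] <- rp_clamps[["emi1"]]; st[["cycA"]] <- 0
    ss <- lapply(c(0.1, 0.9), function(e0) {
      st[["e2f_active"]] <- e0
      tr <- simulate_ode(net, params, init = st, t_end = 300, grid_dt = 50,
                         rtol = 1e-9, atol = 1e-11)
      utils::tail(series(tr, "cyclinE_total"), 1)
    })
    data.frame(rb_hypo = rb, cyclinE_total = unique(round(unlist(ss), 5)))
  })
  # pRb balance: conserve CyclinE total, rb/e2f dynamic
  net_rb <- scan_network(network, "cyclinE", clamps = rp_clamps,
                         keep_dynamic = "e2f_active")
  rb_rows <- lapply(cycE_grid, function(T) {
    ss <- steady_states_rb(net_rb, network, params, T)
    data.frame(cyclinE_total = T, rb_hypo = ss$rb_hypo,
               stability = ss$stability, p27_total = ss$p27_total)
  })
  fp <- rp_fixed_points(network, params)
  list(cyclinE_curve = do.call(rbind, cycE_rows),
       rb_curve = do.call(rbind, rb_rows),
       fixed_points = fp)
}

# steady states of the conserved-CyclinE restriction-point subsystem with
# dynamic rb/e2f; multi-start over p27 and rb branches
steady_states_rb <- function(net_scan, network, params, total) {
  rs <- reduced_system(net_scan, params, total, rp_clamps)
  cap <- params$value[["ks_p27"]] / params$value[["kd_p27"]]
  roots <- list()
  for (pp in c(0.002, 1.2 * cap)) for (rr in c(0.05, 0.95))
    for (bb in unique(c(0, 0.9 * total))) {
      y0 <- numeric(length(rs$free)); names(y0) <- rs$species[rs$free]
      y0["p27"] <- pp
      if ("rb_hypo" %in% names(y0)) y0["rb_hypo"] <- rr
      if ("e2f_active" %in% names(y0)) y0["e2f_active"] <- 1 - rr
      if (!is.na(rs$bound_index)) y0[rs$bound_index] <- bb
      if ("cdh1_active" %in% names(y0)) y0["cdh1_active"] <- 0.98
      if ("skp2" %in% names(y0)) y0["skp2"] <- 0.05
      y <- damped_newton(rs$fn, unname(y0))
      if (is.null(y)) next
      if (!any(vapply(roots, function(r) max(abs(r - y)) < 1e-6, logical(1))))
        roots[[length(roots) + 1]] <- y
    }
  # relaxation-seeded fallback for each p27 branch
  for (branch in c("high", "low")) {
    st <- scan_base_state(net_scan, params, total, rp_clamps)
    st[["p27"]] <- if (branch == "high") 1.5 * cap else 0
    st[["cdh1_active"]] <- 0.98; st[["skp2"]] <- 0.05
    st[["rb_hypo"]] <- if (branch == "high") 0.9 else 0.1
    st[["e2f_active"]] <- if (branch == "high") 0.1 else 0.9
    tr <- simulate_ode(net_scan, params, init = st, t_end = 150,
                       grid_dt = 50, rtol = 1e-10, atol = 1e-12)
    yr <- tr$species[nrow(tr$species), rs$free]
    y <- damped_newton(rs$fn, yr)
    if (is.null(y) && max(abs(rs$fn(yr))) < 1e-7) y <- yr
    if (!is.null(y) &&
        !any(vapply(roots, function(r) max(abs(r - y)) < 1e-6, logical(1))))
      roots[[length(roots) + 1]] <- y
  }
  if (!length(roots)) stop("no steady state found for clamped CyclinE total")
  rows <- lapply(roots, function(y) {
    x <- rs$assemble(y); names(x) <- rs$species
    J <- num_jacobian(rs$fn, y)
    mre <- max(Re(eigen(J, only.values = TRUE)$values))
    data.frame(rb_hypo = x[["rb_hypo"]], e2f_active = x[["e2f_active"]],
               p27_total = x[["p27"]] + x[["p27_cycE"]] + x[["p27_cycA"]] +
                 x[["p27_T187p"]],
               cycE_free = x[["cycE"]],
               stability = if (mre < 0) "stable" else "unstable",
               max_re_eigenvalue = mre)
  })
  do.call(rbind, rows)
}

#' Fixed points of the extended model
#'
#' Locates the steady states of the full extended model (all species
#' dynamic): the Cdk2-low arrest state (E2F off, hypo-phosphorylated pRb,
#' p27 high) and the Cdk2-high S-phase-like state (E2F on, pRb
#' phosphorylated, APC/C-Cdh1 off, CyclinA accumulated), plus the saddle
#' between them. Roots come from multi-start Newton iteration seeded both
#' directly and from long relaxations out of the two fate corners. On
#' default settings at intermediate mitogen there are exactly two stable
#' fixed points and one saddle.
#'
#' @param network the extended network.
#' @param params a \code{g1s_parameters}.
#' @return data.frame with one row per fixed point: rb_hypo, e2f_active,
#'   cyclinE_total, p27_total, cdk2_activity, stability.
#' @export
rp_fixed_points <- function(network, params) {
  net <- network
  base <- rb_postmitotic_state()
  cap <- params$value[["ks_p27"]] / params$value[["kd_p27"]]
  ks_e <- params$value[["ks_e"]]; kd_e <- params$value[["kd_e"]]
  corner <- function(e2f, rb, p27, cdh1, skp2, cycA) {
    c(rb_hypo = rb, e2f_active = e2f,
      cyclinE_mRNA = e2f, cyclinA_mRNA = e2f,
      cycE = max(ks_e * e2f / kd_e - p27, 0.001), p27 = p27,
      p27_cycE = min(p27, ks_e * e2f / kd_e) * 0.9,
      cycA = cycA, emi1 = params$value[["ks_emi1"]] * e2f /
        params$value[["kd_emi1"]],
      skp2 = skp2, cdh1_active = cdh1, p27_T187p = 0.005)
  }
  starts <- list(
    corner(0.95, 0.05, 0.001, 0.01, 1, 4),     # proliferative / S-like
    corner(0.05, 0.95, cap, 0.98, 0.03, 0),    # arrested
    corner(0.5, 0.5, 0.5 * cap, 0.5, 0.5, 0.5),
    corner(0.35, 0.65, 0.8 * cap, 0.9, 0.1, 0.05),
    corner(0.65, 0.35, 0.3 * cap, 0.2, 0.8, 1),
    corner(0.25, 0.6, 0.6 * cap, 0.8, 0.2, 0.1))
  # relaxation-seeded roots from the two corners
  for (st0 in starts[1:2]) {
    init <- base
    init[names(st0)] <- st0
    tr <- simulate_ode(net, params, init = pmax(init, 0), t_end = 300,
                       grid_dt = 75, rtol = 1e-10, atol = 1e-12)
    endpoint <- tr$species[nrow(tr$species), ]
    starts[[length(starts) + 1]] <- endpoint
  }
  ss <- find_steady_states(net, params, base, starts)
  ss$cyclinE_total <- ss$cycE + ss$p27_cycE
  ss$p27_total <- ss$p27 + ss$p27_cycE + ss$p27_cycA + ss$p27_T187p
  ss$cdk2_activity <- params$value[["w_e"]] * ss$cycE +
    params$value[["w_a"]] * ss$cycA
  ss[order(-ss$cdk2_activity),
     c("rb_hypo", "e2f_active", "cyclinE_total", "p27_total",
       "cdk2_activity", "stability", "marginal", "max_re_eigenvalue")]
}

#' Classify post-mitotic fates on an initial-condition grid
#'
#' Simulates the extended model from a grid of post-mitotic (CyclinE, CKI)
#' initial conditions and labels each run \code{cdk2_high} or
#' \code{cdk2_low} by its final Cdk2 activity relative to the geometric
#' midpoint of the two stable fixed-point activities. Trajectories whose
#' final activity sits within a factor \code{ambiguous_fold} of the midpoint
#' are flagged unsettled rather than mislabelled.
#'
#' @param network the extended network.
#' @param params a \code{g1s_parameters}.
#' @param cycE0_grid,cki0_grid initial free CyclinE and p27 levels (a.u.).
#' @param horizon simulation horizon in hours (default 40).
#' @param ambiguous_fold settling band around the midpoint (default 3).
#' @return object of class \code{g1s_fates}: data.frame \code{grid}
#'   (cycE0, cki0, final_activity, label, settled), \code{midpoint},
#'   \code{horizon}.
#' @export
classify_fates <- function(network, params,
                           cycE0_grid = seq(0.02, 0.6, length.out = 5),
                           cki0_grid = seq(0, 0.6, length.out = 5),
                           horizon = 40, ambiguous_fold = 3) {
  fp <- rp_fixed_points(network, params)
  st_act <- fp$cdk2_activity[fp$stability == "stable"]
  if (length(st_act) < 2)
    stop("extended model is not bistable at these settings; ",
         "fate classification needs two stable activities")
  mid <- sqrt(max(min(st_act), 1e-12) * max(st_act))
  rows <- list()
  for (ce in cycE0_grid) for (ck in cki0_grid) {
    init <- rb_postmitotic_state(cycE0 = ce, cki0 = ck)
    tr <- simulate_ode(network, params, init = init, t_end = horizon,
                       grid_dt = 0.25, rtol = 1e-7, atol = 1e-9)
    af <- utils::tail(series(tr, "cdk2_activity"), 1)
    settled <- af > mid * ambiguous_fold || af < mid / ambiguous_fold
    rows[[length(rows) + 1]] <- data.frame(
      cycE0 = ce, cki0 = ck, final_activity = af,
      label = if (af > mid) "cdk2_high" else "cdk2_low",
      settled = settled)
  }
  structure(list(grid = do.call(rbind, rows), midpoint = mid,
                 horizon = horizon, fixed_points = fp),
            class = "g1s_fates")
}

#' @export
print.g1s_fates <- function(x, ...) {
  tab <- table(x$grid$label)
  cat(sprintf("Fate classification over %d initial conditions (horizon %g h): ",
              nrow(x$grid), x$horizon))
  cat(paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
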