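p_def <- default_parameters()
net_def <- build_default_network(p_def)

test_that("generic root finding recovers the closed-form fixed point of a linear model", {
  net <- birth_death_network()
  p <- birth_death_params(k = 3, d = 0.75)
  ss <- find_steady_states(net, p, base_state = c(x = 0),
                           starts = list(c(x = 0.1), c(x = 10)))
  expect_identical(nrow(ss), 1L)
  expect_equal(ss$x, 3 / 0.75, tolerance = 1e-8)
  expect_identical(ss$stability, "stable")
})

test_that("clamping holds species constant while keeping them as modifiers", {
  net <- clamped_subnetwork(net_def, c("emi1", "cycA", "p27_cycA"))
  st <- default_postmitotic_state()
  st[["emi1"]] <- 0.4
  d <- derivatives(net, st, p_def)
  expect_identical(d[["emi1"]], 0)
  expect_identical(d[["cycA"]], 0)
  # emi1 still acts on Cdh1 inactivation
  r <- reaction_rates(net, st, p_def)
  st2 <- st; st2[["emi1"]] <- 0.8
  r2 <- reaction_rates(net, st2, p_def)
  expect_gt(r2[["cdh1_inactivation"]], r[["cdh1_inactivation"]])
  # clamping nothing is an identity on the derivative field
  expect_equal(derivatives(clamped_subnetwork(net_def, character(0)), st, p_def),
               derivatives(net_def, st, p_def))
})

test_that("the p27 switch is monostable-high, bistable, then monostable-low along the CyclinE axis", {
  lowT <- steady_states(net_def, p_def, total = 0.2, "cyclinE")
  expect_identical(sum(lowT$stability == "stable"), 1L)
  expect_gt(lowT$p27_total[1], 0.5)
  midT <- steady_states(net_def, p_def, total = 0.55, "cyclinE")
  expect_identical(nrow(midT), 3L)
  expect_identical(sum(midT$stability == "stable"), 2L)
  # rows are ordered by p27; the intermediate state is the unstable one
  expect_identical(midT$stability[2], "unstable")
  hiT <- steady_states(net_def, p_def, total = 0.9, "cyclinE")
  expect_identical(sum(hiT$stability == "stable"), 1L)
  expect_lt(min(hiT$p27_total), 0.3)
})

test_that("CyclinA thresholds fall with Emi1 and the plane splits into three contiguous territories", {
  tc <- threshold_vs_emi1(net_def, p_def, "cyclinA",
                          emi1_grid = c(0.7, 0.9, 1.1))
  thr <- tc$thresholds
  expect_true(all(diff(thr$inactivation_threshold) <= 1e-9))
  expect_true(all(diff(thr$reactivation_threshold) <= 1e-9))
  expect_true(all(thr$inactivation_threshold > thr$reactivation_threshold))
  # along the cyclin axis at fixed Emi1 the labels form <= 3 contiguous bands
  lab <- territory(tc, 0.9, seq(0.01, 0.8, by = 0.01))
  expect_lte(length(rle(lab)$values), 3L)
  expect_identical(rle(lab)$values,
                   c("high-p27", "bistable", "low-p27"))
})

test_that("scan thresholds agree with the relaxation-sweep oracle (CyclinA scan)", {
  d <- scan_diagram(net_def, p_def, "cyclinA",
                    grid = seq(0.02, 0.6, length.out = 12),
                    clamps = c(emi1 = 0.9))
  ro <- relaxation_thresholds(net_def, p_def, "cyclinA",
                              clamps = c(emi1 = 0.9), range = c(0.005, 1))
  expect_lt(abs(d$upper_threshold - ro$upper_threshold), 2e-3)
  expect_lt(abs(d$lower_threshold - ro$lower_threshold), 2e-3)
  expect_gt(d$upper_threshold, d$lower_threshold)
})

test_that("trajectories project onto the threshold plane with an irreversible crossing", {
  # post-switch the Cdk2 activity is carried by CyclinA (CyclinE is degraded
  # in a Cdk2-dependent way), so the CyclinA plane is the informative
  # projection for irreversibility
  tcA <- threshold_vs_emi1(net_def, p_def, "cyclinA",
                           emi1_grid = c(0.3, 0.6, 0.9, 1.2))
  ctrl <- simulate_ode(net_def, p_def, t_end = 30)
  prA <- project_trajectory(ctrl, tcA)
  expect_false(is.na(prA$crossing_time))
  after <- prA$path$territory[prA$path$time_h >= prA$crossing_time]
  expect_false(any(after == "high-p27"))
  # and dynamically: once down, p27 stays down for the rest of the cycle
  g1s <- detect_g1s(ctrl)
  p27 <- series(ctrl, "p27_total")
  late <- ctrl$time >= g1s + 1
  expect_true(all(p27[late] < 0.2 * max(p27)))
  # the control path commits while Emi1 is still lower than in
  # CyclinE-depleted cells, which must wait for the Emi1-driven threshold fall
  kdE <- simulate_ode(net_def, p_def, t_end = 30,
                      protocol = cyclinE_knockdown())
  prK <- project_trajectory(kdE, tcA)
  emi_at <- function(tr, t) stats::approx(tr$time, series(tr, "emi1"), t)$y
  expect_lt(emi_at(ctrl, prA$crossing_time), emi_at(kdE, prK$crossing_time))
  # constant path inside one territory keeps a single label
  flat <- ctrl
  flat$species <- ctrl$species[rep(1, nrow(ctrl$species)), ]
  flat$observables <- lapply(ctrl$observables, function(x) rep(x[1], length(x)))
  expect_identical(length(unique(project_trajectory(flat, tcA)$path$territory)), 1L)
})
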