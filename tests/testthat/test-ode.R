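p_def <- default_parameters()
net_def <- build_default_network(p_def)

test_that("single-species birth-death matches the closed form", {
  net <- birth_death_network()
  p <- birth_death_params(k = 2, d = 0.5)
  tr <- simulate_ode(net, p, init = c(x = 0), t_end = 10, grid_dt = 0.1)
  expect_equal(series(tr, "x"), (2 / 0.5) * (1 - exp(-0.5 * tr$time)),
               tolerance = 1e-7)
})

test_that("an empty protocol leaves the trajectory bit-identical", {
  tr0 <- simulate_ode(net_def, p_def, t_end = 5)
  tr1 <- simulate_ode(net_def, p_def, t_end = 5,
                      protocol = perturbation_protocol(NULL, "empty"))
  expect_identical(tr0$species, tr1$species)
})

test_that("control simulation shows the G1/S phenomenology", {
  tr <- simulate_ode(net_def, p_def, t_end = 18)
  g1s <- detect_g1s(tr)
  expect_false(is.na(g1s))
  p27 <- series(tr, "p27_total")
  # p27 rises, then collapses to a small fraction of its peak
  expect_gt(max(p27), 10 * p27[2])
  expect_lt(utils::tail(p27, 1), 0.1 * max(p27))
  # CyclinA stays low through G1 and only accumulates after the transition
  cycA <- series(tr, "cyclinA_total")
  pre <- tr$time < g1s - 1
  expect_lt(max(cycA[pre]), 0.05 * max(cycA))
  expect_gt(utils::tail(cycA, 1), 0.5 * max(cycA))
  # Cdk2 activity at the transition exceeds its early-G1 baseline
  act <- series(tr, "cdk2_activity")
  expect_gt(stats::approx(tr$time, act, g1s)$y, 5 * max(act[tr$time < 2]))
})

test_that("G1/S detection follows its operational definition", {
  tt <- seq(0, 12, by = 0.05)
  expect_true(is.na(detect_g1s(fake_trajectory(tt, 0.1 + 0.05 * tt))))
  step <- ifelse(tt < 6, 1, 0)
  expect_equal(detect_g1s(fake_trajectory(tt, step)), 6, tolerance = 0.051)
  # a brief dip that recovers within the persistence window is rejected
  dip <- ifelse(tt >= 4 & tt < 4.3, 0.2, 1)
  expect_true(is.na(detect_g1s(fake_trajectory(tt, dip))))
})

test_that("switch abruptness matches closed forms", {
  tt <- seq(0, 12, by = 0.05)
  step <- ifelse(tt < 6, 1, 0)
  expect_lte(switch_abruptness(fake_trajectory(tt, step)), 0.05 + 1e-9)
  d <- 0.8
  decay <- exp(-d * tt)
  expect_equal(switch_abruptness(fake_trajectory(tt, decay)), log(4) / d,
               tolerance = 0.01)
})

test_that("halving integrator tolerances moves the G1/S time by less than one grid step", {
  tr1 <- simulate_ode(net_def, p_def, t_end = 12, rtol = 1e-8, atol = 1e-10)
  tr2 <- simulate_ode(net_def, p_def, t_end = 12, rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(detect_g1s(tr1) - detect_g1s(tr2)), 0.05)
})

test_that("the activation delay is attributable to p27", {
  # delete every p27-containing reaction: activity then tracks CyclinE from t=0
  no_p27 <- net_def
  no_p27$reactions <- Filter(function(rx) {
    !any(grepl("^p27", c(names(rx$stoich),
                         regmatches(rx$rate, gregexpr("p27[A-Za-z_0-9]*",
                                                      rx$rate))[[1]])))
  }, net_def$reactions)
  tr_free <- simulate_ode(no_p27, p_def, t_end = 4)
  tr_ctrl <- simulate_ode(net_def, p_def, t_end = 4)
  act_free <- series(tr_free, "cdk2_activity")
  act_ctrl <- series(tr_ctrl, "cdk2_activity")
  at2 <- which.min(abs(tr_free$time - 2))
  expect_gt(act_free[at2], 5 * act_ctrl[at2])
  # and activity rises with CyclinE immediately (monotone over early window)
  expect_true(all(diff(act_free[tr_free$time <= 2]) > 0))
})

test_that("post-mitotic state has no p27, low CyclinA and active APC/C-Cdh1", {
  st <- default_postmitotic_state()
  expect_identical(st[["p27"]], 0)
  expect_identical(st[["cycA"]], 0)
  expect_gte(st[["cdh1_active"]], 0.95)
  expect_true(all(st >= 0) && st[["cdh1_active"]] <= 1)
})

test_that("protocol events are exact, piecewise-constant, and compose by concatenation", {
  ev1 <- perturbation_protocol(data.frame(
    time_h = 2, action = "scale_parameter", target = "ks_e", value = 0.5))
  ev2 <- perturbation_protocol(data.frame(
    time_h = 4, action = "scale_species", target = "emi1", value = 0.1))
  comp <- compose_protocols(ev1, ev2)
  both <- perturbation_protocol(rbind(ev1$events, ev2$events))
  tr_a <- simulate_ode(net_def, p_def, t_end = 6, protocol = comp)
  tr_b <- simulate_ode(net_def, p_def, t_end = 6, protocol = both)
  expect_identical(tr_a$species, tr_b$species)
  # species jump at the event, state continuous otherwise
  emi1 <- series(tr_a, "emi1")
  i <- which(tr_a$time == 4)
  expect_lt(emi1[i + 1], 0.2 * emi1[i - 1])
  expect_lt(max(abs(diff(emi1[tr_a$time < 3.9]))), 0.02)
})
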