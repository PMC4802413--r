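p_def <- default_parameters()
net_def <- build_default_network(p_def)

test_that("knockdown protocols carry the siRNA event structure and validate inputs", {
  kdE <- cyclinE_knockdown()
  expect_identical(nrow(kdE$events), 2L)
  expect_true(all(kdE$events$time_h == 0))
  expect_identical(kdE$events$value[kdE$events$target == "ks_me"], 0.05)
  expect_identical(kdE$events$value[kdE$events$target == "kd_me"], 20)
  kdA <- cyclinA_knockdown(residual_synthesis = 0.1, mrna_deg_fold = 5)
  expect_setequal(kdA$events$target, c("ks_ma", "kd_ma"))
  expect_error(cyclinE_knockdown(residual_synthesis = 1.5), "0, 1")
  expect_error(cyclinA_knockdown(mrna_deg_fold = 0.5), ">= 1")
  expect_error(emi1_depletion(fraction = 2), "0, 1")
  expect_error(cdk_inhibition(efficiency = -0.1), "0, 1")
})

test_that("no-op protocols reproduce the control trajectory exactly", {
  ctrl <- simulate_ode(net_def, p_def, t_end = 6)
  for (pr in list(cyclinE_knockdown(1, 1), cyclinA_knockdown(1, 1),
                  emi1_depletion(2, 0), cdk_inhibition(2, 0))) {
    tr <- simulate_ode(net_def, p_def, t_end = 6, protocol = pr)
    expect_equal(tr$species, ctrl$species, tolerance = 1e-6)
  }
})

test_that("the S-phase arrest state has low p27 with CyclinA rising and CyclinE falling", {
  st <- sphase_arrest_state(net_def, p_def)
  ctrl <- simulate_ode(net_def, p_def, t_end = 20)
  expect_lt(st[["p27"]] + st[["p27_cycE"]] + st[["p27_cycA"]] +
              st[["p27_T187p"]], 0.1 * max(series(ctrl, "p27_total")))
  d <- derivatives(net_def, st, p_def)
  expect_gt(d[["cycA"]] + d[["p27_cycA"]], 0)
  expect_lt(d[["cycE"]] + d[["p27_cycE"]], 0)
  expect_true(all(st >= 0) && st[["cdh1_active"]] <= 1)
})

test_that("Cdk inhibition lets p27 re-accumulate only while its synthesis is active", {
  st <- sphase_arrest_state(net_def, p_def)
  tr <- simulate_ode(net_def, p_def, init = st, t_end = 12,
                     protocol = cdk_inhibition(0))
  expect_gt(max(series(tr, "p27_total")), 0.5)
  stop_syn <- compose_protocols(
    cdk_inhibition(0),
    perturbation_protocol(data.frame(time_h = 0, action = "set_parameter",
                                     target = "ks_p27", value = 0)))
  tr0 <- simulate_ode(net_def, p_def, init = st, t_end = 12,
                      protocol = stop_syn)
  expect_lt(max(series(tr0, "p27_total")), 0.05)
})

test_that("partial Cdk inhibition interpolates between control and full block", {
  st <- sphase_arrest_state(net_def, p_def)
  end_p27 <- vapply(c(0, 0.6, 1), function(eff) {
    tr <- simulate_ode(net_def, p_def, init = st, t_end = 8,
                       protocol = cdk_inhibition(0, efficiency = eff))
    utils::tail(series(tr, "p27_total"), 1)
  }, 0)
  expect_true(all(diff(end_p27) > 0))
})
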