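p_def <- default_parameters()
net_def <- build_default_network(p_def)

test_that("default network passes validation and declares 25 unknown rate constants", {
  expect_length(validate(net_def, p_def), 0)
  expect_identical(sum(p_def$fittable), 25L)
  # APC/C-Cdh1-dependent CyclinA degradation: rate proportional to cdh1_active
  st <- default_postmitotic_state()
  st[c("cycA", "p27", "emi1", "skp2")] <- c(0.3, 0.2, 0.4, 0.3)
  st[["cdh1_active"]] <- 1
  r1 <- reaction_rates(net_def, st, p_def)
  st[["cdh1_active"]] <- 0.5
  r2 <- reaction_rates(net_def, st, p_def)
  expect_equal(r1[["cyclinA_degradation_cdh1"]],
               2 * r2[["cyclinA_degradation_cdh1"]])
  # and it consumes CyclinA
  rx <- Filter(function(r) r$name == "cyclinA_degradation_cdh1",
               net_def$reactions)[[1]]
  expect_identical(rx$stoich[["cycA"]], -1L)
})

test_that("derivatives are the stoichiometry-weighted rate sum (hand-summed flux oracle)", {
  set.seed(41)
  st <- stats::setNames(runif(12, 0, 1), net_def$species)
  st[["cdh1_active"]] <- 0.7; st[["e2f_active"]] <- 1
  d <- derivatives(net_def, st, p_def)
  v <- p_def$value
  act <- v[["w_e"]] * st[["cycE"]] + v[["w_a"]] * st[["cycA"]]
  # total CyclinE balance written out by hand: synthesis minus basal and
  # Cdk2-dependent degradation of both free and complexed CyclinE
  cycE_tot_flux <- v[["ks_e"]] * st[["cyclinE_mRNA"]] -
    (v[["kd_e"]] + v[["kd_e_cdk2"]] * act) *
    (st[["cycE"]] + st[["p27_cycE"]])
  expect_equal(d[["cycE"]] + d[["p27_cycE"]], cycE_tot_flux, tolerance = 1e-12)
  # linearity in a mass-action rate constant
  r1 <- reaction_rates(net_def, st, p_def)
  r2 <- reaction_rates(net_def, st, set_parameters(p_def, kass_e =
                                                     2 * v[["kass_e"]]))
  expect_equal(r2[["p27_cycE_binding"]], 2 * r1[["p27_cycE_binding"]])
  # all-zero state: only constant-synthesis fluxes remain
  z <- stats::setNames(rep(0, 12), net_def$species)
  dz <- derivatives(net_def, z, p_def)
  expect_equal(dz[["p27"]], v[["ks_p27"]])
  expect_equal(dz[["skp2"]], v[["ks_skp2"]])
  expect_true(all(dz >= 0))
})

test_that("Cdk2 activity counts only free complexes, linearly", {
  st <- stats::setNames(rep(0, 12), net_def$species)
  st[["p27_cycE"]] <- 3; st[["p27_cycA"]] <- 2
  expect_identical(cdk2_activity(st, p_def), 0)
  st[["cycE"]] <- 1
  expect_equal(cdk2_activity(st, p_def), p_def$value[["w_e"]])
  st[["cycA"]] <- 0.5
  base <- cdk2_activity(st, p_def)
  st[c("cycE", "cycA")] <- 3 * st[c("cycE", "cycA")]
  expect_equal(cdk2_activity(st, p_def), 3 * base)
})

test_that("validation reports name the offending parameter, species or reaction", {
  p_bad <- p_def
  p_bad$value[["ks_e"]] <- -1
  rep1 <- validate(net_def, p_bad)
  expect_true(any(grepl("ks_e", rep1)))
  net_bad <- net_def
  net_bad$reactions[[1]]$stoich <- c(ghost_species = 1L)
  rep2 <- validate(net_bad, p_def)
  expect_true(any(grepl("ghost_species", rep2)))
  net_bad2 <- net_def
  net_bad2$reactions[[2]]$rate <- "kd_me * not_a_species"
  rep3 <- validate(net_bad2, p_def)
  expect_true(any(grepl("not_a_species", rep3)))
})

test_that("nonnegativity and the Cdh1 fraction bound are forward-invariant under random parameter draws", {
  set.seed(7)
  for (i in 1:4) {
    p_i <- p_def
    jitter <- exp(rnorm(length(p_i$value), 0, 0.3))
    p_i$value <- p_i$value * jitter
    p_i$value[c("w_e", "w_a")] <- p_def$value[c("w_e", "w_a")]
    p_i <- kinetic_parameters(p_i$value, p_i$unit, p_i$fittable)
    init <- stats::setNames(runif(12, 0, 0.5), net_def$species)
    init[["cdh1_active"]] <- runif(1)
    init[["e2f_active"]] <- 1
    tr <- simulate_ode(net_def, p_i, init = init, t_end = 10, grid_dt = 0.2)
    expect_true(all(tr$species >= 0))
    expect_true(all(tr$species[, "cdh1_active"] <= 1 + 1e-6))
  }
})

test_that("without p27 synthesis every p27 pool drains to zero", {
  p0 <- set_parameters(p_def, ks_p27 = 0)
  init <- default_postmitotic_state()
  init[["p27"]] <- 0.8; init[["p27_T187p"]] <- 0.2
  tr <- simulate_ode(net_def, p0, init = init, t_end = 30)
  expect_lt(utils::tail(series(tr, "p27_total"), 1), 1e-3)
})
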