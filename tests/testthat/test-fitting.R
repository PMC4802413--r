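p_def <- default_parameters()
net_def <- build_default_network(p_def)

make_target <- function(n = 4, seed = 7, noise = noise_config(0, 0, 0, 0)) {
  cells <- generate_cells(net_def, p_def, n = n, noise = noise, seed = seed,
                          t_end = 15)
  ensemble_average(suppressMessages(process_and_align(cells)))
}

tgt_clean <- make_target()

test_that("the objective self-matches, ignores channel order, and rejects unknown channels", {
  o <- objective(net_def, p_def, tgt_clean)
  expect_lt(as.numeric(o), 2e-3)
  expect_length(attr(o, "per_channel"), 4)
  o_rev <- objective(net_def, p_def, rev(tgt_clean))
  expect_equal(as.numeric(o), as.numeric(o_rev), tolerance = 1e-12)
  bad <- tgt_clean; names(bad)[1] <- "gfp_mystery"
  expect_error(objective(net_def, p_def, bad), "gfp_mystery")
})

test_that("perturbing a synthesis rate strictly increases the objective on a self-target", {
  o0 <- as.numeric(objective(net_def, p_def, tgt_clean))
  for (pn in c("ks_e", "ks_p27", "ks_emi1")) {
    p2 <- set_parameters(p_def, stats::setNames(2 * p_def$value[[pn]], pn))
    expect_gt(as.numeric(objective(net_def, p2, tgt_clean)), o0)
  }
})

test_that("brute force is deterministic and monotone in the (nested) sample count", {
  f1 <- brute_force_fit(net_def, p_def, tgt_clean, fit_names = "ks_e",
                        n_samples = 20, seed = 5, refine = FALSE)
  f2 <- brute_force_fit(net_def, p_def, tgt_clean, fit_names = "ks_e",
                        n_samples = 20, seed = 5, refine = FALSE)
  expect_identical(f1$best_params$value, f2$best_params$value)
  f3 <- brute_force_fit(net_def, p_def, tgt_clean, fit_names = "ks_e",
                        n_samples = 60, seed = 5, refine = FALSE)
  expect_lte(f3$objective, f1$objective)
  expect_true(f1$objective == min(f1$candidates$objective))
})

test_that("a one-parameter fit recovers the generating synthesis rate", {
  fit <- brute_force_fit(net_def, p_def, tgt_clean, fit_names = "ks_p27",
                         lower = c(ks_p27 = p_def$value[["ks_p27"]] / 10),
                         upper = c(ks_p27 = p_def$value[["ks_p27"]] * 10),
                         n_samples = 25, seed = 11, refine = TRUE, top_k = 2)
  expect_lt(abs(fit$best_params$value[["ks_p27"]] - p_def$value[["ks_p27"]]) /
              p_def$value[["ks_p27"]], 0.1)
  expect_lt(fit$objective, 2e-3)
})

test_that("the recovery harness reports per-parameter errors and trajectory NRMSE", {
  rec <- recovery_experiment(net_def, p_def, fit_subset = "ks_e",
                             n_cells = 4, noise = noise_config(0, 0, 0, 0),
                             n_samples = 25, seed = 3)
  expect_named(rec$nrmse, c("p27_gfp", "cyclinE_gfp", "cyclinA_gfp",
                            "cdk2_ratio"))
  expect_identical(rec$param_table$parameter, "ks_e")
  # noise-free single-parameter recovery lands within 10 percent
  expect_lt(rec$param_table$rel_error, 0.1)
  expect_true(all(rec$nrmse < 0.1))
})
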