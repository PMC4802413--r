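p_def <- default_parameters()
net_def <- build_default_network(p_def)
quiet_align <- function(...) suppressMessages(process_and_align(...))

test_that("with noise off the channels equal the model observables exactly", {
  cells <- generate_cells(net_def, p_def, n = 2,
                          noise = noise_config(0, 0, 0, 0), seed = 3,
                          t_end = 12)
  tr <- simulate_ode(net_def, p_def, t_end = 12, grid_dt = 1 / 6)
  for (cell in cells) {
    expect_equal(cell$channels[, "p27_gfp"], series(tr, "p27_total"),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(cell$channels[, "cyclinA_gfp"], series(tr, "cyclinA_total"),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(cell$channels[, "cdk2_ratio"],
                 0.5 + series(tr, "cdk2_activity"),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("generated cells reproduce the imaging phenomenology", {
  cells <- generate_cells(net_def, p_def, n = 6, seed = 11, t_end = 22)
  for (cell in cells) {
    ts <- cell$s_entry_true
    expect_false(is.na(ts))
    # p27 peaks before S entry
    tpk <- cell$time[which.max(cell$channels[, "p27_gfp"])]
    expect_lt(tpk, ts)
    # CyclinA stays below 20 percent of its final level until S entry
    cycA <- cell$channels[, "cyclinA_gfp"]
    expect_lt(max(cycA[cell$time < ts]),
              0.2 * utils::tail(cycA, 1))
  }
})

test_that("S-entry calling is accurate, shift-invariant, and absent for flat traces", {
  cells <- generate_cells(net_def, p_def, n = 3,
                          noise = noise_config(0, 0, 0, 0), seed = 5,
                          t_end = 14)
  for (cell in cells) {
    expect_lt(abs(call_s_entry(cell) - cell$s_entry_true), 2 / 6)
    shifted <- cell
    shifted$channels[, "pcna_proxy"] <- cell$channels[, "pcna_proxy"] + 5
    expect_equal(call_s_entry(shifted), call_s_entry(cell), tolerance = 1e-9)
  }
  flat <- cells[[1]]
  flat$channels[, "pcna_proxy"] <- 0.3
  expect_true(is.na(call_s_entry(flat)))
})

test_that("alignment normalizes to peak, averages identical cells exactly, and is permutation-invariant", {
  cells <- generate_cells(net_def, p_def, n = 1,
                          noise = noise_config(0, 0, 0, 0), seed = 9,
                          t_end = 14)
  one <- quiet_align(cells)
  # peak normalization: per-cell maximum is 1 up to re-gridding interpolation
  expect_true(all(abs(apply(one$cells$p27_gfp, 1, max, na.rm = TRUE) - 1) < 0.02))
  expect_equal(one$mean[, "p27_gfp"], one$cells$p27_gfp[1, ],
               ignore_attr = TRUE)
  many <- quiet_align(rep(cells, 10))
  expect_true(all(many$sd < 1e-12, na.rm = TRUE))
  noisy <- generate_cells(net_def, p_def, n = 6, seed = 21, t_end = 14)
  a1 <- ensemble_average(quiet_align(noisy))
  a2 <- ensemble_average(quiet_align(rev(noisy)))
  expect_equal(a1$p27_gfp$value, a2$p27_gfp$value, tolerance = 1e-12)
})

test_that("the raw-channel ensemble mean converges to the noiseless trace as cells accumulate", {
  clean <- generate_cells(net_def, p_def, n = 1,
                          noise = noise_config(0, 0, 0, 0), seed = 2,
                          t_end = 13)[[1]]$channels[, "p27_gfp"]
  err <- vapply(c(8, 64), function(n) {
    cells <- generate_cells(net_def, p_def, n = n,
                            noise = noise_config(0.08, 0, 0.1, 0), seed = 2,
                            t_end = 13)
    m <- rowMeans(vapply(cells, function(cl) cl$channels[, "p27_gfp"],
                         clean))
    sqrt(mean((m - clean)^2))
  }, 0)
  # law of large numbers: fourfold more cells, about half the error
  expect_lt(err[2], 0.6 * err[1])
})

test_that("generation is pure: one seed, one ensemble", {
  a <- generate_cells(net_def, p_def, n = 3, seed = 33, t_end = 8)
  b <- generate_cells(net_def, p_def, n = 3, seed = 33, t_end = 8)
  expect_identical(lapply(a, `[[`, "channels"), lapply(b, `[[`, "channels"))
  c_ <- generate_cells(net_def, p_def, n = 3, seed = 34, t_end = 8)
  expect_false(identical(a[[1]]$channels, c_[[1]]$channels))
})
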