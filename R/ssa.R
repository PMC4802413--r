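# Stochastic simulation: Gillespie direct method and explicit tau-leap on
# the same declarative network, plus seeded ensembles.

#' Stochastic engine configuration
#'
#' @param omega system size: molecules per a.u. of concentration (>= 1).
#'   Deterministic levels x map to integer counts round(x * omega);
#'   propensities are evaluated as omega * f(n / omega), which yields the
#'   usual k/omega scaling for bimolecular and k*omega for zero-order
#'   mass-action reactions. Fraction-valued species (active Cdh1) are
#'   represented as counts out of omega.
#' @param seed global integer seed; per-cell substreams are derived from it
#'   with a counter-based hash, so ensemble members are independent of
#'   evaluation order.
#' @param method \code{"direct"} (exact) or \code{"tau-leap"}.
#' @param epsilon tau-leap error-control parameter in (0, 0.1].
#' @param n ensemble size (>= 1).
#' @param extrinsic_cv coefficient of variation of optional per-cell
#'   lognormal scaling of synthesis rates (default 0: intrinsic noise only).
#' @return object of class \code{g1s_ssa_config}.
#' @export
stochastic_config <- function(omega = 500, seed = 1, method = c("direct", "tau-leap"),
                              epsilon = 0.03, n = 1, extrinsic_cv = 0) {
  method <- match.arg(method)
  if (omega < 1 || omega != round(omega)) stop("omega must be a positive integer")
  if (n < 1) stop("ensemble size n must be >= 1")
  if (epsilon <= 0 || epsilon > 0.1) stop("epsilon must be in (0, 0.1]")
  structure(list(omega = omega, seed = seed, method = method,
                 epsilon = epsilon, n = n, extrinsic_cv = extrinsic_cv),
            class = "g1s_ssa_config")
}

# deterministic per-stream uniforms derived from (seed, stream, index)
stream_uniform <- function(seed, stream, k) {
  stream_seed_cpp(seed * 1000003 + stream, k) / 9007199254740992
}

# lognormal synthesis-rate scaling for one cell (mean 1, given CV)
extrinsic_scaling <- function(params, seed, cell, cv) {
  if (cv <= 0) return(params)
  syn <- grep("^ks_", names(params$value), value = TRUE)
  sdlog <- sqrt(log(1 + cv^2))
  for (i in seq_along(syn)) {
    u <- stream_uniform(seed, cell, 7000 + i)
    z <- stats::qnorm(u)
    params$value[[syn[i]]] <- params$value[[syn[i]]] *
      exp(z * sdlog - sdlog^2 / 2)
  }
  params
}

#' Exact (or tau-leap) stochastic sample path
#'
#' Runs one stochastic realisation of the jump process whose propensities
#' are the network's rate laws scaled to molecule counts. Reproducible:
#' the same (seed, config, protocol) always yields the same path.
#'
#' @param network a \code{g1s_network}.
#' @param params a \code{g1s_parameters}.
#' @param init named state in a.u.; converted to counts by rounding
#'   \code{init * omega}.
#' @param t_end end time (hours).
#' @param config a \code{g1s_ssa_config}; its \code{seed} seeds this path.
#' @param protocol optional \code{g1s_protocol}.
#' @param grid_dt output grid spacing (hours).
#' @return a \code{g1s_trajectory} with species in a.u. (counts / omega).
#' @export
ssa_run <- function(network, params, init = default_postmitotic_state(),
                    t_end = 15, config = stochastic_config(),
                    protocol = NULL, grid_dt = 0.05) {
  comp <- compiled(network, params)
  x0 <- state_vector(init, comp$species)
  omega <- config$omega
  n0 <- round(x0 * omega)
  tri <- which(comp$stoich != 0, arr.ind = TRUE)
  tri_sp <- as.integer(tri[, 1] - 1L)
  tri_rx <- as.integer(tri[, 2] - 1L)
  tri_coef <- comp$stoich[tri]
  max_counts <- rep(Inf, comp$n_species)
  max_counts[comp$species %in% network$unit_interval] <- omega
  grid <- seq(0, t_end, by = grid_dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  segs <- protocol_segments(protocol, t_end)
  par_now <- params
  counts <- n0
  out <- matrix(NA_real_, nrow = length(grid), ncol = comp$n_species)
  seg_i <- 0L
  for (seg in segs) {
    seg_i <- seg_i + 1L
    if (!is.null(seg$events)) {
      st_au <- stats::setNames(counts / omega, comp$species)
      ae <- apply_events(seg$events, st_au, par_now)
      par_now <- ae$params
      counts <- round(state_vector(ae$state, comp$species) * omega)
    }
    if (seg$t1 <= seg$t0) next
    pv <- unname(par_now$value[comp$param_names])
    seg_sel <- which(grid >= seg$t0 & grid <= seg$t1)
    seg_grid <- grid[seg_sel]
    sd <- stream_seed_cpp(config$seed, seg_i)
    res <- if (config$method == "direct") {
      ssa_cpp(comp$ops, comp$args, comp$consts, comp$offsets,
              tri_rx, tri_sp, tri_coef, comp$n_species, comp$depends,
              counts, pv, omega, seg$t0, seg$t1, seg_grid, sd, 5e8)
    } else {
      tau_leap_cpp(comp$ops, comp$args, comp$consts, comp$offsets,
                   tri_rx, tri_sp, tri_coef, comp$n_species,
                   counts, pv, omega, seg$t0, seg$t1, seg_grid, sd,
                   config$epsilon, max_counts, 1e8)
    }
    out[seg_sel, ] <- res$counts
    counts <- res$final
  }
  mat <- out / omega
  colnames(mat) <- comp$species
  new_trajectory(grid, mat, par_now, network, protocol,
                 engine = "ssa", seed = config$seed,
                 settings = list(omega = omega, method = config$method,
                                 epsilon = config$epsilon, grid_dt = grid_dt))
}

#' Seeded stochastic ensemble with per-cell event statistics
#'
#' Runs \code{config$n} independent stochastic cells (per-cell seeds derived
#' from the global seed by a counter-based hash), detects each cell's G1/S
#' transition and switch abruptness, and summarises the ensemble with
#' time-resolved mean and standard deviation per species.
#'
#' @inheritParams ssa_run
#' @param keep_paths keep the individual \code{g1s_trajectory} objects
#'   (memory permitting).
#' @return object of class \code{g1s_ensemble} with fields
#'   \code{g1s_times}, \code{abruptness}, \code{mean}, \code{sd},
#'   \code{min}, \code{max} (time x species matrices), \code{time},
#'   \code{seeds}, and optionally \code{paths}.
#' @export
run_ensemble <- function(network, params, init = default_postmitotic_state(),
                         t_end = 15, config = stochastic_config(),
                         protocol = NULL, grid_dt = 0.05, keep_paths = FALSE) {
  n <- config$n
  network <- precompile(network, params)
  seeds <- vapply(seq_len(n), function(i) stream_seed_cpp(config$seed, i), 0)
  acc_mean <- NULL; acc_m2 <- NULL; acc_min <- NULL; acc_max <- NULL
  g1s_times <- numeric(n); abrupt <- numeric(n)
  paths <- if (keep_paths) vector("list", n) else NULL
  time <- NULL
  for (i in seq_len(n)) {
    ci <- config; ci$seed <- seeds[i]; ci$n <- 1
    pi_ <- extrinsic_scaling(params, config$seed, i, config$extrinsic_cv)
    tr <- ssa_run(network, pi_, init, t_end, ci, protocol, grid_dt)
    g1s_times[i] <- detect_g1s(tr)
    abrupt[i] <- switch_abruptness(tr)
    m <- tr$species
    if (is.null(acc_mean)) {
      time <- tr$time
      acc_mean <- m; acc_m2 <- m * 0; acc_min <- m; acc_max <- m
    } else {
      # Welford update, elementwise over the time x species matrix
      delta <- m - acc_mean
      acc_mean <- acc_mean + delta / i
      acc_m2 <- acc_m2 + delta * (m - acc_mean)
      acc_min <- pmin(acc_min, m); acc_max <- pmax(acc_max, m)
    }
    if (keep_paths) paths[[i]] <- tr
  }
  sdm <- if (n > 1) sqrt(acc_m2 / (n - 1)) else acc_m2
  structure(list(time = time, mean = acc_mean, sd = sdm,
                 min = acc_min, max = acc_max,
                 g1s_times = g1s_times, abruptness = abrupt,
                 seeds = seeds, n = n, config = config),
            class = "g1s_ensemble") -> ens
  if (keep_paths) ens$paths <- paths
  ens
}

#' @export
print.g1s_ensemble <- function(x, ...) {
  cat(sprintf("Stochastic ensemble: n = %d, omega = %d, %s method\n",
              x$n, x$config$omega, x$config$method))
  ok <- !is.na(x$g1s_times)
  cat(sprintf("G1/S detected in %d/%d cells; median time %.2f h (IQR %.2f-%.2f)\n",
              sum(ok), x$n, stats::median(x$g1s_times[ok]),
              stats::quantile(x$g1s_times[ok], 0.25),
              stats::quantile(x$g1s_times[ok], 0.75)))
  invisible(x)
}
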