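# Synthetic single-cell reporter traces with the statistical structure of
# live-imaging data (GFP-tagged p27, CyclinE1, CyclinA2; a
# cytoplasmic:nuclear Cdk2 sensor ratio; a PCNA-like S-phase marker), plus
# the trace-processing pipeline: S-entry calling, alignment at S entry,
# background subtraction, peak normalization and ensemble averaging.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Noise model configuration for synthetic traces
#'
#' @param sigma per-frame multiplicative lognormal noise (sdlog), default 0.05.
#' @param background_frac additive background as a fraction of the clean
#'   channel peak, default 0.05.
#' @param gain_cv coefficient of variation of the per-cell lognormal gain,
#'   default 0.1.
#' @param g1_cv cell-to-cell G1-duration variability (lognormal CV of a
#'   per-cell kinetic time-dilation factor; deterministic engine only).
#'   Off (0) by default; 0.25 emulates the observed several-hour spread of
#'   G1 durations when the mode is enabled.
#' @return a list of class \code{g1s_noise_config}.
#' @export
noise_config <- function(sigma = 0.05, background_frac = 0.05,
                         gain_cv = 0.1, g1_cv = 0) {
  structure(list(sigma = sigma, background_frac = background_frac,
                 gain_cv = gain_cv, g1_cv = g1_cv),
            class = "g1s_noise_config")
}

new_trace <- function(cell_id, time, channels, s_entry_true = NA_real_,
                      division_time = 0, meta = list()) {
  structure(list(cell_id = cell_id, time = time, channels = channels,
                 s_entry_true = s_entry_true, division_time = division_time,
                 meta = meta),
            class = "g1s_trace")
}

#' @export
print.g1s_trace <- function(x, ...) {
  cat(sprintf("Single-cell trace '%s': %d frames x %d channels, true S entry %.2f h\n",
              x$cell_id, nrow(x$channels), ncol(x$channels), x$s_entry_true))
  invisible(x)
}

lognorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Generate synthetic single-cell reporter traces
#'
#' Each cell is one model trajectory (stochastic, or deterministic with a
#' per-cell lognormal time-dilation emulating G1-duration variability)
#' mapped to imaging channels: GFP channels are species totals scaled by a
#' per-cell gain plus additive background and per-frame multiplicative
#' lognormal noise; \code{cdk2_ratio} is an affine map of the model Cdk2
#' activity (baseline + slope * activity); \code{pcna_proxy} steps up
#' sigmoidally at the model's G1/S time. The true S-entry time is stored as
#' generator ground truth and is not used by any processing step.
#'
#' @param network a \code{g1s_network}.
#' @param params a \code{g1s_parameters}.
#' @param n number of cells.
#' @param noise a \code{\link{noise_config}} (use
#'   \code{noise_config(0, 0, 0, 0)} for a noiseless identity mapping).
#' @param seed integer seed; output is fully reproducible.
#' @param engine \code{"ode"} (with time dilation) or \code{"ssa"}.
#' @param t_end trace length (hours).
#' @param frame_dt frame interval (hours, default 1/6 = 10 min).
#' @param omega system size for the stochastic engine.
#' @param cdk2_baseline,cdk2_slope affine map of the Cdk2-sensor ratio.
#' @return list of \code{g1s_trace}.
#' @export
generate_cells <- function(network, params, n = 20,
                           noise = noise_config(), seed = 1,
                           engine = c("ode", "ssa"), t_end = 15,
                           frame_dt = 1 / 6, omega = 500,
                           cdk2_baseline = 0.5, cdk2_slope = 1.0) {
  engine <- match.arg(engine)
  stopifnot(n >= 1)
  network <- precompile(network, params)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      if (engine == "ode") {
        dil <- lognorm_factor(1, noise$g1_cv)
        # median-1 time dilation: scale every rate constant by 1/dil
        pi_ <- params
        pi_$value <- pi_$value / dil
        pi_$value[c("w_e", "w_a")] <- params$value[c("w_e", "w_a")]
        pi_$value[["j_cdh1"]] <- params$value[["j_cdh1"]]
        pi_$lower <- pmin(pi_$lower, pi_$value)
        pi_$upper <- pmax(pi_$upper, pi_$value)
        traj <- simulate_ode(network, pi_, t_end = t_end, grid_dt = frame_dt)
      } else {
        cfg <- stochastic_config(omega = omega,
                                 seed = floor(stats::runif(1, 0, 2^31)))
        traj <- ssa_run(network, params, t_end = t_end, config = cfg,
                        grid_dt = frame_dt)
      }
      ts <- detect_g1s(traj)
      tt <- traj$time
      clean <- cbind(
        p27_gfp = series(traj, "p27_total"),
        cyclinE_gfp = series(traj, "cyclinE_total"),
        cyclinA_gfp = series(traj, "cyclinA_total"))
      pcna <- if (is.na(ts)) rep(0.1, length(tt)) else
        0.1 + 1 / (1 + exp(-(tt - ts) / 0.1))
      ratio <- cdk2_baseline + cdk2_slope * series(traj, "cdk2_activity")
      gain <- lognorm_factor(1, noise$gain_cv)
      noisy <- function(x, use_gain = TRUE, bg = TRUE) {
        b <- if (bg) noise$background_frac * max(x) else 0
        g <- if (use_gain) gain else 1
        # per-frame multiplicative lognormal noise, sdlog = sigma, mean 1
        f <- exp(stats::rnorm(length(x), -noise$sigma^2 / 2, noise$sigma))
        (x + b) * g * f
      }
      ch <- cbind(p27_gfp = noisy(clean[, 1]),
                  cyclinE_gfp = noisy(clean[, 2]),
                  cyclinA_gfp = noisy(clean[, 3]),
                  cdk2_ratio = noisy(ratio, use_gain = FALSE, bg = FALSE),
                  pcna_proxy = noisy(pcna))
      new_trace(cell_id = sprintf("cell_%03d", i), time = tt, channels = ch,
                s_entry_true = ts,
                meta = list(engine = engine, seed = seed))
    })
  })
}

#' Call S-phase entry from the PCNA-like channel
#'
#' S entry is the first frame where the derivative of the (3-frame smoothed)
#' PCNA proxy exceeds a scale-free threshold: three times the median
#' absolute frame-to-frame change, floored at 10 percent of the channel's
#' dynamic range per frame. Being derivative-based, the call is invariant to
#' adding a constant to the channel.
#'
#' @param trace a \code{g1s_trace}.
#' @return time in hours, or \code{NA_real_} if no sharp increase exists.
#' @export
call_s_entry <- function(trace) {
  p <- trace$channels[, "pcna_proxy"]
  if (length(p) < 4) return(NA_real_)
  sm <- stats::filter(p, rep(1 / 3, 3), sides = 2)
  sm[1] <- p[1]; sm[length(p)] <- p[length(p)]
  d <- diff(as.numeric(sm))
  rng <- max(p) - min(p)
  thr <- max(3 * stats::median(abs(d)), 0.1 * rng)
  if (thr <= 0 || !any(d > thr)) return(NA_real_)
  i <- which(d > thr)[1]
  # refine to the derivative-weighted centroid of the jump so the call sits
  # at the centre of the intensity increase with sub-frame accuracy
  win <- max(1, i - 2):min(length(d), i + 2)
  i <- win[which.max(d[win])]
  win <- max(1, i - 2):min(length(d), i + 2)
  w <- pmax(d[win], 0)
  mid <- (trace$time[win] + trace$time[win + 1]) / 2
  sum(w * mid) / sum(w)
}

#' Process and align traces into a pseudo-synchronized ensemble
#'
#' Implements the imaging pipeline: call S entry per cell (cells without a
#' call are dropped, with a message), subtract the average background,
#' clip at zero, normalize each cell's channels to their peak, shift time so
#' that S entry is zero, re-grid every cell onto a common aligned grid by
#' linear interpolation, and compute the per-timepoint ensemble mean and
#' standard deviation over the cells present.
#'
#' @param traces list of \code{g1s_trace}.
#' @param background average background intensity subtracted from every
#'   channel (scalar or named per-channel vector), default 0.
#' @param channels channels to process (default: all but the PCNA proxy).
#' @return object of class \code{g1s_aligned}: \code{time} (hours relative
#'   to S entry), per-channel cell x time matrices in \code{cells},
#'   \code{mean} and \code{sd} matrices (time x channel), \code{n_at}
#'   (cells contributing per time point), and \code{provenance}.
#' @export
process_and_align <- function(traces, background = 0,
                              channels = c("p27_gfp", "cyclinE_gfp",
                                           "cyclinA_gfp", "cdk2_ratio")) {
  calls <- vapply(traces, call_s_entry, 0)
  drop <- is.na(calls)
  if (any(drop))
    message(sum(drop), " cell(s) without a called S entry dropped")
  traces <- traces[!drop]; calls <- calls[!drop]
  if (!length(traces)) stop("no cells with a called S entry")
  dt <- stats::median(diff(traces[[1]]$time))
  lo <- max(vapply(seq_along(traces), function(i)
    min(traces[[i]]$time - calls[i]), 0))
  hi <- min(vapply(seq_along(traces), function(i)
    max(traces[[i]]$time - calls[i]), 0))
  grid <- seq(ceiling(lo / dt) * dt, floor(hi / dt) * dt, by = dt)
  bg <- if (length(background) == 1)
    stats::setNames(rep(background, length(channels)), channels)
  else background[channels]
  norm_consts <- matrix(NA_real_, length(traces), length(channels),
                        dimnames = list(vapply(traces, `[[`, "", "cell_id"),
                                        channels))
  cells <- lapply(stats::setNames(nm = channels), function(chn) {
    m <- matrix(NA_real_, length(traces), length(grid))
    for (i in seq_along(traces)) {
      x <- pmax(traces[[i]]$channels[, chn] - bg[[chn]], 0)
      pk <- max(x)
      norm_consts[i, chn] <<- pk
      if (pk > 0) x <- x / pk
      m[i, ] <- stats::approx(traces[[i]]$time - calls[i], x, grid)$y
    }
    m
  })
  mean_mat <- sapply(cells, function(m) colMeans(m, na.rm = TRUE))
  sd_mat <- sapply(cells, function(m) apply(m, 2, stats::sd, na.rm = TRUE))
  n_at <- apply(!is.na(cells[[1]]), 2, sum)
  structure(list(time = grid, cells = cells, mean = mean_mat, sd = sd_mat,
                 n_at = n_at,
                 provenance = list(background = bg,
                                   normalization = norm_consts,
                                   s_entry_called = calls,
                                   n_dropped = sum(drop))),
            class = "g1s_aligned")
}

#' @export
print.g1s_aligned <- function(x, ...) {
  cat(sprintf("Aligned ensemble: %d cells, %d aligned frames (%.2f to %.2f h around S entry)\n",
              nrow(x$cells[[1]]), length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Ensemble-average reporter time courses
#'
#' The per-channel mean series of an aligned ensemble: the fitting target
#' that corresponds to averaged pseudo-synchronized single-cell data.
#'
#' @param ensemble a \code{g1s_aligned}.
#' @return named list of data.frames (\code{time_h}, \code{value}), one per
#'   channel; time is hours relative to S entry.
#' @export
ensemble_average <- function(ensemble) {
  lapply(stats::setNames(nm = colnames(ensemble$mean)), function(chn)
    data.frame(time_h = ensemble$time, value = ensemble$mean[, chn]))
}
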