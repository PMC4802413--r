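# File formats: networks and parameters as JSON/YAML, trajectories and
# single-cell traces as tidy long CSV with JSON provenance sidecars.
# All round trips (write then read) are lossless at full double precision.

fmt_of <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) "yaml" else "json"
}

write_structured <- function(x, path) {
  if (fmt_of(path) == "yaml") {
    yaml::write_yaml(x, path, precision = 17)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt_of(path) == "yaml") yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

#' Write / read a reaction network
#'
#' Networks serialise to JSON (or YAML, by file extension) with species,
#' reactions (name, stoichiometry, rate law), observables, unit-interval
#' species and metadata. The round trip is lossless.
#'
#' @param network a \code{g1s_network}.
#' @param path output file (\code{.json}, \code{.yaml}).
#' @return \code{write_network}: the path, invisibly. \code{read_network}:
#'   a \code{g1s_network}.
#' @export
write_network <- function(network, path) {
  x <- list(
    species = network$species,
    reactions = lapply(network$reactions, function(rx)
      list(name = rx$name, stoich = as.list(rx$stoich), rate = rx$rate)),
    observables = lapply(network$observables, as.list),
    unit_interval = network$unit_interval,
    metadata = network$metadata)
  write_structured(x, path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  x <- read_structured(path)
  reactions <- lapply(x$reactions, function(rx) {
    st <- unlist(rx$stoich)
    storage.mode(st) <- "integer"
    list(name = rx$name, stoich = st, rate = rx$rate)
  })
  observables <- lapply(x$observables, function(ob) unlist(ob))
  reaction_network(unlist(x$species), reactions, observables,
                   metadata = if (is.null(x$metadata)) "" else x$metadata,
                   unit_interval = as.character(unlist(x$unit_interval)))
}

#' Write / read a kinetic parameter set
#'
#' @param params a \code{g1s_parameters}.
#' @param path output file (\code{.json} or \code{.yaml}).
#' @return \code{read_parameters} returns a \code{g1s_parameters}.
#' @export
write_parameters <- function(params, path) {
  x <- list(value = as.list(params$value), unit = as.list(params$unit),
            fittable = as.list(params$fittable),
            lower = as.list(params$lower), upper = as.list(params$upper))
  write_structured(x, path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  x <- read_structured(path)
  v <- unlist(x$value)
  kinetic_parameters(v, unlist(x$unit)[names(v)],
                     unlist(x$fittable)[names(v)],
                     lower = unlist(x$lower)[names(v)],
                     upper = unlist(x$upper)[names(v)])
}

#' Write / read a perturbation protocol
#'
#' @param protocol a \code{g1s_protocol}.
#' @param path output file (\code{.json} or \code{.yaml}).
#' @return \code{read_protocol} returns a \code{g1s_protocol}.
#' @export
write_protocol <- function(protocol, path) {
  write_structured(list(label = protocol$label,
                        events = protocol$events), path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- read_structured(path)
  ev <- x$events
  if (!is.data.frame(ev))
    ev <- do.call(rbind, lapply(ev, function(e) as.data.frame(e)))
  perturbation_protocol(ev, label = if (is.null(x$label)) "" else x$label)
}

#' Write / read a trajectory
#'
#' The trajectory goes to tidy CSV (\code{time_h}, \code{species},
#' \code{value}, including observable rows) next to a JSON sidecar
#' (\code{<path>.meta.json}) holding engine, seed and settings. Reading
#' reconstructs the time grid and matrices exactly.
#'
#' @param traj a \code{g1s_trajectory}.
#' @param path CSV output path.
#' @return \code{read_trajectory} returns a list with \code{time},
#'   \code{species} matrix, \code{observables} and \code{meta}.
#' @export
write_trajectory <- function(traj, path) {
  long <- as.data.frame(traj)
  utils::write.csv(format(long, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(engine = traj$engine, seed = traj$seed,
               settings = traj$settings,
               species = colnames(traj$species),
               observables = names(traj$observables),
               protocol = if (is.null(traj$protocol)) NULL else
                 list(label = traj$protocol$label,
                      events = traj$protocol$events))
  write_structured(meta, paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "species", "value")
  miss <- setdiff(need, names(long))
  if (length(miss)) stop("trajectory CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  meta <- read_structured(paste0(path, ".meta.json"))
  sp <- unlist(meta$species)
  time <- sort(unique(long$time_h[long$species == sp[1]]))
  mat <- sapply(sp, function(s) long$value[long$species == s])
  obs <- lapply(stats::setNames(nm = unlist(meta$observables)),
                function(o) long$value[long$species == o])
  list(time = time, species = mat, observables = obs, meta = meta)
}

#' Write / read single-cell traces
#'
#' Long CSV with columns \code{cell_id}, \code{time_h}, \code{channel},
#' \code{intensity}. Unknown extra columns are preserved as an attribute
#' (\code{extra_columns}) and ignored by processing. An empty file is a
#' parse error, not an empty list.
#'
#' @param traces list of \code{g1s_trace} objects
#'   (see \code{\link{generate_cells}}).
#' @param path CSV path.
#' @return \code{read_traces} returns a list of \code{g1s_trace}.
#' @export
write_traces <- function(traces, path) {
  long <- do.call(rbind, lapply(traces, function(tr) {
    ch <- tr$channels
    data.frame(cell_id = tr$cell_id,
               time_h = rep(tr$time, times = ncol(ch)),
               channel = rep(colnames(ch), each = nrow(ch)),
               intensity = as.vector(ch))
  }))
  utils::write.csv(format(long, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(long) == 0) stop("trace file is empty: ", path)
  need <- c("cell_id", "time_h", "channel", "intensity")
  miss <- setdiff(need, names(long))
  if (length(miss)) stop("trace CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(long), need)
  cells <- split(long, long$cell_id)
  traces <- lapply(cells, function(df) {
    chs <- split(df, df$channel)
    time <- sort(unique(df$time_h))
    ch <- sapply(chs, function(d) d$intensity[order(d$time_h)])
    new_trace(cell_id = df$cell_id[1], time = time, channels = ch)
  })
  names(traces) <- NULL
  attr(traces, "extra_columns") <- extra
  traces
}

#' Run a configured scenario end to end
#'
#' Executes one simulation pipeline from a configuration (a list or a
#' JSON/YAML file): deterministic or stochastic engine, optional protocol,
#' and writes the trajectory CSV plus a provenance sidecar (config hash,
#' seed, package version) into the output directory. This is the
#' programmatic equivalent of a command-line run; every artifact is
#' reconstructible from its sidecar.
#'
#' @param config list or path. Fields: \code{engine} ("ode"/"ssa"),
#'   \code{t_end}, \code{seed}, \code{omega}, \code{protocol} (label of a
#'   built-in protocol or a protocol file), \code{network}/\code{params}
#'   (file paths; defaults used when absent), \code{grid_dt}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the trajectory and artifact paths.
#' @export
run_scenario <- function(config, out_dir) {
  if (is.character(config)) config <- read_structured(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- if (!is.null(config$params)) read_parameters(config$params)
    else default_parameters()
  network <- if (!is.null(config$network)) read_network(config$network)
    else build_default_network(params)
  protocol <- NULL
  if (!is.null(config$protocol)) {
    protocol <- switch(config$protocol,
      cyclinE_knockdown = cyclinE_knockdown(),
      cyclinA_knockdown = cyclinA_knockdown(),
      emi1_depletion = emi1_depletion(),
      cdk_inhibition = cdk_inhibition(),
      read_protocol(config$protocol))
  }
  engine <- if (is.null(config$engine)) "ode" else config$engine
  t_end <- if (is.null(config$t_end)) 15 else config$t_end
  grid_dt <- if (is.null(config$grid_dt)) 0.05 else config$grid_dt
  seed <- if (is.null(config$seed)) 1 else config$seed
  init <- default_postmitotic_state()
  traj <- if (engine == "ssa") {
    cfg <- stochastic_config(omega = if (is.null(config$omega)) 500 else config$omega,
                             seed = seed)
    ssa_run(network, params, init, t_end, cfg, protocol, grid_dt)
  } else {
    simulate_ode(network, params, init, t_end, protocol, grid_dt)
  }
  traj_path <- file.path(out_dir, "trajectory.csv")
  write_trajectory(traj, traj_path)
  prov <- list(
    package_version = as.character(utils::packageVersion("g1switch")),
    engine = engine, seed = seed, t_end = t_end, grid_dt = grid_dt,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    g1s_time_h = detect_g1s(traj))
  write_structured(prov, file.path(out_dir, "provenance.json"))
  invisible(list(trajectory = traj, paths = c(traj_path,
                 file.path(out_dir, "provenance.json"))))
}
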