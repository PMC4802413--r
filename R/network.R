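#' @useDynLib g1switch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Rate-law bytecode op codes shared with src/engine.cpp
OP_CONST <- 1L; OP_SPECIES <- 2L; OP_PARAM <- 3L
OP_ADD <- 4L; OP_SUB <- 5L; OP_MUL <- 6L; OP_DIV <- 7L; OP_POW <- 8L; OP_NEG <- 9L

#' Declarative reaction network
#'
#' A reaction network is pure data: an ordered species list, a list of
#' reactions (integer stoichiometry plus a rate-law expression written in
#' terms of species and named parameters), and linear observables. Every
#' simulation and analysis engine in the package (ODE, Gillespie, tau-leap,
#' steady-state continuation) derives its computation from this one object,
#' so alternative networks (e.g. the pRb/E2F extension) can be swapped in
#' without touching engine code.
#'
#' @param species character vector of species names (order defines state order).
#' @param reactions list; each element a list with elements \code{name}
#'   (string), \code{stoich} (named integer vector, names in \code{species}),
#'   and \code{rate} (string: an arithmetic expression in species and
#'   parameter names using \code{+ - * / ^} and parentheses).
#' @param observables named list of named numeric weight vectors over species.
#' @param metadata free-text provenance string.
#' @param unit_interval names of species constrained to the unit interval
#'   (fractions such as active APC/C-Cdh1); the stochastic engine represents
#'   these as counts out of the system size.
#' @return object of class \code{g1s_network}.
#' @export
reaction_network <- function(species, reactions, observables = list(),
                             metadata = "", unit_interval = character()) {
  stopifnot(is.character(species), length(species) > 0, !anyDuplicated(species))
  stopifnot(all(unit_interval %in% species))
  net <- structure(
    list(species = species, reactions = reactions,
         observables = observables, metadata = metadata,
         unit_interval = unit_interval),
    class = "g1s_network")
  net
}

#' @export
print.g1s_network <- function(x, ...) {
  cat("G1/S reaction network:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  cat("species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' Kinetic parameter set
#'
#' Named nonnegative rate constants with units, bounds and a fixed/fittable
#' flag. Parameters flagged fixed correspond to mRNA/protein turnover rates
#' taken from the literature; everything else is unknown and fittable.
#'
#' @param value named numeric vector of parameter values (>= 0).
#' @param unit named character vector, one of \code{"1/h"}, \code{"a.u."},
#'   \code{"a.u./h"}, \code{"dimensionless"}.
#' @param lower,upper named numeric bounds (defaults: value/100 and
#'   value*100 for fittable parameters, the value itself for fixed ones).
#' @param fittable named logical vector.
#' @return object of class \code{g1s_parameters}.
#' @export
kinetic_parameters <- function(value, unit, fittable,
                               lower = NULL, upper = NULL) {
  nm <- names(value)
  stopifnot(!is.null(nm), setequal(nm, names(unit)), setequal(nm, names(fittable)))
  unit <- unit[nm]; fittable <- fittable[nm]
  if (is.null(lower)) lower <- ifelse(fittable, value / 100, value)
  if (is.null(upper)) upper <- ifelse(fittable, value * 100, value)
  names(lower) <- nm; names(upper) <- nm
  structure(list(value = value, unit = unit, fittable = fittable,
                 lower = lower, upper = upper),
            class = "g1s_parameters")
}

#' @export
print.g1s_parameters <- function(x, ...) {
  cat("Kinetic parameters:", length(x$value), "total,",
      sum(x$fittable), "fittable\n")
  print(data.frame(value = x$value, unit = x$unit, fittable = x$fittable))
  invisible(x)
}

#' @export
`[.g1s_parameters` <- function(x, i) x$value[i]

#' Update parameter values
#'
#' Returns a copy of a parameter set with the named values replaced.
#'
#' @param params a \code{g1s_parameters} object.
#' @param ... named scalar replacements, or a single named numeric vector.
#' @return modified \code{g1s_parameters}.
#' @export
set_parameters <- function(params, ...) {
  repl <- c(...)
  bad <- setdiff(names(repl), names(params$value))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  params$value[names(repl)] <- repl
  params
}

# ---- canonical HeLa G1/S model ---------------------------------------------

g1s_species <- c("cyclinE_mRNA", "cyclinA_mRNA", "cycE", "cycA",
                 "p27", "p27_cycE", "p27_cycA", "p27_T187p",
                 "emi1", "skp2", "cdh1_active", "e2f_active")

# Cdk2 activity expression reused inside rate laws (free complexes only)
.ACT <- "(w_e*cycE + w_a*cycA)"

.rxn <- function(name, stoich, rate) list(name = name, stoich = stoich, rate = rate)

default_reactions <- function() {
  A <- .ACT
  list(
    .rxn("cyclinE_mRNA_synthesis",  c(cyclinE_mRNA = 1L),  "ks_me * e2f_active"),
    .rxn("cyclinE_mRNA_degradation", c(cyclinE_mRNA = -1L), "kd_me * cyclinE_mRNA"),
    .rxn("cyclinA_mRNA_synthesis",  c(cyclinA_mRNA = 1L),  "ks_ma * e2f_active"),
    .rxn("cyclinA_mRNA_degradation", c(cyclinA_mRNA = -1L), "kd_ma * cyclinA_mRNA"),

    .rxn("cyclinE_synthesis",       c(cycE = 1L),  "ks_e * cyclinE_mRNA"),
    .rxn("cyclinE_degradation",     c(cycE = -1L), "kd_e * cycE"),
    .rxn("cyclinE_degradation_cdk2", c(cycE = -1L),
         paste0("kd_e_cdk2 * ", A, " * cycE")),
    .rxn("bound_cyclinE_degradation", c(p27_cycE = -1L, p27 = 1L),
         "kd_e * p27_cycE"),
    .rxn("bound_cyclinE_degradation_cdk2", c(p27_cycE = -1L, p27 = 1L),
         paste0("kd_e_cdk2 * ", A, " * p27_cycE")),

    .rxn("cyclinA_synthesis",       c(cycA = 1L),  "ks_a * cyclinA_mRNA"),
    .rxn("cyclinA_degradation",     c(cycA = -1L), "kd_a * cycA"),
    .rxn("cyclinA_degradation_cdh1", c(cycA = -1L),
         "kd_a_cdh1 * cdh1_active * cycA / (j_a + cycA + p27_cycA)"),
    .rxn("bound_cyclinA_degradation", c(p27_cycA = -1L, p27 = 1L),
         "kd_a * p27_cycA"),
    .rxn("bound_cyclinA_degradation_cdh1", c(p27_cycA = -1L, p27 = 1L),
         "kd_a_cdh1 * cdh1_active * p27_cycA / (j_a + cycA + p27_cycA)"),

    .rxn("p27_synthesis",           c(p27 = 1L),  "ks_p27"),
    .rxn("p27_degradation",         c(p27 = -1L), "kd_p27 * p27"),
    .rxn("bound_p27_degradation_E", c(p27_cycE = -1L, cycE = 1L),
         "kd_p27 * p27_cycE"),
    .rxn("bound_p27_degradation_A", c(p27_cycA = -1L, cycA = 1L),
         "kd_p27 * p27_cycA"),

    .rxn("p27_cycE_binding",  c(p27 = -1L, cycE = -1L, p27_cycE = 1L),
         "kass_e * p27 * cycE"),
    .rxn("p27_cycE_release",  c(p27_cycE = -1L, p27 = 1L, cycE = 1L),
         "kdiss_e * p27_cycE"),
    .rxn("p27_cycA_binding",  c(p27 = -1L, cycA = -1L, p27_cycA = 1L),
         "kass_a * p27 * cycA"),
    .rxn("p27_cycA_release",  c(p27_cycA = -1L, p27 = 1L, cycA = 1L),
         "kdiss_a * p27_cycA"),

    .rxn("p27_T187_phosphorylation", c(p27 = -1L, p27_T187p = 1L),
         paste0("kphos_p27 * ", A, " * p27")),
    .rxn("bound_p27_T187_phosphorylation_E",
         c(p27_cycE = -1L, p27_T187p = 1L, cycE = 1L),
         paste0("kphos_p27 * ", A, " * p27_cycE")),
    .rxn("bound_p27_T187_phosphorylation_A",
         c(p27_cycA = -1L, p27_T187p = 1L, cycA = 1L),
         paste0("kphos_p27 * ", A, " * p27_cycA")),
    .rxn("p27_T187p_dephosphorylation", c(p27_T187p = -1L, p27 = 1L),
         "kdephos_p27 * p27_T187p"),
    .rxn("p27_T187p_degradation_skp2", c(p27_T187p = -1L),
         "kd_p27p_skp2 * skp2 * p27_T187p"),

    .rxn("emi1_synthesis",    c(emi1 = 1L),  "ks_emi1 * e2f_active"),
    .rxn("emi1_degradation",  c(emi1 = -1L), "kd_emi1 * emi1"),

    .rxn("skp2_synthesis",    c(skp2 = 1L),  "ks_skp2"),
    .rxn("skp2_degradation",  c(skp2 = -1L), "kd_skp2 * skp2"),
    .rxn("skp2_degradation_cdh1", c(skp2 = -1L),
         "kd_skp2_cdh1 * cdh1_active * skp2"),

    .rxn("cdh1_activation",   c(cdh1_active = 1L),
         "ka_cdh1 * (1 - cdh1_active) / (j_cdh1 + 1 - cdh1_active)"),
    .rxn("cdh1_inactivation", c(cdh1_active = -1L),
         paste0("(ki_cdh1_emi1 * emi1 + ki_cdh1_cdk2 * ", A,
                ") * cdh1_active / (j_cdh1 + cdh1_active)"))
  )
}

#' Default G1/S reaction network
#'
#' Builds the canonical HeLa G1/S control network: E2F-driven synthesis of
#' CyclinE, CyclinA and Emi1; APC/C-Cdh1-dependent CyclinA and Skp2
#' degradation; Emi1- and Cdk2-dependent Cdh1 inactivation; reversible
#' stoichiometric p27 binding to both Cdk2:Cyclin complexes; Cdk2-dependent
#' T187 phosphorylation of p27 feeding SCF-Skp2-dependent degradation; and
#' Cdk2-dependent CyclinE degradation. E2F activity is a constant input
#' (HeLa cells lack functional pRb); see \code{\link{build_rb_network}} for
#' the restriction-point extension that makes it dynamic.
#'
#' Degradation of a cyclin inside a p27 complex releases free p27, and
#' phosphorylation/degradation of complexed p27 releases the free (active)
#' Cdk2:Cyclin complex, so the bookkeeping identities
#' total CyclinE = cycE + p27_cycE (and analogously for CyclinA) hold.
#'
#' @param params parameter set used to validate that every rate-law symbol
#'   resolves; defaults to \code{default_parameters()}.
#' @return a validated \code{g1s_network}.
#' @export
build_default_network <- function(params = default_parameters()) {
  net <- reaction_network(
    species = g1s_species,
    reactions = default_reactions(),
    observables = list(
      p27_total = c(p27 = 1, p27_cycE = 1, p27_cycA = 1, p27_T187p = 1),
      cyclinE_total = c(cycE = 1, p27_cycE = 1),
      cyclinA_total = c(cycA = 1, p27_cycA = 1)),
    metadata = "core HeLa G1/S control network (E2F constant input)",
    unit_interval = c("cdh1_active", "e2f_active"))
  rep <- validate(net, params)
  if (length(rep)) stop("invalid default network:\n  ",
                        paste(rep, collapse = "\n  "))
  net
}

#' Default kinetic parameters for the core network
#'
#' Values are in hours and arbitrary concentration units (a.u.) scaled so
#' that reporter peaks in the control simulation sit near 1. Turnover rates
#' of mRNAs and of the CyclinE, CyclinA, Emi1 and Skp2 proteins are flagged
#' fixed (literature half-lives); the remaining 25 rate constants, including
#' the two Cdk2-activity weights, are the unknown, fittable set.
#'
#' @return a \code{g1s_parameters} object.
#' @export
default_parameters <- function() {
  value <- c(
    # mRNA turnover (fixed half-lives ~30 min)
    ks_me = 1.4,  kd_me = 1.4,
    ks_ma = 1.4,  kd_ma = 1.4,
    # CyclinE protein
    ks_e = 0.105, kd_e = 0.05,  kd_e_cdk2 = 1,
    # CyclinA protein (APC/C-Cdh1 degradation saturates at j_a)
    ks_a = 0.35,  kd_a = 0.05,  kd_a_cdh1 = 10, j_a = 0.05,
    # p27
    ks_p27 = 0.33, kd_p27 = 0.4,
    kass_e = 1000, kdiss_e = 1,
    kass_a = 20000, kdiss_a = 40,
    kphos_p27 = 80, kdephos_p27 = 100,
    kd_p27p_skp2 = 100,
    # Emi1
    ks_emi1 = 0.15, kd_emi1 = 0.1,
    # Skp2
    ks_skp2 = 2,  kd_skp2 = 2, kd_skp2_cdh1 = 38,
    # APC/C-Cdh1 interconversion (zero-order switch, Emi1/Cdk2-inactivated)
    ka_cdh1 = 6,  ki_cdh1_emi1 = 7.8, ki_cdh1_cdk2 = 0.6, j_cdh1 = 0.003,
    # Cdk2 activity observable weights
    w_e = 1, w_a = 4)
  unit <- c(
    ks_me = "a.u./h", kd_me = "1/h", ks_ma = "a.u./h", kd_ma = "1/h",
    ks_e = "1/h", kd_e = "1/h", kd_e_cdk2 = "1/h",
    ks_a = "1/h", kd_a = "1/h", kd_a_cdh1 = "a.u./h", j_a = "a.u.",
    ks_p27 = "a.u./h", kd_p27 = "1/h",
    kass_e = "1/h", kdiss_e = "1/h", kass_a = "1/h", kdiss_a = "1/h",
    kphos_p27 = "1/h", kdephos_p27 = "1/h",
    kd_p27p_skp2 = "1/h",
    ks_emi1 = "a.u./h", kd_emi1 = "1/h",
    ks_skp2 = "a.u./h", kd_skp2 = "1/h", kd_skp2_cdh1 = "1/h",
    ka_cdh1 = "a.u./h", ki_cdh1_emi1 = "1/h", ki_cdh1_cdk2 = "1/h",
    j_cdh1 = "a.u.",
    w_e = "dimensionless", w_a = "dimensionless")
  fixed <- c("kd_me", "kd_ma", "kd_e", "kd_a", "kd_emi1", "kd_skp2")
  fittable <- !(names(value) %in% fixed)
  names(fittable) <- names(value)
  kinetic_parameters(value, unit, fittable)
}

# ---- rate-law compilation ---------------------------------------------------

# Compile one parsed R expression into stack-machine bytecode.
compile_expr <- function(e, species, param_names) {
  ops <- integer(0); args <- integer(0); consts <- numeric(0)
  emit <- function(op, arg = 0L) {
    ops <<- c(ops, op); args <<- c(args, arg)
  }
  rec <- function(e) {
    if (is.numeric(e)) {
      consts <<- c(consts, as.numeric(e)); emit(OP_CONST, length(consts))
    } else if (is.name(e)) {
      nm <- as.character(e)
      i <- match(nm, species)
      if (!is.na(i)) { emit(OP_SPECIES, i); return(invisible()) }
      j <- match(nm, param_names)
      if (!is.na(j)) { emit(OP_PARAM, j); return(invisible()) }
      stop("unresolved symbol '", nm, "' in rate law", call. = FALSE)
    } else if (is.call(e)) {
      fn <- as.character(e[[1]])
      if (fn == "(") { rec(e[[2]]); return(invisible()) }
      if (fn == "-" && length(e) == 2) { rec(e[[2]]); emit(OP_NEG); return(invisible()) }
      if (fn == "+" && length(e) == 2) { rec(e[[2]]); return(invisible()) }
      op <- switch(fn, "+" = OP_ADD, "-" = OP_SUB, "*" = OP_MUL,
                   "/" = OP_DIV, "^" = OP_POW,
                   stop("unsupported function '", fn, "' in rate law",
                        call. = FALSE))
      rec(e[[2]]); rec(e[[3]]); emit(op)
    } else stop("unsupported rate-law element: ", deparse(e), call. = FALSE)
  }
  rec(e)
  list(ops = ops, args = args, consts = consts)
}

# Compile a whole network against a parameter set. Returns the flat bytecode
# plus stoichiometry in both dense and triplet form and reaction/species
# dependency lists used by the stochastic engine.
compile_network <- function(network, params) {
  species <- network$species
  pn <- names(params$value)
  M <- length(network$reactions)
  ops <- integer(0); args <- integer(0); consts <- numeric(0)
  offsets <- integer(M + 1); offsets[1] <- 0L
  for (j in seq_len(M)) {
    rx <- network$reactions[[j]]
    e <- tryCatch(str2lang(rx$rate),
                  error = function(err) stop("cannot parse rate law of reaction '",
                                             rx$name, "': ", conditionMessage(err),
                                             call. = FALSE))
    bc <- tryCatch(compile_expr(e, species, pn),
                   error = function(err) stop("reaction '", rx$name, "': ",
                                              conditionMessage(err), call. = FALSE))
    # shift const indices into global pool
    bc$args[bc$ops == OP_CONST] <- bc$args[bc$ops == OP_CONST] + length(consts)
    consts <- c(consts, bc$consts)
    ops <- c(ops, bc$ops); args <- c(args, bc$args)
    offsets[j + 1] <- length(ops)
  }
  S <- matrix(0, nrow = length(species), ncol = M,
              dimnames = list(species, vapply(network$reactions, `[[`, "", "name")))
  for (j in seq_len(M)) {
    st <- network$reactions[[j]]$stoich
    bad <- setdiff(names(st), species)
    if (length(bad)) stop("reaction '", network$reactions[[j]]$name,
                          "' references undeclared species: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    S[names(st), j] <- st
  }
  # reaction -> species referenced in its rate law
  refs <- lapply(seq_len(M), function(j) {
    idx <- (offsets[j] + 1):offsets[j + 1]
    sort(unique(args[idx][ops[idx] == OP_SPECIES]))
  })
  # dependency: after reaction i fires, which reactions need propensity update
  changed <- lapply(seq_len(M), function(j) which(S[, j] != 0))
  depends <- lapply(seq_len(M), function(i) {
    ch <- changed[[i]]
    which(vapply(refs, function(r) any(r %in% ch), logical(1)))
  })
  list(species = species, param_names = pn, n_species = length(species),
       n_reactions = M, ops = ops, args = args, consts = consts,
       offsets = offsets, stoich = S, refs = refs, depends = depends)
}

# cache the compiled form on the network object (params only matter through
# the parameter-name ordering, which is stable for a given name set)
compiled <- function(network, params) {
  key <- network$.compiled
  if (!is.null(key) && identical(key$param_names, names(params$value)))
    return(key)
  compile_network(network, params)
}

#' Precompile a network for repeated simulation
#'
#' Attaches the compiled bytecode to the network object so repeated calls to
#' the engines skip recompilation. Purely an optimisation; results are
#' identical either way.
#'
#' @param network a \code{g1s_network}.
#' @param params the parameter set whose name ordering the compilation uses.
#' @return the network with a cached compiled form.
#' @export
precompile <- function(network, params = default_parameters()) {
  network$.compiled <- compile_network(network, params)
  network
}

# ---- evaluation -------------------------------------------------------------

#' Evaluate all reaction rate laws at a state
#'
#' @param network a \code{g1s_network}.
#' @param state named nonnegative state vector (a.u.).
#' @param params a \code{g1s_parameters}.
#' @param comp precompiled network (internal use).
#' @return named numeric vector of reaction rates (a.u./h).
#' @export
reaction_rates <- function(network, state, params, comp = NULL) {
  comp <- if (is.null(comp)) compiled(network, params) else comp
  x <- state_vector(state, comp$species)
  r <- eval_rates_cpp(comp$ops, comp$args, comp$consts, comp$offsets,
                      x, unname(params$value[comp$param_names]))
  names(r) <- colnames(comp$stoich)
  r
}

state_vector <- function(state, species) {
  if (is.null(names(state))) {
    if (length(state) != length(species))
      stop("unnamed state of wrong length")
    return(as.numeric(state))
  }
  miss <- setdiff(species, names(state))
  if (length(miss)) stop("state missing species: ", paste(miss, collapse = ", "))
  as.numeric(state[species])
}

#' Per-species rate of change
#'
#' The time derivative of each species: the stoichiometry-weighted sum of
#' rate-law evaluations at the given state.
#'
#' @param network a \code{g1s_network}.
#' @param state named nonnegative numeric vector (a.u.).
#' @param params a \code{g1s_parameters} object.
#' @return named numeric vector (a.u./h), one entry per species.
#' @export
derivatives <- function(network, state, params) {
  comp <- compiled(network, params)
  r <- reaction_rates(network, state, params, comp)
  if (any(!is.finite(r))) {
    bad <- colnames(comp$stoich)[!is.finite(r)]
    stop("non-finite rate law evaluation in reaction(s): ",
         paste(bad, collapse = ", "))
  }
  d <- as.numeric(comp$stoich %*% r)
  names(d) <- comp$species
  d
}

#' Cdk2 kinase activity observable
#'
#' A linear combination of the free (p27-unbound) Cdk2:Cyclin complexes,
#' \code{w_e * cycE + w_a * cycA}. p27-bound complexes are catalytically
#' inactive and contribute zero.
#'
#' @param state named numeric vector, or a matrix with species columns.
#' @param params a \code{g1s_parameters} object supplying \code{w_e}, \code{w_a}.
#' @return nonnegative scalar (or vector for a matrix input), in a.u.
#' @export
cdk2_activity <- function(state, params) {
  w_e <- params$value[["w_e"]]; w_a <- params$value[["w_a"]]
  if (is.matrix(state)) {
    w_e * state[, "cycE"] + w_a * state[, "cycA"]
  } else {
    unname(w_e * state[["cycE"]] + w_a * state[["cycA"]])
  }
}

# ---- validation -------------------------------------------------------------

#' Validate a network / parameter pair
#'
#' Checks every declared invariant: species referenced by stoichiometries and
#' rate laws are declared, rate-law parameters resolve, stoichiometric
#' coefficients are integers, parameter values are nonnegative and within
#' bounds, and rate laws evaluate to finite nonnegative numbers on a
#' deterministic set of nonnegative probe states.
#'
#' @param network a \code{g1s_network}.
#' @param params a \code{g1s_parameters}.
#' @return character vector of violation messages; empty if valid.
#' @export
validate <- function(network, params) {
  report <- character(0)
  species <- network$species
  for (rx in network$reactions) {
    if (any(rx$stoich != round(rx$stoich)))
      report <- c(report, sprintf("reaction '%s': non-integer stoichiometry",
                                  rx$name))
    bad <- setdiff(names(rx$stoich), species)
    if (length(bad))
      report <- c(report, sprintf(
        "reaction '%s': undeclared species in stoichiometry: %s",
        rx$name, paste(bad, collapse = ", ")))
  }
  if (any(params$value < 0))
    report <- c(report, sprintf("negative parameter value: %s",
                                paste(names(params$value)[params$value < 0],
                                      collapse = ", ")))
  out_of_bounds <- params$value < params$lower - 1e-12 |
    params$value > params$upper + 1e-12
  if (any(out_of_bounds))
    report <- c(report, sprintf("parameter outside bounds: %s",
                                paste(names(params$value)[out_of_bounds],
                                      collapse = ", ")))
  for (ob in names(network$observables)) {
    bad <- setdiff(names(network$observables[[ob]]), species)
    if (length(bad))
      report <- c(report, sprintf("observable '%s': undeclared species %s",
                                  ob, paste(bad, collapse = ", ")))
  }
  comp <- tryCatch(compile_network(network, params), error = function(e) e)
  if (inherits(comp, "error")) {
    report <- c(report, conditionMessage(comp))
    return(report)
  }
  # deterministic nonnegativity probing on a fixed lattice of states
  probes <- rbind(0, 0.1, 1,
                  matrix(rep(c(0.01, 0.5, 2, 0.2, 1.5), length.out =
                               5 * length(species)), nrow = 5, byrow = TRUE))
  colnames(probes) <- species
  for (sp in network$unit_interval) probes[, sp] <- pmin(probes[, sp], 1)
  pv <- unname(params$value[comp$param_names])
  for (i in seq_len(nrow(probes))) {
    r <- eval_rates_cpp(comp$ops, comp$args, comp$consts, comp$offsets,
                        as.numeric(probes[i, ]), pv)
    neg <- which(r < -1e-12 | !is.finite(r))
    if (length(neg))
      report <- c(report, sprintf(
        "rate law of reaction '%s' negative or non-finite on a nonnegative probe state",
        paste(colnames(comp$stoich)[neg], collapse = "', '")))
  }
  unique(report)
}
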