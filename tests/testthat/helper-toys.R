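# Tiny hand-built networks and parameter sets used across tests.

birth_death_network <- function() {
  reaction_network(
    species = "x",
    reactions = list(
      list(name = "synthesis", stoich = c(x = 1L), rate = "k"),
      list(name = "degradation", stoich = c(x = -1L), rate = "d * x")))
}

birth_death_params <- function(k = 2, d = 0.5) {
  kinetic_parameters(c(k = k, d = d),
                     c(k = "a.u./h", d = "1/h"),
                     c(k = TRUE, d = TRUE))
}

pure_death_network <- function() {
  reaction_network(
    species = "x",
    reactions = list(
      list(name = "death", stoich = c(x = -1L), rate = "d * x")))
}

# a bare trajectory object carrying prescribed p27_total / activity series
fake_trajectory <- function(time, p27_total,
                            cdk2_activity = rep(0, length(time))) {
  structure(list(time = time,
                 species = matrix(0, length(time), 0),
                 observables = list(p27_total = p27_total,
                                    cdk2_activity = cdk2_activity)),
            class = "g1s_trajectory")
}

# 80-to-20 percent fall time of an arbitrary series (shared with tests of
# population-average smoothing)
fall_time_80_20 <- function(time, y) {
  switch_abruptness(fake_trajectory(time, y))
}
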