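# g1switch

Kinetic modelling of the all-or-none G1/S transition in human cells.

## The problem

Entry into S phase is switch-like: the Cdk inhibitor p27^Kip1^ accumulates
through G1, holding Cdk2:CyclinE and Cdk2:CyclinA complexes inactive, and is
then degraded within fractions of an hour, releasing an abrupt rise in Cdk2
activity that coincides with the onset of DNA replication. `g1switch`
implements a kinetic model of this transition for cells without restriction
point control (constitutively active E2F, the HeLa situation), along with
everything needed to interrogate it: deterministic and stochastic
simulation, bifurcation analysis, in-silico knockdown and inhibitor
protocols, a synthetic single-cell fluorescence-trace generator with the
matching processing pipeline, brute-force parameter estimation, and an
extension with pRb control over E2F for restriction-point-intact cells.

It is aimed at systems biologists who want a reusable, tested
implementation of the p27–Cdk2 double-negative feedback switch rather than
a one-off script.

## The model in brief

Species: CyclinE and CyclinA mRNAs and proteins, free p27, the inactive
complexes p27:Cdk2:CyclinE and p27:Cdk2:CyclinA, T187-phosphorylated p27,
Emi1, Skp2, and the active APC/C^Cdh1^ fraction. Cdk2 activity is the
linear combination of the free complexes,

    A = w_E [Cdk2:CycE] + w_A [Cdk2:CycA],

since p27-bound complexes are catalytically dead. The wiring comprises the
mutual antagonisms of the G1/S network: p27 sequesters the kinases while
Cdk2 activity drives p27 T187 phosphorylation and SCF^Skp2^-dependent
degradation (a direct and, via Cdh1 inactivation and Skp2 stabilisation,
an indirect coherent feed-forward loop); APC/C^Cdh1^ degrades CyclinA and
Skp2 and is inactivated by accumulating Emi1 and by Cdk2. Bistability of
the p27 steady state between two saddle-node thresholds of the cyclin
level makes the transition all-or-none and, because Emi1 keeps lowering
the thresholds through S phase, irreversible. Time is in hours;
concentrations in arbitrary units with control-simulation reporter peaks
near 1. Twenty-five rate constants are treated as unknown (fittable); six
turnover rates with literature half-lives are fixed.

The network is declarative data (species, integer stoichiometries, textual
rate laws); the ODE engine (`deSolve::lsoda`), the exact Gillespie and
tau-leap engines (Rcpp), and the steady-state/bifurcation machinery all
derive from the same object. See the vignette
(`vignettes/g1s-switch-model.Rmd`) for rate-law forms, calibration, event
definitions, and numerical choices.

## Worked example

```r
library(g1switch)

params  <- default_parameters()
network <- build_default_network(params)

## deterministic control cell from mitotic exit
traj <- simulate_ode(network, params, t_end = 18)
g1s  <- detect_g1s(traj)           # p27 half-maximum downward crossing
c(g1s_time_h   = g1s,
  p27_peak_h   = traj$time[which.max(series(traj, "p27_total"))],
  fall_80_20_h = switch_abruptness(traj))
#>   g1s_time_h   p27_peak_h fall_80_20_h
#>     8.481785     6.950000     0.487449

## the Z-shaped p27 diagram vs clamped CyclinE (CyclinA absent, Emi1 low)
diag <- scan_diagram(network, params, "cyclinE",
                     grid = seq(0.05, 1.1, length.out = 25),
                     clamps = c(emi1 = 0.05))
c(lower = diag$lower_threshold, upper = diag$upper_threshold)
#>     lower     upper
#> 0.4591309 0.6293457

## a stochastic cell at system size 500 molecules per a.u.
cell <- ssa_run(network, params, t_end = 15,
                config = stochastic_config(omega = 500, seed = 1))
detect_g1s(cell)
#> [1] 8.698246
```

The control cell commits at ~8.5 h with p27 peaking at ~7 h and
collapsing from 80% to 20% of its peak in ~0.5 h — about 6% of G1. The
bifurcation scan shows the hysteresis loop: the high-p27 (G1) state
disappears only above ~0.63 a.u. of CyclinE, while the low-p27 (S) state
persists down to ~0.46 a.u. Stochastic cells at realistic molecule numbers
reproduce the same abrupt, but variably timed, switch.

In-silico experiments are timed protocols applied to the same engines:

```r
kd  <- cyclinE_knockdown()                    # 5% synthesis, 20x mRNA decay
ens <- run_ensemble(network, params, t_end = 28, protocol = kd,
                    config = stochastic_config(omega = 500, seed = 2, n = 50))
median(ens$g1s_times, na.rm = TRUE)           # delayed by hours vs control
#> [1] 11.26871
```

`emi1_depletion()` reproduces the S-phase reset (Cdh1 reactivation,
CyclinA collapse, p27/CyclinE re-accumulation, a second p27 drop);
`cdk_inhibition()` the p27 re-accumulation under Cdk1/2 inhibitor;
`generate_cells()` / `process_and_align()` / `brute_force_fit()` the full
imaging-and-estimation loop; `build_rb_network()` / `classify_fates()` the
restriction-point extension. Networks, parameters, protocols, trajectories
and traces all round-trip through JSON/YAML/CSV (`write_network`,
`write_traces`, ...), and `run_scenario()` executes a configured pipeline
with a provenance sidecar.

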