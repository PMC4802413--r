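---
title: "A kinetic model of the all-or-none G1/S transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of the all-or-none G1/S transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g1switch)
```

## The model

Human cells commit to DNA replication when Cdk2:Cyclin kinase activity rises
abruptly at the G1/S boundary. `g1switch` implements a kinetic model of this
transition in cells without a functional restriction point (the HeLa
situation, where pRb is inactive and E2F is constitutively on), built around
a proteolytic double-negative feedback loop: the stoichiometric inhibitor
p27^Kip1^ binds and inactivates Cdk2:CyclinE and Cdk2:CyclinA, while active
Cdk2 phosphorylates p27 on T187, tagging it for SCF^Skp2^-dependent
degradation. Around this core sit the APC/C^Cdh1^ arms: Cdh1 keeps CyclinA
and Skp2 low through G1, and is itself inactivated late in G1 by the
accumulating E2F target Emi1 and by Cdk2 phosphorylation. Cdk2 activity is
read out as a weighted sum of the free complexes,
$A = w_E\,[\mathrm{Cdk2{:}CycE}] + w_A\,[\mathrm{Cdk2{:}CycA}]$;
p27-bound complexes contribute nothing.

The network is *data*: an ordered species list, integer-stoichiometry
reactions with textual rate laws, and linear observables
(`build_default_network()`). Every engine — the stiff ODE integrator, the
exact Gillespie and tau-leap stochastic simulators, and the steady-state /
bifurcation machinery — consumes the same declarative object, so the
restriction-point extension and the toy networks used in the tests swap in
without engine changes.

Units are hours and arbitrary concentration units (a.u.) scaled so that the
reporter peaks of the control simulation sit near 1. Of the 31 rate
constants, the 6 mRNA/protein turnover rates with literature half-lives are
fixed; the remaining 25 — including the two activity weights — form the
unknown, fittable set.

## Rate-law forms and their rationale

The supplementary rate expressions of the source study were not available
to this implementation, so the rate laws are the simplest forms consistent
with the stated biology, with three deliberate exceptions:

* **Saturating APC/C^Cdh1^ degradation of CyclinA.** The ubiquitylation
  flux is $k^{A}_{d,\mathrm{cdh1}}\,\mathrm{Cdh1}\cdot X/(j_A + T_A)$,
  shared proportionally between free and p27-bound CyclinA
  ($T_A$ = total CyclinA). An enzymatic (Michaelis) form keeps the G1
  CyclinA pool at ~0.001 a.u. — so that neither its residual kinase
  activity nor its p27 sequestration perturbs G1 — while the same flux
  saturates after Cdh1 switches off and cannot throttle S-phase CyclinA
  accumulation. With a mass-action form, the residual G1 pool (~0.03 a.u.)
  measurably advances the switch, and removing CyclinA then *delays* it, a
  phenotype the imaging data exclude.
* **A futile T187 phosphorylation cycle.** Free and complexed p27 are
  phosphorylated at rate $k_{phos} A$; phospho-p27 is either
  dephosphorylated (fast, $k_{dephos}$) or degraded at a rate proportional
  to Skp2. Degradation of T187-phosphorylated p27 is exclusively
  SCF^Skp2^-mediated. The cycle makes the *committed* fraction of
  phosphorylation events rise ~14-fold between the G1 Skp2 floor and the
  S-phase Skp2 plateau, which is what lets a small CyclinA level
  (~0.2 a.u.) trigger the switch at high Emi1 while a much larger CyclinE
  level (>0.6 a.u.) is needed at low Emi1.
* **Zero-order Cdh1 interconversion.** Cdh1 activation and inactivation
  are Michaelis interconversions of a conserved fraction with a small
  saturation constant, giving the sharp, switch-like Cdh1 drop late in G1;
  inactivation increases linearly in Emi1 and in Cdk2 activity.

Cyclin degradation inside a p27 complex releases free p27, and degradation
or phosphorylation of complexed p27 releases the free, active complex, so
the bookkeeping identities (total CyclinE = free + bound, etc.) hold by
construction.

## Calibration

Default parameter values were calibrated once, by hand followed by small
deterministic/stochastic screens, against the anchors the source imaging
study prints: the upper CyclinE threshold of the p27 steady-state diagram
exceeds 0.6 a.u. at low Emi1 (calibrated value ≈ 0.63); the CyclinA
inactivation threshold at the Emi1 level where CyclinE-depleted cells
actually transition is ≈ 0.2 a.u. (calibrated ≈ 0.24); p27 peaks 5–10 h
after mitotic exit (≈ 6.5 h) and collapses in well under 10% of G1
(≈ 0.5 h against a ≈ 8.5 h G1); CyclinE depletion (5% residual synthesis,
20-fold faster mRNA decay) delays the median stochastic transition by
hours while CyclinA depletion does not shift it outside the control
interquartile range; Emi1 depletion from S phase reactivates Cdh1,
collapses CyclinA, lets p27 and CyclinE re-accumulate and ends in a second
p27 drop; and Cdk2 inhibition in S phase restores p27 only while its
synthesis continues. The calibration was frozen before the acceptance
suite was written.

## In-silico event definitions

* **G1/S time** (`detect_g1s`): first downward crossing of 50% of the
  running maximum of total p27 that stays below that level for ≥ 1 h.
  Experimentally S entry is called from the sharp PCNA increase; in the
  model the two coincide because p27 collapses immediately before S entry.
  The persistence window rejects noise-induced crossings in stochastic
  paths.
* **Switch abruptness** (`switch_abruptness`): time for total p27 to fall
  from 80% to 20% of its maximum, linearly interpolated.
* **S-phase arrest state** (`sphase_arrest_state`): the control trajectory
  sampled at the first time after G1/S where total CyclinA exceeds total
  CyclinE (CyclinA rising, CyclinE falling, p27 low).

## Steady-state analysis

The scanned cyclin enters as a conserved moiety: reactions changing its
total are removed, binding/unbinding and p27 exchange remain, and the free
form is eliminated through the conservation relation. Steady states come
from damped multi-start Newton iteration (a fixed 18-point start grid plus
two relaxation-seeded starts per branch) with finite-difference Jacobians;
stability from the Jacobian eigenvalues, with real parts within 1e-9
flagged marginal rather than silently classified. Saddle-node thresholds
are located by bracketing the change in steady-state count and bisecting
to 1e-3 a.u. An independent oracle (`relaxation_thresholds`) finds the
same thresholds by genuine up/down hysteresis sweeps — long forward
relaxations that carry the branch state across a slowly stepped cyclin
total — and the two routes agree to better than 2e-3 a.u. Count-change
bracketing was chosen over arclength continuation because the system is
small and the bracketing is oracle-checkable.

One caveat the analysis makes explicit: the familiar phase-plane picture
of the transition lives on the *CyclinE* threshold diagram only during G1.
After the switch, Cdk2-dependent CyclinE degradation collapses the CyclinE
pool while CyclinA carries the activity, so the control path drops below
the CyclinE-only reactivation threshold without any p27 return. The
irreversibility of the transition is therefore asserted on the CyclinA
threshold plane (where the committed path never re-enters the high-p27
territory as Emi1 keeps rising) and dynamically (p27 stays below 20% of
its peak after the switch; only Emi1 depletion resets it).

## Stochastic engines

The Gillespie direct method runs on propensities
$a_j = \Omega f_j(n/\Omega)$, where $\Omega$ is the system size (molecules
per a.u., default 500) — this reproduces $k/\Omega$ scaling for bimolecular
and $k\Omega$ for zero-order mass-action reactions and handles the
nonlinear Cdh1 laws uniformly. Fraction-valued species are represented as
counts out of $\Omega$. Propensity updates after each firing follow a
precomputed reaction-dependency graph. An explicit tau-leap
(population-based step control, ε = 0.03 by default, Poisson increments
with normal approximation above mean 30) is available for speed and agrees
with the exact method in ensemble mean within sampling error. Per-cell
substreams derive from one global seed through a counter-based hash
(splitmix64-seeded xoshiro256++), so ensembles are reproducible and
independent of evaluation order. Optional extrinsic variability scales
each cell's synthesis rates by a lognormal factor.

A structural property of switch-like systems worth stating: at finite
$\Omega$ the per-cell transition time jitters (sd ≈ 0.16 h at
$\Omega = 5000$), so the ensemble mean near the switch is the
deterministic cliff convolved with that jitter. The systematic deviation
there is of order (cliff slope × jitter), while the standard error of the
mean shrinks as $1/\sqrt{n}$ — a pointwise mean-vs-ODE band a few standard
errors wide therefore must fail around the switch for large ensembles, at
any system size. Away from the switch the mean tracks the ODE closely,
and the mean transition time agrees with the deterministic one to ~0.01 h.

## Synthetic imaging traces and processing

`generate_cells` emulates post-quantification single-cell reporter data:
GFP channels are the model's total p27, CyclinE and CyclinA scaled by a
per-cell lognormal gain (CV 0.1), plus additive background (5% of the
clean peak) and per-frame multiplicative lognormal noise (sdlog 0.05);
the Cdk2 sensor is an affine map of model activity (baseline 0.5, slope
1.0, placing the early-S plateau near 1.5); a PCNA-like channel steps up
sigmoidally (width 0.1 h) at the model's G1/S time; frames are 10 min
apart. G1-duration variability is emulated in the deterministic engine by
a per-cell lognormal time dilation (median 1; off by default, CV 0.25 when
the mode is enabled, consistent with p27 degradation starting 5–10 h after
mitotic exit); the stochastic engine produces timing spread intrinsically.
Averaging endpoint-normalized monotone channels across time-dilated cells
biases the aligned mean by roughly the dilation CV, which is why the
variability mode is a switch rather than part of the measurement-noise
model. None of these noise figures are
measured values — they are repository defaults chosen small enough that
event calling stays reliable, and the generator makes no attempt to
emulate segmentation or tracking artefacts, bleaching, or cell death.
Passing tests on synthetic data therefore validate the processing and
fitting machinery, not the microscope.

Processing mirrors the experimental pipeline: S entry is called from the
smoothed PCNA derivative (threshold: 3× the median absolute frame change,
floored at 10% of the dynamic range per frame, refined to the local
derivative maximum so the call sits at the centre of the jump); cells
without a call are dropped with a message; channels are
background-subtracted, clipped at zero, peak-normalized per cell, aligned
at S entry = 0, re-gridded by linear interpolation and averaged. The
alignment quantization is half a frame, so a noise-free round trip
(generate → call → align → average) reproduces the normalized
deterministic trajectory to RMSE < 0.02 with the largest residuals at the
p27 cliff. Averaging cells with variable G1 durations makes the
population-mean p27 decline slower than any individual cell's — the
single-cell-vs-population-blot discrepancy, reproduced by construction.

## Brute-force fitting

The objective is the equally weighted mean of per-channel mean squared
residuals between the G1/S-aligned, peak-normalized simulated observables
and the target mean series; peak normalization is taken over the time
window the target covers. The search is a seeded log-uniform sample of the
fittable space (bounds default to 1/100–100× the defaults; samples are
nested under the seed, so enlarging the sample can only improve the best
objective), followed by coordinate descent on the top candidates and a
Nelder–Mead polish in log space — the polish matters because the landscape
has strongly correlated (sloppy) directions that coordinate descent cannot
follow. Trajectory-level agreement is the primary recovery criterion;
`recovery_experiment` reports per-parameter relative errors and flags
parameters that are off while the trajectory matches as sloppy rather than
failed. A twofold perturbation probe around the truth separates locally
identifiable parameters from sloppy ones before any parameter-level
assertion is made.

## The restriction-point extension

`build_rb_network` adds hypo-phosphorylated pRb and dynamic E2F activity:
pRb is phosphorylated by a lumped mitogen-driven (CyclinD-like) activity
plus Cdk2:Cyclin activity and dephosphorylated at a constant rate; E2F
self-activates and is inactivated basally and by hypo-pRb, with the pRb
term quadratic — the sharpness is needed for the E2F switch to
distinguish the partially phosphorylated pRb of a proliferating G1 cell
from the mostly hypo-phosphorylated pRb of an arrested one. The extension's
equations are repository constructions satisfying the qualitative wiring;
they are exercised at the property level only. The core model is recovered
exactly by clamping E2F fully active (the pRb-null limit). At intermediate
mitogen the full extended system has exactly two stable fixed points — a
Cdk2-high, E2F-on, APC/C-off S-like state and a Cdk2-low, E2F-off arrest
with pRb hypo-phosphorylated — separated by a saddle, and post-mitotic
cells are routed to one or the other by their initial CyclinE/CKI balance
(`classify_fates`, horizon 40 h, labels decided against the geometric
midpoint of the two steady activities). The proliferative fixed point
lives in the full system, not in an Emi1-clamped early-G1 subsystem: in
this model, as in the underlying biology, the post-switch state is
maintained by Emi1, so clamping Emi1 low removes the Cdk2-high attractor.

## Numerical choices and problem sizes

* ODE: `deSolve::lsoda`, rtol 1e-8 / atol 1e-10 (1e-6/1e-8 inside the
  fitting objective), dense output every 0.05 h; protocol events by
  stop-and-restart, never smoothing; undershoots within tolerance clipped,
  larger ones an error.
* Newton: damped with backtracking line search, projection to the
  nonnegative orthant, central-difference Jacobians; duplicate roots
  merged at 1e-6 a.u.
* Default analysis sizes: 25–60 scan points per cyclin axis, 40 Emi1
  levels (all configurable); stochastic phenotype comparisons use 50 cells
  at Ω = 500; the large-system consistency check uses 200 cells at
  Ω = 5000; the recovery harness uses 20 synthetic cells and 5000 sampled
  candidates over 6 parameters. These sizes were chosen to keep each
  analysis in the minutes range on a single core while leaving the
  conclusions insensitive to doubling.
* All randomness flows from explicit integer seeds; the C++ engines carry
  their own counter-based generator so results are identical across
  platforms and parallelisation layouts.

## Known limitations

* The rate laws are reconstructions; absolute parameter values are not
  transferable to other cell lines, and only the calibrated anchors above
  are claimed.
* The transient Cdk2-activity dip just after S entry seen in sensor data
  is not modelled, and re-replication phenotypes (origin licensing,
  Geminin) are out of scope.
* The ensemble-mean-vs-ODE band near the switch fails for large ensembles
  for the structural reason described above; transition-time agreement is
  the meaningful consistency statement there.
* Parameter recovery is trajectory-level; several rate constants are
  sloppy (jointly unidentifiable from mean reporter traces), which the
  recovery report exposes rather than hides.
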