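---
title: "Modelling internal fibrinolysis on a fibrin lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling internal fibrinolysis on a fibrin lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(porelysis)
library(dplyr)
```

## The model

Internal fibrinolysis is clot breakdown driven by lytic enzymes trapped
*inside* the clot while it forms, as opposed to external lysis where tissue
plasminogen activator (tPA) arrives at the clot boundary as a bolus.
`porelysis` implements a stochastic multiscale caricature of this process:

* **The clot** is a 3D square lattice one fiber thick in the out-of-plane
  dimension. Each lattice edge is one fibrin fiber; nodes are the junctions.
  The in-plane boundaries are reflecting walls, the out-of-plane direction
  is periodic with thickness one, so an out-of-plane hop returns to the same
  node and molecular motion is effectively in-plane. Every node carries an
  out-of-plane (z) fiber in addition to its up-to-four in-plane fibers, so a
  lattice with `nx * ny` nodes has `3*nx*ny - nx - ny` fibers.
* **tPA molecules** start uniformly distributed over the nodes (internal
  lysis: the enzyme is already inside). Each time step a free molecule
  performs one step of a nearest-neighbour random walk; the time step is
  calibrated so one step covers one pore: `dt = dt_ref * (pore/pore_ref)^2`,
  giving 1.613e-5 s for dense (0.22 um) and 3.424e-4 s for loose
  (1.0135 um) networks.
* **Binding.** A molecule at a node with at least one adjacent intact fiber
  binds one of them (uniformly) with probability `bind_prob` per step. The
  source model never states a contact-binding probability; the default is 1
  (bind on first contact), which also makes small test systems maximally
  deterministic. On binding, the molecule draws an *unbinding time* and a
  *single-fiber lysis time* from the kinetics model, plus one uniform
  variate that decides — with the forced-unbinding probability `q` — whether
  this binding ends in forced unbinding.
* **Unbinding branches.** With probability `1 - q` the molecule kinetically
  unbinds at its drawn unbinding time and is immediately free. With
  probability `q` it is instead ejected on a *small fibrin degradation
  product* (FDP) at that time: it diffuses freely but may not rebind for a
  waiting time `1/k_off` (27.78 s with `k_off = 0.036`). `q` is 0.0852 for
  thin (72.7 nm) and 0.0729129 for thick (145.4 nm) fibers.
* **Degradation.** Each lytic initiation schedules the fiber to degrade at
  its drawn lysis time; a fiber with several initiations degrades at the
  earliest. Molecules still bound when their fiber breaks up ride a *large
  FDP*: it can only hop between adjacent degraded-fiber positions (it cannot
  squeeze through intact pores), and the molecule is released at its
  previously assigned unbinding time.

The simulation advances synchronously in steps of `dt` until every fiber is
degraded (or a safety cap `max_time` is hit, in which case the run is
flagged truncated). The degraded fraction is recorded every
`record_interval` seconds, and full intact-fiber masks are snapshotted at
the first records reaching 5, 20, 50 and 80 % degradation.

### Event ordering and reproducibility

All scheduled events (degradation, unbinding, wait expiry) are applied at
the first step boundary at or after their scheduled time. Within a
boundary the order is: degradations, then releases, then the record, then
one movement-and-binding sweep over molecules in index order. A molecule
released at a boundary may move and rebind within the following step, so
the shortest possible transit is one `dt`. The engine draws all random
variates from R's global RNG stream in a fixed, documented order (see the
header of `src/engine.cpp`), so a run is bit-identical given a seed. The
test suite exploits this: an independently written R discrete-event oracle
consumes the same stream and must reproduce records, per-fiber degradation
times, transit logs and final molecule states exactly on small lattices.

### Fast-forwarding long FDP rides

Molecules riding FDPs interact with nothing; only their release position
matters. A waiting small-FDP carrier is a free reflecting random walk whose
transition matrix is symmetric, so its stationary law is exactly uniform
over nodes; a large-FDP rider performs a simple random walk on its
connected component of degraded fibers, whose stationary law is
degree-weighted. When the remaining ride exceeds `mixing_threshold_steps`
(default 2e4, far beyond the mixing time of the lattices used here), the
engine samples the release position from the stationary law instead of
stepping; shorter rides are stepped exactly, and `Inf` disables the
acceleration entirely (the oracle tests run in that mode). This is a
distribution-preserving acceleration, not a model change; the test suite
checks that accelerated and exact runs agree in their lysis-time
distributions.

## Single-fiber kinetics

The unbinding- and lysis-time distributions belong to a detailed microscale
model of a single fiber cross-section that is *not* part of this package.
`load_kinetics()` accepts its output as empirical samples (inverse-transform
sampling with linear interpolation between order statistics; `inf` marks
initiations that never lyse the fiber). When no such files are available,
`default_kinetics()` provides an exponential surrogate. Its defaults are
chosen once, on physical grounds, and are **uncalibrated**:

| parameter | default | why |
|---|---|---|
| mean unbinding time | 27.78 s | set to `1/k_off`, the only unbinding timescale stated for the system |
| mean lysis time, thin | 50 s | single-fiber transection in tens of seconds; thick fibers about twice slower |
| mean lysis time, thick | 100 s | twice the thin value, matching the diameter ratio |
| lysis probability | 1 | every initiation eventually lyses (the empirical interface supports censoring) |
| `q` | 0.0852 / 0.0729129 | canonical forced-unbinding probabilities per diameter |
| `1/k_off` | 27.78 s | small-FDP waiting time, `k_off = 0.036` |

Quantities that depend strongly on these surrogates — most notably mean tPA
transit times, where the forced-unbinding waiting time and the frequency of
fiber breakup before unbinding enter directly — should be read as
order-of-magnitude under the defaults; structural *comparisons* (dense vs
loose, high vs low tPA) are much less sensitive because both arms share the
same kinetics.

## Scenarios and scaling

`scenario_catalog()` carries the ten canonical clot structures: thin
(72.7 nm) or thick (145.4 nm) fibers crossed with dense (0.22 um) or loose
(1.0135 um) pores, each at several tPA loads chosen to fix either the
tPA:fibrin molecular ratio ("high" 1.6e-4, "low" 5.4e-6) or the tPA
concentration (0.92 molecules/um^3). All clots represent the same total
fibrin (5.6e7 monomers), so dense clots have more fibers in a smaller
volume. The catalog stores the published tPA:fibrin ratios and
concentrations as metadata rather than recomputing them: the monomer-per-
fiber rule and clot volumes are not derivable exactly from the printed
values.

Grid dimensions are never printed in the source material; the package
stores them explicitly and fits them to the published fiber counts. The
thin-loose clot is exact at 93 x 93 nodes (25,761 fibers); the other
structures use the nearest near-square grid (199 x 199 -> 118,405 vs
118,558; 50 x 50 -> 7,400 vs 7,453; 107 x 107 -> 34,133 vs 34,208; all
within 1 %).

Full-size runs are expensive, so the package works at *desk scale*:
`scale_scenario()` shrinks a scenario's lattice while keeping pore size,
diameter and time step physical, and rescales the tPA count with the
realised fiber count so the tPA:fibrin ratio is preserved.
`run_scaled_study()` applies one common factor to all ten scenarios
(largest clot ~3,000 fibers, i.e. about 1/40 of full size; e.g. the
thin-dense structure becomes 32 x 32 nodes with 3,008 fibers and the
thin-loose one 15 x 15 with 645), runs 10 seeded replicates each, and
records every 10 s. These problem sizes are the package's default study
conditions; everything downstream (metrics, pore checkpoints, transit
summaries) is computed from them at run time.

## Measurements

**Degradation metrics** (`lysis_metrics()`): the lysis lag is the first
record with at least 5 % of fibers degraded; times to 20/50/80 % follow the
same first-record-at-or-above rule, deliberately without interpolation.
Interval degradation rates are ordinary least-squares slopes over the
records whose fraction lies in 20-80 %, 20-50 % or 50-80 %, reported as
fraction of clot per minute.

**Pore sizes** (`measure_pores()`): horizontal and vertical scan lines are
traversed between every pair of adjacent node rows and columns — the
densest "evenly spaced" choice — crossing only the perpendicular in-plane
fibers (out-of-plane fibers do not intersect an in-plane line). A gap
between consecutive intact crossings spans `(k+1)` spacings when `k`
consecutive crossings between them are degraded; runs touching the wall are
measured to the wall (reflecting boundaries), and a fully degraded line
counts as one gap of the full line span. On an intact lattice every gap is
one spacing, and degrading any crossing merges two gaps into one of their
combined length, so the mean gap is monotone under degradation.
`pore_expansion()` applies this to the snapshot masks at the 5/20/50/80 %
checkpoints and reports percent change against the intact spacing and the
rate of pore change (um/s) between consecutive checkpoints — the estimator
for that rate is not pinned down by the source material; per-interval
finite differences are used.

**Transit times** (`transit_stats()`): an episode opens when a molecule
starts moving freely — kinetic unbinding from an intact fiber, forced
unbinding onto a freely diffusing small FDP (the `1/k_off` wait is part of
the episode), or release from a large FDP at the previously assigned
unbinding time — and closes at its next binding. Of the readings permitted
by the source text this is the one whose arithmetic is consistent with the
printed transit means (which are close to `q/k_off` plus a travel term);
opening large-FDP episodes at breakup instead would fold the ride time
itself into "transit", and under surrogate kinetics where breakup often
precedes unbinding that term swamps the travel signal entirely.

## Turbidity analysis

`turbidity_metrics()` quantifies plate-reader clotting/lysis curves
(405 nm, 15 s sampling over 4 h is the conventional grid). Two
normalizations precede analysis: subtracting the first point (background)
and dividing by the maximum (fraction of the clot). Seven parameters are
extracted: clotting lag, formation rate, time to 50 % clot, maximum OD,
lysis lag, time to 50 % lysis, and interval degradation rates. Conventions
the source leaves open, fixed here:

* *Clotting lag*: the source defines only the lysis lag (first time the
  fraction drops to 0.95 after the peak). The clotting lag mirrors it:
  first time the rising fraction reaches 0.05.
* *Formation rate*: least-squares slope of the rising fraction over
  0.2-0.8, mirroring the degradation 20-80 % convention.
* *"Closest to 0.5"* is resolved on the relevant phase only (rising for
  the clotting half-time, falling for the lysis half-time), ties to the
  earlier time. On a 15 s grid the reported time is therefore the nearest
  sample to the analytic half-time, never more than one sample away.
* *Degradation intervals* are fractions of lysis: "20-50 % lysis" means
  the normalized signal falling from 0.8 to 0.5.

`fit_decay()` fits `A * exp(-k x)` to degradation rate versus fibrinogen
concentration by `nls` with a deterministic log-linear initialisation, so
exact exponential data are recovered to numerical precision and repeated
fits are identical. `synth_turbidity()` generates biphasic test curves as a
product of a rising and a falling logistic plus optional Gaussian noise;
the parameter-recovery tests compare extracted metrics against the same
functional evaluated on a 0.01 s grid.

```{r turbidity-example}
curve <- synth_turbidity(t_clot = 900, tau_clot = 90,
                         t_lysis = 7000, tau_lysis = 350, seed = 1)
turbidity_metrics(curve)
```

## What the synthetic data do and do not show

The generators in this package (the lattice simulator with surrogate
kinetics, the logistic turbidity curves) emulate the *structure* of the
study: geometry, event scheduling, dosing arithmetic, normalization and
metric definitions. They do not reproduce plasma biochemistry — no
plasminogen activation kinetics, no inhibitors (PAI-1), no factor XIII
cross-linking, no flow, no clot contraction, and no optical model linking
fibrin mass to OD. Passing tests therefore demonstrate that the machinery
computes the intended quantities and reproduces the *relative* behaviour of
clot structures (dense networks resist lysis; pore expansion accelerates
around half-lysis; tPA dose shortens lag times), not that absolute times or
rates match any particular plasma experiment.

## A worked desk-scale comparison

A two-scenario slice of the study design: the validation pair of opposite
structures, thin/loose versus thick/dense at fixed tPA concentration.

```{r study-example, eval = FALSE}
study <- run_scaled_study(scenarios = c("TN-L 9350", "TK-D 307"),
                          n_replicates = 3, seed = 1)
replicate_aggregate(select(study$metrics, scenario, lag_s, t50_s, rate_20_80),
                    scenario)
```

(Not evaluated during package build; a three-replicate slice takes tens of
seconds. The full ten-scenario, ten-replicate study behind
`scripts/acceptance.R` runs in a few minutes.)

## Numerical choices and degenerate inputs

* Event times are converted to step indices with
  `ceiling(t/dt - 1e-9)`; all bookkeeping is integer steps, so runs of
  10^8+ steps accumulate no floating-point drift.
* Ties: simultaneous degradations are applied in ascending (time, fiber
  id) order; molecule sweeps are in molecule index order; uniform choices
  among fibers use ascending fiber id. None of these tie rules consume
  randomness beyond the documented draws.
* Non-lytic kinetics (censored-only lysis, or `lysis_prob = 0`) refuse to
  run without a finite `max_time`.
* A 1 x 1 lattice (a single out-of-plane fiber) is a legal clot but has no
  scan-line crossings, so `measure_pores()` rejects it explicitly.
* Empirical CDFs with a single sample are degenerate point masses; draws
  still consume one uniform variate each so seeded streams stay aligned.
* `fit_decay()` on constant rates reports `k = 0` with a degenerate flag
  rather than failing inside the optimiser.

## Known limitations

* The microscale biochemistry is reduced to two independent draws per
  binding; any correlation between unbinding outcome and lysis time in the
  original microscale model is lost (treated as independent here).
* Desk-scale lattices (hundreds to thousands of fibers) have stronger
  boundary effects than full-size clots; pore statistics near complete
  degradation are dominated by whole-line gaps.
* Absolute transit times inherit the surrogate kinetics; see above.
* Large FDPs do not occlude pores for other molecules, and small-FDP
  diffusion uses the tPA step length.
* The out-of-plane (z) fibers are bindable but not crossed by scan lines;
  at a given overall degraded fraction the scanned in-plane fibers are
  slightly more degraded than the z fibers, because each in-plane fiber is
  reachable from two nodes and a z fiber from one.
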