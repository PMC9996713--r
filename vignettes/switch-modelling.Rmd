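---
title: "Modelling the FlpO/FRT inversion–excision CAR switch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the FlpO/FRT inversion–excision CAR switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flpswitch)
```

## The system and the two models

The circuit starts in State 1: a non-expressing blank sequence sits
immediately downstream of the promoter and the CAR gene is inverted.
Activated (nuclear) FlpO inverts either FRT pair, producing two transient
states in which the CAR gene is correctly oriented and expressed; both
transient states present the blank sequence between parallel FRT sites, so
a second, excision event deletes it, leaving the stably expressing State 2
plus a free loop of excised DNA (SX) that is diluted by cell division at
rate `delta`. The OFF switch is the mirrored construct (blank and CAR
swapped), so the same dynamical system serves both observables: for the ON
switch the expressing states are `{tS1, tS2, S2}`, for the OFF switch only
`{S1}`.

**Mechanistic model.** `build_mechanistic_network()` enumerates the four
recombination sub-networks (inversions i1, i2; excisions e1, e2) sharing
the five free genetic states. Each event proceeds through a cooperative
monomer-binding cascade `free → F1 → {F1,1 | F2,0} → F3 → F4` — `F1,1` has
one monomer on each FRT site, `F2,0` two on one — then Holliday-junction
entry (`k3`/`k3_rev`), four internal strand exchanges across five junction
complexes (`k4`–`k7` with reverses), and product release: a mirrored
dissociation cascade for inversions (product-side junction entry at `k3`,
exit at `k3_rev`, so the ladder is symmetric), or resolution into an
S2-strand·F2 and an SX-loop·F2 pair for excisions (`k8`, with bimolecular
re-association `k8_rev`). Cooperativity is encoded by
`effective_binding_rates()`: with base rates `k_on`, `k_off` shared within
a site pair and multipliers `0 < m1, m2 < 1`, free-site binding uses
`m1·k_on`/`k_off` and occupied-site binding `k_on`/`m2·k_off`, which
guarantees the affinity ordering `k1/k-1 < k2/k-2`. Site-pair A serves
events i1 and e2, pair B serves i2 and e1. The enumeration yields 63
DNA-containing species, the four protein/drug states `F`, `Fa`, `Fb`,
`OHT`, and 27 fitted rate constants; these counts are asserted by tests
rather than hard-coded anywhere.

Nuclear import is volume-corrected: activation consumes `Fa` and `OHT` at
rate `K_a·[OHT]·[Fa]` but produces only `vbar = 0.3` units of nuclear `F`
(the cytoplasm-to-nucleus volume quotient of a T cell), and the leak
pathway `Fb → vbar·F` behaves likewise. This enters the network as a
fractional product stoichiometry, so the same mass-action machinery serves
every reaction. Degradation (`beta_p`) acts only on free FlpO pools, not on
DNA-bound monomers, and dilution (`delta`) acts only on the free SX loop.

**Aggregation.** Percent CAR is computed on group totals: the State-1 group
(free S1, its bound cascades, and the inversion junction complexes) versus
the expressing group (everything else), with every S2-strand and SX species
weighted 1/2 so that one excised parental DNA counts once, not twice. With
these weights the State-1 total obeys the boundary-flux equation
`dS1/dt = k3·([tS1·F4] + [tS2·F4]) − k3_rev·([HJ5_i1] + [HJ5_i2])`,
which the suite verifies by finite differences along simulated
trajectories. Whether the excision resolution rate is called `k8` and the
re-association `k8_rev` or vice versa is a pure label swap between two
free fitted constants; the package fixes resolution = `k8`.

**Reduced model.** `reduced_rhs()` implements the nine-ODE simplification
in which cooperative binding and the junction ladder are collapsed so each
recombination event is one reversible reaction: forward inversions `k1`,
`k2` (State 1 → transients), forward excisions `k3`, `k4` (transients →
State 2 + SX), one shared reverse rate `k_r`, and the six protein/drug
rates, twelve fitted constants in all. The equations are implemented
term for term as printed in the source system, including two deliberate
asymmetries a modeller might otherwise "fix": active FlpO is consumed by
the reverse inversion fluxes (`−k_r·F·D_tS1`, `−k_r·F·D_tS2` in the `F`
balance), and the excision reverse flux `k_r·D_SX·D_S2` proceeds without
`F` and appears twice in both the SX and S2 balances. Fidelity to the
printed system takes precedence over kinetic convention; the genomic total
`D_S1 + D_tS1 + D_tS2 + D_S2` still cancels algebraically, which the tests
assert exactly. The same system is compiled (`src/reduced_rhs.c`) for the
deSolve integrators; the R implementation is the readable reference and the
two are cross-checked against an independently transcribed oracle.

## Observables, dose mapping, and response time

4-OHT enters as a source rate `alpha_d` (continuous media replenishment)
scaling linearly with dose, `alpha_d = dose_uM × alpha_d_at_1uM` with the
calibration default `alpha_d_at_1uM = 1 a.u./day`; an optional initial
concentration channel (`oht0_at_1uM`, default 0) is provided because the
drug could equally be modelled as a bolus. Neither calibration constant is
fitted.

The response time is the earliest time at which the ON series reaches 90%
of its maximum over the horizon (default 10 days, the experimental
window), or the OFF series completes 90% of its total decrease; crossings
are located by linear interpolation on a dense grid (step 0.005 days in
the scan functions). Series that never act are censored at the horizon and
flagged, never silently clipped. Two degenerate cases are fixed by
convention: a constant positive ON series is already at 90% of its maximum
(response time 0), while an ON series that never expresses at all and an
OFF series that never decreases are censored — the switch never acts.

## Synthetic data: what it emulates and what it does not

`generate_datasets()` stands in for the four experimental time courses,
which are not published in machine-readable form. It simulates the reduced
model at 0 and 1 µM, samples days 1–10 (the actual sampling days of the
experiments are not published; a uniform daily grid is a documented
convention), adds independent Gaussian noise (default sd 3 percentage
points — a typical flow-cytometry replicate spread), clips to [0, 100],
and by default rescales to the global maximum, the normalization used
experimentally to restrict attention to cells carrying both the
recombinase and the switch. The shipped `default_truth()` is a synthetic
parameter set, not a published fitted optimum: it was chosen once so that
at 1 µM the ON switch rises to a high plateau (~96% by day 10) with the
OFF switch falling correspondingly, and 0 µM shows a small basal rise
(~2%) through the leak pathway. Changing it is a breaking change gated by
tests.

Two interactions are worth knowing. First, with noise the global maximum
usually hits the clip bound, so normalization is a near-identity; for
noiseless data it rescales by `100/max` and makes the data *not* exactly
producible by the model, which is why recovery experiments switch it off.
Second, clipping shrinks the observable noise at points near 0 or 100 —
and since a realistic switch spends much of its trajectory near those
bounds, the expected fitting distance at the truth sits visibly below the
unclipped analytic floor `4·E|N(0, 3)| ≈ 9.6`.

What passing the recovery tests shows is that the pipeline is correct and
that the error landscape at this truth is benign; it does not show that
real flow-cytometry data (cell-to-cell heterogeneity, transduction
subpopulations, non-Gaussian measurement error) would be fit equally well,
nor that every individual rate constant is practically identifiable — the
ABC marginals, not the point fit, carry that information.

## Inference

**Distance.** `error_distance()` is one tenth of the sum of the forty
absolute residuals across the four datasets. Note the divisor is the ten
observation days, not the forty points, so forty unit residuals give 4.0;
the function is often described as a mean absolute error, but the printed
divisor-ten form is what the package implements.

**Genetic algorithm.** The underlying study used a generic built-in GA;
the operator set here is therefore a documented package choice satisfying
the two contracts that matter — elitism (best-so-far error is
non-increasing) and seed-reproducibility. Defaults: tournament selection
(size 3), uniform crossover (probability 0.9), per-gene Gaussian mutation
(probability 0.15) with step size annealed geometrically from 0.15 to 0.01
across generations, clipped to the `[0, 1]` search box, two elites.
Candidates whose integration fails receive ten times the worst finite
score of the population, reflecting that large search boxes risk stiff
failures; they are counted, logged, and never crash the run. The
desk-scale default (population 200, 150 generations, ~2 × 30,200 ODE
solves, under a minute with the compiled right-hand side) recovers a
noiseless synthetic truth to a distance below 0.5; the study-scale setting
(population ≥ 1000, 1000 generations) is configuration, not a different
code path.

**ABC-SMC.** Population 1 is rejection sampling from the uniform prior at
the first threshold; later populations resample the previous one by
weight, perturb with a component-wise Gaussian kernel whose scale is half
the weighted standard deviation of the previous population per parameter
(a uniform kernel of the same half-width is available), reject proposals
outside the prior box before simulating, and accept at the current
threshold; weights follow the standard SMC rule (uniform prior density
over the kernel-weighted mixture). The source procedure's kernel and
per-population draw cap are not published, so both are explicit
configuration: the cap defaults to 200,000 proposals, and when a
population cannot be filled the run stops and reports the last completed
population — the behaviour expected at an unreachable final threshold,
e.g. a schedule deliberately ending at a previously attained GA error.
The default schedule is the ten-threshold study sequence ending at 28.15;
desk-scale runs on synthetic data use short reachable schedules such as
`c(50, 20, 10)`.

## Post-fit analyses

Sensitivity is one-at-a-time by design (matching the procedure the model
reduction was based on), multiplying each fitted constant over a log-spaced
factor grid spanning two decades either side (19 points by default) and
ranking by the maximum absolute log-change of the response time over both
switches. Censoring interacts with this metric: any perturbation that
pushes the response past the 10-day horizon contributes at most
`log(horizon/baseline)`, so with a baseline response around 7.6 days all
slow-side effects are capped and the ranking compresses. At the shipped
truth the protein/drug-side rates (`alpha_a`, `beta_p`, `beta_d`, `K_a`)
all outrank the per-event recombination rates and the dilution rate, but
their exact order among the top positions is not meaningful under the cap —
and the ordering at the study's own fitted optimum cannot be checked, since
those parameter values are unpublished.

Dose–response uses doses 10⁻¹–10¹ µM (21 log-spaced points by default),
each an independent simulation; fold scans multiply `alpha_a` and
`alpha_b` jointly (FlpO expression is tuned through its promoter, which
drives both pools) by 1, 2 and 5; the trade-off grid crosses one order of
magnitude of fold change with the dose range and censors at the horizon
rather than extrapolating. All scans are pure functions of their inputs;
the fold-1 row of the trade-off grid is bitwise the dose–response curve.

## Numerical choices and problem sizes

Integration uses `lsoda` (stiff-capable) at `rtol = 1e-8`,
`atol = 1e-10`; halving the tolerances moves percent-CAR outputs by far
less than 0.1 percentage points. The mechanistic right-hand side is the
sparse stoichiometry matrix applied to the mass-action flux vector, checked
against a naive per-reaction accumulation to floating tolerance; genomic
conservation holds to better than 1e-6 relative over ten days across
random parameter draws (the suite uses 100 for the reduced model). The
test and acceptance runs use desk-scale problem sizes chosen for quick
iteration — GA population 200 × 150 generations, 100 ABC particles with a
three-threshold schedule, 9–21-point scan grids — stated here as package
choices; the study-scale settings are reachable purely through
configuration.

## Known limitations

* The reverse-flux conventions of the reduced system are implemented as
  printed even where kinetically unusual (see above); the mechanistic and
  reduced models are therefore not exact coarse-grainings of one another,
  and no automatic model-reduction machinery is provided.
* No stochastic (SSA) simulation: the deterministic output approximates
  the mean of the ensemble, which is the appropriate observable for
  percent-of-cells data.
* Spatial effects on re-insertion of the excised loop, cell
  proliferation, antigen response, and downstream cytotoxicity are out of
  scope; SBML export is not provided.
* The synthetic generator does not model flow-cytometry gating or the
  transduction-efficiency subpopulations beyond the global-maximum
  normalization that absorbs them.
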