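# flpswitch

Deterministic mass-action modelling and parameter inference for an
inducible FlpO/FRT inversion–excision genetic switch that gates chimeric
antigen receptor (CAR) expression in engineered T cells.

## The problem

Tyrosine recombinases such as FlpO mediate reversible DNA inversion, which
makes a plain inversion switch leaky; flanking the payload with a gated
arrangement of FRT sites lets a first (reversible) inversion create a
parallel-site configuration whose subsequent excision locks the state far
more stably. The circuit is induced by 4-hydroxytamoxifen (4-OHT), which
licenses nuclear entry of cytosolically expressed FlpO; leaky nuclear
localisation gives a small basal switching rate even without drug.

`flpswitch` is for modellers and circuit designers who want to

* build the **full mechanistic reaction network** of the switch
  programmatically — cooperative FlpO monomer binding on each FRT pair
  (`k1/k-1 < k2/k-2`, enforced with multipliers `0 < m1, m2 < 1`), five
  sequential Holliday-junction strand-exchange complexes per recombination
  event, mirrored inversion product release, excision into an S2 strand
  plus an excised loop (SX) diluted by cell division — 63 DNA-containing
  species, 4 protein/drug states and 27 fitted rate constants;
* simulate the **reduced nine-ODE model** in which each recombination event
  is a single reversible reaction (12 fitted rate constants, shared reverse
  rate `k_r`), with states
  `F, 4OHT, Fa, Fb, D_S1, D_tS1, D_tS2, D_SX, D_S2`;
* fit either model to the four percent-CAR time courses (ON and OFF switch,
  each at 0 and 1 µM 4-OHT, ten days) **simultaneously**, by a bounded
  genetic algorithm and by ABC with sequential Monte Carlo, under the
  distance `d = (1/10) Σᵢ₌₁⁴⁰ |xᵢ − yᵢ|` and a uniform `[0, 1]` search
  box on every fitted constant;
* analyse the fitted model: one-at-a-time sensitivity of the 90% response
  time, dose–response curves over 10⁻¹–10¹ µM, FlpO-expression fold-change
  scans, and the dose × expression trade-off grid;
* generate **synthetic four-dataset time courses with known ground truth**
  (Gaussian observation noise, clipping to [0, 100], global-maximum
  normalization) so that every stage is testable end to end.

Everything is tibble-first and pipe-friendly; fitted objects have broom
`tidy()`/`glance()` methods and results have `autoplot()`/`plot_*()`
visualisations.

## Worked example

Generate noisy synthetic data from the shipped ground truth, fit the
reduced model with the genetic algorithm, and ask how fast the fitted
switch turns on at 1 µM:

```r
library(flpswitch)

gen <- generate_datasets(synthetic_config(noise_sd = 3, seed = 1))
gen
#> <synthetic_timecourses> 40 observations; noise_sd = 3

fit <- fit_ga(gen$datasets,
              config = ga_config(population_size = 200, generations = 60,
                                 seed = 1))
glance(fit)
#> # A tibble: 1 × 6
#>   model   error evaluations failed_evaluations generations  seed
#>   <chr>   <dbl>       <int>              <int>       <int> <int>
#> 1 reduced  6.04       12200                  0          60     1

tidy(fit)
#> # A tibble: 12 × 2
#>   term    estimate
#>   <chr>      <dbl>
#> 1 alpha_a  0.913
#> 2 alpha_b  0.00963
#> 3 beta_p   0.0582
#> 4 beta_d   0.187
#> # ℹ 8 more rows

traj <- simulate_switch(as_reduced_parameters(fit$parameters),
                        dose_condition(1), seq(0, 10, 0.01))
response_time(percent_car(traj, "ON"), "ON")
#> <response_time> 7.237 days (horizon 10 d)
```

The fitted error 6.04 is the sum of the forty absolute residuals divided by
ten; with 3-point observation noise its expectation at the true parameters
is near the analytic floor `4·E|N(0,3)| ≈ 9.6`, reduced here by boundary
clipping and by the fit absorbing part of the noise. The response time is
the first day at which the ON switch reaches 90% of its maximum percent-CAR
level; `dose_response()` shows it shrinking monotonically as the 4-OHT dose
rises from 0.1 to 10 µM, and `fold_change_scan()` shows the same speed-up —
at the price of higher basal switching — when FlpO expression is raised
two- and five-fold.

A thin command-line interface wraps the same functions
(`exec/flpswitch generate|simulate|fit-ga|fit-abc|sensitivity|dose-response|fold-scan|tradeoff`),
writing CSV/JSON outputs with a provenance block (seed, config hash,
package version).

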