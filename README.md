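# anomdiff

Anomalous-diffusion modelling of disease-symptom evolution from binned
longitudinal observations.

## The problem

In longitudinal monitoring of a clinical parameter — the motivating case is
thoracic fluid content (TFC, the inverse of chest impedance, 1/Ohm), a
fluid-overload marker recorded by impedance cardiography in heart-failure
cohorts — sudden large excursions are common.  Under a Gaussian
(ordinary-diffusion) model of symptom evolution such jumps should be rare;
under *subdiffusion* the propagator has a fat tail and large deviations are
a structural feature.  The package lets an analyst ask which regime binned
visit data supports, by fitting the anomalous-diffusion exponent.

The model: the parameter's variance grows as a power law,

    <x²(t)> = 2 K_α t^α / Γ(1+α),    0 < α < 2,    H = α/2,

and its density is the Green's function of a fractional Fokker–Planck
equation, evaluated here from its similarity series (an M-Wright function
in ξ = |x−x₀| / (√K_α t^{α/2})) with a fixed-Talbot inverse-Laplace and a
saddle-point asymptotic taking over where double precision degrades.
`H = α/2` is the Hurst exponent; `H < 1/2` is the fat-tailed, subdiffusive
regime.  One time unit is one 31-day registration period.

The package provides, as separate composable pieces:

* `evaluate_propagator()`, `laplace_oracle()`, `msd()`,
  `check_admissibility()` — propagator numerics and diagnostics;
* `binned_distribution()`, `evolve_distribution()`,
  `stationary_estimate()`, `distribution_distance()` — evolution of 15-slot
  binned distributions;
* `fit_params()`, `rmse()`, `hurst()` — RMSE estimation of (α, K_α) and the
  Hurst exponent;
* `simulation_config()`, `simulate_cohort()`, `bin_observations()`,
  `ctrw_scaling()` — a CTRW-based synthetic cohort generator emulating a
  605-patient, ~2860-measurement heart-failure monitoring protocol
  (irregular visits, 15 value slots, 31-day periods), since the original
  clinical data is not deposited;
* `anomdiff_cli()` plus `inst/cli/anomdiff.R` — a command-line pipeline
  (`simulate`, `fit`, `evolve`, `propagator`).

## Worked example

Simulate a cohort with subdiffusive latent dynamics (α* = 0.8), bin it by
the clinical protocol, and fit:

```r
library(anomdiff)

cfg <- simulation_config(seed = 3)          # 605 patients, ~2860 visits
tab <- simulate_cohort(cfg)
obs <- bin_observations(tab, cfg$slot_edges,
                        cfg$period_length_days, cfg$n_periods)
fit <- fit_params(obs, fit_config(target = "all_periods",
                                  initial = "first_period"))
fit
#> Subdiffusion fit (RMSE criterion)
#>   alpha   = 0.9331
#>   K_alpha = 7.756
#>   Hurst H = 0.4666
#>   RMSE    = 0.0135157 over slot masses (all_periods target, first_period start)
#>   admissible pair: TRUE; 1642 objective evaluations (12 skipped)
```

Reading the output: `alpha` is the anomalous-diffusion exponent (values
below 1 mean subdiffusion, hence a fat-tailed propagator), `K_alpha` the
generalized diffusion coefficient in (1/Ohm)² per 31-day-period^α,
`Hurst H = alpha/2`, and `RMSE` the root-mean-square discrepancy between
evolved model slot masses and observed slot frequencies — its ~0.014
magnitude is the multinomial noise floor of roughly 400 hits per period.
The generating dynamics here had α* = 0.8 and an implied K_α ≈ 7.9; at
this cohort size the α estimate is noisy (spread of roughly ±0.3 across
seeds — see the vignette's identifiability discussion), while K_α, which
sets the amount of spreading, is recovered more stably.

The propagator itself:

```r
p <- fractional_params(0.47, 1)   # strongly subdiffusive, H = 0.235
evaluate_propagator(c(0, 1, 3), t = 1, params = p)
#> [1] 0.41460740 0.19073930 0.03068067
#> attr(,"fallback")
#> [1] FALSE FALSE FALSE
msd(p, 1)                         # 2 K t^alpha / Gamma(1+alpha)
#> [1] 2.258271
```

Note the peak–tail contrast with the Gaussian of equal K (peak 0.415
vs 0.282, and a far tail orders of magnitude heavier).

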