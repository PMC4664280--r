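# occbaci

Hierarchical Bayesian occupancy models for Before-After Control-Impact
(BACI) experiments with nested sampling, and a simulation harness for
evaluating the frequentist properties of their treatment-effect
estimators.

## The problem

Cryptic species such as plethodontid salamanders are surveyed on small
plots nested within management units (forest stands), with repeated visits
per plot. Detection is imperfect: an occupied plot can yield no detection
on a visit. In a BACI experiment — units split into control and impact
arms, followed before and after a manipulation — the scientific target is
the treatment-by-period interaction on the logit scale of occupancy, and
study designers need to know how many units, plots and visits are required
for that interaction to be estimated with acceptable bias, precision, and
credible-interval calibration.

`occbaci` provides, for that setting:

* **Two occupancy processes.** The *hierarchical single-scale* model puts
  occupancy at the plot level,

  `u_ijk ~ Bern(psi_ijk)`, `y_ijkl ~ Bern(u_ijk * p_ijkl)`,
  `logit(psi_ijk) = beta0 + b0_i + beta1*Year + beta2*Trt + beta3*Trt*Year`,

  with a unit random intercept `b0_i ~ N(0, sigma_b^2)`; `exp(beta3)` is
  the treatment effect on plot-level occupancy odds. The *multi-scale*
  model adds a nested unit-level state `z_ij ~ Bern(theta_ij)` with the
  same BACI mean model (treatment effect `alpha3`), and constant
  conditional plot occupancy and detection below it.
* **Exact marginal likelihoods** (latent states summed out analytically)
  and an adaptive Metropolis-within-Gibbs sampler in C++, with
  Gelman-Rubin diagnostics and equal-tail intervals.
* **Simulators** for the factorial BACI evaluation design (90 conditions
  per model) and for two-species plot surveys with removal sampling,
  habitat (coarse woody debris) and survey-date covariates.
* **An evaluation harness** (`run_condition()`, `run_grid()`) measuring
  bias, precision (mean posterior SD), sampling SD and 95% interval
  coverage of the treatment-effect estimator over replicated experiments.
* **A survey-data fitting path** (`read_empirical()`, `fit_empirical()`,
  `derived_summaries()`) for plot-level occupancy with CWD, year and block
  effects and quadratic Julian-date detection.

## A worked example

```r
library(occbaci)

cond <- baci_condition("single", n_units = 20, n_plots = 7,
                       p_detect = 0.3, post_plot_occ = 0.1)
sim <- simulate_baci(cond, seed = 1)
fit <- occu_fit(sim$data, "single", chains = 3, n_iter = 4000,
                burnin = 2000, thin = 1, seed = 2)
fit
#> hierarchical single-scale occupancy model
#>   data: 20 units x 2 years x 7 plots x 3 visits
#>   3 chains x 4000 iterations (burn-in 2000, thin 1), priors: default
#>  parameter   mean    sd  lower  upper
#>      beta0  2.436 0.832  1.022  4.368
#>      beta1 -0.742 0.828 -2.353  0.988
#>      beta2 -0.783 0.898 -2.506  0.992
#>      beta3 -2.558 1.102 -4.939 -0.582
#>     gamma0 -0.953 0.141 -1.216 -0.665
#>    sigma_b  1.019 0.535  0.157  2.183
#>   max R-hat (mean model): 1.015
sim$truth$effect
#> [1] -3.044522
```

The dataset was generated with plot occupancy 0.7 before and 0.1 after
treatment, so the true interaction is `logit(0.1) - logit(0.7) = -3.04`.
The fit recovers it inside a wide 95% interval (`beta3` mean -2.56, SD
1.10 — 20 units with detection 0.3 is not much information), estimates
detection near the truth (`plogis(-0.95) = 0.28` against 0.3), and the
chains pass the R-hat < 1.1 filter.

Estimator properties at that design point, over replicated experiments:

```r
res <- run_condition(cond, n_reps = 200, seed = derive_seed(1, 1))
res
#> BACI condition (single-scale): 20 units, 7 plots, 3 visits
#>   plot occupancy 0.70 -> 0.10, detection 0.30, sigma_b 1.00
#>   priors default, 193/200 replicates converged (R-hat < 1.1)
#>   true effect -3.045 | bias 0.261 | mean posterior SD 0.952 |
#>   sampling SD 0.739 | coverage 0.979
```

Coverage of the nominal 95% interval is slightly conservative (0.979),
and the average posterior SD exceeds the estimator's actual sampling SD —
the calibration pattern `calibration_table()` quantifies.

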