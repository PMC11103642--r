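# cjsnow

Bayesian Cormack–Jolly–Seber (CJS) survival analysis for radio-tracked
juvenile birds monitored over biweekly occasions, built around one
question: how do season and winter snow cover shape first-year survival?

Radio-telemetry of juvenile little owls (*Athene noctua*) and similar
resident species produces encounter histories at a fortnightly resolution,
with tracking effort that varies over time (including fortnights with no
tracking at all) and mortality concentrated in the post-fledging weeks and
in snowy winters. `cjsnow` provides the full pipeline for such data:

* a biweekly occasion calendar with seasonal date windows (summer
  post-fledging, autumn dispersal, winter, spring first breeding) and
  explicit effort regimes (`full` / `reduced` / `none`);
* a snow-days covariate (days per fortnight with snow cover ≥ 1 cm) read
  from generic CSVs or DWD "KL daily" climate files;
* the CJS likelihood with seasonal survival intercepts, covariate effects
  restricted to configurable seasons, effort-stratified detection with
  structural zeros and individual heterogeneity — marginalized over death
  times by a forward algorithm (C++ core) and cross-checked against a
  brute-force enumeration oracle;
* an adaptive Metropolis-within-Gibbs sampler with informative priors,
  rank-normalized split R-hat diagnostics, and a Freeman–Tukey m-array
  posterior predictive check;
* derived demography computed per posterior draw: season-level and annual
  survival, mild- vs harsh-winter scenarios, the seasonal partition of
  first-year mortality, and expected cohort trajectories;
* a synthetic-data generator (cohorts, broods, staggered releases, daily
  snow series with winters of varying severity) with known truth, so the
  whole pipeline is testable end to end.

## The model

For individual $i$ over the interval from occasion $t$ to $t+1$:

$$\mathrm{logit}(\phi_{i,t}) = \alpha_{s(t)} + \beta_{\text{snow}} z_t
+ \beta_{\text{mass}} m_i + \beta_{\text{sex}} x_i + \beta_{\text{fed}} g_i$$

with the mass/sex/feeding terms active only in the seasons named by a
season mask (default: mass and feeding act in the post-fledging summer
only), and $z_t$ the standardized snow-days covariate. Detection at
occasion $t$ is 0 where effort was `none`, otherwise

$$\mathrm{logit}(p_{i,t}) = \mathrm{logit}(p_{\text{regime}(t)})
+ \beta_{\text{snow,det}} z_t + \varepsilon_i,\qquad
\varepsilon_i \sim N(0, \sigma^2_{\det}).$$

Priors: Beta(95, 10) on each season's baseline biweekly survival,
Uniform(0.7, 1) and Uniform(0.3, 0.9) on the full- and reduced-effort
detection baselines, Normal(0, 1) on coefficients, half-Normal(0, 1) on
$\sigma_{\det}$. Seasonal survival is powered up by 4/6/10/6 biweekly
periods (summer/autumn/winter/spring) and multiplied into annual survival;
a harsh winter distributes 60 snow days over the 10 winter fortnights.

See `vignettes/seasonal-survival.Rmd` for the full methods account.

## Worked example

Simulate a study — three cohorts of 100 fledglings over three winters
(harsh, harsh, mild) — fit the model, and derive the demography:

```r
library(cjsnow)

cal  <- study_calendar()                       # 79 biweekly occasions
snow <- simulate_snow_series(cal, seed = 1,
                             severity = study_winter_severity())
sdy  <- snow_days_by_occasion(snow, cal)
sc   <- snow_standardization(sdy, cal)
z    <- standardize_snow(sdy, sc$center, sc$scale)

ind  <- simulate_individuals(100, 3, 0.5, seed = 2, calendar = cal)
sim  <- simulate_encounters(ind, study_params(), cal, z, seed = 3)
sim$data
#> <cjs_data> 300 individuals x 79 biweekly occasions
#>   effort: 69 full, 6 reduced, 4 none

fit <- sample_posterior(sim$data, mcmc = mcmc_settings(2, 1200, 300, 3),
                        seed = 4)
summarize_posterior(fit$draws[, 3:14])
#>          quantity median  lower  upper
#> 1      phi_summer  0.843  0.809  0.870
#> 2      phi_autumn  0.942  0.926  0.956
#> 3      phi_winter  0.970  0.955  0.978
#> 4      phi_spring  0.949  0.926  0.968
#> 5  beta_snow_surv -0.442 -0.657 -0.221
#> ...
```

The biweekly estimates recover the generating values (0.844 / 0.936 /
0.970 / 0.945; snow effect −0.389): survival is lowest in the post-fledging
summer, high in a snow-free winter, and each winter-SD of extra snow days
multiplies the odds of fortnightly survival by about `exp(-0.44) ≈ 0.64`.
Derived season-level survival:

```r
demography_tables(fit)$survival
#>                             quantity median lower upper
#>               Summer (post-fledging)  0.504 0.428 0.573
#>                               Autumn  0.701 0.630 0.765
#>                        Winter (mild)  0.734 0.630 0.802
#>                       Winter (harsh)  0.534 0.419 0.634
#>                               Spring  0.731 0.629 0.824
#>   Annual survival (with mild winter)  0.188 0.130 0.245
#>  Annual survival (with harsh winter)  0.137 0.093 0.182

dd <- derive_demography(fit)
median(relative_change(dd$annual_mild, dd$annual_harsh))
#> 27.2   # percent of first-year survival lost to a harsh winter
```

A fifth to a sixth of juveniles survive their first year; a winter with 60
days of snow cover removes about a quarter to a third of that. The
`analysis/` directory walks the same pipeline as four narrated scripts
(calendar + covariate, simulation, fitting, derived demography), writing
tables and the cohort-trajectory figure under `results/`.

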