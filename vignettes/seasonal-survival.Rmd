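---
title: "Seasonal CJS survival with a snow-cover covariate: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal CJS survival with a snow-cover covariate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cjsnow)
```

## The problem

Juvenile survival from fledging to first breeding is a key driver of
population growth in many birds, and it is rarely uniform over the year:
mortality concentrates in the weeks just after fledging and, in resident
species that depend on access to ground-dwelling prey, in winters with long
periods of snow cover. `cjsnow` estimates season-specific biweekly survival
of radio-tagged juveniles with a Bayesian Cormack–Jolly–Seber (CJS)
mark–recapture model and converts the estimates into the demographic
quantities practitioners report: season-level and annual survival, the
seasonal partition of first-year mortality, the cost of a harsh winter, and
expected cohort trajectories.

The package is organised as an analysis workflow: every computational step
lives in package functions (tested in `tests/testthat/`), and the numbered
drivers in `analysis/` narrate one full pass — calendar and covariate, data
simulation, model fitting, derived demography.

## Time axis and seasons

Tracking data are aggregated into *biweekly occasions*: contiguous half-open
14-day intervals `[start, start + 14)` anchored at a configurable origin
(default 15 May of the first cohort year). The interval boundaries are a
package convention — only the 14-day resolution is fixed by the design —
and an occasion's season is decided by the date of its midpoint (day 8),
which breaks ties for fortnights straddling a season boundary.

Four seasons are defined by year-agnostic date windows:

| season | window | biological phase |
|---|---|---|
| summer | 15 May – 1 Aug | post-fledging, in the natal home range |
| autumn | 2 Aug – 23 Oct | natal dispersal |
| winter | 24 Oct – 12 Mar | stationary winter period |
| spring | 13 Mar – 15 Jun | first breeding season |

Spring and summer deliberately overlap by four weeks so that staggered
fledging and staggered onset of first breeding both fit their windows. A
shared calendar has to resolve the overlap one way:

* `overlap_rule = "first_summer"` (default) labels overlap occasions before
  the calendar's first 2 August as summer and later ones as spring — the
  right reading for a single cohort tracked from fledging into the next
  breeding season. Under this rule a full annual cycle after the first
  summer has exactly 4 summer, 6 autumn, 10 winter and 6 spring occasions,
  matching the season lengths used for all derived quantities.
* `overlap_rule = "summer"` labels every overlap occasion summer. This is
  what `study_calendar()` uses, because a multi-cohort calendar must place
  every cohort's May–July releases in summer-labelled occasions; the cost is
  that the *previous* cohort's spring is truncated at mid-May. With
  staggered releases no single labelling serves all cohorts exactly; the
  rule is explicit configuration, not inference.

Tracking effort is an input, not something inferred from detections: each
occasion is `full`, `reduced` or `none`, and `none` forces detection
probability to exactly 0 (a structural zero). `study_effort_spec()` encodes
the default layout: 4 zero-effort occasions in the first winter/early
spring and 6 reduced-effort occasions split between the two winters.

## The snow covariate

Daily snow depths (generic CSV or DWD "KL daily" files, whose `-999`
sentinel is mapped to missing, never to zero) are reduced to the number of
days per occasion with snow cover of at least 1 cm — a proxy for how long
prey under snow stayed inaccessible. Missing days are an error under the
strict policy and count as snow-free under the permissive one.

The covariate enters both linear predictors after an affine transform
`z = (snow_days - center) / scale`. The default policy is `center = 0` and
`scale =` the SD of snow days over winter occasions: dividing by the winter
SD puts the coefficient on a per-winter-SD scale, while keeping `z = 0`
exactly at zero snow days so the winter intercept stays interpretable as
*snow-free* winter survival. A full z-score (mean-centering over winter)
would move the intercept to survival at average snow cover; it remains
available by passing an explicit center. Because the published coefficient
scale for this class of model is not recoverable from summary estimates,
the scaling in force is always recorded in the run manifest and must be
reported alongside any coefficient.

## The model

For individual $i$ over interval $(t, t+1]$ (governed by the season and
snow value of occasion $t+1$, the fortnight being survived):

$$\mathrm{logit}(\phi_{i,t}) = \alpha_{s(t)} + \beta_{\text{snow}}
z_t + \beta_{\text{mass}} m_i \, [s(t) \in M_{\text{mass}}] +
\beta_{\text{sex}} x_i \, [s(t) \in M_{\text{sex}}] +
\beta_{\text{fed}} g_i \, [s(t) \in M_{\text{fed}}]$$

with four seasonal intercepts $\alpha_s$ and season masks $M$ restricting
where each individual covariate acts. The two study formulations are
`season_mask()` (mass and feeding act only in the post-fledging summer, the
default and the retained model) and `season_mask(mass = SEASONS, fed =
SEASONS)` (year-round effects). The mask mechanism expresses any other
combination; since the design leaves a third formulation open, the fitted
mask is written into the run manifest rather than hard-coded.

Detection at occasion $t$ is 0 when effort is `none`, otherwise

$$\mathrm{logit}(p_{i,t}) = \mathrm{logit}(p_{\text{regime}(t)}) +
\beta_{\text{snow,det}} z_t + \varepsilon_i, \qquad
\varepsilon_i \sim N(0, \sigma_{\det}^2),$$

a hybrid forced by the prior structure: the regime baselines live on the
probability scale with bounded uniform priors, while snow and individual
heterogeneity are logit-additive offsets. The snow term absorbs temporary
escape movements during severe weather so they do not masquerade as
mortality; permanent emigration remains confounded with death, which is why
$\phi$ is *apparent* survival.

### Likelihood

The likelihood is the marginalized (forward-algorithm) CJS likelihood:
conditioning on first release, a two-state hidden Markov recursion over
alive/dead sums over all death times consistent with the history, with
per-step renormalization against underflow. It is exact given
$\varepsilon$, which the sampler treats as parameters (no data
augmentation of latent alive states, and no quadrature). A deliberately
naive oracle, `brute_force_loglik()`, enumerates every death interval
explicitly; the test suite checks agreement to `1e-12` exhaustively for all
histories up to 8 occasions and on 1000 random 20-occasion cases. Cells
with $p = 0$ and $y = 0$ contribute a factor of 1, so the likelihood is
invariant to the structurally unobservable occasions — also verified
exactly, by deleting those occasions and folding their survival into the
adjacent interval.

A datum with a detection where $p = 0$ is an error, never a silent
$-\infty$.

### Priors

* Each season's baseline biweekly survival (at covariate 0):
  Beta(95, 10) — mean 0.905 — attached to each season independently. The
  design describes a single "biweekly survival probability" prior; with
  four intercepts the per-season attachment is the natural reading, and it
  is recorded in the manifest.
* Detection baselines: Uniform(0.7, 1) under full effort, Uniform(0.3, 0.9)
  under reduced effort (supports enforced during sampling).
* All regression coefficients: Normal(0, 1). The protocol allows SD 1–2;
  1 is the conservative end and `prior_spec(coef_sd = 2)` the alternative.
* $\sigma_{\det}$: positive-truncated Normal(0, 1).

### Sampler

`sample_posterior()` runs an adaptive Metropolis-within-Gibbs:
single-parameter random walks for the baselines (on the probability scale,
where their priors live, with out-of-support proposals rejected via the
prior), the coefficients and $\sigma_{\det}$, plus an element-wise vector
update for $\varepsilon$ — valid because likelihood contributions are
independent across individuals given the rest. Because the random effects
are only weakly identified when detection is near 1, the
$(\varepsilon, \sigma_{\det})$ hierarchy forms a funnel that stalls
separate updates; a joint multiplicative rescaling move
$(\varepsilon, \sigma) \to (a\varepsilon, a\sigma)$ with log-normal $a$
(acceptance ratio: likelihood difference + prior difference + $\log a$)
traverses it. Proposal scales adapt toward ~44% acceptance during burn-in
only, so retained draws form a valid chain.
Defaults follow the analysis protocol: 3 chains × 3500 iterations, burn-in
200, thinning 6 (550 retained draws per chain). Initial values come from
the priors (baselines) and zero (coefficients, $\varepsilon$), which
guarantees a finite starting density.

Convergence is assessed with rank-normalized split R-hat
(`gelman_rubin()`), flagging parameters at or above 1.02; at the default
protocol all parameters of a study-scale fit come in under that threshold.
$\sigma_{\det}$ remains the slowest-mixing parameter, and the reduced
settings used in parts of the test suite are chosen for the quantities
those tests assert, not for publication-grade inference on
$\sigma_{\det}$.

Goodness of fit uses a posterior predictive check on the m-array (releases
× first recaptures) with the Freeman–Tukey discrepancy
$\sum (\sqrt{m} - \sqrt{\hat m})^2$; the protocol names no specific
statistic, so the choice is configurable and logged. Replicates are
simulated per draw, each side conditioned on its own releases, and the
Bayesian p-value counts ties as extreme.

## Derived demography

All derived quantities are computed **per draw and summarized last**
(median, 2.5th/97.5th percentile); powering a posterior median is not the
median of powered draws, which is exactly why season-level tables derived
from per-draw computation can differ by a few thousandths from powering the
printed biweekly medians.

* Season-level survival: $\phi^L$ with $L = 4, 6, 10, 6$ biweekly periods
  for summer, autumn, winter, spring (26 periods: one annual cycle, 1 July
  to 30 June).
* Winter scenarios: the mild winter has zero snow throughout; the harsh
  winter distributes 60 snow days over the 10 winter periods as
  2 extreme + 3 high + 3 intermediate + 2 snow-free periods. The per-class
  day counts (12, 12, 8, 8, 8, 4, 4, 4, 0, 0) are configuration — the
  class structure and the 60-day total are fixed by the design, the split
  is this package's documented default (`winter_composition()`).
* Annual survival: the product of the four season-level survivals.
* Mortality partition: the share of first-year deaths falling in each
  season, $S_1 \cdots S_{k-1}(1 - S_k) / (1 - S_{\text{annual}})$; shares
  sum to 100% before rounding (reported to 1 decimal, probabilities to 3).
* Cohort trajectories: 100 birds of average mass multiplied through the 26
  scenario-specific biweekly survivals of each draw; deterministic within a
  draw, with uncertainty from the posterior. Under the summer-only feeding
  mask, fed and unfed trajectories are parallel (constant ratio) after the
  4 summer periods — an algebraic consequence the tests verify.

## The synthetic-data generator

`simulate_individuals()` + `simulate_encounters()` generate datasets with
the statistical structure the model assumes, with known truth, so every
downstream stage is testable without field data: 3 cohorts × ~100
fledglings (broods of 1–5; feeding assigned at brood level to half the
broods; fair-coin sex; standard-normal age-corrected mass; staggered
May–July tagging), detection under the full/reduced/none effort layout, and
a winter snow covariate from a synthetic daily series
(`simulate_snow_series()`: November–March snow episodes with day-to-day
persistence 0.85 and lognormal depths). Winter severity varies between
years through a per-winter multiplier on the episode onset rate — by
default drawn from a lognormal, or fixed via the `severity` argument.
`study_winter_severity()` encodes the study period's documented sequence:
two harsh winters (roughly 40–50% of winter days under snow, with extreme
fortnights of 12–14 snow days) followed by a nearly snow-free mild winter.
That mix is statistically load-bearing, not decoration: the mild winter
pins the snow-free winter intercept, the harsh winters identify the snow
slope. Three uniformly moderate winters leave intercept and slope
confounded at study scale — the informative survival prior then pulls the
intercept down and the slope toward zero, and parameter-recovery
experiments show exactly that attenuation.

Generating parameter defaults (`study_params()`) are the study-scale
posterior medians: biweekly survival 0.844/0.936/0.970/0.945
(summer/autumn/snow-free winter/spring), snow effect −0.389, mass 0.480,
sex 0.153, feeding 0.345, detection 0.994 (full) and 0.803 (reduced), snow
effect on detection −0.229. The detection heterogeneity SD is not
identifiable from published summaries; 0.5 on the logit scale is the
package's default, a mild heterogeneity. Brood-size and tagging-date
distributions are likewise plausible stand-ins, flagged as such in the
generator's documentation.

What the generator does **not** emulate: spatial movement or emigration (so
recovery tests cannot detect confounding of dispersal with death), tag
failure (battery life exceeds the tracking window), brood-level random
effects on survival (the model has none; broods exist only for realistic
feeding assignment), and time-varying individual covariates. Passing
parameter-recovery tests therefore demonstrates correctness of the
likelihood, sampler and derivations under the model's own assumptions — not
robustness to the ways real telemetry data violate them.

## Numerical and testing choices

* Forward recursion renormalizes each step; log-likelihoods are exact to
  double precision against enumeration.
* Quantiles are R's default linear-interpolation (type 7) quantiles.
* Degenerate inputs fail loudly: empty season windows, duplicate snow
  dates, negative depths, out-of-span tagging dates, detections at
  structural zeros, all-survivors mortality partitions.
* The test suite runs its statistical checks at deliberately moderate
  sizes: parameter recovery on 20 datasets of 300 individuals × 27
  occasions with 2 chains × 1200 iterations; PPC calibration on 20 datasets
  of 150 individuals; the prior-recovery run at the full default protocol.
  These sizes give the assertions (CrI coverage ≥ 80%, p-values inside
  (0.05, 0.95), 3-MC-SE prior means) comfortable statistical margins while
  keeping a full suite run in the tens of minutes on one core.

## Known limitations

* Apparent survival only: permanent emigration is indistinguishable from
  death in this design.
* The occasion count and date anchoring of the historical study (80 full +
  6 reduced + 4 none occasions reported, vs ~79 biweekly intervals in the
  May 2009 – May 2012 span) cannot both hold exactly; both are
  configuration here, with 79 as the default.
* $\sigma_{\det}$ mixes slowly when detection is near 1; treat its
  posterior from short runs with caution.
* No model selection is provided (none was used in the protocol); masks
  are compared by refitting, and the manifest records which was fitted.
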