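---
title: "Methods: nutrient availability accounting, panel completion, and the intake bridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutrient availability accounting, panel completion, and the intake bridge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nutledger` estimates the national per-capita availability of nutrients
from commodity supply accounts, completes sparse country-year panels with
a spatiotemporal smoother, summarises the results across a development
gradient, and predicts survey intake from availability.  This vignette is
the package's own account of each model, its assumptions, the parameters
that matter, and the choices made where the design was genuinely open.

## 1. From commodity supply to nutrients

The accounting stage is deterministic arithmetic with three conventions
worth stating precisely.

**Refuse adjustment.** Supply quantities refer to gross commodity weight;
the inedible proportion (`refuse_fraction`, in [0, 1]) is removed before
any nutrient calculation.  Refuse factors are modelled as constant across
countries and years — the schema deliberately has no country or year
dimension for refuse, so differences in trimming practice are a known
source of error, not a fittable parameter.

**Atwater energy.** Metabolizable energy uses the general factors
4 kcal/g protein, 4 kcal/g carbohydrate, 9 kcal/g fat, 7 kcal/g alcohol.
Total energy in `aggregate_availability()` is re-derived from the
aggregated macronutrient masses, which makes the four-macronutrient energy
shares close to exactly 100% — a property the tests assert to 1e-9.

**Carbohydrate by difference.** Digestible carbohydrate is
`(E − 4P − 9F − 7A) / 4` per 100 g edible portion, computed from the
*stored* energy field of each composition record.  Real composition tables
occasionally carry an energy value below the protein+fat+alcohol energy;
the negative difference is clamped to zero with a warning naming the item,
because negative digestible carbohydrate has no physical meaning.  Fat
subtypes that fail to sum to total fat are reported as-is with a
validation warning; total fat governs energy.

Two unit conventions: raw tonnage converts to g/person/day with a
365.25-day year (averaging leap years), and every panel entry carries its
unit string — mixing units in endpoint arithmetic is an error, not a
silent coercion.

## 2. Completing the panel: the three-stage smoother

Observed availability covers only part of the location-year grid, with
some locations entirely unobserved.  `fill_time_series()` completes the
grid in three stages, per nutrient.

**Stage 1 — covariate prior.** A linear regression of the nutrient value
on log lag-distributed income (LDI) with super-region intercepts,
evaluated everywhere.  LDI is a weighted mean of the trailing 10 years of
income with linearly decaying weights `(10, 9, …, 1)/55`, renormalised
over the available history in early years; the weights are a declared
default, not an estimate.  Income enters in log space because incomes are
positive and right-skewed.  A location with no observations receives its
super-region's line; a super-region never observed receives the average
line.

**Stage 2 — spatiotemporal residual smoothing.** Every location-year
receives a weighted mean of all observed stage-1 residuals with weight
(time kernel) × (spatial tier):

* time: `(1 − (|Δt| / (1 + Δt_max))^λ)^3` with `lambda_time = 0.5`;
* space: `ζ` for the same location, `ζ(1−ζ)` for the same super-region,
  `(1−ζ)²` elsewhere, with `zeta_space = 0.9`.

Weights are strictly positive and normalised per target cell, so the
smoothed surface is defined whenever at least one residual exists.  The
implementation aggregates residual sums by (location, year),
(super-region, year) and year before applying the year-kernel matrix;
this is algebraically identical to the naive double loop, and the test
suite asserts equality with a brute-force oracle to 1e-12.

**Stage 3 — per-location Gaussian process.** With prior mean equal to the
stage-1+2 surface, an independent GP over years per location with
Matérn-3/2 covariance is conditioned on the observed values.  Defaults:
length scale 10 years; amplitude, when unset, the SD of the stage-1
residuals; nugget, when unset, the mean squared deviation of observed
residuals from the stage-2 surface.  These are standard settings for this
estimator family, declared rather than inferred; all are exposed in
`stgpr_params()`.  Space enters only through stages 1–2 — the
per-location factorisation is the usual one for this estimator, and a
full space-time kernel is out of scope.

**Uncertainty.** The 95% interval is the 2.5–97.5 percentile range of
seeded *predictive* draws (posterior draws of the latent series plus
observation noise).  Predictive rather than latent intervals are the
deliberate choice because the quantity being covered in validation is a
data-scale panel value, which includes observation-level noise.  Draws are
seeded per (nutrient, location) from the root seed, so reruns are
bit-identical.  Filled values and bounds are floored at zero:
availability cannot be negative.

Numerical safeguards: a nugget floor (default 1e-8) keeps the observation
covariance positive definite, and the same jitter stabilises the Cholesky
factor of the posterior covariance before drawing.

## 3. Development index and aggregation

The Socio-demographic Index is the geometric mean of three components
min-max rescaled over the *pooled* study period (all location-years
together): LDI and education ascending (higher is better), total
fertility descending (lower is better — stated explicitly because
"best" is directional).  A constant component is an error, not a silent
division by zero.  Quintile membership is computed at a reference year
(default: the final year) and held fixed across the series for trend
reporting; ties break lexicographically by location id, making the
assignment permutation-stable.  Level and global aggregates are
population-weighted means — the only aggregation consistent with
reporting per-person values at higher scopes.

Substitution correlations (`share_correlation_matrix()`) are computed
cross-sectionally at the final year by default; the year is configurable
because pooling years would mix the development trend into the
cross-country pattern.  P-values come from the t transform and are
reported unadjusted; no multiple-testing correction is applied at this
descriptive stage.

## 4. The intake bridge

National availability is split across age/sex groups by a multiplicative
pattern renormalised so the population-weighted group mean equals the
national value — the pattern redistributes, never creates mass.  The
intake regression is

```
intake_{c,a,s,t} = β · availability_{c,a,s,t} + age_a + sex_s + α_super-region
```

with the super-region term fitted as a random (exchangeable) intercept via
`lme4::lmer`; with fewer than three super-regions, or a singular mixed
fit, a fixed-effects `lm` fallback is used and the fitted object records
which path was taken.  Optimizer notes are captured into the fit's
`diagnostics` field rather than emitted as warnings.

Because the regression is on availability (not waste-adjusted
availability), retail and household waste is absorbed into the slope: a
generator slope `β_true` with waste factor `w` yields an effective
regression slope `β_true·(1 − w)`, and the slope-recovery experiment
scores coverage against that effective slope.

Survey validation uses energy *shares*, which are invariant to any
uniform multiplicative waste factor — the waste-invariant comparison
between availability and consumption.  Out-of-sample evaluation defaults
to holding out whole locations (predicting intake where no survey
exists); the regressor registry accepts anything with a fit/predict
contract, and the bundled tree ensembles (random forest, gradient
boosting) are smoke-tested only, with no seed-exact assertions, since
their hyperparameters are not part of the method.

## 5. The synthetic world

The generator produces internally consistent supply, composition,
covariate and intake tables with known ground truth.  What it emulates:

* **Compositions** in four item classes (carbohydrate staples, fat-rich,
  protein-rich, alcoholic) with energy set *forward* as the Atwater sum,
  so carbohydrate-by-difference is exactly invertible; refuse drawn in
  [0, 0.6]; MUFA/PUFA/SFA as a random partition of total fat; three
  micronutrients (iron mg, zinc mg, vitamin A µg RAE).
* **Development-linked diets**: each location has a development score
  rising over 1980–2013; item-mix weights are proportional to
  `exp(trend_class · development)` with negative trend for staples and
  positive for fat- and protein-rich items, so carbohydrate energy share
  falls and fat/protein shares rise with development — the coefficients
  are recorded as ground truth and the monotone pattern is asserted in
  the noise-free setting.  Calibrated defaults put energy around
  2100–3200 kcal/person/day and carbohydrate shares around 55–75%,
  falling with development.
* **Missingness**: a configurable fraction of location-years is masked,
  with part of the budget spent on entirely unobserved locations,
  emulating countries absent from the source accounts.
* **Survey intake** = slope × availability × age/sex multiplier ×
  (1 − waste) + additive age, sex and super-region effects + Gaussian
  noise, all parameters stored in the ground truth.

Defaults and why: `waste_factor = 0.3` (retail + household losses; share
validation is waste-invariant, so this only affects absolute-intake
checks); multiplicative log-normal supply noise with SD 0.05 (keeps
quantities positive; the magnitude of real measurement error is unknown,
so this is a free parameter, not an estimate); five age bins and two
sexes (group definitions are configuration, not substance); seven
super-regions assigned round-robin by development rank (gives the spatial
hierarchy some structure without a real geography).  All randomness flows
from one root seed through a documented stream-splitting rule
(`seed_child(root, stream)`), so every generator is individually and
jointly reproducible.

What the world does *not* emulate — and therefore what passing tests do
not show about real data: real commodity taxonomies and matching
ambiguity; country-varying refuse and composition; fortification;
processing additions such as sodium or trans fats; trade/stock/feed
accounting; non-random missingness correlated with the outcome; survey
measurement error structure beyond additive Gaussian noise.

## 6. Validation experiments and problem sizes

The simulation experiments the package ships (and that the acceptance
script reruns) use: 10 worlds of 150 locations × 34 years × 40 items at
20% missingness for held-out smoother recovery (scoring stage-3 RMSE
against the stage-1 prior and 95% interval coverage), and 50 replicates
of roughly 5100 matched rows for slope recovery.  These sizes were chosen
as the smallest at which the panel dimensions match the study design the
package targets while the experiments remain quick to rerun.

## 7. Known limitations

* Availability is an upper bound on consumption, not intake; nothing here
  models within-country distribution or access.
* The interval method is draw-based; alternative uncertainty estimators
  built on between-country variance decompositions would give different
  widths.
* The per-location GP factorisation cannot transfer year-specific shocks
  across countries beyond what stages 1–2 carry.
* Quintile membership fixed at a reference year makes level trends easy
  to read but ignores countries crossing quintile boundaries over time;
  set `reference_year` or recompute per year if that matters.
* The mixed-effects fallback logic (fixed effects when super-regions are
  few) changes the interpretation of the super-region term from
  population draw to estimated constants.
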