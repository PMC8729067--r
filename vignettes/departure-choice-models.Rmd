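---
title: "Modelling migration departure as a temporal discrete choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling migration departure as a temporal discrete choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migchoice)
library(dplyr)
```

## The model

`migchoice` treats the decision of a tracked bird to depart on a
migration-scale flight as a discrete choice among dated alternatives.
Each observed departure day is paired with the `J - 1 = 6` daily records
that directly precede it at the same location; the departure day is the
chosen alternative and is always last in the set. The latent utility of
alternative `j` in set `i` for bird `a` is

    U_aij = z'_aij b_a + e_aij,

with `z` the standardized covariate vector, `b_a` the bird's coefficient
vector, and `e` independent standard Gumbel errors. Conditional on
`b_a`, the probability that alternative `j` is chosen is the softmax
(conditional-logit) probability within the set, and the probabilities in
a set sum to one. Heterogeneity across birds is modelled by drawing
`b_a` from independent normals with mean `beta_k` and standard deviation
`s_k`; integrating the conditional-logit probability over this mixing
distribution gives the mixed-logit choice probability. Because roughly
half the birds contribute repeated choices, the data are a panel: one
draw of `b_a` applies to all of a bird's sets, so the simulated
likelihood multiplies the per-set probabilities within a bird before
averaging over draws.

Standard Gumbel errors (location 0, scale 1) are fixed by construction:
the softmax form of the choice probability presupposes unit-scale
errors, and the utility scale is absorbed by the coefficients.

## Covariates

Ten covariates describe the day's conditions at the bird's location.
Seven are daily: air temperature at 2 m (degC), snow depth (m),
barometric-pressure difference to the bird's previous record (Pa; 0 for
a first record, the neutral value under centering), precipitation
(kg/m2), cloud cover (%), and head- and tailwind speed (m/s). Wind
components follow the reanalysis "blowing toward" convention; the vector
heading is compared with the 162-degree mean relocation heading, and air
moving within 60 degrees to either side counts as tailwind (boundary
inclusive — a convention, tested explicitly), the remaining 240-degree
arc as headwind, with the full speed assigned to one side and zero to
the other.

Three covariates accumulate over a bird's stay at one location
(residency episodes are circles of 30 km radius around the episode's
anchoring position):

* **frost days** — consecutive days with mean temperature below 0 degC;
  reset by a day above 0 degC or by moving to a new episode. A day at
  exactly 0 degC neither increments nor resets: the two stated
  inequalities are strict, so the counter holds.
* **snow days** — consecutive days with snow depth of at least 2.54 cm
  (1 inch), computed like frost days.
* **ice cover** — a binary index of ice at least 1 cm thick on shallow
  water, from a freezing/thawing degree-day heuristic: growth of 1 cm
  per 3.3 freezing degree-days and melt of 1 cm per 1.3 thawing
  degree-days, with tracking triggered after two consecutive freezing
  days (accrual starts the day after the trigger completes, with zero
  initial thickness — the conservative reading of "two days of freezing
  temperatures for initial ice formation") and a full reset when the
  estimate drops back below 1 cm after having reached it.

When successive records are separated by multiple calendar days and both
bounding records lie in the same episode, the bird is assumed present at
the earlier record's location throughout, and the counters advance
through the gap using that location's weather.

All ten covariates are standardized by centering and dividing by twice
the standard deviation, so a coefficient is the change in utility per
2-SD increase and binary and continuous inputs are roughly comparable.
The binary ice indicator is rescaled like the rest by default (the
covariates are treated uniformly); `standardize_covariates()` has a
`center_only` argument for the alternative convention of centering
binary inputs without rescaling.

## Estimation

`fit_choice_model()` maximizes the panel simulated log-likelihood with
BFGS using analytic gradients, started from the conditional-logit
estimates with every SD initialized at 0.1. Simulation uses 500 draws by
default, either inverse-normal-transformed Halton sequences (default;
one prime base per random coefficient, first 50 points dropped, then
centred on exactly zero mean — rescaling their SD is deliberately
avoided, as it degrades agreement with the quadrature oracle) or
pseudo-random normals. Draws are common across an individual's sets, as
the panel likelihood requires, and the estimator gives each individual
its own consecutive block of the sequence so that per-individual
integration errors partially cancel across individuals. The likelihood
*evaluator* (`panel_simulated_loglik()`) instead shares one draw set
across all individuals, which makes its value exactly additive over
individuals (a duplicated panel doubles it exactly) — a pinned test
property.
With any SD fixed at zero the simulated likelihood collapses *exactly*
to the conditional-logit likelihood — an identity, not an approximation
— and with one random coefficient it is checked against 64-node
Gauss–Hermite quadrature.

SDs are estimated unconstrained (the likelihood is even in each `s_k`)
and reported as absolute values; standard errors come from the inverse
numerical Hessian at the optimum. Convergence is the optimizer's
report at relative tolerance 1e-9 within the iteration cap, and
non-convergence is flagged in the result rather than silently ignored.

The candidate set mirrors the departure analysis: a statistical null
model (equal utilities; log-likelihood `n log(1/J)` in closed form), ten
univariate models, a full model, daily-scale and multi-day-scale
bundles, and the winter-conditions model (temperature, snow depth,
frost days, snow days, ice cover). `K` counts the coefficient means and
the between-individual SDs; the null model is scored with `K = 2`, the
convention under which its BIC on a 73-set panel reproduces the
published model-selection table's 292.7 (with `n` = number of choice
sets — the only sample-size convention consistent with that value).
Models are ranked by BIC, with weights `exp(-dBIC/2)` normalized to sum
to one.

## Validation and prediction

Leave-one-out cross-validation refits the model without each set in turn
(warm-started from the full-data estimates, with the per-fold optimizer
capped at 100 BFGS iterations) and scores the held-out set as correct
when its chosen (last) alternative has strictly the highest utility at
the population-mean coefficients; individual deviations are unknowable
out of sample, so only the means are used. Ties score as incorrect, with
one exception: under the null model every alternative ties by
construction, so the prediction is a seeded uniform draw from the
model's own predictive distribution, giving the expected `1/J` = 14%.
A fold is dropped from the average only if its refit fails outright
(error or non-finite estimates); a refit stopped by the iteration cap is
scored at the capped estimates, because only the utility *ranking*
matters out of sample and separable folds — where the maximum-likelihood
estimates diverge — would otherwise be unscorable.

Response curves (`predict_response_curves()`) sweep one covariate over
its observed raw range while fixing the others at their mean, 25th or
75th percentile, mapped through the stored scaling constants; the
selection index `w(z) = exp(z'beta)` is proportional to selection
probability, and its within-set ratios equal the ratio of choice
probabilities. Uncertainty bands are +/- 1 SE from a parametric
bootstrap (1000 multivariate-normal resamples of the coefficient means,
seeded).

Two auxiliary tests are included. `fisher_pitman()` is the permutation
test of a mean difference under random relabeling, with `Z` the observed
statistic standardized by the permutation moments and an add-one
corrected two-sided p. `ks_gumbel_test()` compares choice residuals with
a moment-fitted Gumbel distribution; the discrete-choice literature
defines no canonical residual, so the package uses the explicit
convention *chosen indicator minus predicted probability*, which sums to
zero within each set.

## The synthetic-data generator

No tracking or reanalysis data ship with the package, so every
downstream stage is exercised on synthetic data with known structure.

`simulate_weather()` draws daily fields on a regular ~32 km lat/lon
grid: temperature is a linear seasonal trend (default -0.15 degC/day from
a 14 degC September baseline) plus a latitudinal gradient (-0.8 degC per
degree north) and per-cell AR(1) noise (coefficient 0.65, innovation SD
3.5 degC — enough day-to-day persistence to produce realistic multi-day
runs of frost and snow); snow accumulates from Poisson snowfall events
(0.05/day) while the cell is below freezing and melts at 2 cm/day above
freezing; wind components, precipitation, cloud and pressure are
independent daily draws. These defaults produce a plausible
autumn-to-early-winter transition over the upper-midcontinent domain.
What the generator does **not** emulate: spatial covariance beyond the
latitude gradient, weather fronts (so pressure carries no predictive
signal), terrain, or measurement error in locations — passing tests
show the pipeline arithmetic and the estimator are correct under the
stated model, not that real weather behaves this way.

`simulate_choice_sets()` inverts the choice model directly: individual
coefficients from the mixing distribution, covariates drawn
pre-standardized (mean 0, SD 0.5, i.e. already on the 2-SD scale so
generating values are directly comparable to fitted coefficients),
standard Gumbel noise, argmax choice. Its default generating values
(`winter_truth()`) are the winter-conditions estimates for
autumn-migrating mallards.

`simulate_tracks()` produces southward multi-bird tracks over a weather
grid, with two fixes per day. Observed departures are *conditioned on*
in the real analysis — there is no generative departure model to copy —
so the track generator offers a scheduled mode, in which each bird
performs a fixed number of departures each preceded by a fixed residence
(used to pin exact downstream counts: 43 birds and 73 scheduled
departures must yield exactly 73 sets and 511 alternatives), and a
stochastic stand-in mode in which each day's departure is a
Gumbel-argmax comparison of the current day's utility against recent
days'. The stochastic mechanism is a constructed device for end-to-end
exercises, not an estimated or published model.

## Numerical choices and problem sizes

* UTC calendar days define the daily-collapse boundary (the source
  criterion "per 24 h" does not state one; calendar days are
  reproducible and timezone-free).
* "Southward component" means strictly decreasing latitude; due
  east/west ties are excluded.
* Distances are haversine on a sphere of radius 6371 km; at these scales
  the difference from an ellipsoid is under 0.5%.
* Grid matching is nearest cell centre by great-circle distance, exact
  ties resolved to the lowest cell id.
* Residency episodes for covariate accumulation are labelled on
  start-of-day positions, so a departure day still carries the counters
  of the episode it leaves (its decision context), and the first record
  at the new site starts from zero.
* Choice-set histories are restricted to records after the bird's
  previous relocation by default (`within_previous_relocation = FALSE`
  relaxes this); small sub-30 km moves never break a set.
* Simulation studies in the tests use 200 Halton draws, 2000 sets / 500
  individuals for parameter recovery, and a 43-individual / 73-set panel
  for cross-validation — sizes chosen so the full suite runs on a
  laptop-class single core in minutes while leaving the recovery
  criteria (estimates within 3 SEs, signs correct) comfortably
  testable.

## Limitations

With study-sized panels (tens of individuals) and strong generating
effects, the mixed-logit likelihood can be nearly separable: estimates
drift to large magnitudes along a flat ridge and the SDs are weakly
identified. Rank-based quantities (percent correct) are stable under
this drift; reported coefficient magnitudes from such fits are not, and
the convergence flag should be checked. The binary ice covariate's
2-SD rescaling convention, the wind-component sign convention, and the
definition of residuals are explicit package conventions where the
source analyses leave details unstated; each has a documented toggle or
is isolated in one function.
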