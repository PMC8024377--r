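---
title: "Subtype and staging inference for MS MRI cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype and staging inference for MS MRI cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multiple sclerosis is heterogeneous in both *what* becomes abnormal on MRI
(cortical atrophy, diffuse normal-appearing white-matter damage, focal
lesions) and *when*. sustainMS models a patient population as a mixture of
latent **subtypes**, each defined by its own strict ordering of biomarker
abnormality **events**, and places every scan at a **stage** along its
subtype's ordering. Subtype and stage are then used as predictors of
disability progression, disease activity and treatment response.

## The z-score event-sequence model

### Normative referencing

Each of the 18 MRI features (ten regional volumes, seven regional NAWM
T1/T2 ratios, total T2 lesion volume) is regressed, in healthy controls
only, on total intracranial volume, sex, age and age squared. The point
fit is the posterior mean under a flat prior, which coincides with
ordinary least squares, so no sampler is needed; residual SDs use
denominator $n - 5$. A patient visit's z-score is

$$ z_i = \frac{r_i - \bar r^{\mathrm{ctl}}_i}{s^{\mathrm{ctl}}_i}, $$

the covariate-adjusted residual standardised by the control residual
distribution. Volumes and T1/T2 ratios are sign-flipped so that higher z
always means worse; lesion volume is not flipped. Features enter the
model only if the patient-versus-control |Cohen's D| on adjusted values
exceeds 0.5; when a region's volume and T1/T2 ratio would both pass,
grey-matter regions keep the volume and white-matter regions the ratio,
since the two are strongly correlated within a region.

### Events, stages and trajectories

An event is a feature crossing a z threshold in $\{1, 2, 3\}$ (mild,
moderate, severe). With 13 features the event grid has $E = 39$ events and
stages $k = 0..39$; stage $k$ means the first $k$ events of the subtype's
sequence $S$ have occurred (stage 0 = no abnormality; patient displays use
1..E). The expected value of feature $i$ at stage $k$ is piecewise-linear
through $(0, 0)$, the points $(p_r, z_r)$ for each of the feature's
threshold events at sequence position $p_r$, and $(E, z_{\max})$ — the
terminal point is dropped if the feature's last event already sits at
position $E$. $z_{\max} = 5$ by default: it must exceed the top threshold
of 3, and 5 control SDs is a reasonable ceiling for fully established
abnormality; it is a documented default, configurable per feature.

### Likelihood

A visit with z-scores $x$ at stage $k$ of subtype $c$ is modelled as
independent Gaussian noise around the expected trajectory with emission
SD $\sigma_i$, default 1 — the natural scale of control-referenced
z-scores, and a choice that keeps the noise model identifiable on real
data. $\sigma$ should cover every within-stage deviation the model does
not represent; on the packaged synthetic fixture, whose emission noise
(0.25 control SDs), dataset offsets and stage discretisation are known,
the fixture analyses set $\sigma = 0.5$. An over-tight $\sigma$ makes
cross-validation reward extra components that soak up unmodelled
dataset-level structure, while an over-wide one lets maximum likelihood
blend genuinely distinct subtypes. The stage is
marginalised under a uniform prior over $0..E$, and subtypes are mixed
with fractions $f_c$:

$$ \log L = \sum_v \log \sum_c f_c \frac{1}{E + 1} \sum_{k=0}^{E}
   \prod_i \mathcal{N}\!\big(x_{vi};\, g_i(k \mid S_c),\, \sigma_i\big). $$

Visits are staged independently; there is no within-subject longitudinal
coupling in the likelihood (matching the cross-sectional treatment of
each scan).

### Fitting

Sequences are estimated by coordinate ascent: each event is removed and
re-inserted at its best admissible position, with the within-feature
threshold order ($z{=}1$ before $z{=}2$ before $z{=}3$) enforced as a
hard constraint, until no move improves the likelihood; the best of
several random valid starts is kept (default 25; reduced profiles use
2–3 since the synthetic likelihood surface is benign). Mixtures are fit
hierarchically: the $C$-subtype model is initialised by splitting, in
turn, each cluster of the $(C-1)$-model in two — the bisection uses
2-means on the residuals from the parent trajectory at each visit's
modal stage, since raw z-scores mostly encode severity while the
residual pattern encodes the ordering deviation that distinguishes a
subtype — and the best-scoring split is then
refined by EM — soft responsibilities in the E-step, responsibility-
weighted sequence re-optimisation and fraction updates in the M-step —
until the log-likelihood gain falls below $10^{-4}$ (at most 100
iterations; the training likelihood is non-decreasing by construction,
and a test asserts this). Ties everywhere break to the lowest index.
Visits with responsibility below $10^{-10}$ of the maximum are dropped
from weighted M-steps; their contribution is below numerical resolution.

### Posterior uncertainty

Sequence uncertainty is quantified by Metropolis–Hastings: move one
uniformly chosen event of one uniformly chosen subtype to a uniformly
chosen admissible position (a symmetric proposal), accept with
probability $\min(1, e^{\Delta \log L})$, and refresh the mixture
fractions each iteration by responsibility re-normalisation (sampling
the fractions is a documented alternative; refreshing matches the
EM estimate and mixes faster at this scale). Default run length is
100,000 iterations with 10% burn-in and thinning 10; reduced runs of
10,000 are used at desk scale. On instances small enough to enumerate
($E \le 4$), sampled sequence frequencies are checked against the exact
posterior.

### Choosing the number of subtypes

Leave-one-dataset-out cross-validation: for each fold the model is fit
on all other datasets and the held-out dataset's total log-likelihood is
recorded for each candidate $C$; the selected $C$ maximises the held-out
log-likelihood **summed over folds** (the aggregation rule is our
choice; per-fold selection is the documented alternative), with ties to
the smaller $C$. The final model is refit on all data. Agreement across
folds is measured per subtype by the Bhattacharyya coefficient between
the events' positional posterior distributions, averaged over events
(the averaging unit is our choice), after aligning subtypes between each
fold pair by exhaustive bijection search ($C \le 4$ keeps this exact).

## Clinical endpoints

* **CDP (24-week confirmed disability progression)**: an EDSS increase
  over baseline of 1.5 (baseline 0), 1.0 (0.5–5.5) or 0.5 (>5.5) points,
  sustained: every visit up to and including the first visit at least
  168 days after onset must meet the threshold. Requiring *all* interim
  visits is the strict reading; a flag relaxes it to the confirming
  visit only. Baseline is the first visit; subjects whose worsening has
  no confirming visit are censored.
* **Survival comparisons**: k-group log-rank (two-sided) and Cox
  proportional hazards with Wald 95% CIs, via the survival package.
* **Annualised relapse rate**: total relapses over person-years per
  group; SEs from Poisson regression with a log person-years offset.
* **Concordance index**: over comparable pairs (smaller time is an
  event), the fraction where higher risk goes with shorter survival,
  ties counting 1/2; implemented natively and cross-checked against
  `survival::concordance` in the tests.
* **Treatment response**: per subtype, a linear mixed model
  `EDSS ~ arm * time` with random intercepts for subject nested in
  dataset (lme4); the response is the percentage difference of the
  treated versus placebo EDSS slope with a delta-method SE, flagged
  undefined when the placebo slope is indistinguishable from zero.
* **Stage dynamics**: per-subject least-squares slope of assigned stage
  on years, averaged per group; subtype stability is the fraction of
  multi-visit subjects whose modal subtype never changes.
* Stage tertiles use empirical type-1 quantile cuts with ties to the
  lower stratum (the exact tie rule is unstated in the endpoint
  definition; this is our documented choice).

## The synthetic cohort generator

Real multi-trial MS MRI datasets of this kind are not publicly
deposited, so the package ships a seeded generator whose statistical
structure matches everything the downstream modules assume, with a
packaged fixture (`default_fixture()`): 18 features of which 13 are
affected, three subtypes whose sequences echo cortex-led, NAWM-led and
lesion-led orderings, mixture fractions 0.43/0.32/0.25, truncated-
geometric baseline stage laws (means about 14.5/13.8/16.2), progression
rates 0.2/0.3/0.65 stages/year, 500 controls and 2000 patients across 3
pseudo-trials with 3 annual visits.

Choices a user should know about:

* **Control distributions are documented constants**, plausible adult
  values (e.g. deep grey matter ≈ 31–33 ml), not estimates from any real
  cohort; the fixture is built for testability, not epidemiological
  realism. Lesion-volume scales in particular are compressed relative to
  real MS cohorts because trajectories cap at $z_{\max} = 5$ control SDs.
* **Stage advancement** is discretised by rounding (stages are
  discrete), with a per-subject uniform phase dither so that rounding is
  unbiased: subjects cross stage boundaries at different times, and mean
  observed stage advances at the planted rate.
* **Patient residual noise** around the planted trajectory is 0.25
  control SDs on the z scale: the stage explains most pathology
  variance, and the control SD additionally contains between-subject
  anatomical variance that the trajectory model absorbs. Recovery
  invariants are additionally exercised at noise 0.5.
* **Clinical coupling**: baseline EDSS is linear in stage with a subtype
  offset, rounded to the half-point lattice; relapses are Poisson with
  subtype rates 0.25/0.25/0.55 per year; contrast-enhancing lesion
  counts are Poisson (0.9/0.5/2.3). Disability progression is a latent
  exponential event time with subtype hazards 0.20/0.20/0.26 per year
  (a 1.30 hazard ratio for the lesion-led analogue) that adds a
  sustained EDSS step of the required increase plus a 0.25 margin.
* **Treatment** multiplies the EDSS slope and the relapse rate by a
  subtype factor (0.34 for the lesion-led analogue, i.e. −66% EDSS
  worsening, 1.0 elsewhere) and *thins* the progression event with the
  same factor — thinning, rather than accelerating the clock, makes the
  treated step process exactly the placebo process scaled by the
  multiplier, so the mixed-model percentage response is unbiased at any
  follow-up length.
* **Dataset offsets** of ±0.1 control SDs emulate small between-trial
  shifts; the package deliberately performs no centre harmonisation
  beyond these offsets.
* The generator does **not** emulate images, scanner effects, missing
  data, relapse-proximal EDSS visits, or informative dropout; passing
  recovery tests on it demonstrates internal consistency of the
  estimator chain, not performance on real data.

## Problem sizes and numerical choices

The packaged analyses run at desk scale: fixture fits use 2–3 random
starts, EM capped at 8–12 iterations with 2 optimizer sweeps per M-step
(candidate splits are scored with a 2-iteration EM and only the winner
refined; stored levels get a short polish phase with a generous sweep
budget), 10,000 MCMC iterations, and cross-validation over 3
pseudo-trials with candidates 1–4 — sizes chosen so the whole suite
re-runs comfortably on one CPU. Endpoint-recovery analyses use a 5-visit (4-year) schedule from
the same configuration, since the 3-visit fixture tables are too short
to observe slow progression precisely. The full-scale configuration
(25 starts, 100 EM iterations, 100,000 MCMC iterations) is available
through `pipeline_config(profile = "full")`.

Degenerate inputs are rejected with named diagnostics: rank-deficient
covariate designs, zero control residual SDs, empty feature selections
(with all D values listed), off-lattice EDSS values, non-monotone visit
times, all-censored survival data, and fewer than three distinct stages
for tertiles.

## Known limitations

* Z-scoring assumes the control covariate model transfers to patients;
  no study/centre harmonisation is performed.
* The likelihood treats visits as independent; longitudinal coupling of
  stages within subject is not modelled (stability is assessed
  empirically instead).
* The stage prior is uniform; strongly non-uniform true stage
  distributions bias expected-stage estimates near the boundaries.
* Exhaustive subtype alignment and enumeration oracles are exact only
  for small C and E; beyond that the package relies on the sampled
  posterior.
* The mixed-model covariance structure for treatment response is random
  intercepts only; random slopes are a possible extension.
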