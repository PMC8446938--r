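---
title: "Estimating the hypertension care cascade from sparse surveys: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the hypertension care cascade from sparse surveys: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htncascade)
```

## The estimation problem

National blood-pressure surveys are sparse, uneven, and heterogeneous: some
countries run one every few years, many have none at all, and the surveys
that exist differ in coverage (national, sub-national, community), in
whether they sampled only urban or only rural populations, and in whether
they asked about a previous hypertension diagnosis. `htncascade` turns such
data into comparable country-year estimates of five quantities for adults
aged 30--79:

* **prevalence** of hypertension -- systolic blood pressure (SBP) $\ge$ 140
  mm Hg, diastolic (DBP) $\ge$ 90 mm Hg, or current use of medication for
  high blood pressure;
* among people with hypertension: **detection** (reporting a previous
  diagnosis), **treatment** (taking medication), **control** (on medication
  with SBP < 140 and DBP < 90), and the share with **severe unmanaged**
  hypertension (SBP $\ge$ 160 or DBP $\ge$ 100 while undiagnosed or
  untreated).

The analysis range is restricted to ages 30--79 in ten half-open five-year
bands $[30,35), \dots, [75,80)$; a 79-year-old belongs to $[75,80)$.
Each outcome and sex is modelled independently (ten separate fits).

## From microdata to study estimates

`classify_records()` applies the definitions above to individual records.
Records with missing medication status, non-positive pressures, or DBP
$\ge$ SBP are rejected with logged reasons, never imputed. When a study
provides repeated readings, the first is dropped whenever at least three
exist and the rest are averaged -- a common protocol convention; with only
two readings both are kept. `build_study_estimates()` then produces one
crude cell per sex $\times$ age band $\times$ outcome with survey-weighted
proportions

$$\hat p = \frac{\sum_i w_i y_i}{\sum_i w_i}, \qquad
  n_\mathrm{eff} = \frac{(\sum_i w_i)^2}{\sum_i w_i^2}, \qquad
  \mathrm{se} = \sqrt{\hat p (1-\hat p)/n_\mathrm{eff}},$$

the Kish effective-sample-size approximation to the design variance.
Stratum and PSU identifiers are retained in the microdata dialect so a full
Taylor linearization could be added, but the model consumes $(\hat p,
\mathrm{se})$ pairs and the Kish form is sufficient for that interface.
Cascade outcomes use the hypertensive subset as denominator; studies whose
diagnosis question was never asked emit no detection cells.

On the observation scale (`logit_transform()`), cells become
$y = \mathrm{logit}(p^*)$ with delta-method variance
$v = \mathrm{se}^2 / (p^*(1-p^*))^2$. Exact 0/1 proportions receive the
continuity correction $p^* = (x + 0.5)/(n_\mathrm{eff}+1)$ (chosen over
$(x+0.5)/(n+0.5)$ for symmetry between the 0 and 1 boundaries), with the
standard error recomputed from $p^*$; $v$ is floored at $10^{-6}$ so no
cell can claim unbounded precision. A probit link is available behind the
`link` option of `model_spec()`; logit is the default because the outcomes
are proportions and offsets then have an odds-ratio reading.

## The hierarchical model

For study cell $i$ in country $c$, year $t$ (centered at 2004.5, the
midpoint of the 1990--2019 window) and age-band midpoint $z$ (centered at
55), the observation model is

$$y_i \sim N(\eta_i,\; v_i + \tau^2),$$
$$\eta_i = a_c + b_c t + u_\mathrm{glob}(t) + u_{s(c)}(t) + u_{r(c)}(t) +
  u_c(t) + \gamma(z) + \theta\, z\, t + \beta^\top X_i + e_i .$$

* **Nested intercepts and slopes.** $a_c = a_\mathrm{glob} + \alpha_{s(c)}
  + \alpha_{r(c)} + \alpha_c$ with independent Gaussian deviations at
  super-region, region and country level (equivalently $a_c \sim
  N(a_{r(c)}, \sigma^2)$ nested upwards); likewise for $b_c$. Countries
  with data inform their region; countries without data inherit the
  region's distribution automatically, because their parameters remain in
  the model and are drawn from the conditional prior.
* **Non-linear trends.** Each unit at each of the four levels carries a
  second-order random-walk (RW2) deviation over years, the standard
  smoothness prior whose null space is the set of linear trends. Walks are
  parameterised in the spectral basis of the RW2 penalty (eigenvectors of
  $D^\top D$, $D$ the second-difference matrix) truncated to the 12
  smoothest modes: this removes the null space exactly -- so walks never
  compete with the intercept and slope, and the usual post-hoc sum-to-zero
  constraints hold by construction -- and the prior precision of the
  coefficients is simply $\mathrm{diag}(\lambda)/\sigma_\mathrm{rw}^2$.
  Modes beyond the twelfth are penalised by eigenvalues so large that their
  prior contribution is negligible at the smoothness scales used here.
* **Non-linear age pattern.** $\gamma(z)$ is a natural cubic spline with
  interior knots at midpoints 42.5, 55, 67.5 and boundary knots 32.5, 77.5
  (linear beyond the boundaries, via `splines::ns`).
* **Age-varying time trend.** A single linear interaction $\theta z t$ per
  fit; trends "varying by age" admits many forms, and this is the smallest
  one that lets older and younger ages trend differently. A spline-in-age
  slope would slot into the same design machinery if needed.
* **Coverage and scope offsets.** $X_i$ flags sub-national, community,
  urban-only and rural-only studies; $\beta$ is estimated jointly, so
  non-national studies are systematically adjusted toward the national
  reference. Predictions set $X = 0$.
* **Non-sampling variation.** Study random effects $e_i \sim N(0,
  \kappa^2_{\mathrm{cov}(i)})$ with coverage-specific variances whose prior
  scales are ordered national $\le$ sub-national $\le$ community, plus a
  shared additive $\tau^2$ for residual between-cell variation beyond
  binomial noise.
* **Priors.** $N(0, 10^2)$ on fixed effects; half-Cauchy priors on all
  standard deviations, with scales 1 (intercept SDs), 0.05 (slope and walk
  SDs, per-year units), (0.1, 0.15, 0.25) for $\kappa$ by coverage, and
  0.15 for $\tau$.

## Sampling

Given the 14 variance parameters, every location parameter is jointly
Gaussian. `run_mcmc()` exploits this: one sparse-Cholesky draw per
iteration samples all of them exactly (a "one-block" Gibbs update, so their
mixing is immediate), with the posterior precision refreshed by a single
precomputed sparse matrix-vector product. The variance parameters are
slice-sampled on the log scale, each followed by a non-centered
(ancillarity) rescaling move that keeps the standardised effects fixed
while moving the SD -- the interweaving removes the funnel geometry that
makes centered-only Gibbs mix badly when a variance is small, and with no
data it reduces to exact prior draws. Runs are bit-reproducible given the
seed; chains run sequentially from one RNG stream.

Defaults follow the publication-scale convention scaled to a desk: 4 chains
of 2000 burn-in and 5000 post-burn-in iterations thinned by 10 (500
retained per chain); `mcmc_config_publication()` gives the 50 000 post-burn-in /
thin 10 preset (5000 retained per chain). Split-$\hat R$ and effective
sample sizes are computed for all variance parameters and fixed effects,
and $\hat R > 1.1$ warns -- never silently.

`predict_surface()` composes $\eta$ on the full country $\times$ year
$\times$ age-band grid per draw with offsets and study effects zeroed, then
inverse-links to proportions.

## Post-processing

All summaries are computed draw-wise and only then reduced, so intervals
propagate uncertainty exactly:

* **Age standardisation.** Prevalence uses WHO world-standard weights
  $W_h$ (normalised internally, hence invariant to rescaling):
  $\sum_h W_h p_h$. Cascade rates are proportions *of the hypertensive
  population*, whose age pattern sits in the denominator:
  $\left(\sum_h W_h q_h r_h\right) / \left(\sum_h W_h q_h\right)$ with
  $q_h$ the same draw's prevalence. When prevalence is age-constant this
  collapses to plain standardisation.
* **Aggregation.** Regions, super-regions and the world are
  population-weighted averages of age-specific country draws
  ($p_{\mathrm{agg},h} = \sum_j N_{jh} p_{jh} / \sum_j N_{jh}$), aggregated
  *before* standardisation.
* **Counts.** $\sum_h N_h p_h$ per draw; cascade-stage counts multiply the
  stage share by prevalence.
* **Cascade stream.** Hypertensives partition into undiagnosed ($1-d$),
  diagnosed-untreated ($d-m$), treated-uncontrolled ($m-c$) and controlled
  ($c$). Because the three rates are fitted independently, draws can cross;
  the stream enforces the ordering per draw ($m \leftarrow \min(m,d)$,
  $c \leftarrow \min(c,m)$) so the four stages always sum to exactly 1,
  and reports the number of clipped values. Crossings are reported, not
  constrained away in the fits themselves -- whether a joint model should
  enforce cascade ordering across outcomes is left open deliberately.
* **Change.** For matched draws, `change_stats()` reports the mean
  1990--2019 difference in percentage points, its posterior SD, and the
  posterior probability that the estimated direction is the true direction
  (ties split evenly, so the two directional probabilities always sum
  to 1). Change is computed on age-standardised draws.
* All intervals are 2.5th--97.5th posterior percentiles.

## The synthetic world generator

`make_world()` exists so that every stage of the pipeline can be tested
against known truth without access to restricted survey microdata. It
draws true parameters from the model's own generative structure at fixed,
stated scales and composes prevalence and detection surfaces through the
*same* basis code used for fitting; treatment, control and severe-unmanaged
surfaces are built multiplicatively (treatment $=$ detection
$\times\,\mathrm{expit}(g_1)$, control $=$ treatment
$\times\,\mathrm{expit}(g_2)$, severe $=$ (1 $-$ treatment)
$\times\,\mathrm{expit}(g_3)$ with $g_k$ smooth in year and age), which
enforces the cascade ordering everywhere by construction.

The default world is deliberately about a tenth of the real problem's
size -- 24 countries in 6 regions and 3 super-regions over 1990--2019 --
so that full pipeline validation runs at desk scale; a
`full_scale_shape = TRUE` preset (200/21/9) exists for profiling. Survey
heterogeneity mirrors the real corpus: a fifth of countries has no study
at all, the rest 2--6 studies; half the studies are national, with
guaranteed national coverage in every region; 82% carry the diagnosis
question; cell sample sizes are log-uniform between 100 and 2000;
non-national studies receive the true coverage/scope offsets
($-0.10$ sub-national, $-0.30$ community, $+0.20$ urban-only, $-0.20$
rural-only on the logit scale), study effects with coverage-specific SDs,
and cell-level non-sampling noise before binomial sampling. Cascade cells
are drawn from the realised hypertensive count of their own cell.

`make_microdata()` generates individual records whose *classified* outcomes
reproduce the target cell probabilities mechanistically: blood pressure is
bivariate normal (SD 18/11 mm Hg, correlation 0.7) with the SBP mean solved
per cell so the 140/90 rule hits the target prevalence; medication is
assigned among hypertensives at the target treatment rate and shifts
pressure by $-12/-7$ mm Hg, so realised control rates *emerge* from the
distribution rather than being imposed; diagnosis is a superset of
treatment. These distributional parameters are fixtures chosen for realism,
not estimates.

What the generator does **not** emulate -- device and protocol measurement
error, multi-visit regression to the mean, non-response, within-country
spatial structure, real age pyramids -- bounds what passing tests show:
they validate the estimation machinery under the model's assumptions plus
controlled misspecification (the multiplicative cascade construction is
*not* the fitted form), not robustness to every artefact of real survey
data.

## Validation strategy and problem sizes

The test suite checks, among other things: exact hand-computed truth
tables for the outcome definitions; the Kish formulas against hand
evaluation; the log posterior against an independently coded term-by-term
oracle ($10^{-8}$ relative tolerance); exact prior recovery with zero
observations (using the pivotal fact that block draws standardised by
their sampled SD are standard normal under the prior); the sparse joint
Gaussian update against dense closed-form algebra; and, end to end on
default synthetic worlds, pooled 95% credible-interval coverage of true
age-standardised prevalence within [90%, 98%], recovery of the community
offset in at least 18 of 20 worlds, mean absolute error at or below 2.5
percentage points for countries with two or more national studies, and
strictly wider intervals for zero-data countries.

The end-to-end checks fit twenty default worlds with a single chain of 400
burn-in and 1200 kept iterations thinned by 3 (400 retained draws) -- the
package's desk-scale test schedule, chosen so the whole suite runs in
minutes while leaving the world generator's conditions untouched. At these
settings, measured pooled coverage is about 95% and country MAE just over
1 percentage point.

## Known limitations

* The model treats design-based variances $v_i$ as known; very small
  reported SEs are guarded only by the variance floor.
* Outcomes are fitted independently, so cascade ordering can cross at the
  draw level (handled and reported at the stream stage).
* No device/protocol calibration or multi-visit harmonisation is
  attempted; imputing DBP from SBP (or vice versa) is out of scope.
* The spectral truncation of the RW2 walks discards very high-frequency
  trend wiggles; at the prior scales used their contribution is
  negligible, but an analysis expecting sharp year-on-year breaks should
  raise `rw_dim`.
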