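---
title: "Dyadic inter-subject correlation and information sharing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyadic inter-subject correlation and information sharing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the unit of analysis

`iscshare` implements a dyadic analysis of neural similarity and information
sharing. Members of a community watch the same set of naturalistic videos
while a regional brain time series is recorded, and afterwards rate how
likely they would be to share each video (1--5). The scientific question is
whether pairs of people whose brains respond more similarly to a video are
pairs in which both members want to share it.

The unit of observation is the *dyad x video*: for every unordered pair of
subjects and every video both watched, the inter-subject correlation (ISC)
in a brain region is the Pearson correlation of the two subjects' regional
time series. With $n$ subjects there are $\binom{n}{2}$ dyads (2145 for a
66-subject cohort), and a complete design contributes
$\binom{n}{2} \times \text{videos}$ observations per region. Regions are an
opaque label registry — by default 200 cortical parcels plus 14 subcortical
regions, 214 labels in all; parcel geometry is out of scope.

## From time series to the modeled outcome

For each (dyad, video, region) the pipeline computes the sample Pearson
correlation $r$, maps it through the Fisher transform $z = \mathrm{atanh}(r)$
to a variance-stabilized scale, and finally standardizes $z$ *within each
region* (sample standard deviation, denominator $n-1$), pooling all dyads
and videos of that region. The within-region z-scoring makes effects
comparable across regions with different baseline synchrony; the
`z_norm` column is the modeled outcome.

Two deliberate guardrails:

* A correlation of exactly $\pm 1$ (possible only on noise-free synthetic
  input) is refused by `fisher_z()` rather than silently mapped to
  $\pm\infty$; `compute_dyadic_isc(clamp = TRUE)` clamps to
  $1 - 10^{-7}$ explicitly.
* Zero-variance series, regions with fewer than two records, and regions
  with zero spread raise errors that name the offender — degenerate input is
  never silently normalized.

## Dyad-level predictors

Participant ratings are binarized: 1--2 count as *low* sharing likelihood,
3--5 as *high* (the threshold is a parameter of `binarize_rating()` and
`build_dyad_design()`, defaulting to this rule). Each dyad x video then
falls into one of three categories: HH (both high), LL (both low), or LH
(exactly one high; unordered, so low/high and high/low are the same level).
The headline planned contrast is HH $-$ LL: more synchronized pairs should
more often be pairs that both want to share.

Demographic-similarity covariates guard against the confound that similar
people are both more synchronized and more likely to agree about sharing:

* `age_similarity` $= 1 - |\Delta\text{age}| / \max |\Delta\text{age}|$,
  where the maximum is over the retained analysis dyads. This makes the
  covariate *cohort-relative*: adding a subject who widens the age range
  rescales every value. When all ages are identical the guard returns 1 for
  every dyad with a warning instead of dividing by zero.
* `gender_match` and `country_match` are exact string-equality indicators.
  No fuzzy normalization is applied; labels differing only by case trigger
  a warning because that usually means unnormalized input.

## The doubled-data crossed mixed model

A dyadic outcome is symmetric — observation $(i, j)$ is observation
$(j, i)$ — yet each member should carry their own random intercept. The
package follows the doubling device: every (dyad, video) row enters the fit
twice, once per role ordering, and the model

$$ z^{norm}_{(i,j),v} = \beta_0 + \beta_{HH}\,[\text{HH}] +
\beta_{LH}\,[\text{LH}] + \beta_a\,\text{age} + \beta_g\,\text{gender} +
\beta_c\,\text{country} + u_i + w_j + s_v + (us)_{iv} + (ws)_{jv} +
\varepsilon $$

carries five crossed random-intercept groupings: role-1 subject, role-2
subject, video, and the two role x video interactions. Fitting is by REML
through `lme4::lmer`.

Doubling makes the rows redundant, and inference must undo that redundancy
twice over. First, the information matrix of the doubled fit counts every
observation twice, so the naive fixed-effect covariance is half its true
size; the package multiplies the sampling covariance by 2 (SEs by
$\sqrt{2}$). Second, all t-based inference uses

$$ \mathrm{df} = N - k, $$

where $N$ is the number of *unique* (undoubled) observations and $k$ the
number of fixed-effect coefficients. Null-panel simulations in the test
suite confirm that the corrected t-statistics are calibrated (uniform
p-values; family-wise error at its nominal level after Holm correction) —
and that omitting the covariance factor inflates the nominal 5% level to
roughly 10%. Two conventions are worth making
explicit because they are genuinely underdetermined:

* $k$ **includes the intercept** (the design-matrix column count; $k = 6$
  for the full model). This is the conservative reading of "number of fixed
  effects"; `model_spec(include_intercept_in_k = FALSE)` flips it, and the
  fitted object records both $N$ and $k$.
* **Standardization** z-scores the outcome and *every* predictor column,
  including the 0/1 category dummies, before fitting — the most literal
  reading of converting all variables to z-scores. Contrasts are
  re-expressed per raw predictor unit afterwards, so they are reported in
  outcome-SD units; `model_spec(standardize = FALSE)` gives the raw-scale
  fit.

The reference level is LL, making the HH dummy the headline coefficient;
planned contrasts are reference-free, so this choice does not affect
results. Contrasts are differences of estimated marginal category means
with covariates held at their means; for this additive model that is a
linear combination of dummy coefficients, with the standard error taken
from the fixed-effect covariance and two-tailed p-values on the corrected
df. (A test cross-checks this arithmetic against `emmeans` on the same
fitted model.)

Region-wise analysis loops the fit over regions and corrects each contrast
family across regions with Holm--Bonferroni (step-down FWER control;
Benjamini--Hochberg step-up FDR is available, as is no correction). Both
adjustments are thin validated wrappers over `stats::p.adjust`, and both
are tested against longhand step-down/step-up oracles. A region whose fit
does not converge is recorded (`converged = FALSE`) and excluded from the
corrected family — never imputed.

Predictors that are constant in a given region's data (for example a
country-match indicator in a single-country cohort) are dropped with a
warning and excluded from $k$; a constant outcome is an error, never a
silent fit.

## Permutation test

`permutation_null()` provides a nonparametric check. The exchangeable units
are *participants within a video*: binarized sharing labels are permuted
across the subjects who rated each video, dyad categories are rebuilt, and
the contrast statistic is recomputed. Permuting dyadic rows instead would
break the dependence structure (each subject sits in many dyads), which is
exactly why the labels are exchanged at the participant level.

The default statistic is the difference of mean `z_norm` between the two
contrasted categories. Any statistic yields a valid permutation test; the
mean difference is chosen because it is fast enough to calibrate the test
itself by simulation (hundreds of panels times hundreds of permutations).
A model-based alternative (`statistic = "lmm"`) refits the full crossed
model per permutation and uses the contrast t-statistic; it is orders of
magnitude slower and is exercised only lightly in the tests. P-values use
the add-one estimator
$(1 + \#\{|T_b| \ge |T_{obs}|\}) / (1 + B)$, which can never be zero.

## Behavioral models

**Similarity ratings study.** `fit_study2()` models sharing likelihood from
perceived similarity with crossed random intercepts for participant and
item: `sharing ~ similarity + (1 | participant) + (1 | article)`, REML via
`lme4`, optionally adding interest and valence ratings as fixed covariates.
With `scale = "all"` every variable is z-scored and the slope is a
standardized regression coefficient. Slope inference uses residual-style
df $= n_{obs} - k$; published analyses of this design report df values that
do not follow from any stated rule (492 and 495 from 500 observations), so
the package documents its own rule in the fitted object rather than
claiming to reproduce an unstated one. Rank-deficient fixed-effect designs
(e.g. a covariate equal to the predictor) are refused.

**Social-context experiment.** `fit_study3()` is an ordinary linear model
of sharing likelihood on a four-level condition factor (similar /
dissimilar / unclear / mixed), optionally controlling for baseline sharing
and interest. `study3_contrasts()` evaluates pairwise condition contrasts
(the full family of six, or any subset) with BH-FDR correction across
exactly the requested family. Without covariates the contrast estimates
equal raw group-mean differences (an OLS identity the tests assert to
$10^{-10}$). Sharing ratings are modeled as continuous responses, as is
standard for these linear analyses, not as ordinal outcomes.

## The synthetic-data generator

Every stage is testable without data download because the generator
produces panels with known ground truth.

For video $v$ and region $g$ a shared latent signal $s_{vg}$ is white noise
passed through a 5-timepoint moving average (mimicking the autocorrelation
of slow hemodynamic responses; the window is configurable and does not
affect population correlations) and standardized to unit variance. Subject
$i$'s series is

$$ y_{ivg} = \lambda_{ivg}\, s_{vg} + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2), $$

with $\lambda = $ `coupling_high` when the subject's latent engagement with
the video crosses the high-sharing threshold *and* the region is a signal
region, else `coupling_low`. Engagement is uniform on $[0,1]$ per subject x
video and cut at fixed quantiles (0.35, 0.65, 0.85, 0.95) into the 1--5
rating; the cut-points give a low-skewed rating distribution (mean
$\approx 2.2$, about 35% high raters) of the kind community samples
produce, and the monotone engagement-to-(rating, coupling) link is the
minimal structure that makes the HH $>$ LL contrast true by construction in
signal regions and absent elsewhere. The population ISC between subjects
with couplings $\lambda_1, \lambda_2$ is

$$ \rho = \frac{\lambda_1 \lambda_2}
{\sqrt{(\lambda_1^2 + \sigma^2)(\lambda_2^2 + \sigma^2)}}, $$

which the tests verify empirically at $10^4$ timepoints (tolerance
$\pm 0.02$) and by Monte-Carlo averaging over replicate draws.

All randomness flows from one integer seed through deterministic
sub-streams keyed by subject, video and region *labels*, so a panel is
bit-reproducible and the shared dimensions do not change when, say, regions
are added. The `"test"` preset (20 subjects, 4 videos, 10 regions of which
3 carry signal, 150 timepoints) is the geometry used throughout the
simulation studies; the `"paper"` preset mirrors the emulated study's
published 66 / 14 / 214 design with 0.8 s sampling of 91--734 s videos.
Partial data (a subject missing a video) are supported via `drop_cells`.

The behavioral generators mirror the two study designs: a crossed
participant x item table with participant and item intercepts and a slope
on standardized similarity (so `slope_similarity` is the true effect of a
1-SD similarity increase in outcome units), and a balanced four-condition
experiment with condition-specific means plus covariates that track the
residual sharing propensity.

`simulate_dyadic_outcome()` attaches an outcome with known fixed effects
directly to a dyad design. Its `exact_zero_re = TRUE` option projects the
residuals orthogonal to the span of every random-effect grouping, so the
generated data carry *exactly* zero in-sample random-effect variance. This
is the right way to instantiate the degenerate limit in which the mixed
model must collapse to OLS: with merely independent residuals the
in-sample group means still fluctuate, REML estimates small positive
variance components about half the time (the familiar half-chi-square
boundary mixture), and the GLS fixed effects drift away from OLS at any
finite sample size. Under the projected construction the REML fit provably
lands on the all-zero boundary and the package asserts agreement with OLS
to $10^{-4}$ (observed: $\sim 10^{-13}$).

### What the generator does and does not emulate

It reproduces the *statistical* structure the models assume: a shared
stimulus-locked signal with engagement-dependent coupling, iid measurement
noise, crossed participant/video dependence, balanced condition allocation.
It does not emulate hemodynamic convolution, head motion, scanner noise
spectra, spatial correlation between neighboring regions, non-stationary
engagement within a video, or stimulus-order effects. Passing tests
therefore demonstrate that the estimators recover the truth *under the
model's assumptions* and are calibrated under the null — they do not
validate the assumptions themselves against real recordings.

## Numerical choices and problem sizes

* Canonical ordering everywhere: dyads store members lexicographically,
  doubled tables sort by (role1, role2, video), regions iterate in sorted
  label order. Outputs are keyed, never order-dependent, and reruns of the
  pipeline are byte-identical.
* `lme4` fits use `calc.derivs = FALSE` (the derivative check is the
  dominant cost at these sizes and is not used for inference); singular
  fits are tolerated (boundary variance components are legitimate here),
  while optimizer warnings mark a fit non-converged and suppress its
  inference.
* Simulation-study sizes are chosen to make Monte-Carlo error a small
  fraction of the tested tolerance: 200 null panels for family-wise error
  calibration, 200 permutation p-values (199 permutations each) for
  uniformity, 100 replicates for signal-region recovery, 200 replicates for
  the behavioral slope (within $\pm 0.05$ of the true 0.4) and condition
  gap (within $\pm 0.1$ of the true 0.6).

## Known limitations

* No Satterthwaite or Kenward--Roger df, no random slopes, no ordinal
  model for the 1--5 ratings, no non-binarized sharing variant, and no
  matched-subsample analysis; the binarization threshold and $k$ convention
  are exposed as parameters precisely so such variants can be bolted on.
* The $N - k$ correction fixes the doubling redundancy but, like any
  residual-style rule for mixed models, it is an approximation; its
  calibration is demonstrated by simulation, not by theory.
* The cohort-relative age-similarity covariate changes value when the
  cohort changes; comparisons across cohorts should not reuse it.
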