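---
title: "Reliable change analysis for two-session neuropsychological cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliable change analysis for two-session neuropsychological cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogchange)
```

## The problem

Patients treated for brain tumours (the motivating setting is IDH-mutated
glioma, assessed before surgery and one year after) are followed with a
multi-test neuropsychological battery. Two questions recur:

1. **Impairment**: how many patients score below the normal range, and is
   that more than a battery of this length would produce by chance?
2. **Change**: which individual patients *declined* between sessions, given
   that healthy people *improve* on retest (practice effects) and that
   extreme baseline scores drift back toward the mean (regression to the
   mean)?

Group-level means answer neither question: a cohort can look stable on
average while a quarter of its members decline and a few improve.
`cogchange` implements the within-individual methodology — normative
z-scoring, multivariate impairment base rates with a Monte Carlo chance
test, regression-based reliable change indices (RCIs) calibrated on a
paired control cohort, logistic models of who declines, and lesion-overlap
maps — together with a synthetic cohort generator, because real patient
cohorts of this kind cannot usually be shared.

## Normative scoring and impairment

Raw scores are standardised against published norms, `z = (raw - mean)/SD`,
and *oriented* so that higher z is always better: timed tests (Trail
Making, colour-word interference) are declared `lower_better` in the
battery config and flipped once at scoring time. Every downstream stage can
then use a single sign convention.

Impairment is `z < -1.645` (the 5th percentile), strict at the boundary; a
secondary cutoff of `-1.5` is also first-class because both conventions are
common in this literature. Base rates are reported as the proportion of
subjects with at least *k* impaired scores, counted over each subject's
*available* tests — multi-site batteries have per-test n well below the
cohort size, and imputing zeros would manufacture impairments.

A long battery makes some impairment likely by chance: with 17 independent
tests, `1 - 0.95^17 = 58%` of healthy subjects have at least one score
below the 5th percentile. Inter-test correlation pulls that number down, so
the chance test matters only if the null is *correlated*:
`simulate_chance_rates()` draws replicate cohorts from a multivariate
normal with a correlation matrix estimated from the observed baseline
z-scores (`estimate_null_correlation()`, pairwise-complete with eigenvalue
clipping to restore positive semidefiniteness), and
`chance_p_value()` reports the one-sided add-one Monte Carlo p-value
`(1 + #exceedances)/(n_reps + 1)`, which can never be exactly zero. The
independence case is kept as an analytic cross-check (the closed form
above), and the near-perfect-dependence limit collapses the battery to one
effective test (chance rate ~5%).

## The regression-based reliable change index

For each test, follow-up z is regressed on baseline z over controls
assessed at the same interval:

    y2_hat = b0 + b1 * x1,    RCI = (y2 - y2_hat) / SEE

where `SEE` is the residual SD of the control fit (n-2 denominator). The
intercept absorbs the practice effect; a slope below 1 encodes regression
to the mean; the denominator is the controls' natural retest variability.
A patient is *declined* if `RCI < -1.645`, *improved* if `RCI > +1.645`
(strict, two-tailed alpha = 0.10), mirroring the impairment percentile.

Two denominator variants are implemented because the Maassen-family
literature uses both and published reports rarely say which:

* `"see"` (default): the residual SD alone;
* `"prediction"`: `SEE * sqrt(1 + 1/n + (x1 - x_bar)^2 / SS_x)`, the full
  out-of-sample prediction standard error, which additionally charges for
  estimation error in the control fit and widens away from the control
  baseline mean.

They agree as the control sample grows; with n = 88 controls the
difference is under 1% near the centre of the baseline distribution. The
default is the simpler variant; the choice is a config switch rather than
a silent assumption.

Key behavioural properties (all enforced by tests):

* **Null calibration.** Fitting on simulated controls and applying to
  fresh no-change subjects flags ~5% per tail, ~10% total.
* **Practice-effect discrimination.** A patient whose scores are literally
  unchanged while controls gain `g` on retest gets `RCI = -g/SEE < 0`,
  while the naive change score `delta_z = y2 - x1` is 0. This is exactly
  the case where RCIs and simple difference criteria disagree, and why
  both are reported.
* **Regression to the mean.** With `b1 < 1`, two subjects with the same
  raw change but baselines symmetric about the control mean receive
  different RCIs — the low-baseline subject is expected to rebound, so an
  unchanged score is worse news for them.

The simple criterion `delta_z <= -1` ("lost at least one z") is kept for
comparability with older studies; note its boundary is *inclusive* while
the RCI boundary is *exclusive* — both follow the conventions of the
reporting style this package emulates.

Tests can be declared RCI-ineligible in the battery (the default battery
flags the Rey figure copy, whose control retest distribution is too skewed
and ceilinged for a least-squares calibration); they still get delta-z.

Domain-level change is the unweighted mean of a subject's available
per-test RCIs within each domain, classified with the same ±1.645 rule.
The minimum number of contributing tests defaults to 1 (the convention in
the emulated reports states no completeness rule); it is a parameter
because sites with heavy per-test missingness may want 2+.

## Predicting who declines

Tests whose decline proportion strictly exceeds 20% feed univariable and
multivariable logistic models on seven pre-specified clinical predictors
(age, Karnofsky performance status, tumour volume, 1p19q codeletion,
grade, HADS > 8, chemoradiotherapy). Restricting the predictor set is the
multiplicity control; no p-value correction is applied across models.

Reporting follows clinical convention: odds ratios with 95% Wald intervals
`exp(coef ± 1.96 SE)` and Wald p-values. Complete or quasi-complete
separation (e.g. *every* declined patient received chemoradiotherapy — a
zero cell) makes the ML estimate diverge; `detect_separation()` catches
zero cells for binary predictors, perfect thresholding for continuous
ones, and coefficient divergence as a fallback, and the affected estimate
is *withheld and reported as N.A.* rather than replaced. A penalised
(Firth-type) fallback was deliberately not made the default, to keep the
reported surface faithful to the withhold-and-flag convention; none of the
installed model stacks provides one, so offering it would have meant
authoring a second estimator that the reported analyses never use.

Diagnostics mirror the standard screen: pairwise predictor correlations
flagged above 0.7; variance inflation factors from auxiliary linear
regressions (`1/(1 - R^2)`, flagged at 5, tolerance = 1/VIF); and
Box-Tidwell linearity-of-the-logit checks that augment the model with
`x * ln(x)` terms for each strictly positive continuous predictor.
Zero-valued volumes are shifted by +0.5 ml with a warning (logs are
undefined at zero; the shift size is the smallest half-unit of the
measurement scale). Under a truly linear logit the Box-Tidwell Wald test
rejects at its nominal 5% — verified by simulation in the test suite.

Fisher's exact test (two-sided, point-probability method) compares
proportions, including the pre/post impaired proportions per test. The
pre/post comparison treats the two sessions as independent samples — that
is the convention of the emulated reports, kept deliberately;
a paired McNemar test would be the statistically stricter choice and can
be run by hand from the same counts.

## Lesion overlap maps

Binary tumour masks, already registered to a common space (registration is
out of scope — consume the output of your registration pipeline), are
summed voxelwise per group: `counts[v] = number of masks covering v`.
Total counts equal the sum of individual mask volumes (a conservation law
used as a test oracle). Each group's map is normalised by *its own*
maximum, so a 2-subject declined group and a 20-subject stable group are
each displayed on a [0, 1] scale. Hemisphere mirroring is a pure
left-right reflection about the grid's midsagittal plane (an involution
that conserves counts); if the volume's affine puts the midline elsewhere,
the call errors and asks for an explicit midline rather than silently
reflecting about the wrong plane. No smoothing or thresholding is applied
before display.

## The synthetic cohort generator

`sim_config()` fixes the study conditions; the generators are pure
functions of (config, seed).

* **Controls** (default n = 88): per test, `(X1, Y2)` bivariate normal on
  the z scale with retest correlation `r12 = 0.7`, retest mean
  `X1 mean + 0.3` (the practice gain, z units), unit variances;
  cross-test correlation is exchangeable `rho = 0.3` by default (a full
  matrix is accepted). Scores are mapped to raw units via the battery
  norms and polarity. Defaults: 0.7 is a typical test-retest reliability
  for clinical cognitive measures; 0.3 z matches the order of retest gains
  observed in healthy adults (e.g. about a third of an SD on naming).
* **Patients** (default n = 127): controls' process plus per-domain
  baseline z offsets (defaults echo the observed baseline profile of a
  treated lower-grade-glioma cohort: language and executive most
  affected); a per-subject decline indicator drawn from a logistic model
  on the seven covariates (defaults: OR 1.06 per year of age, OR 5 for
  chemoradiotherapy, intercept set for ~20% prevalence — inside the
  11.9–32.4% per-test range such cohorts show); declined subjects' retest
  mean drops by 1.5 z before noise. True labels are returned for
  sensitivity/specificity recovery tests. Per-test missingness defaults
  reproduce the per-test n (85–126 of 127) of a two-site battery, applied
  per subject-test at both sessions (site differences, not dropout).
* **Covariates** echo typical marginals (age ~ N(42, 12) truncated to
  19–76, KPS ≥ 80 in ~94%, chemoradiotherapy 79%, codeletion 41%, high
  grade 31%, HADS > 8 25%).
* **Masks** are jittered ellipsoids around per-group hotspot centres on a
  common grid; centre and radius jitter both scale with `spread`, so
  `spread = 0` yields identical masks.

What the generator does *not* emulate: item-level scores and their floors/
ceilings, non-normal raw-score distributions, informative missingness,
more than two sessions, and any spatial relationship between tumour
location and which tests decline (masks and decline labels are linked only
through group membership). Passing tests therefore demonstrate that the
*pipeline* is correct under its stated model, not that the model captures
every feature of real data.

## Numerical choices and degenerate inputs

* Strict inequalities at the −1.645/+1.645 boundaries; inclusive at the
  delta-z −1 boundary (both verbatim conventions of the emulated style).
* Control regressions require ≥ 3 complete pairs and non-constant
  baselines; `SEE = 0` (a perfectly collinear control sample) is an error
  instructing a larger control sample, not an infinite RCI.
* Pairwise-complete correlation matrices are repaired by eigenvalue
  clipping and rescaling to unit diagonal; the repair is logged.
* Monte Carlo p-values use the add-one correction; with 999 replicates the
  smallest reportable p is 0.001.
* The Kolmogorov-Smirnov normality gate (alpha = 0.05) uses estimated
  parameters, which is anticonservative; it is retained because it is the
  gate named by the reporting convention, and the choice is documented
  rather than silently replaced by Lilliefors/Shapiro.
* All-zero difference vectors short-circuit the paired test to p = 1 with
  a note.
* Problem sizes in the test suite (10,000 null subjects, 100–999 Monte
  Carlo cohorts, 500 Box-Tidwell replicates at n = 2,000) were chosen so
  each stochastic check resolves its stated 2-SE tolerance.

## Known limitations

* Norms are (mean, SD) lookups, optionally stratified by covariate
  predicates; full demographic regression-based norming (T-scores) is out
  of scope.
* Only the two Maassen-family denominators are offered — no
  Jacobson-Truax or unequal-variance variants.
* No imputation anywhere: subjects contribute where they have data.
* Overlay maps are descriptive; no voxelwise statistics are computed.
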