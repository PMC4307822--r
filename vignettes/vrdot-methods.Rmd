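---
title: "Scoring and screening with the virtual-reality day-out task: methods"
author: "vrdot package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and screening with the virtual-reality day-out task: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrdot)
```

## The problem

Performance-based assessment of activities of daily living (ADL) records
*how* an older adult carries out a complex everyday routine — here, a
simulated fire-evacuation drill — rather than asking an informant how well
they usually manage. The raw material is a session event log: timestamped
performances of protocol activities, with attempt counts and completion
flags. `vrdot` turns such logs into a functional index, calibrates the
index against standard cognitive and functional scales, estimates annual
rates of change over up to three yearly visits, and evaluates the index as
a screening and prognosis instrument for amnestic mild cognitive
impairment (aMCI) and mild Alzheimer-type dementia (AD).

## The functional index

Two session-level quantities are extracted against a protocol (the
canonical, ordered activity list of a scenario):

* the **efficacy ratio** `REff`: the fraction of total session time spent
  performing protocol activities. Overlapping intervals of the same
  activity are unioned before summing, and the ratio is clamped to
  `[0, 1]`.
* four **error counts**: omissions `O` (protocol activities never
  completed), repetitions `R` (completed performances beyond the first),
  order errors `W`, and extra attempts `A` (attempts beyond the first on
  each first completion; retries inside repeated performances are already
  counted by `R`).

Order errors are the *order-restoration deficit*: map the first-completion
sequence to protocol positions and subtract the length of its longest
increasing subsequence from the number of completed activities. This is
the minimum number of activities one must ignore for the remainder to be
in canonical order; it is zero exactly when first completions occur in
protocol order, and it is invariant to how the remaining events are
interleaved. We chose it over inversion counting because a single
activity performed far out of place counts once, not once per crossed
pair.

The **functional impairment index** combines the two through a rational
penalty:

$$FI = \frac{100 \cdot R_{eff}}{1 + k_1 O + k_2 R + k_3 W + k_4 A},
\qquad k_i \ge 0.$$

This form was chosen because it (a) reduces to `100 * REff` at zero
errors, (b) is bounded in `[0, 100]`, so published-style cutoffs in the
tens are representable, and (c) is strictly monotone — non-increasing in
every error count and increasing in `REff` — which the calibration
procedure requires. It is one exported function (`functional_index()`)
and can be swapped without touching the rest of the pipeline. Throughout
the package, **higher FI means better everyday function**; the scales it
is validated against run in both directions (MMSE higher = better,
Bristol/Blessed ADL higher = more impaired), and every correlation or ROC
direction is stated explicitly rather than inferred.

## Calibrating the penalty weights

The weights are fitted on a pilot sample in two steps: every candidate
`(k1, k2, k3, k4)` on a grid (default `0–1` in steps of `0.05`) is scored;
candidates whose baseline FI is strongly *positively* Spearman-correlated
with MMSE and strongly *negatively* correlated with an IADL scale
(Bristol by default, Blessed selectable) are accepted; the final weight
set is the componentwise mean of the accepted candidates. "Strong" has no
universal value, so both thresholds are configuration; the package
default is `|rho| >= 0.6`, the conventional reading of a strong Spearman
correlation. A grid, rather than a continuous optimiser, keeps the
procedure exactly reproducible and mirrors the discrete candidate-set
description of the original fitting.

Two geometric facts shape how this procedure should be used, and how we
test it:

* Because FI is monotone in every error count for *any* non-negative
  weight set, any pilot in which all four error processes co-vary with
  impairment yields strong correlations over most of the grid. With
  permissive thresholds the accepted region is then most of the cube and
  its mean sits near the cube centre regardless of the weights that
  actually generated the data. Threshold choice trades robustness against
  identifiability.
* The weights are identifiable beyond a common rescaling only if the
  pilot contains independent variation: error types must vary separately
  across subjects, and `REff` must vary independently of the counts
  (the overall scale of `k` matters only through the balance between the
  numerator and the penalty).

The parameter-recovery study in the test suite is built accordingly:
`make_pilot()` draws the four error counts independently (subject-level
Poisson rates uniform over a wide range, unlinked across types), spreads
`REff` widely, and ties MMSE and Bristol monotonically to the FI computed
with a known weight set, plus small noise (`scale_noise_sd = 0.05` in the
recovery study). Recovery uses tight thresholds (`0.99 / -0.99`) chosen
from this geometry before the recovery test was frozen: they select a
small neighbourhood of the best-fitting candidate, whose mean recovers
the generating weights to within 0.15 per component on a step-0.1 grid.
With the default `0.6` thresholds the same study would return the
cube-centre average — accurate to the procedure's definition, but
uninformative about the generating weights; applied users should treat
the threshold as the knob that controls how sharply the pilot's opinion
is concentrated.

The package default weight set `score_params()` = (0.3, 0.2, 0.4, 0.1) is
the reference set used in the worked examples and simulation studies: it
penalises order errors and omissions most heavily (the behaviours most
indicative of executive failure in a sequenced routine) and extra
attempts least. It is a documented default, not a clinical claim; applied
use should calibrate on a pilot.

## Psychomotor metrics

From the raw measures recorded at each visit the package derives gait
speed over a 4.6-m course (m/s), stride length (course length divided by
step count, m), and 15-s finger-tapping rates (taps/s) for each hand;
grip strength is ingested as the best of up to three attempts. Gait speed
and stride length may be normalised to a 50-cm knee-heel (lower-leg)
length by the multiplicative rule `value * 50 / knee_heel_cm` — identity
at the reference length, scale-equivariant, and invertible. A
regression-residual adjustment would also remove stature effects but is
not invertible to an interpretable per-subject value, so it is not the
default. The normalisation mode is a pipeline flag: `"apply"` (default),
`"skip"`, or `"auto"`, which applies it only when the knee-heel covariate
reaches 10% significance in a baseline regression of the raw metric on
knee-heel length. Adjusted values *replace* the raw ones in downstream
models (the alternative — carrying knee-heel as a covariate — is
available by passing `"skip"` and including knee-heel among forced-in
covariates).

## Annual rates of change

Each measure's trajectory over visits 1–3 is summarised per subject by
ordinary least squares on visit year; the slope is the annual rate of
change, and the baseline (year-1) value and the slope enter downstream
models as separate predictors. Population and per-group mean rates come
from a transparent two-stage estimator: the mean of per-subject OLS
slopes with its standard error, plus empirical-Bayes shrinkage of each
subject's slope toward its group mean with weight
`tau^2 / (tau^2 + v_i)`, where `v_i` is the sampling variance of the
subject's OLS slope and `tau^2` a method-of-moments estimate of the
between-subject slope variance. This is the estimator a random
intercept-and-slope mixed model reduces to under balanced designs; we
prefer it because every stage has a closed form that can be tested
exactly, and a full REML fit (e.g. `lme4::lmer`) can be substituted by
replacing `pool_slopes()`. On three yearly visits the linearity
assumption is untestable per subject; it is a design assumption carried
over from the instrument's validation, not something the package checks.
Missing visits are handled by fitting on the available points (at least
two); no imputation. Subjects with one visit keep their baseline and get
a missing slope. Raw slopes are the default predictor; shrunken slopes
are emitted alongside (`shrink = TRUE`) because the original analysis
does not state which entered its models.

## The screening battery

* **Correlations**: Spearman's rho is the product-moment correlation of
  mid-ranks, with a two-sided p from the t approximation on `n - 2`
  degrees of freedom. The partial version rank-transforms all variables,
  residualises the two targets on the covariates by OLS, and correlates
  the residuals — the standard rank analogue of a partial correlation,
  used for the age/sex/education-controlled correlation matrix. A target
  fully explained by the covariates has partial rho 0 by convention.
* **ROC**: the empirical curve over every distinct score value, with the
  direction (whether high or low scores flag the positive class) always
  stated per measure. The AUC is the Mann–Whitney probability with ties
  credited 1/2 — tested against exhaustive pairwise enumeration.
  Confidence intervals are stratified percentile bootstrap (resampling
  within class, 2000 replicates by default, seeded); the original
  analysis does not state its CI method, and DeLong intervals can be
  obtained via `pROC` if preferred. Cutoffs maximise Youden's
  `J = sens + spec - 1`, ties broken toward higher specificity (a
  screening instrument should not sacrifice specificity for a tied J),
  and the reported cutoff is placed midway between the selected
  threshold and the adjacent score on its negative side.
* **Conversion models**: logistic regression (maximum likelihood via
  IRLS) with Wald standard errors, `exp(b ± 1.96 SE)` odds-ratio
  intervals, Nagelkerke pseudo-R², and in-sample classification at
  probability 0.5. Slope predictors are standardised, so odds ratios are
  per 1 SD of annual change. Backward stepwise elimination removes the
  predictor with the largest Wald p at or above 0.10, refitting until all
  free predictors sit below it; the "enter at P < .10" phrasing of the
  original description is read as this retention rule, forced-in
  covariates are exempt, and ties break toward the later column so the
  procedure is deterministic. Perfect separation is flagged rather than
  silently diverging, and a Firth bias-reduction penalty
  (`firth = TRUE`) keeps estimates finite when it occurs — near-perfect
  published sensitivities make separation a realistic condition, not an
  edge case.

## The synthetic cohort generator

No subject-level data accompany the instrument's validation, so the
generator is a first-class module: it emulates the *statistical
structure* the analysis assumes, anchored to the published group-level
table. Three groups (72 controls / 65 aMCI / 68 mild AD completers; an
11.6% dropout rate adds a deterministic `round(n p/(1-p))` baseline-only
subjects per group, giving 232 enrolled and 205 completers), three annual
visits, scales drawn from normals truncated at instrument bounds with the
published group means and SDs (several anchors — control MMSE 29.1 (1.0),
control FAQ 0.1 (0.6) — sit close enough to a bound that truncation is
necessary; it also pulls realised means slightly off the anchors, which
the moment tests account for), and per-subject linear decline with
group-specific slope distributions.

Quantities the source does not publish as distributions are package
design choices, stated here once:

* **Error rates** per session are Poisson with group means ordered
  control < aMCI < mild AD (e.g. omission rates 0.15 / 0.9 / 2.0) and
  grow with visit year. **Efficacy-ratio levels** (0.85 / 0.65 / 0.45,
  SDs 0.05–0.08) are set so that the functional index separates the
  groups strongly — the defining property the instrument's published
  discrimination (AUCs ≈ 0.95) implies. The group-separation test
  documents this as a property of the chosen configuration, not a
  reproduction of the published table.
* **Session construction is the scorer's inverse**: error counts are
  drawn first and an event log is built to realise them exactly —
  omissions as absent activities, order errors as pairwise-disjoint
  adjacent transpositions of the performed order (each lowers the LIS
  length by exactly one, so the drawn count is recovered), repetitions
  appended after the first completions, extra attempts spread over them,
  and timings laid out to hit the drawn efficacy ratio to millisecond
  rounding. Infeasible order-error draws (more than
  `floor(performed / 2)`) are capped. This construction is what makes
  scorer testing exhaustive rather than statistical.
* **Stride length, grip strength and knee-heel length** have no published
  anchors; defaults (stride ≈ 0.56–0.62 m, grip ≈ 26–29 kg, knee-heel
  50 ± 4 cm) are plausible for a mixed-sex cohort in its early seventies.
* **Conversion** (aMCI only) is drawn from a logistic model in the
  subject's generating efficacy-ratio slope, intercept −7.0 and
  coefficient −120 (slope in ratio units/year, so 1 SD = 0.02 of slope
  shifts the log-odds by 2.4). These values give a 3-year conversion
  fraction near 35–40% and a univariate conversion model with Nagelkerke
  R² around 0.5 — the strong rate-of-change prognosis the instrument's
  validation reports. Coupling conversion to the *generating* slope
  (rather than the estimated one) keeps the generator honest: the
  pipeline must recover the signal through its own slope estimates.
* Visit-to-visit correlation enters only through the subject-level
  intercepts and slopes, matching the longitudinal module's model, so
  slope-recovery tests are fair rather than flattering.

What passing tests on this generator do **not** show: robustness to
non-linear trajectories, informative dropout, measurement error
correlated across scales, practice effects on repeated VR exposure, or
real instruments' discreteness beyond simple rounding. The generator
makes no attempt to reproduce the clinical cohort's joint distribution
beyond the documented marginal anchors and orderings.

## Numerical choices and degenerate inputs

* Timestamps are seconds from session start at millisecond precision;
  visits are indexed 1–3, and slopes are reported per year on the raw
  visit-year scale (the intercept is the value extrapolated to year 0).
* Truncated normals are drawn by inverse-CDF so the RNG stream length per
  subject is fixed; all generators and the bootstrap take explicit seeds
  (`withr::with_seed`, leaving the caller's RNG state untouched).
* First completions are ordered by completion instant (`end_s`), ties by
  start and then event order; the session builder guarantees distinct
  completion instants at realistic durations.
* An empty session scores `O = |protocol|`, `REff = 0`; an all-identical
  score vector yields Youden J 0; an empty predicted-positive margin
  yields an `NA` predictive value rather than an error; a constant
  functional index during calibration is an explicit undefined-correlation
  error; a grid on which no candidate meets the thresholds reports the
  best candidate and its correlations in the error message.
* Cohort I/O round-trips exactly: tables are written with fixed column
  and row order (JSON document or CSV bundle of `subjects`, `visits`,
  `sessions`, `events` plus `protocol.csv`, which carries the canonical
  activity order the four data tables cannot), and loading re-validates
  every invariant, so any file that loads is a valid cohort.

## Problem sizes in the shipped studies

The test-suite studies use: 1000 random sessions against the brute-force
enumeration oracle (protocols up to 8 activities, the scale at which
exhaustive subsequence enumeration is still exact); 1000 generated
sessions for the generator–scorer inverse; 200 random instances (n ≤ 30)
for the AUC oracle; a 75-subject pilot on a step-0.1 grid for weight
recovery; 500 replicates of 60 subjects for slope recovery; n = 500 for
logistic recovery; and 20 seeds of the full 232-subject cohort for the
group-separation property. The pipeline demonstration runs the full
default cohort with 500 bootstrap replicates per ROC.

## Known limitations

The exact published form of the impairment adjustment is not available;
the rational-penalty form is this package's own, chosen for the
boundedness and monotonicity properties above, and results should be
read as properties of that form. The original reporting is also
internally ambiguous about the index's direction (its methods require a
positive MMSE correlation while its correlation table shows a positive
coefficient against a disability scale); the package fixes
higher-is-better and keeps every direction explicit at the analysis
surface. The two-stage longitudinal estimator assumes balanced,
non-informative missingness; under heavy informative dropout a full
likelihood-based mixed model should replace it. Stepwise selection
inherits all the usual caveats of data-driven variable selection and is
provided because the emulated analysis used it, not as a recommendation.
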