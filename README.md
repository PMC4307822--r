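# vrdot

Scoring and screening analysis for virtual-reality day-out task (VR-DOT)
assessments of everyday functioning in older adults.

Performance-based ADL assessment records *how* a person carries out a
complex everyday routine — here a simulated fire-evacuation drill — as a
timestamped event log, instead of relying on an informant's rating.
`vrdot` implements the full analysis pipeline around such logs for
three-group studies (healthy controls, amnestic MCI, mild Alzheimer-type
dementia):

* **Scoring.** Each session yields an efficacy ratio
  `REff` (fraction of session time spent on protocol activities) and four
  error counts — omissions `O`, repetitions `R`, order errors `W`
  (the longest-increasing-subsequence deficit of the first-completion
  order), and extra attempts `A`. The functional impairment index is

  ```
  FI = 100 * REff / (1 + k1*O + k2*R + k3*W + k4*A),      k_i >= 0,
  ```

  on a 0–100 scale, higher = better function.
* **Calibration.** The weights `(k1..k4)` are fitted on a pilot by grid
  search: candidates whose FI correlates strongly and positively
  (Spearman) with MMSE and strongly and negatively with an IADL scale are
  accepted, and the final set is their componentwise mean.
* **Psychomotor metrics.** Gait speed and stride length over a 4.6-m
  course (optionally normalised to a 50-cm knee-heel length), 15-s
  finger-tapping rates, best-of-three grip strength.
* **Longitudinal rates of change.** Per-subject OLS slopes over three
  annual visits, pooled with empirical-Bayes shrinkage — a transparent
  two-stage analogue of a random intercept-and-slope model.
* **Screening battery.** Partial Spearman correlations (controlling age,
  sex, education), ROC curves with Mann–Whitney AUCs, stratified
  bootstrap CIs and Youden cutoffs, and logistic models of conversion to
  dementia (odds ratios, Nagelkerke R², backward stepwise selection,
  optional Firth penalty under separation).
* **Synthetic cohorts.** A generator anchored to the published group
  table (72/65/68 completers, 11.6% dropout, published scale means/SDs)
  whose sessions are constructed to be the scorer's exact inverse, so
  every stage is testable without clinical data.

## Worked example

Score one session against the default eight-activity evacuation protocol:

```r
library(vrdot)
set.seed(11)
protocol <- default_protocol()
session  <- generate_session(protocol, omissions = 1, repetitions = 1,
                             order_errors = 1, extra_attempts = 2,
                             reff = 0.62, total_duration_s = 300)
count_errors(session, protocol)
#> <vrdot_error_counts> O=1 R=1 W=1 A=2
functional_index(session, protocol, score_params())
#> <vrdot_score> REff=0.620 FI=29.52 (O=1 R=1 W=1 A=2)
```

The session spent 62% of its time on protocol activities; one omission,
one repetition, one order error and two extra attempts inflate the
penalty denominator to `1 + 0.3 + 0.2 + 0.4 + 0.2 = 2.1`, giving
`FI = 100 * 0.62 / 2.1 = 29.5` — a markedly impaired performance.

Run the full pipeline on a simulated cohort:

```r
report <- run_pipeline(pipeline_config(seed = 1, n_boot = 500))
report
#> <vrdot_report> seed 1
#>
#> Group mean baseline scores:
#>    group   fi  reff
#>  control 73.5 0.859
#>     aMCI 36.6 0.649
#>   mildAD 15.7 0.442
#>
#> Partial Spearman correlations (age, sex, education controlled):
#>  test1       test2   rho p_value   n
#>     fi        mmse  0.76 5.9e-44 232
#>     fi bristol_adl -0.78 3.0e-48 232
#>   mmse bristol_adl -0.72 3.3e-37 232
#>
#> AUC table:
#>        measure            pair   auc ci_low ci_high cutoff sensitivity specificity
#>           mmse control vs aMCI 0.875  0.820   0.927  27.50       0.730       0.901
#>    bristol_adl control vs aMCI 0.821  0.749   0.887   5.05       0.770       0.840
#>    blessed_adl control vs aMCI 0.802  0.722   0.879   2.25       0.662       0.938
#>  ravlt_delayed control vs aMCI 0.782  0.721   0.850   6.50       0.878       0.593
#>             fi control vs aMCI 0.977  0.957   0.992  56.74       0.959       0.877
#>           mmse  aMCI vs mildAD 0.865  0.805   0.919  24.50       0.779       0.838
#>    bristol_adl  aMCI vs mildAD 0.999  0.998   1.000   8.20       1.000       0.986
#>    blessed_adl  aMCI vs mildAD 0.987  0.968   0.998   3.30       0.961       0.946
#>  ravlt_delayed  aMCI vs mildAD 0.828  0.763   0.892   2.50       0.896       0.649
#>             fi  aMCI vs mildAD 0.982  0.964   0.994  25.23       1.000       0.865
#>
#> Conversion predictors (aMCI), ranked by |log OR|:
#>          predictor odds_ratio or_low or_high p_value nagelkerke_r2 pct_correct
#>         reff_slope      0.383  0.203   0.723 0.00305      0.211700        67.7
#>  blessed_adl_slope      1.448  0.867   2.417 0.15705      0.042242        60.0
#>  bristol_adl_slope      1.041  0.635   1.706 0.87297      0.000527        55.4
```

Reading the report: the functional index orders the groups
(control > aMCI > mild AD) and, at baseline, discriminates controls from
aMCI better (AUC 0.977) than any conventional scale in the battery —
under this cohort configuration the MMSE reaches 0.875. Odds ratios are
per 1 SD of annual change; `reff_slope` has OR < 1 because a *more
negative* efficacy-ratio slope (faster decline) predicts conversion, and
it is the only predictor with `p < .01` here. Under a fixed seed the
report and all written artifacts (`run_pipeline(..., out_dir = )`) are
byte-reproducible.

The methods vignette (`vignettes/vrdot-methods.Rmd`) documents the model,
the calibration geometry, every generator anchor and default, and the
known limitations.

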