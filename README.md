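# depfacet

Item-, facet- and factor-level psychometrics for depression rating scales
in two-arm clinical trials.

## The problem

Antidepressant trials usually report change on a single scale sum-score.
When one instrument disagrees with every other outcome measure — as can
happen with the QIDS-SR16, whose total is built from *compound criteria*
(the highest-scored item among several is selected for the Sleep,
Weight/appetite and Psychomotor criteria) — the discrepancy can reflect
measurement artefacts rather than treatment biology. `depfacet` implements
the analysis toolkit needed to interrogate that possibility and to
re-analyse a trial at three more granular levels:

* **Items.** Every item of the QIDS-SR16, MADRS, HAM-D-17 and BDI-IA is
  placed on a common 0–1 metric (score ÷ points-possible, so 2 on a 1–4
  item becomes 0.50) and regressed on *Time × Condition* with a random
  patient intercept.
* **Facets.** The pooled 78-item bank (including the 14-item SHAPS) is
  allocated to seven narrow symptom facets (Depressed Mood, Anhedonia,
  Amotivation, Negative Cognition, Impaired Sleep, Reduced Appetite,
  Suicidal Thoughts), filtered by baseline endorsement (> 5 patients above
  the floor) and corrected item-total correlation (r.drop ≥ 0.20), and
  scored as means of the retained rescaled items.
* **A core depression factor.** Rescaled items/composites from the four
  depression scales enter a one-factor minres (unweighted least squares)
  extraction; composites loading above 0.40 are averaged into a 0–1 factor
  score.

Measurement diagnostics include Cronbach's α with per-item r.drop,
response-option ordinality checks, highest-item switching tables for the
compound criteria (with item and change-score correlations), and SE/SD
comparisons across scale mean-scores. Treatment inference uses
random-intercept mixed models, `y ~ Time * Condition + (1 | patient)`
(lme4), whose interaction coefficient is the difference-in-differences;
expectancy moderation adds a full *Time × Condition × Relative-Expectancy*
factorial.

Because item-level trial data of this kind are not public, the package
ships a seeded generator (`generate_cohort()`) producing trial-shaped
ordinal data: 30 + 29 patients, baseline / week-5 / week-6 assessments
(week 5 QIDS-only), graded-threshold ordinal items driven by a latent core
factor plus correlated facet deviations, arm-specific facet change
calibrated exactly on the 0–1 score scale, and expectancy ratings linked
to improvement.

## Worked example

```r
library(depfacet)

g <- generate_cohort(generator_config(), seed = 1)
g$cube
#> <response_cube> 59 patients (30 PT / 29 ET), 10148 responses, timepoints: baseline, week5, week6

head(qids_sum_score(g$cube, "baseline"), 3)
#>   patient_id timepoint scale_id  variant value
#> 1       P001  baseline     QIDS qids_sum    20
#> 2       P002  baseline     QIDS qids_sum    25
#> 3       P003  baseline     QIDS qids_sum    20

fac <- build_facets(g$cube)
dm  <- fac$scores[fac$scores$facet == "DepressedMood",
                  c("patient_id", "timepoint", "value")]
fit_time_condition(dm, g$cube$arms, outcome_id = "DepressedMood")
#> <lme_tc> outcome: DepressedMood ( 59 patients, 118 obs )
#>              term      B   SE_B      b  SE_b DF      t        p
#>         Intercept  0.502 0.0258  0.119 0.188 57 19.479 7.19e-27
#>         Condition -0.032 0.0362 -0.234 0.264 57 -0.886 3.79e-01
#>              Time -0.147 0.0151 -1.075 0.110 57 -9.732 1.01e-13
#>  Time x Condition -0.102 0.0212 -0.747 0.155 57 -4.826 1.08e-05
```

Reading the last row: patients in the PT arm improved 0.102 points more
(on the 0–1 facet metric, 0.75 baseline SDs) than ET patients between
baseline and week 6 — the generator's configured differential effect for
this facet is −0.11, recovered here within sampling error. `Time` is the
change in the reference (ET) arm; `Condition` the baseline arm difference,
which randomization keeps near zero.

`run_pipeline()` chains every stage (scoring → compound diagnostics →
variance diagnostics → item profiles → facets → factor → mixed models →
expectancy moderation) and writes tidy CSV artifacts plus a manifest.

## Scope

The package performs no multiple-testing correction (deliberately, with
the type-I caveat that implies), no IRT or test-retest (ICC) modelling,
and no multi-factor solutions — a single unrotated factor only. See
`vignettes/depression-psychometrics.Rmd` for the methods account,
parameter defaults and limitations.
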