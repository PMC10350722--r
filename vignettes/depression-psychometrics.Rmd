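---
title: "Methods: item-, facet- and factor-level depression psychometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: item-, facet- and factor-level depression psychometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depfacet)
```

## Overview

`depfacet` analyses two-arm depression-trial data at three levels of
granularity below the familiar scale sum-score: individual items, narrow
symptom facets pooled across instruments, and a single core-depression
factor. This vignette is the package's account of the models it fits, the
defaults it ships, the numerical choices behind them, and what the
synthetic cohort generator does and does not emulate.

## Instruments and rescaling

Five instruments are built in: QIDS-SR16 (16 items, 0–3), MADRS (10
items, 0–6), HAM-D-17 (nine 0–4 items and eight 0–2 items, standard
composition, overridable via `scale_definition()`), BDI-IA (21 items,
0–3) and SHAPS (14 anhedonia items, four response choices scored 1–4).

Cross-instrument work requires a common metric. The package's default is
the *literal points-possible* convention: raw score divided by the number
of response choices, so 2 on a 1–4 item maps to 0.50 and a 0–3 item spans
0.00–0.75. The alternative min–max convention ((score − min)/(max − min)),
which maps every item's range onto exactly [0, 1], is available everywhere
through `mode = "minmax"` for sensitivity analysis but is never the
default: the literal convention is the one under which the package's
worked numbers are defined, and switching conventions rescales (and for
min > 0 items, shifts) all downstream scores.

## QIDS-SR16 scoring and compound-criterion diagnostics

The conventional sum (0–27) indexes three DSM criteria by the *maximum*
of several items (Sleep = items 1–4, Weight/appetite = 6–9, Psychomotor =
15–16) and adds six singleton items. Two de-compounded mean-scores drop
the max-selection and average 13 rescaled items, excluding either the
"increased" (variant 1) or "decreased" (variant 2) appetite/weight items
plus hypersomnia — averaging opposite-direction items without
reverse-coding would be incoherent, so each variant keeps one direction.

Max-selection makes the criterion sensitive to *which* member is highest.
`inconsistency_table()` counts patients whose highest member changes
between two visits, tabulates each ordered switching pattern, and attaches
two cohort-wide Pearson correlations per pattern: between the two items at
baseline, and between their change scores. Correlations are computed over
all complete-case patients, not just switchers, because the pattern-level
question ("do these two items track the same construct?") is a property of
the cohort. Ties in the maximum are resolved to the first item in
within-scale order by default (`tie = "first"`, also `"last"` or
`"error"`); a tie resolved to the same winner at both visits is not
counted as switching. Percentages are integers, rounded half away from
zero, with the full cohort size as denominator (both choices are exposed
as arguments).

## Reliability

`cronbach_alpha()` implements the closed form
α = k/(k−1) · (1 − Σᵢ varᵢ / var(total)) with listwise deletion
(dropped patients are counted in the report) and per-item corrected
item-total correlations (r.drop = Pearson r between an item and the total
of the others). Degenerate inputs — a constant item, zero total variance,
fewer than two items or three complete patients — are hard errors, never
silent `NA`s. Note that α on raw versus standardized scores differs unless
item variances are equal; r.drop is invariant to positive affine rescaling
of the whole item set, so computing it on rescaled scores within one
instrument is inert.

`ordinality_check()` encodes the expectation that, in a general
population, endorsement frequency should not rise with option severity;
each adjacent strictly-increasing pair is flagged (ties pass).

## Facet construction

`build_facets()` runs: rescale → allocate → endorsement filter → r.drop
prune → score.

* **Allocation.** The shipped item → facet table
  (`default_facet_allocation()`, YAML in `inst/extdata/`) assigns all 78
  items to seven emitted facets plus a Tension facet; every row is marked
  `rational-default` because it is a reconstruction by content analysis,
  not a published table, and it is fully user-replaceable. Items with no
  relevant facet (e.g. hypochondriasis, insight, the "increased"
  appetite/weight items) are logged as `no_relevant_factor`.
* **Endorsement filter** (default `endorsement_min = 5`): an item is
  dropped when *no more than five* patients score above its floor at
  baseline — exactly five endorsers drops, six keeps.
* **r.drop pruning** (default threshold 0.20, strict `<` excludes): a
  single pass computes r.drop once over the facet's candidates and drops
  all sub-threshold items simultaneously. Single-pass is deterministic and
  order-free; an iterative mode (`iterative = TRUE`) recomputes after each
  pass for users who prefer the stepwise convention.
* **Scoring.** Facet value = mean of retained rescaled items, per patient
  per timepoint; α is reported per facet per timepoint, flagged for
  two-item facets. Tension is always dropped (`tension_dropped`), and any
  facet reduced below two items is dropped as degenerate. Every excluded
  item carries exactly one logged reason.

## The core-depression factor

`depression_factor()` works on the four depression instruments (SHAPS is
an anhedonia measure, not a holistic depression index, and is excluded):

1. **Composites.** To keep the correlation matrix well-conditioned at
   trial sample sizes, within-scale facet composites are averaged
   (`default_composites()`: six composites such as *QIDS Depressed Mood* =
   QIDS5 + QIDS15, the remainder passing through as single items; each of
   the 64 items appears exactly once). A composite is missing whenever any
   member is missing, and the count is logged.
2. **Low-variability exclusion.** Variables with fewer than six patients
   above the floor at baseline are dropped (`min_endorsers = 6`).
3. **Extraction.** One factor by minres: minimise the sum of squared
   off-diagonal residuals of the correlation matrix over the loading
   vector, L-BFGS-B with analytic gradient, bounds ±1, convergence factor
   `factr = 1e4`, started from the first principal component (clipped to
   ±0.995). Loadings are sign-flipped to be severity-positive (mean ≥ 0);
   |λ| ≥ 1 − 1e−6 is flagged as a Heywood case and clipped. Communality
   and uniqueness are the exact identities λ² and 1 − λ².
4. **Scores.** Composites with λ > 0.40 (strict) are averaged, unweighted,
   per patient per timepoint, giving a 0–1 factor score.

Two genuinely open choices were decided as follows. *Which data feed the
extraction:* baseline only, because endpoint data mix treatment response
into the covariance structure and the factor is meant to describe the
construct, not the treatment (`pool_timepoints = TRUE` reverses this).
*Missing-data rule for the correlation matrix:* complete-case by default
— auditable and guaranteed positive semi-definite — with pairwise
available behind `use = "pairwise.complete.obs"`.

A caution: with an exactly diagonal correlation matrix the minres
discrepancy is minimised equally by the zero vector and by any
single-spike loading vector, so the exact-identity input is unidentified;
with sampled data (the realistic case) the fitted loadings shrink to the
sampling noise level, which is what the tests assert.

## Mixed-model inference

`fit_time_condition()` fits `value ~ time * cond + (1 | patient)` by REML
(lme4) with Time ∈ {0, 1} and Condition 0 = ET (the reference arm), 1 =
PT. The Time × Condition coefficient is the between-arm difference in
change; with complete balanced two-timepoint data it coincides, to
numerical precision, with OLS of per-patient change on arm
(difference-in-differences) — an equivalence the test suite asserts at
1e−8.

* **Standardized coefficients.** `b` rescales the outcome by its pooled
  baseline mean/SD — baseline because it is treatment-free. This is an
  exact affine transform: every slope's t and p are identical between `B`
  and `b`; the standardized intercept is additionally location-shifted, so
  reported t/p always come from the unstandardized fit.
* **Degrees of freedom.** A containment (between–within) rule: terms
  involving Time get N_patients − 2; purely between-patient terms get
  N_obs − N_patients − (number of between terms). Satterthwaite
  approximations are deliberately not implemented; the containment rule is
  simple, deterministic, and conservative for the within-patient contrasts
  that carry the scientific questions. p-values are two-tailed at α = 0.05.
* **Timing convention.** `item_response_profile()` analyses QIDS items at
  week 5 *and* week 6 but other instruments at week 6 only, reflecting a
  design in which the self-report comparison instrument covers a two-week
  window. Per-item failures are logged, not fatal.
* **Expectancy.** `expectancy_moderation()` adds the patient's relative
  expectancy (PT rating − ET rating, 100-point scale) as a full-factorial
  moderator. Expectancy is mean-centered by default; centering moves
  lower-order terms but never the three-way coefficient.
* **Missing data.** Mixed models use all available rows; no imputation.

`variance_diagnostics()` compares scale mean-scores on interaction-term
SE, baseline SD and change-score SD, with percent-excess contrasts of each
QIDS variant against the other instruments.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* the analyses assume — it is
the package's test bed, not a claim about any real trial's effect sizes.

Latent model, per patient i, item j (facet f), time t:

z = λ_core·C_i + λ_facet·D_{i,f} + 1[t follow-up]·(δ_{j,arm} + σ_γ·γ_i) + ε

with C, γ ~ N(0,1), D multivariate normal with exchangeable inter-facet
correlation ρ, ε ~ N(0, σ_ε²). Ordinal scores arise by cutting z at
thresholds chosen so the baseline marginal matches a binomial
option-frequency profile (parameter `severity`, default 0.6 for a
clinically severe baseline; `population = "community"` switches to a
floor-heavy 0.12 profile of the kind seen in general-population
screening, for ordinality demonstrations).

The one non-obvious design element is **effect calibration**. Arm effects
are configured on the interpretable 0–1 rescaled-score scale
(`default_arm_effects()`: ET change −0.14 and PT extra change −0.11 for
Depressed Mood, −0.08/−0.12 for Anhedonia, modest equal-arm change
elsewhere). A naive latent shift would be attenuated by thresholding, so
the generator inverts the Gaussian-threshold expectation per item
(`uniroot`, tolerance 1e−10), folding the follow-up variance inflation
from change heterogeneity into the inversion. The configured `pt_extra` is
therefore the *exact* difference-in-differences estimand of the
corresponding facet score, which is what makes unbiased-recovery and
type-I-error tests meaningful.

Defaults: 30 + 29 patients; baseline/week-5/week-6 with week 5 QIDS-only;
λ_core = 0.5, λ_facet = 0.6, σ_ε = 0.62 (total latent SD ≈ 1), ρ = 0.3,
σ_γ = 0.25; expectancy ratings PT ~ 65 (SD 20), ET ~ 45 (SD 20) on the
100-point scale with correlation 0.25 between the PT rating's latent and
individual improvement — plausible values for a trial population with
strong prior interest in the experimental arm; no published moments exist
for these, so they were fixed once at these values.

What the generator does **not** emulate: item-specific content (all items
of a facet are exchangeable), differential item functioning or
non-ordinal response-option wording, clinician-vs-self-report rater
effects, dropout, and floor/ceiling asymmetries beyond the binomial
threshold profile. Passing tests therefore certify the pipeline's
statistical machinery, not the behaviour of any real instrument.

## Test problem sizes

Simulation-based tests use sizes chosen to make Monte-Carlo error small
relative to the asserted tolerances while keeping the default suite quick:
loading recovery and null-factor checks at n = 5,000; r.drop behaviour at
n = 2,000; facet item-set recovery at n = 500; type-I error of the
interaction test over 500 replicates at the 30/29 design (accepted band
0.03–0.08); effect-calibration checks analytically (exact expectation
identities) plus unbiased difference-in-differences recovery over 30
replicates at n = 2,000; an effect-magnitude monotonicity sweep at
n = 800; inter-facet correlation monotonicity at n = 1,000 across three
parameter points.

## Limitations

* The facet allocation and composite tables are rational reconstructions,
  flagged as such; users replicating a specific published allocation
  should supply their own YAML.
* The containment DF rule is one defensible convention among several;
  with two timepoints and complete data the within-patient DF matches the
  change-score t-test, but between-patient DFs are approximate.
* No multiple-testing correction is applied anywhere, by design; at item
  level (dozens of models) the type-I risk is material and results should
  be read as exploratory.
* Minres here is single-factor only: no rotations, no fit indices, no
  standard errors on loadings.
* α and r.drop assume (at least) tau-equivalent continuous items;
  applying them to 3–7-option ordinal items understates reliability
  somewhat, a known property shared with standard practice.
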