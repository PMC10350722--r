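Package: depfacet
Title: Item-, Facet- and Factor-Level Psychometrics for Depression Rating Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring and psychometric diagnostics for multi-instrument
    depression trial data (QIDS-SR16, MADRS, HAM-D-17, BDI-IA, SHAPS):
    compound-criterion sum-scoring and de-compounded mean-score variants,
    internal-consistency reliability (Cronbach's alpha, corrected item-total
    correlations), highest-item switching diagnostics for compound criteria,
    cross-scale symptom-facet construction with endorsement and item-total
    pruning, single-factor minres extraction with loading-threshold factor
    scores, and random-intercept Time x Condition mixed-model inference for
    treatment response, including expectancy moderation. A seeded generator
    of trial-shaped ordinal item data makes every stage runnable and testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
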