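Package: avsli
Title: Lateralization Indices and Diagnostic Evaluation for Adrenal Venous Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for subtyping primary aldosteronism from adrenal venous
    sampling (AVS) hormone measurements. Computes the selectivity index,
    aldosterone/cortisol ratios, the conventional lateralized index and a
    modified lateralized index that substitutes an inferior vena cava sample
    for the right adrenal vein; applies rule-based subtype classification
    (right APA, left APA, idiopathic hyperaldosteronism) with a cohort
    eligibility filter; evaluates diagnostic performance with ROC curves,
    rank-statistic AUC and likelihood-ratio-maximizing thresholds; and
    generates synthetic cohorts from a mechanistic secretion/dilution model
    or from moment-matched lognormal score distributions, so every stage of
    the analysis can be validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
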