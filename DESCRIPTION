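Package: syndromet
Title: Serum Metabolomics Pipeline for Discriminating Intermingled Phlegm
    and Blood Stasis from Its Concurrent Syndromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A wide-targeted serum metabolomics analysis pipeline for
    characterizing the intermingled phlegm and blood stasis (IPBS)
    syndrome of stable angina pectoris and discriminating it from three
    concurrent syndromes (phlegm stasis with Qi deficiency, Qi
    stagnation, or toxin). Provides strict readers and writers for
    abundance, metadata, annotation and pathway (GMT) tables; a seeded
    synthetic cohort generator with group-specific spiked markers;
    half-minimum imputation, log2 transformation and unit-variance
    scaling; principal component analysis and two-class OPLS-DA with VIP
    scores, S-plot coordinates, cross-validated Q2 and label-permutation
    validation; differential and non-differential metabolite calling by
    VIP and fold-change thresholds; per-group top-k abundance cores and
    the derived "essence" metabolite set; hypergeometric pathway
    over-representation analysis; and linear metabolite score panels
    evaluated by ROC curve, AUC and the Youden index, including bundled
    fixed-coefficient reference panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
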