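Package: parkcart
Title: Decision-Tree Diagnosis of Parkinsonian Syndromes from DAT SPECT and
    MIBG Quantitative Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-index extraction from dopamine-transporter SPECT and
    cardiac MIBG scintigraphy (striatal binding ratio, putamen-to-caudate
    ratio, asymmetry index, heart-to-mediastinum ratios and washout rate), a
    from-scratch CART engine with Gini-impurity growth, cost-complexity
    pruning, cross-validation and Min-1SE subtree selection, a published
    fixed decision tree for classifying non-Parkinsonian presentations, PD,
    DLB and PSP, one-vs-rest diagnostic-performance metrics, and seeded
    synthetic cohort and phantom generators so the whole pipeline can be
    exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    RNifti,
    yaml,
    stats,
    utils
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
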