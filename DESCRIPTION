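Package: repurposeDR
Title: Signature-Reversal Drug Repurposing for DNA-Repair-Deficient
    Cancer Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stratifies tumor patients into DNA-repair-deficiency cohorts
    (HR, BER, MMR, NER, NHEJ) from somatic-variant tables and pathway gene
    sets, derives per-cohort tumor-versus-adjacent-normal differential
    expression signatures with an empirical-Bayes moderated t-statistic,
    ranks drugs by connectivity-map style signature reversal with a
    permutation null, scores upstream chemical/drug/toxicant regulators on
    a signed interaction network with a weighted z-score, and evaluates
    drug rankings with NDCG and sensitivity-at-cutoff curves against
    random controls. Includes a fully seeded synthetic-data generator that
    emulates every input so the complete pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
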