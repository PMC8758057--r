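Package: bladderphen
Title: Unsupervised Phenotyping of Perceived Bladder Pain from
    Patient-Reported Outcome Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores the symptomatic questionnaire battery used in
    interstitial cystitis / bladder pain syndrome (IC/BPS) research
    (O'Leary-Sant ICSI/ICPI, OAB-q short form, female Genitourinary Pain
    Index, PFDI-20) and derives composite indices; discovers symptomatic
    phenotypes by two-step clustering (Ward dendrogram with elbow-method
    selection of k, then K-means with k-means++ starts); quantifies
    cluster stability by bootstrap resampling with kappa-based label
    alignment and per-cluster Rand/Jaccard indices; profiles
    discriminatory items by random-forest variable importance and
    phenotype z-score matrices; maps symptom co-expression with a Kohonen
    self-organizing map; and analyses treatment responder contingency
    tables. Includes a calibrated synthetic-cohort generator (discretized
    truncated-normal moment matching of per-item means and standard
    deviations) so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
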