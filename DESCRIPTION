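Package: normaudit
Title: Auditing and Scoring Toolkit for Biomedical Entity Normalization
Version: 0.1.0
Authors@R:
    person("Norm", "Audit", email = "maintainer@normaudit.dev", role = c("aut", "cre"))
Description: Evaluation machinery for entity normalization (concept
    normalization) systems.  Provides a family of accuracy metrics
    generalized to multi-normalization (top-k, per-mention credit with and
    without an over-prediction penalty, and a lenient any-correct variant),
    intra- and inter-fold dataset-bias indicators (few-shot statistics,
    multi-normalization, NIL, ambiguity, train/test redundancy and zero-shot
    rates), a two-sieve baseline normalizer (lexicon exact match after
    stemming, then linear embedding projection with cosine nearest-label
    search), readers and writers for BioNLP-ST standoff, PubTator, OBO,
    MEDIC TSV and word2vec formats, ontology subsetting ablation helpers,
    and a seeded synthetic-data generator with controllable bias rates so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
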