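Package: occucode
Title: Decision Support for Coding Free-Text Job Descriptions into
    Hierarchical Occupational Classifications
Version: 0.1.0
Authors@R:
    person("Occucode", "Developers", email = "maintainer@occucode.dev",
           role = c("aut", "cre"))
Description: Tools for semi-automatic occupational coding in epidemiological
    cohorts: hierarchical classification schemes (NAF-, PCS-, ISCO-style)
    with placeholder-aware codes, text normalization with an English
    Snowball stemmer and a deterministic hashed bag-of-stems sentence
    embedder, a multiclass gradient-boosted-tree coder producing
    confidence-scored code suggestions, confidence-threshold routing with
    workload-reduction estimation, per-level accuracy and Cohen's kappa
    agreement evaluation with human-vs-model comparison statistics,
    job-exposure-matrix (JEM) based exposure assessment (continuous
    probability/intensity/frequency matrices and ordinal 0-2 agent
    matrices), and a synthetic-data generator emulating the structure of
    short, heavily imbalanced occupational corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
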