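Package: neurodyad
Title: Dyadic Analysis of Social Networks and Inter-Subject Neural Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for relating proximity in a social network to the
    similarity of neural response time series across pairs of people.
    Builds friendship graphs from roster-based nomination surveys and
    computes their descriptive statistics (density, reciprocity, geodesic
    distances); turns per-subject ROI-mean fMRI time series into
    dyad-by-ROI inter-subject correlation matrices with imputation,
    per-ROI normalization and volume-weighted composites; fits dyad-level
    ordered and binary logistic regressions with two-way (both members of
    each dyad) cluster-robust standard errors, likelihood-ratio tests,
    per-ROI regressions with false-discovery-rate correction and
    deviation-coded contrasts; runs Kolmogorov-Smirnov, Wilcoxon rank-sum
    and topology-preserving node-relabeling permutation tests; and
    predicts social-distance categories out of sample with a linear
    support vector machine under stratified cross-validation, within-fold
    oversampling and label-permutation significance testing. A
    synthetic-data generator with a tunable planted distance effect
    provides ground-truth inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    sandwich,
    withr
Config/testthat/edition: 3
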