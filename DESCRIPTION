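Package: CoFracNet
Title: Co-Fractionation Interactome Inference and Condition-Dependent
    Network Rewiring
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers protein-protein interaction networks from
    co-fractionation (protein correlation profiling) chromatograms and
    quantifies interactome rewiring between two conditions. Implements
    chromatogram cleaning (single-gap imputation, minimum-observation
    filtering, sliding-average smoothing), Gaussian mixture fitting with
    bias-corrected AIC model selection, MODERN outlier removal of
    high-magnitude quantitation errors via leave-one-out interaction-profile
    autocorrelation, naive Bayes co-complex classification with tenfold
    cross-validation and precision thresholding against a complex-derived
    gold standard, and differential-network statistics built on
    degree-preserving rewiring nulls: the delta-nPPI gene-set permutation
    test, annotation-sharing enrichment, Stouffer-aggregated chromatogram
    autocorrelation, Brunner-Munzel correlation-shift tests, log-odds
    enrichment, and Jaccard enrichment-map construction. A seeded synthetic
    chromatogram generator with planted complexes, rewiring, noise,
    missingness and quantitation spikes makes every stage testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    minpack.lm,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
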