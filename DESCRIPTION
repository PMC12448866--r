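Package: lipidlda
Title: Binned Lipid Fingerprint Classification for Ambient Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for rapid tissue-type classification from ambient mass
    spectrometry lipid profiles. Per-sampling-event peak lists are binned onto
    a fixed 0.1 Da grid over 100-1000 Da, TIC-normalized, quality-filtered,
    and modeled with principal component analysis followed by linear
    discriminant analysis (PCA-LDA). Query events are called by cluster
    overlap within a standard-deviation gate on squared Mahalanobis distance,
    with Gaussian class posteriors and a probability threshold. Includes
    leave-one-specimen-out and stratified event-level cross-validation,
    specimen-level label permutation null models, learning curves, loading
    based marker ranking, sparse classification restricted to a curated
    41-lipid marker array, one-vs-rest sensitivity/specificity reporting, and
    a hierarchical synthetic-cohort generator for end-to-end testing without
    patient data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
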