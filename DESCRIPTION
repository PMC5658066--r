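Package: emsynapse
Title: Segmentation-Based Synapse Detection for 3D Electron Microscopy Connectomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects chemical synapses in segmented 3D electron microscopy
    volumes by classifying directed neurite-neurite interfaces. Texture
    features from an anisotropy-aware 3D filter bank (structure tensor and
    Hessian eigenvalues, Gaussian derivatives, local entropy, variance and
    sphere averages) are aggregated over seven perisynaptic subvolumes and
    combined with interface shape features into a 3224-entry feature vector
    per candidate direction. A cost-weighted LogitBoost decision-stump
    ensemble scores both pre-to-postsynaptic directions of every interface.
    Detections are evaluated with overlap-based synapse-level precision and
    recall, aggregated into contactomes and weighted/binary connectomes via
    single-linkage synapse clustering, and single-synapse error rates are
    propagated to neuron-to-neuron connectome precision and recall with an
    exact binomial/Poisson connectivity model. A seeded synthetic neuropil
    generator provides ground-truth volumes for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
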