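Package: mtmmbrain
Title: Multitrait-Multimethod Latent-Variable Models of Gray-Matter
    Integrity and Episodic Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling regional gray-matter structural integrity
    from multimodal imaging (voxel-based morphometry, magnetization transfer
    ratio, mean diffusivity) with multitrait-multimethod confirmatory factor
    models, and for relating the resulting latent integrity factors to
    episodic memory ability. Includes a full-information maximum likelihood
    structural-equation engine for arbitrary missingness patterns (RAM
    parameterization, fit indices, likelihood-ratio and Wald inference,
    multigroup measurement-invariance testing), deterministic data-preparation
    operators (magnetization-transfer ratio, intracranial-volume adjustment,
    robust multivariate outlier screening, rescaling, subsample selectivity),
    a synthetic-data generator emulating the design of a large aging cohort
    with a partially scanned subsample, and a configuration-driven pipeline
    that renders descriptive and model-summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
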