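Package: periomics
Title: Peritumoral Radiomics Modelling of Distant Metastasis Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying whether the CT texture of the tissue immediately
    around a lung tumor carries prognostic information about distant metastasis.
    The package constructs peritumoral rim and exterior regions from a tumor mask
    by physical-distance morphology restricted to the lung, extracts filtered
    radiomic texture features (first-order, GLCM, GLRLM, NGTDM over Laplacian of
    Gaussian and wavelet derived images), selects features by test-retest
    stability (ICC) and minimum-redundancy maximum-relevance ranking, and builds
    cross-validated Cox proportional-hazards signatures evaluated with the
    concordance index, Noether inference, Kaplan-Meier stratification and
    log-rank tests. A synthetic CT phantom generator provides seeded cohorts with
    controllable region-specific texture signal and censored outcomes so the full
    pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    survival,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    RNifti,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
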