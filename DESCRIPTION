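Package: anatgamma
Title: Gamma-Index Monitoring of Anatomical Change in CBCT-Guided Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares serial cone-beam CT (CBCT) volumes of a radiotherapy
    course against a fraction-1 reference using a 3D gamma index that
    combines distance-to-agreement (mm) with CT-number difference (HU).
    Summarises each comparison by a match quality parameter (MQP), the
    difference between percentiles of the failed-pixel (gamma > 1) histogram
    of the reference and current comparisons, and raises a repeat-CT alert
    when a run of consecutive MQP values falls at or below a decision
    threshold. Includes ROC-based training of the gamma criteria, histogram
    percentile and decision threshold against recorded repeat-CT orders, and
    a synthetic head-and-neck phantom course generator (progressive lateral
    soft-tissue loss, HU noise, setup jitter, ring/streak artifacts) with
    ground-truth labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
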