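Package: tfnetevo
Title: Evolutionary Rate Determinants of Transcription Factors in Gene
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of transcription-factor (TF) evolutionary-rate
    determinants in a gene regulatory network: rank-space subset-slope
    tests against a mean-matched resampling null, TF-to-target
    evolutionary aggregation, knockout-based regulatory edge-sign
    inference, sign-stratified co-evolution statistics, a co-regulation
    spread test with a degree-proportional null, two-species expression
    divergence comparison, and a fully configurable synthetic-data
    generator emulating the statistical structure of the yeast
    regulatory network, with ground truth recorded for parameter
    recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
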