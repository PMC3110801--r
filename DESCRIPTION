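Package: hkgspectra
Title: Housekeeping Gene Prediction from Expression Time-Series Spectra
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate housekeeping genes from uniformly sampled
    gene-expression time series. Each probe's series is triaged for missing
    values, gap-filled by shape-preserving piecewise cubic Hermite
    interpolation, detrended by least squares against five variation basis
    functions, and summarised by the power spectrum of its discrete Fourier
    transform. A soft-margin support vector machine with a Gaussian radial
    basis kernel, trained on reference housekeeping probes against resampled
    negative pools, is applied over many bootstrap rounds; per-probe vote
    tallies are thresholded and aggregated to gene-level predictions.
    Includes evaluation by coefficient of variation across tissue expression
    matrices and by exon conservation scores, plus seeded synthetic-data
    generators so the whole pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
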