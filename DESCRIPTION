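Package: nervePNI
Title: Rule-Flow Detection of Perineural Invasion in Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage detection of perineural invasion (PNI) in
    hematoxylin-eosin histology images. A compact multi-resolution
    encoder-decoder produces per-pixel probability maps for nerve fibers
    and PNI signal; a domain-knowledge rule flow then turns the maps into
    per-nerve diagnoses via Gaussian-pyramid smoothing, combined
    constant/Otsu thresholding, calibrated connected-component size
    filtering and per-nerve adjacency inspection. Includes size-filter
    calibration from irregular-component area samples, conversion between
    pixel areas and equivalent tumor-cell counts, confusion-matrix
    evaluation with cutoff sweeps and diagnostic-time analysis, and a
    seeded synthetic-scene generator with ground-truth masks so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    png,
    jsonlite,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
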