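Package: histofuse
Title: Nonrigid Registration of Serial Histology Sections and Spatial
    Multi-Omics Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Registration engine for stained serial tissue sections
    (tissue segmentation, mean-shift denoising, multi-resolution affine
    registration under a local normalized cross-correlation metric, and a
    greedy diffeomorphic nonrigid stage with pre/post Gaussian
    regularization), with pairwise and groupwise modes, and application of
    the composited displacement field to images, masks, pointsets and
    polygon annotations.  On top of the registration engine, a spatial
    multi-omics integration layer projects spot-based (Visium-style) and
    pixel-based (mass spectrometry imaging style) omics geometries into
    full-resolution reference matrices, registers them across sections and
    fuses source measurements into target spots via area-fraction-weighted
    statistics, with landmark-based target registration error evaluation
    and seeded synthetic data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
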