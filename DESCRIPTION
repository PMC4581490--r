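Package: ishquant
Title: Quantification and Comparative Analysis of Spatial Gene Expression
    from In Situ Hybridization Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies spatial gene expression from in situ hybridization
    (ISH) images of embryos with cylindrically symmetric staining, following
    the segment-averaging approach of the GenExp pipeline: the cell layer
    between two boundary polylines is decomposed into quads, per-quad mean
    pixel intensities are edited for artifacts, interpolated at one hundred
    equidistant arc-length points and scaled to unit maximum. Standardized
    profiles are clustered per developmental stage with unweighted average
    linkage (UPGMA) on the 1 - Pearson correlation distance, dendrograms are
    cut at stage-specific thresholds, and expression-domain descriptions are
    summarized into transition statistics (minor/major change, appearance,
    disappearance) between consecutive available stages with respect to three
    major embryonic regions. Includes a synthetic-data generator producing
    embryo-like images, planted-cluster profile sets and domain tables with
    known transition kernels, so the whole pipeline is testable end to end,
    plus reference transition counts for Nematostella vectensis from the Kahi
    Kai ISH database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    pracma,
    png,
    tiff,
    jsonlite,
    yaml,
    optparse,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr
Config/testthat/edition: 3
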