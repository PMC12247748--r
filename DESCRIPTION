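Package: germquant
Title: Quantification of Germ-Plasm Enrichment at the Anterior of
    Drosophila Oocytes and Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pixel-level quantification of germ-plasm component enrichment
    in masked, anteroposterior-oriented confocal micrographs of Drosophila
    oocytes and early embryos. Implements the per-pixel z-score
    standardization, the anterior integrated enrichment statistic (sum of
    z-scores over the anterior-most 15 percent of the specimen),
    standardized 300-point anteroposterior intensity profiles with
    group-level confidence bands, and HA-anchored thresholded Pearson
    colocalization. Includes pooled-bootstrap and one-sided Fisher exact
    tests for pole-cell penetrance and count comparisons, analytical
    size-exclusion-chromatography calibration (partition coefficient,
    log-linear molecular-weight fit, oligomeric-state calls), and a
    synthetic-micrograph generator with known ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
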