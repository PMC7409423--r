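Package: xenoquant
Title: Quantification of Zebrafish Larval Tumor Xenograft Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reproducible quantification of fluorescence micrographs of
    zebrafish larval tumor-cell xenografts. Segments the dye-labelled tumor
    channel, excludes sub-cellular debris by a size rule, measures
    dye-positive area inside yolk and trunk regions of interest
    (proliferation and invasion readouts), scores cell dispersion with a
    coverage-polygon migration index, and provides companion analytics for
    qRT-PCR relative expression (2^-ddCt, knockdown efficiency), CCK-8
    viability time courses, and the group-comparison statistics used with
    such assays (unpaired Student's t, mean +/- SEM, 2x2 combination
    contrasts). Ships a synthetic larva image simulator with full ground
    truth so every stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
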