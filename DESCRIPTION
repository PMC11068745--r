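Package: migrochip
Title: Quantification of Confined T-Cell Migration in Microfabricated Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for regulatory T-cell migration and morphology
    experiments in microfabricated devices. Simulates persistent random walks
    in micropillar forests and one-dimensional motion in microchannels with
    known ground truth, renders nuclear-stain time-lapse movies, detects and
    links nuclei into tracks, and computes the standard confined-migration
    statistics: channel entries, instantaneous speed and its per-cell
    fluctuation, furthest-distance density profiles, turning angles with
    persistent/confined step classification, and percent of motile time
    confined. Also quantifies cell morphology from confocal z-stacks
    (projected inner-membrane surface, membrane spike counts, organelle
    volume fractions) and computes Foxp3 TSDR demethylation percentages from
    methylation-specific qPCR Ct values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
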