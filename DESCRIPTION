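Package: lipidmsi
Title: Processing, Annotation and Segmentation of Mass Spectrometry Imaging Data for Lipidomics
Version: 0.1.0
Authors@R: person("MSI", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for matrix-assisted laser desorption ionisation (MALDI)
    mass spectrometry imaging (MSI) of lipids: reads and writes imzML/ibd file
    pairs, extracts and bins per-pixel peak lists into ppm-width mass bins,
    filters features by detection proportion, removes 13C isotope peaks using
    carbon-count-based expected abundances, annotates features by accurate mass
    against a combinatorially generated sum-composition lipid library,
    normalises pixel spectra (median, total ion count, or standard ions),
    applies centering and Pareto scaling, and classifies pixels into tissue
    regions by principal components analysis and k-means clustering. Includes a
    synthetic phantom generator emitting standard imzML with known ground truth
    so every stage is testable without external data, and a command-line
    interface for full-pipeline and per-stage runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    grDevices,
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
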