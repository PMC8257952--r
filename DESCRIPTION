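Package: leafletquant
Title: Regional Quantification of Aortic Valve Leaflet Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for quantitative analysis of aortic valve leaflet
    histology sections: equal-area partition of a leaflet region of interest
    into base, middle and tip thirds along the anatomical axis; pixel
    classification of histological stains (Movat's pentachrome, van Gieson,
    AEC chromogen) by hue/saturation/intensity thresholds; fractional
    distribution of each stain class across the three leaflet portions with
    cohort summaries and region comparisons. Also provides relative qPCR
    expression by the Livak 2^-ddCt method, peptide monoisotopic mass and
    precursor m/z verification for targeted (PRM) proteomics lists, and a
    synthetic-histology generator that produces leaflet-shaped images, stain
    scenes and Ct tables with exact ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
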