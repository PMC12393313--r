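Package: centmorph
Title: Morphometry of Pericentrosomal Membrane Reticula in Fluorescence
    and Volume-EM Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated, tested re-implementation of the image-quantification
    procedures used to characterise the centriculum, the ER-derived membrane
    reticulum that envelops C. elegans embryonic centrosomes, and to test
    whether it acts as a microtubule filter. Provides calibrated-image and
    polygon-ROI input/output; ring morphometry of annular fluorescent signals
    (dual perpendicular line-scan diameters, threshold masks built from
    region-statistic formulas, void/PCM/microtubule areas and intensities,
    two independent tubulin-ring-width estimators, and the gap-area
    statistic); porosity analysis of segmented membrane panels (per-hole
    areas, open-area fraction, microtubule-passability cutoff, binned size
    distributions, viewing-angle checks); stopped-versus-continuing
    classification of traced microtubules with angles to the radial vector;
    seed-deterministic synthetic-scene generators with ground truth for every
    input class; and the statistical layer (two-group and multi-group
    comparisons, ordinary least squares) with tabular and graphical report
    assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    png,
    pracma,
    stats,
    tiff,
    utils,
    withr
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
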