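Package: flarequant
Title: Quantitative Fluorescence Microscopy of Membrane Lipid Reporters in Budding Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement pipelines for quantitative fluorescence microscopy of
    lipid reporter (FLARE) distributions in budding yeast, together with a
    synthetic-data generator so that every measurement stage has a
    parameter-recovery test. Implements plasma-membrane polarity ratios
    (daughter/mother, Fd/Fm) from line-scan intensity profiles conditioned on a
    membrane marker, prominence-based intensity maxima detection with binary
    ER-association classification from a data-derived threshold, thresholded
    pixel-overlap colocalization, a FRAP (fluorescence recovery after
    photobleaching) pipeline with bias correction, incidental-photobleach
    normalization and exponential recovery fitting of mobile/immobile
    fractions, aggregation time-course scoring, sedimentation densitometry
    fractions, and the cohort statistics used alongside them.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
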