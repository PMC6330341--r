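Package: tilscape
Title: Spatial Heterogeneity of Tumor-Infiltrating Lymphocytes from Whole-Slide Cell Coordinates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intra- and inter-tumoral spatial heterogeneity of
    CD8+ T cells from whole-slide cell coordinates and tissue-region
    annotations. Provides moving-window spatial point-pattern analysis
    (Clark-Evans test for complete spatial randomness, Ripley's K with
    isotropic edge correction, minimum-contrast fitting of the Thomas
    cluster process), density-based cluster detection (HDBSCAN) with
    alpha-shape and confidence-ellipse morphometrics, quartile-coefficient-
    of-dispersion heterogeneity indices, tissue-context assignment with
    invasive-front band construction, responder/non-responder outcome
    statistics, and a synthetic virtual-slide generator that supplies
    ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    spatstat.geom,
    spatstat.explore,
    deldir,
    polyclip,
    sp,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
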