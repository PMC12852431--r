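Package: microgliaMorph
Title: Automated Morphometry of Retinal Microglia from Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of microglial morphology in calibrated
    2-D fluorescence fields (Iba-1 immunostaining of retinal whole mounts).
    Detects cell somas, skeletonizes processes, measures arborization
    territory as a convex-hull area, computes the Feret's Diameter Ratio of
    the soma by rotating calipers, and reports soma fluorescence intensity
    with a two-anchor affine normalization across images. Includes a
    synthetic-field generator with exhaustive ground truth, per-field
    counting and density under a quadrant-by-eccentricity sampling plan, and
    the study-level statistics (one-way ANOVA with Tukey-Kramer post hoc
    tests within groups, Mann-Whitney U between groups, star codes and
    percent change) used to compare genotypes across ages.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    optparse,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
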