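Package: stainseg
Title: Color-Stain Segmentation and Damage Quantification for Muscle Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies muscle damage from photographs of color-stained
    cross-sectional slices. Damaged (yellow) and undamaged (blue) stain
    classes are modelled per RGB channel from small training regions and
    pixels inside a bounding box are classified with a mean plus or minus
    k standard deviations rule (k = 1.7 by default); the damage percentage
    is the yellow share of all colored pixels at the midsubstance
    cross-section. Includes a synthetic stained-slice generator with known
    ground truth, intraclass-correlation reliability of repeated
    segmentations, rank-based group comparison with Bonferroni-adjusted
    thresholds, and noncentral-t power and sample-size calculations for
    two-group designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
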