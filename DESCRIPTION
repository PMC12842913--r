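Package: ldctqa
Title: Scan-Coverage and Image-Noise Quality Assurance for Low-Dose Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated acquisition-level quality assurance for low-dose chest
    CT (LDCT) lung-screening examinations. Quantifies cranial and caudal over-
    and underscanning from a cleaned lung segmentation mask, extracts a pure
    descending-aortic-blood volume by largest-component selection, in-plane
    binary erosion to a metric margin, arch splitting and trimming to the lung
    extent, and measures in-vivo image noise as the standard deviation of
    Hounsfield units within that blood volume, normalized to a 1 mm^3 voxel.
    Includes exact binomial (Clopper-Pearson) confidence intervals and cohort
    aggregation, a synthetic chest-phantom generator with ground truth for
    end-to-end verification, NIfTI and basic DICOM-series input with pre-flight
    integrity checks, and JSON/PDF per-scan reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
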