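Package: petmrbids
Title: Curation and Quality Control of Preclinical Hybrid PET/MR Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Config-driven conversion of raw DICOM series trees from hybrid
    PET/MR acquisitions into Brain Imaging Data Structure (BIDS) datasets,
    compensating DICOM tags that are missing in preclinical and retrospective
    data, together with an image quality-control battery: Otsu-threshold
    volume-of-interest signal-to-noise, contrast-to-noise and median-intensity
    metrics, static and dynamic pseudo noise-equivalent count rate (PNECR) for
    dynamic PET, cohort availability reporting, and a fully synthetic DICOM
    phantom cohort generator for end-to-end testing without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
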