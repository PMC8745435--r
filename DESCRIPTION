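Package: msibreslow
Title: Breslow Thickness Classification from Multispectral Skin Lesion Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multispectral-imaging (MSI) decision pipeline for
    pigmented skin lesions imaged in three co-registered narrow-band channels
    (green 525 nm, red 660 nm, infrared 940 nm). A log-ratio spectral score
    computed against the peri-lesional skin (parameter s') separates melanomas
    from nevi, and a three-step threshold decision tree on lesion circularity
    and channel intensities assigns melanomas to Breslow thickness classes
    (<= 1 mm, 1-2 mm, > 2 mm). Includes ImageJ-style shape morphometry
    (circularity, solidity, roundness) from traced boundary polygons,
    diagnostic performance statistics (ROC/AUC, Cohen's kappa, one-vs-rest
    sensitivity and specificity, Pearson correlation), and a seeded generator
    of synthetic multispectral lesion cohorts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
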