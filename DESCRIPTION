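Package: octaquant
Title: Quantification of Diabetic Macular Ischemia from OCT-Angiography En-Face Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometry of the foveal avascular zone (surface, perimeter,
    ordinal contour grade), a brightness-threshold nonperfusion index for
    superficial-plexus en-face angiograms, and seeded measurement of the
    central nonperfused area on deep-plexus images, together with the
    cohort-level nonparametric statistics (Kruskal-Wallis, Fisher exact,
    Spearman, Mann-Whitney) and backward-elimination covariance models used
    to relate these measurements to nonproliferative diabetic retinopathy
    stage. Includes a synthetic angiogram and cohort generator with full
    ground truth so the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
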