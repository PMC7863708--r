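Package: renalGSM
Title: Gray-Scale Median Analysis and Fascia-Anchored Normalization of
    Renal Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computer-aided gray-scale analysis of B-mode renal ultrasound
    images. Reads 8-bit grayscale bitmaps, rasterizes manually drawn
    polygon regions of interest, computes the gray-scale median (GSM) and
    the proportional pixel distribution over 14 brightness ranges
    ("virtual histology"), renders pseudocolor overlays, and normalizes
    whole images by anchoring the GSM of the posterior renal fascia to
    gray level 200 through a linear transfer function. Includes a
    speckle-textured synthetic phantom and multi-operator study generator,
    and the nonparametric comparability analysis (Anderson-Darling,
    Kruskal-Wallis, Wilcoxon-Mann-Whitney) used to compare operators and
    devices across random, standardized, and normalized image categories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    nortest,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
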