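Package: colocbench
Title: Local Thresholding and Colocalization Coefficients for Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Local adaptive thresholding of greyscale images from
    circular-window statistics (local mean, median, standard deviation,
    local-background mean and the Phansalkar method), colocalization
    coefficients over explicitly declared pixel populations (Pearson
    correlation, Manders M1/M2, the Manders overlap coefficient and the
    H coefficient), offset and background correction, and seeded generators
    for the synthetic image families (disc test images with Poisson
    background, random-object pairs, copy-fraction pairs with tunable
    correlation, and a two-compartment cartoon cell) used to benchmark
    them.  Includes the evaluation experiments that score per-region
    pixel classification of the thresholding methods and trace coefficient
    responses to fill fraction, copy fraction, empty pixels and intensity
    offsets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
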