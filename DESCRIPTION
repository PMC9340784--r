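Package: gonadquant
Title: Quantitative Histology of Reproductive Effort in Oyster Gonads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures reproductive effort in bivalve gonad cross sections from
    trichrome-stained histology scans. Segments the whole tissue section, the
    gonadal tubules (GT) and the storage tissue (ST) by colour-space
    thresholding (HSI intensity, CIELAB L*/a*) and random-forest pixel
    classification, measures each tubule (area, Crofton perimeter,
    circularity, equivalent-ellipse axes, Gravelius compactness K) and applies
    the K < 1.7 circularity filter, computes the Gonadal Tubule Index (GTI)
    and Tubule Area Index (TAI), and provides the accompanying group
    statistics (Student's t with SEM and significance stars), delta-Ct qPCR
    normalisation against EF1-alpha, and mitosis phase-frequency tables. A
    synthetic slide-phantom generator with exact ground-truth masks makes the
    whole pipeline testable without scanned slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
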