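Package: glomtopo
Title: Glomerular Response Spectra, Receptive-Range Models and Chemotopy
    from Functional Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for functional imaging of the olfactory
    bulb: preprocessing of intrinsic optical signal (IOS) and
    synapto-pHluorin (SpH) recordings into a frames-by-pixels measurement
    matrix, segmentation of overlapping glomeruli by regularized
    non-negative matrix factorization with smoothness and sparseness
    penalties, extraction and filtering of odorant response spectra,
    EVA vibrational descriptors and combined physico-chemical descriptor
    spaces, support vector regression models of the molecular receptive
    range with bootstrap predictive power (q-squared), and tunotopic and
    chemotopic spatial statistics (UPGMA clustering, activation
    barycentres, normalized Mann-Whitney U proximity tests with shuffle
    controls). Includes a synthetic-data generator with planted ground
    truth so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite,
    ape,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
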