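Package: vibrospec
Title: Preprocessing and Decomposition of Vibrational Microspectroscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Batch preprocessing and analysis of hyperspectral vibrational
    spectroscopy (FTIR/Raman) images. Implements atmospheric water-vapor and
    CO2 subtraction by derivative-smoothness fitting with windowed refinement,
    clustered resonant Mie scattering correction (EMSC with Kramers-Kronig
    coupled van de Hulst extinction dictionaries), Savitzky-Golay denoising,
    rubberband/AsLS/arPLS baselines, MCR-ALS decomposition with SIMPLISMA
    initialization and region-of-interest masking, and k-means segmentation
    with cluster annotation. Includes a seeded phantom-image generator with
    known ground truth, delimited-text and MATLAB v5 container readers, and
    settings-driven batch pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    signal,
    pracma,
    Matrix,
    jsonlite,
    data.table,
    png
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
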