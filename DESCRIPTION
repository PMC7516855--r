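Package: mosaicentropy
Title: Wasserstein Metric-Based Boltzmann Entropy of Landscape Mosaics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the Wasserstein metric-based Boltzmann entropy of
    categorical rasters (landscape mosaics): the compositional term Wc, the
    configurational term Ws under four- or eight-neighbor connectivity, the
    relative entropy Wdist = (1 - Wc)(1 - Ws), and the absolute extended
    Boltzmann entropy. Includes raster input from text grids and grayscale
    images, quantization of continuous surfaces into classes, deterministic
    batch computation over many files, and a neutral-landscape simulator
    (Hurst-controlled fractal surfaces, quantile classification, and
    row-randomization of a seed raster).
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    parallel,
    stats,
    utils,
    png,
    jpeg,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
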