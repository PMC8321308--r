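Package: shockfilter
Title: Smoothed Shock Filtering for Image Enhancement and Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative image enhancement with the smoothed shock filter, a
    PDE-style scheme that replaces the classic erosion/dilation switch of
    shock filtering with smoothed rank-order operators derived from smoothed
    local histograms. Provides the smoothed median / erosion / dilation
    family, the classic shock and median baselines they reduce to in limiting
    parameter regimes, scale-space iteration with residual maps, synthetic
    test-image generators, and an (alpha, sigma)-robustness evaluation
    harness built on SSIM over ladders of additive Gaussian noise. Reads and
    writes PNG, TIFF and PGM rasters and ships a command-line interface for
    filtering and robustness experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    generics,
    ggplot2,
    grDevices,
    png,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
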