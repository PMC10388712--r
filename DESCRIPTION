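Package: holopollen
Title: Quantitative Phase Imaging Pipeline for Pollen Viability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of off-axis image-plane digital holograms
    of pollen grains. Provides a synthetic hologram generator with known
    ground truth, Fourier-transform and total-variation regularised sparse
    reconstruction of the complex object field, transport-of-intensity phase
    unwrapping, per-grain morphometry (area, perimeter, mean phase, optical
    volume) and two-class viability calling from the mean-phase distribution
    via a Gaussian mixture, with Welch's t-test and overlap flagging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
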