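Package: nanodpk
Title: Dose Point Kernel Rescaling for Gold Nanoparticle Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds electron dose point kernels (DPKs) from energy-deposition
    events and rescales them with equivalent path length (EPA) factors to
    estimate nanoscale dose distributions around gold nanospheres, nanorods,
    and pixelated two-dimensional nanoparticle clusters. Provides unity, total
    stopping power (TSP), linear range ratio (LRR), and physical density ratio
    (PDR) rescaling factors computed from secondary-electron spectra and
    material stopping-power tables, a simplified straight-line CSDA transport
    oracle for validation, Bresenham-based pixel-grid dosimetry for clustered
    nanoparticles segmented from microscopy images, and mean absolute
    percentage error (MAPE) comparison of radial dose profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
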