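Package: geldiff
Title: Drug Diffusion and Cellular Uptake Analysis for Hydrogel Chip Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies apparent drug diffusion coefficients in hydrogel
    reservoirs from fluorescence time-lapse imaging, using a Crank-Nicolson
    finite-difference forward model with a data-driven, time-dependent donor
    boundary condition and Levenberg-Marquardt inverse fitting. Includes
    single-cell uptake analysis from nuclear-stain segmentation (intracellular
    uptake rates per gel zone, a transport rate constant and an apparent cell
    permeability), fluorescence-to-concentration calibration, a statistical
    comparison workflow for fitted diffusion coefficients, and a ground-truthed
    synthetic chip-experiment generator for offline validation of the full
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
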