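Package: pcdsim
Title: Signal-Chain Simulation for Edge-On Silicon Photon-Counting CT Detectors
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the full signal chain of an edge-on silicon strip
    photon-counting detector channel with adjustable shaping time: photon
    interactions and drift-diffusion charge transport with Shockley-Ramo
    induced currents, semi-Gaussian pulse shaping through rational transfer
    functions, two-source electronic noise power spectral densities, a
    clocked comparator bank with deadtime logic, filtered x-ray tube spectra
    with a simplified silicon energy response, and the power versus
    shaping-time noise tradeoff. Includes threshold-scan simulation, modified
    complementary-error-function calibration fits, grid-search recovery of
    shaper time constants from pulse-length data, and dose-efficiency
    evaluation versus the lowest counting threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
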