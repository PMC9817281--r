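Package: med64ltp
Title: Analysis and Super-Resolution of MED64 Field-Potential LTP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for 64-channel (8x8) planar multi-electrode array
    field-potential experiments on brain slices: fEPSP slope and amplitude
    extraction with baseline-stability gating, classification of channels into
    non-LTP, early-phase and late-phase long-term potentiation and
    tagging-like responses, recruitment time courses and activation-area
    convex hulls, and two-group comparisons. Includes maximum a posteriori
    estimation on a partially observed Markov random field with Lanczos-kernel
    smoothness weights to project the sparse 8x8 electrode observations onto a
    high-resolution latent field, both per frame and spatio-temporally, and a
    synthetic recording generator that emulates theta-burst-stimulation
    protocols, late-phase LTP, synaptic-tagging capture and channel
    recruitment so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
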