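Package: segcaipi
Title: Segmented CAIPI Sampling and Structured Low-Rank Reconstruction
    for 3D Multi-Shot EPI
Version: 0.1.0
Authors@R:
    person("segcaipi", "developers", email = "segcaipi@example.org",
           role = c("aut", "cre"))
Description: Tools for navigator-free 3D multi-shot echo-planar imaging
    (EPI) in physiological-noise dominated regimes.  Generates standard
    blipped-CAIPI and segmented-CAIPI ("seg-CAIPI") ky-kz shot schedules
    and their per-shot-group sampling masks, implements the SENSE forward
    model E = M.F.S.F^-1 together with a block-Hankel structured low-rank
    ADMM reconstruction that jointly recovers one k-space per shot group,
    and provides a simulation framework (phantom, smooth coil maps,
    second-order-harmonic respiratory phase fluctuations, calibrated
    thermal noise) plus temporal-SNR and power-spectrum metrics for
    evaluating robustness to inter-shot phase variations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
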