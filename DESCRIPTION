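Package: megshield
Title: Extended Signal-Space Separation for MEG Interference Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Suppression of environmental magnetic interference in
    magnetoencephalography (MEG) recordings by extended signal-space
    separation (eSSS), which augments the external vector-spherical-harmonic
    basis of signal-space separation (SSS) with principal components
    estimated from empty-room recordings, combining the generality of the
    physical SSS model with the calibration insensitivity of statistical
    signal-space projection (SSP). Includes SSS and SSP reference
    implementations, a synthetic 306-channel helmet array generator,
    dipole-in-sphere forward simulation, whitened least-squares dipole
    fitting, shielding-factor and spectral metrics, and a config-driven
    simulation testbench.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
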