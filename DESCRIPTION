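Package: octoquant
Title: Quantitative Optical Property Estimation for OCT Phantom Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating optical attenuation and scattering
    coefficients of thin-film and step phantoms imaged with spectral-domain
    optical coherence tomography (OCT). Implements the depth-resolved A-scan
    two-way exponential decay fit, Beer-Lambert and diffusion-approximation
    spectrophotometric models, Lorenz-Mie scattering coefficients for
    microsphere suspensions, a Monte Carlo photon-transport simulator with
    Henyey-Greenstein scattering and Fresnel boundaries, and OCT system
    performance metrics (SNR, Gaussian-fit axial resolution, sensitivity
    roll-off, step-phantom imaging depth). A synthetic-data module generates
    speckled B-scans, point-spread-function A-scans, roll-off curves and
    spectrophotometric thickness series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tiff,
    png,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
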