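Package: eptycho
Title: Low-Dose Electron Ptychography Simulation and Bayesian Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dose-calibrated simulation of cryo electron ptychography
    experiments (defocused, zone-plate and randomized probes, thin-object and
    multislice exit waves, DQE/NTF/Poisson detector model) and non-convex
    Bayesian reconstruction of the specimen transmission function from
    low-dose diffraction data, using a truncated Poisson-likelihood gradient,
    Tikhonov or sparse-denoiser priors, conjugate-gradient updates and
    spectral or random initialization. Includes Fourier ring correlation with
    1-bit and half-bit resolution thresholds, spectral signal-to-noise ratio,
    normalized root-mean-square error, multi-dataset averaging, a synthetic
    macromolecule-in-ice phantom generator, MRC volume import and an
    HDF5-based run container.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    yaml,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
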