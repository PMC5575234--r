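# eptycho

Low-dose cryo electron ptychography in R: a dose-calibrated diffraction
simulator and a non-convex Bayesian reconstructor for the specimen
transmission function, with the evaluation metrics used to quantify
low-dose phase imaging.

## Who this is for

Electron ptychography retrieves quantitative phase images of a specimen
from far-field diffraction patterns recorded while a confined coherent
probe scans overlapping positions. Conventional reconstruction algorithms
need doses far beyond what biological macromolecules tolerate
(≳10³ e⁻/Å²). This package implements the statistical route to the
low-dose regime — 5–80 e⁻/Å², where counts are Poisson-limited at well
under one electron per detector pixel — for method developers and
simulation studies.

## The model

Noise-free measurements follow the design-matrix form

    I = |F Q T|²  = |P T|² ,      y_i ~ Poisson(I_i),

with `T` the vectorized complex transmission function, `Q` the
probe-times-crop operator over the K scan positions and `F` the unitary
2-D DFT. The reconstruction minimizes the Poisson MAP objective

    L(T) = Σ_i [ |p_i T|² − y_i log |p_i T|² ]  +  prior(T)

by Polak–Ribière conjugate gradients on the Wirtinger gradient, with

* gradient **truncation**: measurements with
  `|y_i − I_i| > (α_h/KM)·‖y−I‖₁·|p_i T|/‖T‖₂` are dropped from the
  gradient (α_h ≥ 5) to stabilize the non-convex descent;
* a **Tikhonov** prior `(μ₀/κ)‖∇T‖²` or a **sparse denoiser** prior
  `μ₁‖T − T_sparse‖²`, where `T_sparse` is a periodically refreshed
  denoised copy of the iterate (domain-colored to RGB, wavelet-shrunk,
  mapped back; external denoisers plug in);
* **random** (unit amplitude, N(0.1, 0.1) phase) or **truncated spectral**
  initialization (power iteration on the top-20%-intensity masked
  operator).

The simulator provides three engineered illuminations (400 nm defocused,
ideal Fresnel zone plate, randomized phase-plate probe), thin-object and
multislice exit waves, a contrast-transfer-function arm for cryo-EM
comparison images (including a Zernike π/2 phase plate), dose calibration
(`dose × (step·r_d)²` electrons per pattern) and a
√DQE → Poisson → NTF detector model. Evaluation: Fourier ring correlation
with 1-bit/½-bit thresholds, ring-resolved spectral SNR in dB,
gauge-aligned NRMSE, and multi-dataset averaging with split-half FRC.

## Worked example

```r
library(eptycho)

# reference study: 64x64 phantom, r_d = 1.7 A, 32x32 randomized probe,
# 4-px raster (K = 81), 20 e-/A^2, sparse denoiser prior
setup <- phantom_study_setup(dose = 20)
state <- phantom_study_recon(setup, noise_seed = 1)
phantom_study_metrics(setup, state)[c("nrmse", "halfbit_resolution", "lowfreq_snr_db")]
```

which prints (59 CG iterations, ~2 s on one CPU):

```
$nrmse
[1] 0.07374373
$halfbit_resolution
[1] 9.684907
$lowfreq_snr_db
[1] 0.9801424
```

NRMSE is the gauge-aligned relative L2 error of the recovered transmission
(0.074: the complex field is recovered to ~7%); `halfbit_resolution` is the
half-period at which the phase-map FRC against ground truth drops below the
½-bit information threshold (9.7 Å at 20 e⁻/Å² on this phantom — about 5.7
pixels); `lowfreq_snr_db` is the mean spectral SNR over the lowest quartile
of frequency rings. At 80 e⁻/Å² the same pipeline reaches ~9 Å with higher
low-frequency SNR; at 5 e⁻/Å² only the coarsest features survive.

A file-based pipeline with full provenance (HDF5 container holding counts,
probe, positions, ground truth and the complete configuration) is available
through `cmd_simulate()` / `cmd_reconstruct()` / `cmd_evaluate()` /
`cmd_average()`, or from a shell:

```sh
Rscript inst/cli/eptycho.R simulate --config run.yaml --out data.h5
Rscript inst/cli/eptycho.R reconstruct --data data.h5 --out recon.h5
Rscript inst/cli/eptycho.R evaluate --recon recon.h5 --data data.h5 --out report
```

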