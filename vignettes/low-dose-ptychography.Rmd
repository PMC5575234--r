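---
title: "Low-dose electron ptychography: model, priors and validation conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-dose electron ptychography: model, priors and validation conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eptycho)
```

## The imaging problem

In electron ptychography a confined coherent probe $\psi(\vec r)$ is stepped
across a specimen described by a complex transmission function $T(\vec r)$,
and at each of the $K$ scan positions $\vec r_i$ a far-field diffraction
pattern is recorded,

$$ I_i(\vec q) = \left| \mathcal F\left[\psi(\vec r + \vec r_i)\,
T(\vec r)\right] \right|^2 . $$

Collecting the $K$ patterns of $M$ detector pixels each and vectorizing the
object, the noise-free measurements are $\mathbf I = |\mathbf{FQ}\,
\mathbf T^V|^2 = |\mathbf P\,\mathbf T^V|^2$, where $\mathbf Q$ crops each
illuminated patch and multiplies by the probe, and $\mathbf F$ is the
(unitary) 2-D DFT. `eptycho` implements this design matrix $\mathbf P$ as the
matrix-free pair `op_forward()` / `op_adjoint()`. At biologically tolerable
doses the recorded counts are deep in the Poisson regime (of order 0.5
electrons per detector pixel at 20 e⁻/Å²), which is the regime this package
targets.

The diffraction-limited half-period pixel size is
$r_d = \lambda\,\Delta z / (N_{\rm pix}\, d_{\rm pix})$. The default
geometry fixes $r_d = 1.7\,$Å at 300 keV on a 128-pixel detector; the
detector side is not uniquely determined by the dose bookkeeping alone, and
128² is adopted because 8540 electrons per pattern at 0.52 e⁻/pixel implies
approximately $128^2$ pixels.

## The estimator

Counts follow $y_i \sim \mathrm{Poisson}(I_i(\mathbf T^V))$, giving the
negative log-likelihood

$$ \mathcal L(\mathbf T^V) = \sum_{i=1}^{KM}
\left[ |\mathbf p_i \mathbf T^V|^2 -
y_i \log |\mathbf p_i \mathbf T^V|^2 \right], $$

(`poisson_nll()`; the model intensity is floored at $10^{-12}$ of its mean
nonzero value inside the logarithm so the objective stays finite at zero
model intensity). Two priors are available for the MAP objective:

* **Tikhonov**: $\frac{\mu_0}{\kappa} \lVert \nabla T \rVert^2$ with forward
  differences and replicate boundaries, and
  $\kappa = 8 N_{\rm pix}^2 / (N_m \lVert I \rVert_1)$ scaling the penalty to
  the numerical range of the likelihood. The printed form of the gradient of
  this penalty omits the adjoint difference operators; `tikhonov_prior()`
  implements the true gradient (discrete-Laplacian form), since the
  finite-difference consistency of objective and gradient fails otherwise.
* **Sparse (denoiser) prior**: $\mu_1 \lVert \mathbf T^V -
  \mathbf T^V_{\rm sparse}\rVert^2$, where $\mathbf T^V_{\rm sparse}$ is a
  denoised copy of the current iterate, refreshed every
  `refresh_interval` iterations (default 10; the refresh cadence is a free
  choice). The iterate is domain-colored
  (phase → hue, amplitude → value, saturation 1), the RGB channels are
  denoised, and the channels are mapped back. The bundled default denoiser
  is multi-level Haar wavelet soft-thresholding at the universal threshold
  (five levels by default: the deep decomposition also regularizes the
  coarse spatial frequencies, which ptychographic data with a localized
  probe constrain only weakly through the overlap); any matrix-to-matrix
  channel denoiser (e.g. an external BM3D binding) can be plugged in through
  `refresh_denoiser()`.

Wirtinger gradients are assembled through the operator adjoint. Gradient
**truncation** discards measurements whose residual violates

$$ |y_i - |\mathbf p_i \mathbf T^V|^2| \le \frac{\alpha_h}{KM}
\lVert \mathbf y - \mathbf I \rVert_1
\frac{|\mathbf p_i \mathbf T^V|}{\lVert \mathbf T^V \rVert_2}, $$

with $\alpha_h \ge 5$; the retained fraction is non-decreasing in
$\alpha_h$, and $\alpha_h = \infty$ recovers the plain gradient. The printed
truncated expression is an objective restricted to the retained set;
consistently with the truncated-gradient scheme it originates from, the
package implements the *gradient* restricted to that set.

`reconstruct()` iterates Polak–Ribière conjugate gradients. The search
direction is built from the truncated gradient (plus the prior gradient);
the Armijo backtracking line search acts on the full MAP objective, with a
steepest-descent restart whenever the conjugate direction fails the descent
test. The recorded objective trace is therefore non-increasing — for the
sparse prior, within each denoiser-refresh epoch, since a refresh redefines
the reference and hence the objective.

### Initialization

Two initializers are provided. `random_initialize()` sets $|T| = 1$ with
i.i.d. normal phase (mean 0.1, variance 0.1) and is the default: it is the
reliable choice below roughly 100 e⁻/Å². `spectral_initialize()` implements
the truncated spectral method: power iteration on the object-space operator
$(\mathbf Q^\dagger\mathbf Q)^{-1}\mathbf Q^\dagger \mathbf F^\dagger
\mathbf 1\,\mathbf F\mathbf Q$, where $\mathbf 1$ retains exactly
$\lceil 0.2\,KM \rceil$ of the strongest intensities (the 80th-percentile
rule) and the diagonal $(\mathbf Q^\dagger \mathbf Q)^{-1}$ — the reciprocal
summed illumination — is floored at $10^{-6}$ of its maximum for
unilluminated pixels. The measurement-space operator it is equivalent to has
the same nonzero spectrum; the object-space form is cheaper. An alternative
count-threshold truncation rule exists in the literature with a free
parameter; only the percentile rule is implemented as the default because
the free parameter has no stated value.

## Simulation side

`generate_phantom()` builds a weak-phase macromolecule-in-ice specimen:
Gaussian pseudo-atoms inside a compact particle mask on a weakly fluctuating
ice background, rescaled so the peak phase equals `peak_phase` (default
0.3 rad — a free choice of display scale), with amplitude contrast
$e^{-t/2\Lambda}$ from the inelastic mean free path (defaults: 50 nm
thickness, $\Lambda$ = 350 nm in ice and 280 nm in protein, giving the
minimal transmission contrast characteristic of vitrified specimens).
Pseudo-atoms deliberately replace atomic scattering factors: the package's
validation surface is algorithmic (recovery, metrics), not biophysical
fidelity, and solvent amorphousness is not modelled because its effect at
very low dose is negligible. External volumes can be imported from MRC
mode-2 files (`load_mrc_potential()`).

`multislice_exit_wave()` (simulation side only) alternates per-slice
transmission $\exp(i\sigma V \mathrm{d}z - W \mathrm{d}z)$ with band-limited
Fresnel propagation; the standard 2/3-Nyquist band-limit convention is
adopted for the propagator. The reconstruction forward model remains the
thin-object product, because specimen thickness is negligible at the
resolutions considered. The detector model filters the intensity by
$\sqrt{\rm DQE}$ in Fourier space, draws Poisson counts, and convolves with
the NTF. The bundled DQE/NTF tables are smooth synthetic counting-detector
curves (CSV, editable); on the reconstruction path the response defaults to
identity because heavy detector binning makes DQE nearly constant and NTF
nearly unity.

Dose accounting defines electrons per pattern as
$\text{dose} \times (\text{step} \cdot r_d)^2$, which reproduces
57.8 ≈ 58 e⁻ per 1.7 Å image pixel at 20 e⁻/Å² exactly. The stated
"roughly 3 nm" step at 75% overlap and the 8540 e⁻ per pattern figure imply
slightly different steps (8540 e⁻ corresponds to a 2.07 nm step at this
dose); the package reports both numbers from its actual configuration
rather than forcing agreement. The 75% *area* overlap is interpreted on the
1%-of-maximum intensity support, using the circular-equivalent radius, which
gives a single well-defined integer step.

## Evaluation

`frc()` computes the Fourier ring correlation with the 1-bit and ½-bit
information thresholds from the per-ring sample counts;
`resolution_from_frc()` interpolates the first threshold crossing linearly
and flags curves that never cross; a curve already below threshold at the
first ring carries no resolution information and scores infinity (the ring-0
sample, n = 1, has a degenerate threshold and is never used for
interpolation). `snr_db()` is the ring-summed spectral
power ratio in dB (the curve is plotted against spatial frequency, so
ring-summed power is the natural reading), capped at ±120 dB, after aligning
a single global complex scale — without that alignment the metric is
gauge-dependent. `nrmse()` adopts the gauge-aligned relative L2 definition
$\min_c \lVert T - c\,T_{\rm model}\rVert / \lVert T \rVert$ (the
supplementary definition of the source method is not restated anywhere;
this reading is flagged as an assumption). `average_reconstructions()`
aligns the global scale of each field to the first, averages, and estimates
resolution from the split-half FRC.

All quantitative comparisons exclude a border of a quarter probe side: the
scan border receives one to two orders of magnitude less illumination than
the interior, so its pixels are essentially unconstrained by the data, and
including them only measures the initializer.

## Validation study conditions

The experiments in `tests/` and `scripts/acceptance.R` run at a deliberately
desk-scale problem size (single CPU, minutes): a 64×64 phantom at
$r_d = 1.7$ Å, a 32×32 probe, a 4-pixel raster step ($K = 81$, $KM/N = 20$),
and 150 CG iterations. Within these conditions:

* The **sparse-prior weight** is $\mu_1 = 20$. The method prescribes
  choosing $\mu_0, \mu_1$ by a grid search on the final NRMSE; the published
  values ($\mu_0 = 10^{-2}$, $\mu_1 = 8\times10^{-2}$, kept as the
  `recon_config()` defaults) were calibrated at a much larger problem size
  ($KM \sim 2\times10^6$), where the likelihood term is correspondingly
  larger. Re-running the same grid-search protocol at the 64² study scale
  selects $\mu_1 \approx 20$; with the published value the prior is
  numerically negligible at this scale and the low-dose phase estimate
  remains at the shot-noise floor.
* The **dose sweep** (5 → 20 → 80 e⁻/Å², five Poisson seeds) uses 2-pixel
  FRC rings: on a 48-pixel evaluation window, 1-pixel rings hold as few as
  8 samples and the threshold crossing becomes erratic. Curves that start
  below threshold are scored at the window extent.
* The **probe comparison** (400 nm defocused vs. ideal zone plate vs.
  randomized probe at 20 e⁻/Å²) is asserted as an SNR *ordering* over the
  lowest quartile of frequency rings, not a magnitude: at this field size
  the lowest accessible frequencies are far higher than in a
  several-hundred-Å field, which compresses the contrast between probes.
* The **spectral-initialization benchmark** uses a strong-phase
  (1.5 rad peak) 32² phantom, a focused probe and unit scan step, evaluated
  over the probe-centre-visited region. The spectral estimator needs strong
  scattering contrast: on the default weak-phase phantom its leading
  eigenvalue is nearly degenerate and the initial phase is uninformative —
  consistent with its documented restriction to doses ≳100 e⁻/Å² and
  strongly scattering specimens.

What passing these tests shows — and what it does not: the pipeline
reproduces the *mechanisms* (dose scaling of resolution, probe-design
ordering at low frequency, $1/n$ averaging gains, exact bookkeeping and
gradients) at phantom scale. It does not reproduce the headline resolutions
of macromolecular simulations, which require atomic potential maps from PDB
models and correspondingly large fields; those remain external-data
integration targets.

## Numerical choices and known limitations

* Unitary FFTs everywhere; zero frequency at index (1,1) internally,
  `fftshift2()` for display. Scan positions are integer pixel offsets;
  sub-pixel positions are out of scope.
* Probe support threshold 1% of maximum intensity, with an infinitesimal
  slack so that a threshold of exactly 1 keeps the arg-max set.
* The line search shrinks by factors of 2 with Armijo constant $10^{-4}$
  and at most 40 backtracks; failure to find an admissible step terminates
  the iteration (treated as converged to line-search precision).
* The global phase gauge is not fixed during iteration; every comparison to
  truth aligns a single global complex scalar first.
* Probe retrieval, position refinement, partial coherence and 3-D
  reconstruction are out of scope; the probe is treated as known exactly.
* HSV round-tripping is exact except at zero amplitude, where hue is
  undefined; iterates with |T| = 0 pixels would lose phase there.

## A worked example

```{r example, eval = FALSE}
setup <- phantom_study_setup(dose = 20)
state <- phantom_study_recon(setup, noise_seed = 1)
phantom_study_metrics(setup, state)[c("nrmse", "halfbit_resolution",
                                      "lowfreq_snr_db")]
```

See the README for the command-line surface (`inst/cli/eptycho.R`) and the
HDF5 container layout written by `cmd_simulate()`.
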