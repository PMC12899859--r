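---
title: "Methods: quantitative optical property estimation for OCT phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative optical property estimation for OCT phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octoquant)
```

## Scope

octoquant estimates optical attenuation and scattering coefficients of
thin-film calibration phantoms from spectral-domain OCT data, and
characterises the imaging system itself. Five analysis layers work
together: depth-resolved A-scan decay fitting, spectrophotometric
coefficient models (Beer–Lambert and the diffusion approximation),
Lorenz–Mie scattering for microsphere suspensions, Monte Carlo photon
transport through a scattering slab, and OCT system-performance metrics.
Because real phantom acquisitions are bulky and instrument-bound, a
synthetic-data layer generates every input the analysis needs with full
ground-truth bookkeeping; all statements below about estimator accuracy
refer to what the test suite computes on those synthetic inputs.

## The two-way decay model

OCT probes a sample in reflection: light travels to depth $z$ and back, so
a medium with effective attenuation coefficient $\mu$ (mm$^{-1}$) attenuates
the detected intensity at twice the single-pass rate. The package models
peak backscatter intensities versus depth as

$$I(z) = (I_0 - C)\, e^{-2\mu (z - z_0)} + C,$$

where $z_0$ is the first-surface depth, $I_0$ the intensity at the surface,
and $C$ a constant residual-background term used instead of explicit
background subtraction. Fitting the single-pass model instead multiplies
the recovered coefficient by exactly two, which the tests assert as an
algebraic identity.

The estimation pipeline (`estimate_attenuation()`) runs, in order: ROI
extraction, 2-D Gaussian denoising, lateral averaging, Savitzky–Golay
smoothing, peak detection, and constrained nonlinear least squares. The
stage order is recorded in the returned fit. Defaults (all in
`run_config()`):

| parameter | default | units | why |
|---|---|---|---|
| ROI | x 50–100, y 40–900 | px | homogeneous lateral band, skips the zero-delay rows |
| Gaussian sigma | 1 | px | speckle pre-smoothing without washing out 2-px interface peaks |
| Savitzky–Golay | window 11, order 3 | samples | polynomial-preserving smoothing of the averaged A-scan |
| peak spacing | 20 | px | below the ~27 px interface period of the reference films |
| peak prominence | 0.005 | — | on the max-normalised A-scan (see below) |
| valid depth | 2.5 | mm | effective imaging range of the system |
| axial pitch | 0.003 | mm/px | 3.0 mm imaging depth over a 1000-px axis |
| anisotropy g | 0.9 | — | strongly forward-scattering media |

Numerical choices that were genuinely open:

* **Prominence scale.** The prominence threshold is interpreted on the
  max-normalised A-scan, since raw OCT intensities carry arbitrary units;
  the normalisation constant is kept in the report.
* **$z_0$ fixed, not fitted.** The model is degenerate in $(I_0, z_0)$
  jointly; the first detected peak defines the surface reference.
* **Absolute depth.** The ROI's axial offset is preserved, so the 2.5 mm
  validity cut refers to true depth, not ROI-relative depth.
* **Optimiser.** Levenberg–Marquardt with bounds $\mu \in [0, 50]$,
  $C \in [0, \min I]$, $I_0 \ge 0$; starts at $I_0 = $ first peak,
  $C = \tfrac12\min I$, $\mu$ from the first/last-peak log-slope. At
  exactly $\mu = 0$ the Jacobian column for $C$ vanishes, so the start is
  floored at $\mu = 10^{-3}$; exactly flat peak sets short-circuit to the
  $\mu = 0$, $C = 0$ solution (any $\mu$ fits a flat set once $I_0 = C$,
  so the zero-decay representative is reported).
* **Tied peaks.** Equal-height peaks closer than the spacing keep the
  shallower one: the surface-referenced fit favours the first interface.
* **No surface flattening.** The rectangular ROI is used as-is; phantoms
  are mounted flat, and flattening would add an unvalidated resampling
  step.

## Spectrophotometric models

With integrating-sphere reflectance and transmittance fractions $R$ and
$T$, the absorbed fraction is $A = 1 - R - T$. The Beer–Lambert law
$T = e^{-\mu_t d}$ gives the total attenuation coefficient
$\mu_t = -\ln(T)/d$ for a film of thickness $d$. In the multiple-scattering
regime the diffusion approximation applies,
$\mu_{eff}^2 = 3\mu_a(\mu_a + \mu_s')$ with $\mu_s' = (1-g)\mu_s$, inverted
as $\mu_s = (\mu_{eff}^2 - 3\mu_a^2)/(3\mu_a(1-g))$.

Two routes from $(\mu_{eff}, \mu_a)$ to $\mu_s$ are deliberately exposed:

* `mu_s_from_diffusion()` — the diffusion-approximation inversion above,
  the physically documented model;
* `mu_s_subtractive()` — the simple split $\mu_s = \mu_{eff} - \mu_a$,
  which is what published per-sample coefficient tables in this problem
  area actually follow.

The two disagree by large factors at $g = 0.9$ (the diffusion inversion
amplifies $\mu_{eff}^2/\mu_a$), and a table built with one cannot be
reproduced by the other; reports must state which route was used. The
package reproduces tabulated decompositions with the subtractive route and
keeps the diffusion route for model-based work.

Thickness-series fitting (`fit_mu_eff_vs_thickness()`) estimates
$\mu_{eff}$ by least squares on $-\ln T$ versus $d$ constrained through
the origin, which encodes $T(0) = 1$ exactly and stabilises small-$T$
rows; $R^2$ is reported in the same log domain against the through-origin
null. Wavelength selection ("at 840 nm") is a nearest-row lookup with a
±2.5 nm tolerance, half a 5 nm instrument resolution step.

## Mie scattering

`mie_efficiencies()` evaluates the Lorenz–Mie series with the standard
logarithmic-derivative downward recurrence (stable for complex index) and
Riccati–Bessel upward recurrences, truncated at
$\lceil x + 4x^{1/3} + 2\rceil$ terms. Conventions for embedded spheres:
size parameter $x = \pi d\, n_{med}/\lambda_0$ (wavelength in the medium)
and relative index $m = n_{sph}/n_{med}$. For the reference suspension
(1 µm spheres of index 1.8 in an index-1.6 host at 840 nm) this gives
$Q_{sca} = 1.04531$ and an asymmetry parameter $g = 0.9231$; the vacuum
convention would give a fourfold smaller $Q_{sca}$ and is clearly not what
suspension calibration tables use. The series is verified in the tests
against frozen values from an independent direct Riccati–Bessel
implementation on a 24-point $(x, m)$ grid at $10^{-6}$ relative
tolerance, plus the Rayleigh $x^4$ limit. The suspension coefficient
$\mu_s = N \, Q_{sca}\pi r^2$ is exactly linear in concentration $N$.

## Monte Carlo photon transport

`run_photon_transport()` propagates photon packets through a homogeneous
slab: exponential step lengths with rate $\mu_t = \mu_s + \mu_a$,
Henyey–Greenstein scattering (by default with $g$ set to the Mie asymmetry
parameter of the medium, since the suspension itself does not prescribe a
transport phase function and HG keeps sampling closed-form), continuous
absorption $\mu_a/\mu_t$ per event, and unpolarised Fresnel
reflection/refraction at both faces against air. Choices worth recording:

* **Boundary weight splitting.** A packet reaching a face deterministically
  splits: the Fresnel-transmitted fraction is tallied outside, the
  reflected fraction continues. This removes one Bernoulli draw of
  variance per boundary event.
* **Roulette with an exact ledger.** Packets below weight $10^{-4}$
  survive with probability 0.1 and a tenfold boost. The roulette's weight
  residual (killed weight minus survival boosts) is folded into the
  absorbed tally: its expectation is zero, so the absorbed estimate stays
  unbiased, while absorbed + transmitted + back-reflected sums to 1
  exactly — the conservation identity the tests assert at $10^{-6}$.
* **Ballistic shortcut.** A slab with $\mu_t = 0$ is handled analytically:
  transmission $(1-R_F)^2$ through the two faces, with multiple internal
  reflections neglected (they contribute $O(R_F^2) \approx 0.3\%$ and are
  not part of the single-pass reference model).
* **Distance-0 tally.** Depth curves are normalised to a reference that
  sums the plane-0 downward crossings and the total back-reflected weight,
  so the reference exceeds the incident power whenever anything reflects —
  matching how detector-side simulations that capture reflected light
  report their 100% point. Later bins are plain downward plane crossings.
* **Plane tallies.** Detectors are full lateral planes with no
  numerical-aperture clipping; the ray-tracing detector optics such curves
  are sometimes produced with are proprietary and unspecified.

The test suite checks the sampler's mean cosine, the ballistic Beer–Lambert
law $e^{-\mu_s z}$ in an index-matched absorption-free slab at the 3-s.e.
level, the Fresnel-limited transmission of a clear slab, seed determinism,
and the monotone steepening of the depth curve with $\mu_s$.

## System metrics

* `snr_db()` uses the $10\log_{10}$ amplitude-ratio form as the reporting
  convention, with the conventional $20\log_{10}$ available behind a flag:
  published system characterisations in this area print the factor-10
  form, and the package follows what it must reproduce.
* `axial_resolution()` drops samples shallower than 0.02 mm (residual
  zero-order reflection), then fits a Gaussian to the dominant peak;
  FWHM $= 2\sqrt{2\ln 2}\,\sigma$.
* `rolloff_6db()` fits sensitivity-versus-depth by linear regression in
  the dB domain — equivalent to a single-exponential amplitude decay but
  convex and unambiguous — and reports where the fit falls 6 dB below its
  value at the shallowest measured depth. Slopes indistinguishable from
  zero (≥ −10⁻⁹ dB/mm) are rejected as non-decreasing.
* `imaging_depth()` is the exact sum of visible step heights of a
  staircase phantom; how many steps are visible is an observer input, not
  an image computation. For the non-uniform reference staircase the
  package carries rises of 0.6+0.5+0.4+0.3+0.3+0.2 mm: the reported total
  (2.3 mm) and visible-step count (6) jointly determine this list, and
  the commonly printed five-term expression for it is internally
  inconsistent (it sums to 2.0).

## What the synthetic data does and does not emulate

`gen_bscan()` produces B-scans whose noise-free lateral mean follows the
two-way decay model exactly, with optional interface peaks of 2 px width
riding on the envelope at a configurable layer period (emulating stacked
thin-film interfaces), unit-mean exponential multiplicative speckle (fully
developed speckle intensity statistics, chosen because it is
mean-preserving: lateral averaging then converges to the true envelope and
the decay fit is unbiased), and additive Gaussian background. The
interface amplitude between peaks (`interface_floor = 0.15`) is a free
parameter; reference phantoms' interface reflectivity profiles are not
characterised.

Test fixtures use a layer period of 0.081 mm — 27 exact pixels at the
0.003 mm pitch, and within the 0.08–0.082 mm single-layer thicknesses of
the reference films. A grid-commensurate period makes every interface peak
sample identically, so noise-free recovery is exact; an incommensurate
period adds a small (≈0.1%) sampling jitter to peak amplitudes, which is a
property of discrete sampling, not of the estimator.

Not emulated: confocal gating and focus-dependent signal shaping,
depth-dependent sensitivity roll-off coupled into B-scans, field-summed
(partially developed) speckle, polarisation, and real interface roughness.
Consequently, passing recovery tests shows the estimator chain is correct
and unbiased under the stated noise model — not that fitted coefficients
from a real instrument are free of the geometry-induced biases (confocal
and roll-off) that depth-decay methods are known to carry; correcting for
those is out of scope and fitted OCT coefficients should be interpreted
within the same modality.

`gen_psf_ascan()`, `gen_rolloff()` and `gen_spectro_series()` are direct
forward models of the corresponding estimators' assumptions (Gaussian
peak; linear-in-dB decay; Beer–Lambert transmittance with constant surface
reflectance, constrained so $R + T \le 1$ always holds). The roll-off
noise-robustness test uses a 251-point curve: at 0.5 dB noise that makes
the 3-sigma slope uncertainty smaller than the 5% acceptance band, a
precision-budget requirement of the check itself.

## Problem sizes and reproducibility

The shipped checks use: 1000 × 500 px B-scans with 500-column lateral
averaging, a recovery grid of $\mu \in \{0.25, 0.5, 1, 2, 4\}$ mm$^{-1}$
with 20 speckled replicates each, Monte Carlo runs of $10^5$ packets
(default $10^6$ for production curves), and 200-replicate noise studies
for the thickness fit. One integer seed drives each generator through R's
default Mersenne-Twister stream, restored after use; identical seeds give
bit-identical outputs, which the tests assert.

## Known limitations

* The fitted OCT $\mu$ is an *effective* coefficient of the same modality
  and geometry that produced the image; transmission-derived coefficients
  of the same material can differ by factors of several, systematically.
* The diffusion inversion needs $\mu_a > 0$ and
  $\mu_{eff}^2 \ge 3\mu_a^2$; absorption coefficients are user inputs, not
  estimated.
* The Monte Carlo slab is homogeneous and unbounded laterally; structured
  or heterogeneous media (the regime where simple analytical models break
  down) would need a voxelised extension.
* Peak detection assumes discrete interface peaks; continuously scattering
  media should be fitted on the smoothed A-scan envelope instead of
  detected peaks.
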