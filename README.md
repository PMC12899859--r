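# octoquant

Quantitative optical property estimation for spectral-domain OCT phantom
imaging.

## The problem

Optical coherence tomography (OCT) images are usually read
morphologically, but the rate at which the backscattered signal decays
with depth carries intrinsic material information: the scattering
coefficient μs and the effective attenuation coefficient μeff. Extracting
these reliably requires validation against phantoms with controlled
optics — thin-film stacks of known layer thickness and microsphere
suspensions of known concentration — and a characterised imaging system.
octoquant is for physicists and image-analysis engineers who need that
whole chain in one place: the depth-decay estimator, the
spectrophotometric reference models, Mie theory for the phantom design,
a Monte Carlo photon-transport simulator, OCT system metrics, and a
synthetic-data generator with ground truth for every estimator.

## The models at the core

**Two-way A-scan decay.** Peak backscatter intensities versus depth are
fitted with

    I(z) = (I0 − C)·exp(−2μ(z − z0)) + C

where the factor 2 is the OCT round trip, z0 the first-surface depth and C
a residual-background term. The pipeline is: rectangular ROI → Gaussian
denoise (σ = 1 px) → lateral mean → Savitzky–Golay (11/3) → peak detection
(spacing 20 px, prominence 0.005 on the normalised A-scan, depth ≤ 2.5 mm)
→ constrained nonlinear least squares, with R² reported.

**Spectrophotometry.** A = 1 − R − T; Beer–Lambert μt = −ln(T)/d; the
diffusion approximation μeff² = 3μa(μa + (1−g)μs); and the subtractive
split μs = μeff − μa that per-sample coefficient tables follow. Both μs
routes are exposed and labelled.

**Mie + Monte Carlo.** Lorenz–Mie efficiencies (log-derivative
recurrence) with size parameter x = πd·n_med/λ0 give μs = N·Qsca·πr²,
exactly linear in concentration N; a Henyey–Greenstein photon-packet
random walk with Fresnel boundaries produces depth-resolved relative
intensity curves normalised to a distance-0 tally that includes reflected
light.

**System metrics.** SNR = 10·log10(A_signal/σ_noise), Gaussian-fit axial
resolution (FWHM), linear-in-dB sensitivity roll-off with its 6 dB depth,
and step-phantom imaging depth ID = Σ hᵢ.

## Worked example

Generate a speckled phantom B-scan with a known coefficient
(μ = 1.224 mm⁻¹, the kind of value a moderately scattering polymer film
shows in OCT), then recover it:

```r
library(octoquant)

truth <- ground_truth(mu = 1.224, i0 = 1, c0 = 0.01, z0 = 0.12,
                      speckle = TRUE, noise_sigma = 0.001, seed = 42)
bscan <- gen_bscan(truth, shape = c(1000L, 500L), layer_period = 0.081)
bscan
#> <bscan> 1000 x 500 px (3.000 x 2.000 mm), axial pitch 0.003 mm/px [synthetic mu=1.224]

fit <- estimate_attenuation(bscan, run_config(roi = roi_spec(0, 500, 40, 900)))
fit
#> <attenuation_fit> mu = 1.2826 /mm (two-way), I0 = 0.6653, C = 0.01651, z0 = 0.2010 mm, R2 = 0.99922, 24 peaks
#>   pipeline: extract_roi -> denoise_gaussian -> lateral_mean -> savgol_smooth -> detect_peaks -> fit_two_way_decay
```

The recovered μ = 1.2826 mm⁻¹ sits 4.8% above the ground truth — typical
single-image speckle scatter; across replicates the estimator is unbiased
and its median error stays under 10% (the test suite measures this on a
5-value × 20-replicate grid). z0 is the first *detected* interface
(0.201 mm: the surface peak at 0.12 mm falls on the A-scan's first sample,
where no local maximum exists), and R² is the goodness of the peak-decay
fit.

Mie design of a scattering suspension and the reference tables:

```r
scattering_coefficient(mie_medium(sphere_diameter = 1, n_sphere = 1.8,
                                  n_medium = 1.6, concentration = 1.25e6,
                                  wavelength_vacuum = 840))
#> [1] 1.026234

man <- reproduce(run_config())
man$table1$imaging_depth_mm
#> [1] 2.4 2.5 2.4 2.3
```

`reproduce()` rebuilds all reference tables (imaging depths, the
μs-versus-concentration grid, and both coefficient decompositions) from
configuration alone and, given an output directory, writes them as CSV
with a seed- and version-stamped JSON manifest. A thin command-line
wrapper is installed at `inst/cli/octoquant.R`
(`Rscript octoquant.R <synth|mie|mc|fit-ascan|metrics|reproduce> ...`).

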