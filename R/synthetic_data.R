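#' Ground truth for a synthetic speckled B-scan
#'
#' Parameters of the two-way decay model
#' \eqn{I(z) = (I_0 - C)\exp(-2\mu(z - z_0)) + C} that the B-scan generator
#' embeds, plus the noise model. The factor 2 reflects the round-trip path
#' of OCT light.
#'
#' @param mu Decay (effective attenuation) coefficient in 1/mm, >= 0.
#' @param i0 Peak intensity at the first surface (arbitrary units).
#' @param c0 Baseline intensity, with \code{i0 > c0 >= 0}.
#' @param z0 First-surface depth in mm, >= 0.
#' @param speckle Logical: multiply each pixel by unit-mean exponential
#'   speckle (fully developed speckle statistics).
#' @param noise_sigma Standard deviation of additive Gaussian background.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return An object of class \code{"ground_truth"}.
#' @export
ground_truth <- function(mu = 1.224, i0 = 1, c0 = 0.01, z0 = 0.12,
                         speckle = TRUE, noise_sigma = 0.001, seed = 1L) {
  if (mu < 0) stop("mu must be >= 0", call. = FALSE)
  if (!(i0 > c0 && c0 >= 0)) stop("need i0 > c0 >= 0", call. = FALSE)
  if (z0 < 0) stop("z0 must be >= 0", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(mu = mu, i0 = i0, c0 = c0, z0 = z0,
                 speckle = isTRUE(speckle), noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# Evaluate the set.seed()-based block reproducibly without disturbing the
# caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic speckled B-scan with known decay
#'
#' The noise-free lateral mean follows the two-way decay model of
#' \code{\link{ground_truth}} for depths at and below the first surface
#' \code{z0}, and equals the baseline above it. When \code{layer_period} is
#' given, narrow Gaussian interface peaks (s.d. 2 px) ride on the decay
#' envelope at that spacing, emulating the stacked thin-film interfaces a
#' peak detector locks onto; the envelope is attained exactly at the peak
#' centres and drops to \code{interface_floor} of the decaying component
#' between them.
#'
#' @param truth A \code{\link{ground_truth}}.
#' @param shape Integer vector \code{c(rows, cols)}.
#' @param axial_pitch Axial calibration, mm per pixel.
#' @param layer_period Interface spacing in mm, or NULL for a continuous
#'   scattering medium.
#' @param interface_floor Fraction of the decaying component retained
#'   between interface peaks (free generator parameter; the reference
#'   phantoms' interface reflectivity profile is not characterised).
#' @param lateral_pitch Lateral calibration, mm per pixel.
#' @return A \code{\link{bscan}}.
#' @export
gen_bscan <- function(truth, shape = c(1000L, 1000L), axial_pitch = 0.003,
                      layer_period = NULL, interface_floor = 0.15,
                      lateral_pitch = 0.004) {
  stopifnot(inherits(truth, "ground_truth"))
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (nr < 1L || nc < 1L) stop("shape must be positive", call. = FALSE)
  z <- (seq_len(nr) - 1) * axial_pitch
  if (truth$z0 > z[nr])
    stop("z0 lies beyond the image depth range", call. = FALSE)
  decay <- (truth$i0 - truth$c0) * exp(-2 * truth$mu * pmax(z - truth$z0, 0))
  decay[z < truth$z0] <- 0
  if (!is.null(layer_period)) {
    if (layer_period <= 0) stop("layer_period must be > 0", call. = FALSE)
    w <- 2 * axial_pitch                      # interface peak s.d., 2 px
    centers <- seq(truth$z0, z[nr], by = layer_period)
    bump <- rep(0, nr)
    for (zc in centers) bump <- pmax(bump, exp(-(z - zc)^2 / (2 * w^2)))
    comb <- interface_floor + (1 - interface_floor) * bump
    decay <- decay * comb
  }
  profile <- truth$c0 + decay
  img <- with_seed(truth$seed, {
    m <- matrix(rep(profile, nc), nrow = nr)
    if (truth$speckle)
      m <- m * matrix(stats::rexp(nr * nc), nrow = nr)
    if (truth$noise_sigma > 0)
      m <- m + matrix(stats::rnorm(nr * nc, sd = truth$noise_sigma),
                      nrow = nr)
    m
  })
  img[img < 0] <- 0
  bscan(img, axial_pitch = axial_pitch, lateral_pitch = lateral_pitch,
        label = sprintf("synthetic mu=%.4g", truth$mu))
}

#' Generate a synthetic mirror point-spread-function A-scan
#'
#' A Gaussian main peak of exactly the requested full width at half maximum
#' centred at \code{center}, with an optional residual zero-order
#' (autocorrelation) peak at depth 0 for exclusion testing, and optional
#' additive Gaussian noise.
#'
#' @param fwhm Full width at half maximum of the main peak, in micrometres.
#' @param center Main peak depth in mm.
#' @param axial_pitch Sample spacing in mm.
#' @param n Number of depth samples.
#' @param noise_sigma Additive Gaussian noise s.d. (peak amplitude is 1).
#' @param zero_order_amp Amplitude of the residual zero-order peak at depth
#'   0 (0 disables it).
#' @param seed Integer seed for the noise.
#' @return An \code{\link{ascan}}.
#' @export
gen_psf_ascan <- function(fwhm = 16.30, center = 0.094, axial_pitch = 0.003,
                          n = 334L, noise_sigma = 0, zero_order_amp = 0,
                          seed = 1L) {
  if (fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  z <- (seq_len(n) - 1) * axial_pitch
  if (center < 0 || center > z[n])
    stop("center lies outside the depth range", call. = FALSE)
  sigma_mm <- (fwhm / 1000) / (2 * sqrt(2 * log(2)))
  y <- exp(-(z - center)^2 / (2 * sigma_mm^2))
  if (zero_order_amp > 0)
    y <- y + zero_order_amp * exp(-z / (2 * axial_pitch))
  if (noise_sigma > 0)
    y <- y + with_seed(seed, stats::rnorm(n, sd = noise_sigma))
  y[y < 0] <- 0
  ascan(z, y)
}

#' Generate a synthetic sensitivity roll-off curve
#'
#' Noise-free sensitivity is linear in dB,
#' \eqn{S(z) = s_0 - 6 z / z_{6dB}}, i.e. a single-exponential amplitude
#' decay whose 6 dB depth is \code{z6db}.
#'
#' @param depths Depth grid in mm.
#' @param s0 Sensitivity at zero depth, dB.
#' @param z6db Depth at which sensitivity has dropped 6 dB, mm (> 0).
#' @param noise_sigma Additive Gaussian noise in dB.
#' @param seed Integer seed for the noise.
#' @return A \code{"rolloff_curve"} data frame with columns \code{depth}
#'   and \code{sensitivity}.
#' @export
gen_rolloff <- function(depths = seq(0, 2.5, by = 0.05), s0 = 32.4,
                        z6db = 1.81, noise_sigma = 0, seed = 1L) {
  if (z6db <= 0) stop("z6db must be > 0", call. = FALSE)
  s <- s0 - 6 * depths / z6db
  if (noise_sigma > 0)
    s <- s + with_seed(seed, stats::rnorm(length(depths), sd = noise_sigma))
  rolloff_curve(depths, s)
}

#' Generate a spectrophotometric thickness series from known optics
#'
#' Forward Beer-Lambert model: transmittance \eqn{T(d) = e^{-\mu_t d}} with
#' a constant surface reflectance, so that the absorption fraction
#' \eqn{1 - R - T} stays in [0, 1]. Optional multiplicative measurement
#' noise with coefficient of variation \code{noise_cv} perturbs T.
#'
#' @param mu_t Total attenuation coefficient in 1/mm (>= 0). An
#'   \code{\link{optical_properties}} object may be given instead, in which
#'   case its \code{mu_t} (fallback \code{mu_eff}) is used.
#' @param thicknesses Sample thicknesses in mm, all > 0.
#' @param wavelength Wavelength in nm recorded with each row.
#' @param surface_reflectance Constant reflectance fraction.
#' @param noise_cv Multiplicative noise coefficient of variation on T.
#' @param seed Integer seed for the noise.
#' @return A \code{\link{spectro_series}}.
#' @export
gen_spectro_series <- function(mu_t, thicknesses = (1:6) * 0.07,
                               wavelength = 840,
                               surface_reflectance = 0.05,
                               noise_cv = 0, seed = 1L) {
  if (inherits(mu_t, "optical_properties")) {
    mu_t <- if (!is.na(mu_t$mu_t)) mu_t$mu_t else mu_t$mu_eff
  }
  if (!is.finite(mu_t) || mu_t < 0) stop("mu_t must be >= 0", call. = FALSE)
  if (any(thicknesses <= 0)) stop("thicknesses must be > 0", call. = FALSE)
  tr <- exp(-mu_t * thicknesses)
  if (noise_cv > 0) {
    tr <- tr * with_seed(seed, exp(stats::rnorm(length(tr), sd = noise_cv) -
                                     noise_cv^2 / 2))
    tr <- pmin(tr, 1)
  }
  if (any(surface_reflectance + tr > 1))
    stop("surface_reflectance + max transmittance exceeds 1; ",
         "reduce the reflectance or use thicker samples", call. = FALSE)
  spectro_series(thicknesses, rep(wavelength, length(thicknesses)),
                 rep(surface_reflectance, length(thicknesses)), tr)
}

#' Step-phantom geometry
#'
#' Describes a staircase calibration phantom: per-step rises, a common step
#' width, and the overall bounding box. Lateral extent beyond the stepped
#' region is rendered as the zero-height base plateau.
#'
#' @param step_heights Per-step rises in mm, all > 0.
#' @param step_width Lateral width of each step in mm.
#' @param total_length Phantom length in mm (must fit all steps).
#' @param total_height Phantom bounding height in mm.
#' @return An object of class \code{"step_phantom_spec"}.
#' @export
step_phantom_spec <- function(step_heights = rep(0.4, 6), step_width = 1.0,
                              total_length = 12.5, total_height = 3.0) {
  if (any(step_heights <= 0)) stop("step heights must be > 0", call. = FALSE)
  if (step_width <= 0) stop("step_width must be > 0", call. = FALSE)
  if (length(step_heights) * step_width > total_length + 1e-9)
    stop("steps do not fit in total_length", call. = FALSE)
  if (sum(step_heights) > total_height + 1e-9)
    stop("cumulative height exceeds total_height", call. = FALSE)
  structure(list(step_heights = as.numeric(step_heights),
                 step_width = step_width, total_length = total_length,
                 total_height = total_height),
            class = "step_phantom_spec")
}

#' Render a step phantom as a synthetic B-scan
#'
#' Piecewise-constant surface with sharp vertical edges: step i's top sits
#' at cumulative height \eqn{\sum_{j \le i} h_j} above the base, so the
#' surface row encodes the staircase exactly. The surface is drawn as a
#' bright (1.0) line over a dim (0.2) bulk.
#'
#' @param spec A \code{\link{step_phantom_spec}}.
#' @param axial_pitch,lateral_pitch Calibration in mm per pixel.
#' @return A \code{\link{bscan}}.
#' @export
gen_step_bscan <- function(spec, axial_pitch = 0.003, lateral_pitch = 0.004) {
  stopifnot(inherits(spec, "step_phantom_spec"))
  nr <- ceiling(spec$total_height / axial_pitch) + 1L
  nc <- ceiling(spec$total_length / lateral_pitch)
  img <- matrix(0, nr, nc)
  cum <- cumsum(spec$step_heights)
  n <- length(cum)
  x <- (seq_len(nc) - 0.5) * lateral_pitch        # column centres, mm
  step_idx <- pmin(floor(x / spec$step_width) + 1L, n + 1L)
  height <- c(cum, 0)[step_idx]                    # beyond steps: base level
  surf_row <- round((spec$total_height - height) / axial_pitch) + 1L
  surf_row <- pmin(pmax(surf_row, 1L), nr)
  for (j in seq_len(nc)) {
    img[surf_row[j], j] <- 1
    if (surf_row[j] < nr) img[(surf_row[j] + 1L):nr, j] <- 0.2
  }
  bscan(img, axial_pitch = axial_pitch, lateral_pitch = lateral_pitch,
        label = "synthetic step phantom")
}

#' Surface depth profile of a B-scan
#'
#' Depth (mm) of the brightest pixel in each column; on step-phantom images
#' this recovers the rendered staircase.
#'
#' @param x A \code{\link{bscan}}.
#' @return Numeric vector of per-column surface depths in mm.
#' @export
surface_profile <- function(x) {
  stopifnot(inherits(x, "bscan"))
  rows <- apply(x$intensity, 2L, which.max)
  (rows - 1) * x$axial_pitch
}
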