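#' Sensitivity roll-off curve container
#'
#' @param depth Strictly increasing depths in mm.
#' @param sensitivity Sensitivities in dB (finite).
#' @return A data frame of class \code{"rolloff_curve"}.
#' @export
rolloff_curve <- function(depth, sensitivity) {
  depth <- as.numeric(depth); sensitivity <- as.numeric(sensitivity)
  if (length(depth) != length(sensitivity))
    stop("depth and sensitivity lengths differ", call. = FALSE)
  if (any(diff(depth) <= 0))
    stop("depth must be strictly increasing", call. = FALSE)
  if (any(!is.finite(sensitivity)))
    stop("sensitivities must be finite", call. = FALSE)
  structure(data.frame(depth = depth, sensitivity = sensitivity),
            class = c("rolloff_curve", "data.frame"))
}

#' Signal-to-noise ratio in dB
#'
#' \eqn{SNR = 10 \log_{10}(A_{signal}/\sigma_{noise})}: the ratio of the
#' mirror-peak amplitude to the standard deviation of the background.
#' The conventional amplitude-ratio form uses a factor 20; both are
#' exposed, with the factor-10 form as the default reporting convention
#' here.
#'
#' @param signal_peak Peak signal amplitude (> 0).
#' @param noise_sd Background standard deviation (> 0), same units.
#' @param convention \code{"10log10"} (default) or \code{"20log10"}.
#' @return SNR in dB.
#' @export
snr_db <- function(signal_peak, noise_sd,
                   convention = c("10log10", "20log10")) {
  convention <- match.arg(convention)
  if (any(signal_peak <= 0) || any(noise_sd <= 0))
    stop("signal and noise must be > 0", call. = FALSE)
  fac <- if (convention == "10log10") 10 else 20
  fac * log10(signal_peak / noise_sd)
}

#' Axial resolution from a mirror PSF A-scan
#'
#' Excludes the residual zero-order reflection near zero delay, then fits a
#' Gaussian to the dominant reflection peak by nonlinear least squares and
#' reports its full width at half maximum,
#' \eqn{FWHM = 2\sqrt{2\ln 2}\,\sigma}, in micrometres, together with the
#' peak depth in mm.
#'
#' @param psf An \code{\link{ascan}} of the mirror point-spread function.
#' @param exclude_zero_order Drop samples shallower than
#'   \code{zero_order_max_depth} before fitting.
#' @param zero_order_max_depth Zero-order exclusion depth in mm.
#' @return List with \code{fwhm_um}, \code{peak_depth_mm},
#'   \code{sigma_um}.
#' @export
axial_resolution <- function(psf, exclude_zero_order = TRUE,
                             zero_order_max_depth = 0.02) {
  stopifnot(inherits(psf, "ascan"))
  z <- psf$depth; y <- psf$intensity
  if (exclude_zero_order) {
    keep <- z >= zero_order_max_depth
    z <- z[keep]; y <- y[keep]
  }
  if (length(z) < 5L || max(y) <= 0)
    stop("no usable peak after zero-order exclusion", call. = FALSE)
  i <- which.max(y)
  ymax <- y[i]
  bg <- stats::median(y)
  if (ymax < bg + 5 * (stats::mad(y) + .Machine$double.eps))
    stop("no peak detected above the noise background", call. = FALSE)
  half <- y >= ymax / 2
  sigma0 <- max(sum(half) * (z[2] - z[1]), z[2] - z[1]) / 2.3548
  df <- data.frame(z = z, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ a * exp(-(z - mu)^2 / (2 * s^2)),
    data = df,
    start = list(a = ymax, mu = z[i], s = sigma0),
    lower = c(a = 0, mu = min(z), s = (z[2] - z[1]) / 10),
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 500))
  p <- stats::coef(fit)
  list(fwhm_um = unname(2 * sqrt(2 * log(2)) * p["s"] * 1000),
       peak_depth_mm = unname(p["mu"]),
       sigma_um = unname(p["s"] * 1000))
}

#' 6 dB sensitivity roll-off depth
#'
#' Fits the sensitivity-versus-depth curve with a linear model in the dB
#' domain (equivalent to a single-exponential amplitude decay) and returns
#' the depth at which the fitted sensitivity has dropped 6 dB below its
#' value at the shallowest measured depth. An \code{"extrapolated"}
#' attribute flags results beyond the measured range.
#'
#' @param curve A \code{\link{rolloff_curve}} with >= 4 points.
#' @return The 6 dB depth in mm.
#' @export
rolloff_6db <- function(curve) {
  stopifnot(inherits(curve, "rolloff_curve"))
  if (nrow(curve) < 4L) stop("need at least 4 points", call. = FALSE)
  fit <- stats::lm(sensitivity ~ depth, data = curve)
  slope <- stats::coef(fit)[["depth"]]
  if (slope >= -1e-9)
    stop("sensitivity does not decrease with depth", call. = FALSE)
  z_ref <- curve$depth[1]
  z6 <- z_ref - 6 / slope
  if (z6 > max(curve$depth)) {
    oq_log("6 dB depth %.3f mm extrapolates beyond the measured range", z6)
    attr(z6, "extrapolated") <- TRUE
  }
  z6
}

#' Imaging depth of a step phantom
#'
#' The cumulative height of the visible steps,
#' \eqn{ID = \sum_{i=1}^{n} h_i}; the number of visible steps is an input
#' judgement, not computed from images.
#'
#' @param step_heights Heights of the visible steps in mm, all >= 0.
#' @return Imaging depth in mm.
#' @export
imaging_depth <- function(step_heights) {
  if (length(step_heights) == 0L) return(0)
  if (any(step_heights < 0))
    stop("step heights must be >= 0", call. = FALSE)
  sum(step_heights)
}

#' System performance report
#'
#' Bundles the headline OCT system metrics.
#'
#' @param snr_db Signal-to-noise ratio, dB.
#' @param axial_resolution_um Axial resolution FWHM, micrometres.
#' @param peak_depth_mm Mirror peak depth, mm.
#' @param z6db_mm 6 dB sensitivity roll-off depth, mm.
#' @param imaging_depth_mm Step-phantom imaging depth, mm.
#' @return An object of class \code{"system_report"}.
#' @export
system_report <- function(snr_db = NA_real_, axial_resolution_um = NA_real_,
                          peak_depth_mm = NA_real_, z6db_mm = NA_real_,
                          imaging_depth_mm = NA_real_) {
  v <- c(snr_db, axial_resolution_um, peak_depth_mm, z6db_mm,
         imaging_depth_mm)
  if (any(!is.na(v) & v < 0))
    stop("system metrics must be >= 0 when set", call. = FALSE)
  structure(list(snr_db = snr_db,
                 axial_resolution_um = axial_resolution_um,
                 peak_depth_mm = peak_depth_mm, z6db_mm = z6db_mm,
                 imaging_depth_mm = imaging_depth_mm),
            class = "system_report")
}

#' @export
print.system_report <- function(x, ...) {
  cat("<system_report>\n")
  cat(sprintf("  SNR: %.2f dB | axial resolution: %.2f um | peak depth: %.3f mm\n",
              x$snr_db, x$axial_resolution_um, x$peak_depth_mm))
  cat(sprintf("  6 dB roll-off: %.2f mm | imaging depth: %.2f mm\n",
              x$z6db_mm, x$imaging_depth_mm))
  invisible(x)
}
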