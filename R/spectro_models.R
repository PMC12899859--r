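#' Optical property bundle for one material
#'
#' Holds the coefficients used across the spectrophotometric and OCT
#' analyses: absorption \eqn{\mu_a}, scattering \eqn{\mu_s}, reduced
#' scattering \eqn{\mu_s' = (1 - g)\mu_s}, effective attenuation
#' \eqn{\mu_{eff}}, Beer-Lambert total attenuation \eqn{\mu_t}, and the
#' anisotropy factor g. All coefficients are in 1/mm; unknown entries stay
#' NA.
#'
#' @param mu_a,mu_s,mu_s_reduced,mu_eff,mu_t Coefficients in 1/mm, >= 0.
#' @param g Anisotropy factor in [0, 1).
#' @return An object of class \code{"optical_properties"}.
#' @export
optical_properties <- function(mu_a = NA_real_, mu_s = NA_real_,
                               mu_s_reduced = NA_real_, mu_eff = NA_real_,
                               mu_t = NA_real_, g = NA_real_) {
  vals <- c(mu_a = mu_a, mu_s = mu_s, mu_s_reduced = mu_s_reduced,
            mu_eff = mu_eff, mu_t = mu_t)
  if (any(!is.na(vals) & vals < 0))
    stop("optical coefficients must be >= 0", call. = FALSE)
  if (!is.na(g) && (g < 0 || g >= 1))
    stop("g must lie in [0, 1)", call. = FALSE)
  if (!is.na(g) && !is.na(mu_s) && !is.na(mu_s_reduced) &&
      abs(mu_s_reduced - (1 - g) * mu_s) > 1e-8 * max(1, mu_s))
    stop("inconsistent bundle: mu_s_reduced must equal (1 - g) * mu_s",
         call. = FALSE)
  structure(list(mu_a = mu_a, mu_s = mu_s, mu_s_reduced = mu_s_reduced,
                 mu_eff = mu_eff, mu_t = mu_t, g = g),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  v <- unlist(x)
  cat("<optical_properties> [1/mm except g]\n")
  print(round(v, 4))
  invisible(x)
}

#' Absorption fraction from reflectance and transmittance
#'
#' Light energy splits into reflected, transmitted and absorbed parts, so
#' the absorbed fraction is \eqn{A = 1 - R - T}.
#'
#' @param R,T Reflectance and transmittance fractions in [0, 1] with
#'   \code{R + T <= 1}.
#' @return Absorption fraction in [0, 1].
#' @export
absorption_fraction <- function(R, T) {
  if (any(R < 0 | R > 1) || any(T < 0 | T > 1))
    stop("R and T must lie in [0, 1]", call. = FALSE)
  if (any(R + T > 1 + 1e-12))
    stop("R + T exceeds 1: negative absorption is non-physical",
         call. = FALSE)
  pmin(pmax(1 - R - T, 0), 1)
}

#' Beer-Lambert transmittance forward model
#'
#' \eqn{T(d) = e^{-\mu_t d}}.
#'
#' @param mu_t Total attenuation coefficient, 1/mm (>= 0).
#' @param d Path length in mm (>= 0).
#' @return Transmittance fraction.
#' @export
beer_lambert_transmittance <- function(mu_t, d) {
  if (any(mu_t < 0)) stop("mu_t must be >= 0", call. = FALSE)
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  exp(-mu_t * d)
}

#' Total attenuation coefficient from the Beer-Lambert law
#'
#' Inverts \eqn{T = e^{-\mu_t d}} to \eqn{\mu_t = -\ln(T)/d}.
#'
#' @param T Transmittance fraction in (0, 1].
#' @param d Sample thickness in mm (> 0).
#' @return \eqn{\mu_t} in 1/mm.
#' @export
beer_lambert_mu_t <- function(T, d) {
  if (any(T > 1)) stop("transmittance cannot exceed 1", call. = FALSE)
  if (any(T <= 0))
    stop("T = 0 implies infinite attenuation (domain error)", call. = FALSE)
  if (any(d <= 0)) stop("thickness must be > 0", call. = FALSE)
  -log(T) / d
}

#' Effective attenuation coefficient: diffusion-approximation forward model
#'
#' \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + (1 - g)\mu_s)}}.
#'
#' @param mu_a Absorption coefficient, 1/mm (> 0).
#' @param mu_s Scattering coefficient, 1/mm (>= 0).
#' @param g Anisotropy factor in [0, 1); default 0.9, typical of strongly
#'   forward-scattering soft tissue.
#' @return \eqn{\mu_{eff}} in 1/mm.
#' @export
mu_eff_diffusion <- function(mu_a, mu_s, g = 0.9) {
  if (any(mu_a < 0) || any(mu_s < 0))
    stop("coefficients must be >= 0", call. = FALSE)
  if (any(g < 0 | g >= 1)) stop("g must lie in [0, 1)", call. = FALSE)
  sqrt(3 * mu_a * (mu_a + (1 - g) * mu_s))
}

#' Scattering coefficient from the diffusion approximation
#'
#' Inverts \eqn{\mu_{eff}^2 = 3\mu_a(\mu_a + \mu_s')} with
#' \eqn{\mu_s' = (1-g)\mu_s} to
#' \eqn{\mu_s = (\mu_{eff}^2 - 3\mu_a^2) / (3\mu_a(1-g))}.
#'
#' @param mu_eff Effective attenuation coefficient, 1/mm.
#' @param mu_a Absorption coefficient, 1/mm (> 0).
#' @param g Anisotropy factor in [0, 1).
#' @return \eqn{\mu_s} in 1/mm.
#' @export
mu_s_from_diffusion <- function(mu_eff, mu_a, g = 0.9) {
  if (any(mu_a <= 0))
    stop("mu_a must be > 0 for the diffusion inversion", call. = FALSE)
  if (any(g < 0 | g >= 1)) stop("g must lie in [0, 1)", call. = FALSE)
  if (any(mu_eff^2 < 3 * mu_a^2 - 1e-12))
    stop("mu_eff^2 < 3 mu_a^2 implies negative scattering", call. = FALSE)
  pmax((mu_eff^2 - 3 * mu_a^2) / (3 * mu_a * (1 - g)), 0)
}

#' Scattering coefficient by subtractive decomposition
#'
#' The simple additive split \eqn{\mu_s = \mu_{eff} - \mu_a}. This is the
#' decomposition that published per-sample coefficient tables in this
#' problem area typically follow, and is provided alongside the
#' diffusion-approximation inversion; reports should state which was used.
#'
#' @param mu_eff Effective attenuation coefficient, 1/mm.
#' @param mu_a Absorption coefficient, 1/mm, with \code{mu_eff >= mu_a >= 0}.
#' @return \eqn{\mu_s} in 1/mm.
#' @export
mu_s_subtractive <- function(mu_eff, mu_a) {
  if (any(mu_a < 0)) stop("mu_a must be >= 0", call. = FALSE)
  if (any(mu_eff < mu_a))
    stop("mu_eff < mu_a implies negative scattering", call. = FALSE)
  mu_eff - mu_a
}

#' Fit an effective attenuation coefficient to a thickness series
#'
#' Fits \eqn{T(d) = e^{-\mu d}} to a fixed-wavelength transmittance versus
#' thickness series by ordinary least squares on \eqn{-\ln T} against d
#' through the origin (the Beer-Lambert model pins T(0) = 1, and the log
#' domain stabilises small transmittances). The coefficient of
#' determination is reported in the same log domain, against the
#' through-origin null.
#'
#' @param series A \code{\link{spectro_series}} (single wavelength).
#' @param at_nm Optional wavelength (nm) to select before fitting.
#' @param tol_nm Wavelength selection tolerance, nm (default 2.5 nm, half a
#'   5 nm instrument resolution step).
#' @return List with \code{mu_eff} (1/mm), \code{r2}, and \code{n} rows
#'   used.
#' @export
fit_mu_eff_vs_thickness <- function(series, at_nm = NULL, tol_nm = 2.5) {
  stopifnot(inherits(series, "spectro_series"))
  df <- as.data.frame(series)
  if (!is.null(at_nm)) {
    keep <- abs(df$wavelength - at_nm) <= tol_nm
    if (!any(keep))
      stop("no rows within ", tol_nm, " nm of ", at_nm, " nm", call. = FALSE)
    df <- df[keep, , drop = FALSE]
  }
  if (length(unique(df$thickness)) < 3L)
    stop("need at least 3 distinct thicknesses", call. = FALSE)
  if (any(df$transmittance <= 0))
    stop("transmittance must be positive for the log-domain fit",
         call. = FALSE)
  y <- -log(df$transmittance)
  d <- df$thickness
  mu <- sum(d * y) / sum(d * d)            # through-origin least squares
  resid <- y - mu * d
  ss_tot <- sum(y^2)                        # null model: y = 0 (T(0) = 1)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else 1
  if (r2 < 0.5)
    oq_log("thickness fit has low r2 = %.3f; data may be non-exponential",
           r2)
  list(mu_eff = mu, r2 = r2, n = nrow(df))
}
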