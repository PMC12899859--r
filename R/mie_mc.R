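#' Microsphere suspension description
#'
#' A monodisperse suspension of dielectric spheres in a non-absorbing host
#' medium, the standard construction for scattering calibration phantoms.
#'
#' @param sphere_diameter Sphere diameter in micrometres (> 0).
#' @param n_sphere Sphere refractive index (may be complex; Re >= 1).
#' @param n_medium Host medium refractive index (>= 1, real).
#' @param concentration Number density in spheres per cubic mm (>= 0).
#' @param wavelength_vacuum Vacuum wavelength in nm.
#' @return An object of class \code{"mie_medium"}.
#' @export
mie_medium <- function(sphere_diameter = 1.0, n_sphere = 1.8,
                       n_medium = 1.6, concentration = 1.25e6,
                       wavelength_vacuum = 840) {
  if (sphere_diameter <= 0) stop("diameter must be > 0", call. = FALSE)
  if (Re(n_sphere) < 1 || n_medium < 1)
    stop("refractive indices must be >= 1", call. = FALSE)
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  if (wavelength_vacuum <= 0) stop("wavelength must be > 0", call. = FALSE)
  structure(list(sphere_diameter = sphere_diameter, n_sphere = n_sphere,
                 n_medium = n_medium, concentration = concentration,
                 wavelength_vacuum = wavelength_vacuum),
            class = "mie_medium")
}

#' Lorenz-Mie scattering and extinction efficiencies
#'
#' Evaluates the Lorenz-Mie partial-wave series for a homogeneous sphere
#' using the logarithmic-derivative downward recurrence (numerically stable
#' for complex relative index) and Riccati-Bessel upward recurrences,
#' truncated at \code{ceiling(x + 4 x^(1/3) + 2)} terms. Also returns the
#' asymmetry parameter g (mean scattering-angle cosine), used as the
#' default Henyey-Greenstein parameter in the photon-transport simulator.
#'
#' @param size_parameter Size parameter \eqn{x = \pi d n_{med} / \lambda_0}
#'   (dimensionless, > 0).
#' @param m_relative Relative refractive index \eqn{n_{sph}/n_{med}}
#'   (complex allowed; Im(m) >= 0 for an absorbing sphere).
#' @return List with \code{q_sca}, \code{q_ext}, \code{g} and the number of
#'   series terms \code{n_terms}.
#' @export
mie_efficiencies <- function(size_parameter, m_relative) {
  x <- size_parameter
  m <- as.complex(m_relative)
  if (!is.finite(x) || x <= 0)
    stop("size_parameter must be finite and > 0", call. = FALSE)
  if (!is.finite(Re(m)) || !is.finite(Im(m)))
    stop("m_relative must be finite", call. = FALSE)
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  mx <- m * x
  nmx <- max(nmax, ceiling(Mod(mx))) + 16L
  # d[k + 1] holds the logarithmic derivative D_k(mx), downward recurrence
  # from D_nmx = 0: D_{n-1} = n/mx - 1/(D_n + n/mx)
  d <- complex(nmx + 1L)
  for (n in nmx:1) {
    rn <- n / mx
    d[n] <- rn - 1 / (d[n + 1L] + rn)
  }
  n <- seq_len(nmax)
  # Riccati-Bessel psi_n(x), chi_n(x) by upward recurrence
  psi <- numeric(nmax); chi <- numeric(nmax)
  psi_m1 <- cos(x); psi_0 <- sin(x)
  chi_m1 <- -sin(x); chi_0 <- cos(x)
  for (k in n) {
    fac <- (2 * k - 1) / x
    psi[k] <- fac * psi_0 - psi_m1
    chi[k] <- fac * chi_0 - chi_m1
    psi_m1 <- psi_0; psi_0 <- psi[k]
    chi_m1 <- chi_0; chi_0 <- chi[k]
  }
  psi_prev <- c(sin(x), psi[-nmax])
  chi_prev <- c(cos(x), chi[-nmax])
  xi <- complex(real = psi, imaginary = -chi)
  xi_prev <- complex(real = psi_prev, imaginary = -chi_prev)
  dn <- d[n + 1L]
  ta <- dn / m + n / x
  tb <- dn * m + n / x
  a <- (ta * psi - psi_prev) / (ta * xi - xi_prev)
  b <- (tb * psi - psi_prev) / (tb * xi - xi_prev)
  q_ext <- 2 / x^2 * sum((2 * n + 1) * Re(a + b))
  q_sca <- 2 / x^2 * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  a1 <- c(a[-1], 0i); b1 <- c(b[-1], 0i)
  gq <- 4 / x^2 * (sum(n * (n + 2) / (n + 1) *
                         Re(a * Conj(a1) + b * Conj(b1))) +
                   sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b))))
  list(q_sca = q_sca, q_ext = q_ext, g = gq / q_sca, n_terms = nmax)
}

#' Scattering coefficient of a microsphere suspension
#'
#' \eqn{\mu_s = N \sigma_{sca}} with \eqn{\sigma_{sca} = Q_{sca}\pi r^2}.
#' The size parameter uses the wavelength in the host medium,
#' \eqn{x = \pi d n_{med}/\lambda_0}, and the relative index
#' \eqn{m = n_{sph}/n_{med}}, the standard convention for embedded
#' spheres. Exactly linear in concentration.
#'
#' @param medium A \code{\link{mie_medium}}.
#' @return \eqn{\mu_s} in 1/mm.
#' @export
scattering_coefficient <- function(medium) {
  stopifnot(inherits(medium, "mie_medium"))
  lambda_um <- medium$wavelength_vacuum / 1000
  x <- pi * medium$sphere_diameter * medium$n_medium / lambda_um
  m <- medium$n_sphere / medium$n_medium
  q <- mie_efficiencies(x, m)$q_sca
  sigma_um2 <- q * pi * (medium$sphere_diameter / 2)^2
  medium$concentration * sigma_um2 * 1e-6      # um^2 -> mm^2
}

#' Sample scattering-angle cosines from the Henyey-Greenstein phase function
#'
#' Closed-form inverse-CDF sampler; g = 0 reduces to isotropic scattering.
#' Draws from the session RNG stream.
#'
#' @param n Number of draws.
#' @param g Anisotropy parameter in (-1, 1).
#' @return Numeric vector of cosines in [-1, 1].
#' @export
sample_hg <- function(n, g) {
  if (abs(g) >= 1) stop("|g| must be < 1", call. = FALSE)
  xi <- stats::runif(n)
  if (abs(g) < 1e-8) return(2 * xi - 1)
  f <- (1 - g^2) / (1 - g + 2 * g * xi)
  pmin(pmax((1 + g^2 - f^2) / (2 * g), -1), 1)
}

#' Monte Carlo photon-transport run parameters
#'
#' @param n_photons Number of photon packets (>= 1). Default 1e6, matching
#'   common practice for smooth depth curves; scale down for quick checks.
#' @param beam_diameter Gaussian beam 1/e^2 intensity diameter in mm.
#' @param slab_thickness Scattering slab thickness in mm.
#' @param depth_bins Number of tally planes spanning [0, slab_thickness].
#' @param g_phase Henyey-Greenstein anisotropy; NA means use the Mie
#'   asymmetry parameter of the medium.
#' @param seed Integer seed; runs are deterministic given it.
#' @return An object of class \code{"mc_config"}.
#' @export
mc_config <- function(n_photons = 1e6, beam_diameter = 2.2,
                      slab_thickness = 3.0, depth_bins = 31L,
                      g_phase = NA_real_, seed = 1L) {
  if (n_photons < 1) stop("n_photons must be >= 1", call. = FALSE)
  if (beam_diameter <= 0) stop("beam_diameter must be > 0", call. = FALSE)
  if (slab_thickness <= 0) stop("slab_thickness must be > 0", call. = FALSE)
  if (depth_bins < 2L) stop("depth_bins must be >= 2", call. = FALSE)
  structure(list(n_photons = as.integer(n_photons),
                 beam_diameter = beam_diameter,
                 slab_thickness = slab_thickness,
                 depth_bins = as.integer(depth_bins),
                 g_phase = g_phase, seed = as.integer(seed)),
            class = "mc_config")
}

# Unpolarised Fresnel reflectance for incidence cosine ci, going n1 -> n2.
fresnel_reflectance <- function(ci, n1, n2) {
  ci <- pmin(pmax(ci, 0), 1)
  si <- sqrt(1 - ci^2)
  st <- n1 / n2 * si
  r <- rep(1, length(ci))                    # total internal reflection
  ok <- st < 1
  if (any(ok)) {
    ct <- sqrt(1 - st[ok]^2)
    cio <- ci[ok]
    rs <- ((n1 * cio - n2 * ct) / (n1 * cio + n2 * ct))^2
    rp <- ((n1 * ct - n2 * cio) / (n1 * ct + n2 * cio))^2
    r[ok] <- (rs + rp) / 2
  }
  r
}

# Add weight w to the diff-array representation of plane-crossing tallies
# for plane indices k1..k2 (1-based); returns updated diff vector.
add_crossings <- function(diffv, k1, k2, w) {
  keep <- k2 >= k1
  if (!any(keep)) return(diffv)
  k1 <- k1[keep]; k2 <- k2[keep]; w <- w[keep]
  add <- rowsum(c(w, -w), c(k1, k2 + 1L))
  idx <- as.integer(rownames(add))
  diffv[idx] <- diffv[idx] + add[, 1]
  diffv
}

#' Simulate photon transport through a scattering slab
#'
#' Photon-packet random walk through a homogeneous slab of the given
#' microsphere medium: exponential step lengths with rate
#' \eqn{\mu_t = \mu_s + \mu_a}, Henyey-Greenstein scattering, continuous
#' absorption by weight attenuation \eqn{\mu_a/\mu_t} per event, and
#' unpolarised Fresnel reflection/refraction at the entry and exit faces
#' (medium index versus air). Packets below the roulette threshold (1e-4)
#' survive with probability 0.1 and a tenfold weight boost; the roulette's
#' weight residual is folded into the absorbed tally so that absorbed +
#' transmitted + back-reflected sums to 1 exactly while all tallies remain
#' unbiased. Downward packet-weight crossings are tallied on equally spaced
#' planes across the slab; the plane-0 tally plus the total back-reflected
#' weight forms the "distance 0" reference of the relative-intensity curve,
#' which therefore can exceed the incident power. A slab with
#' \eqn{\mu_t = 0} takes a deterministic single-pass ballistic path
#' (multiple internal reflections neglected), transmitting
#' \eqn{(1 - R_F)^2}.
#'
#' @param medium A \code{\link{mie_medium}}; sets \eqn{\mu_s}.
#' @param mu_a Absorption coefficient of the host, 1/mm (>= 0).
#' @param config An \code{\link{mc_config}}.
#' @param max_steps Safety cap on random-walk steps; any weight still alive
#'   at the cap is folded into the absorbed tally with a logged warning.
#' @return An object of class \code{"mc_result"}: \code{depth_grid} (mm),
#'   \code{downward} and \code{ballistic} per-plane crossing fractions,
#'   \code{absorbed}, \code{transmitted}, \code{back_reflected} fractions,
#'   \code{distance0} reference tally, and run metadata.
#' @export
run_photon_transport <- function(medium, mu_a = 0, config = mc_config(),
                                 max_steps = 20000L) {
  stopifnot(inherits(medium, "mie_medium"), inherits(config, "mc_config"))
  if (mu_a < 0) stop("mu_a must be >= 0", call. = FALSE)
  mu_s <- scattering_coefficient(medium)
  mu_t <- mu_s + mu_a
  g <- config$g_phase
  if (is.na(g)) {
    lambda_um <- medium$wavelength_vacuum / 1000
    x <- pi * medium$sphere_diameter * medium$n_medium / lambda_um
    g <- mie_efficiencies(x, medium$n_sphere / medium$n_medium)$g
  }
  n_med <- medium$n_medium
  L <- config$slab_thickness
  nb <- config$depth_bins
  dz <- L / (nb - 1)
  N <- config$n_photons
  r0 <- ((n_med - 1) / (n_med + 1))^2       # normal-incidence Fresnel

  if (mu_t == 0) {
    down <- rep((1 - r0), nb)
    back <- r0 + (1 - r0) * r0
    trans <- (1 - r0)^2
    res <- list(depth_grid = (0:(nb - 1)) * dz, downward = down,
                ballistic = down, absorbed = 0, transmitted = trans,
                back_reflected = back, distance0 = down[1] + back,
                n_photons = N, seed = config$seed, mu_s = mu_s, mu_a = mu_a,
                g_phase = g, n_medium = n_med, ballistic_shortcut = TRUE)
    class(res) <- "mc_result"
    return(res)
  }
  if (N < 1e4)
    oq_log("n_photons = %d is small; depth-curve noise will be large", N)

  res <- with_seed(config$seed, {
    w <- rep(1 - r0, N)
    z <- numeric(N); uz <- rep(1, N)
    ux <- numeric(N); uy <- numeric(N)
    nscat <- integer(N)
    alive <- rep(TRUE, N)
    down_diff <- numeric(nb + 1L)
    ball_diff <- numeric(nb + 1L)
    absorbed <- 0; transmitted <- 0; back <- r0 * N
    w_thresh <- 1e-4; p_surv <- 0.1
    steps <- 0L
    while (any(alive) && steps < max_steps) {
      steps <- steps + 1L
      id <- which(alive)
      s <- -log(stats::runif(length(id))) / mu_t
      z1 <- z[id]; u <- uz[id]
      z2 <- z1 + u * s
      hit_bot <- u > 0 & z2 > L
      hit_top <- u < 0 & z2 < 0
      interior <- !hit_bot & !hit_top
      # downward plane-crossing tallies for this flight segment
      dn <- u > 0
      if (any(dn)) {
        zz1 <- z1[dn]
        k1 <- pmax(ceiling(zz1 / dz - 1e-9), 0) + 1L
        k2 <- ifelse(hit_bot[dn], nb,
                     pmin(ceiling(z2[dn] / dz - 1e-9) - 1, nb - 1L) + 1L)
        ww <- w[id][dn]
        down_diff <- add_crossings(down_diff, k1, k2, ww)
        b <- nscat[id][dn] == 0L
        if (any(b))
          ball_diff <- add_crossings(ball_diff, k1[b], k2[b], ww[b])
      }
      # bottom face: partial transmission, rest reflects back up
      if (any(hit_bot)) {
        ib <- id[hit_bot]
        rf <- fresnel_reflectance(uz[ib], n_med, 1)
        transmitted <- transmitted + sum(w[ib] * (1 - rf))
        w[ib] <- w[ib] * rf
        z[ib] <- L
        uz[ib] <- -uz[ib]
      }
      # top face: partial escape into the back-reflected tally
      if (any(hit_top)) {
        it <- id[hit_top]
        rf <- fresnel_reflectance(-uz[it], n_med, 1)
        back <- back + sum(w[it] * (1 - rf))
        w[it] <- w[it] * rf
        z[it] <- 0
        uz[it] <- -uz[it]
      }
      # interior interaction: absorb a weight fraction, then scatter
      if (any(interior)) {
        ii <- id[interior]
        z[ii] <- z2[interior]
        absorbed <- absorbed + sum(w[ii]) * mu_a / mu_t
        w[ii] <- w[ii] * mu_s / mu_t
        ct <- sample_hg(length(ii), g)
        st <- sqrt(pmax(1 - ct^2, 0))
        phi <- 2 * pi * stats::runif(length(ii))
        cp <- cos(phi); sp <- sin(phi)
        uxi <- ux[ii]; uyi <- uy[ii]; uzi <- uz[ii]
        near_pole <- abs(uzi) > 0.99999
        den <- sqrt(pmax(1 - uzi^2, 1e-30))
        nx <- ifelse(near_pole, st * cp,
                     st * (uxi * uzi * cp - uyi * sp) / den + uxi * ct)
        ny <- ifelse(near_pole, st * sp,
                     st * (uyi * uzi * cp + uxi * sp) / den + uyi * ct)
        nz <- ifelse(near_pole, ct * sign(uzi), -den * st * cp + uzi * ct)
        nrm <- sqrt(nx^2 + ny^2 + nz^2)
        ux[ii] <- nx / nrm; uy[ii] <- ny / nrm; uz[ii] <- nz / nrm
        nscat[ii] <- nscat[ii] + 1L
      }
      # terminate exhausted packets; roulette the faint ones
      dead <- alive & w == 0
      alive[dead] <- FALSE
      faint <- which(alive & w < w_thresh)
      if (length(faint)) {
        surv <- stats::runif(length(faint)) < p_surv
        kill <- faint[!surv]
        keep <- faint[surv]
        absorbed <- absorbed + sum(w[kill])          # roulette residual fold
        alive[kill] <- FALSE
        absorbed <- absorbed - sum(w[keep]) * (1 / p_surv - 1)
        w[keep] <- w[keep] / p_surv
      }
    }
    if (any(alive)) {
      absorbed <- absorbed + sum(w[alive])
      oq_log("max_steps reached with %d packets alive; weight folded into absorbed",
             sum(alive))
    }
    down <- cumsum(down_diff)[seq_len(nb)] / N
    ball <- cumsum(ball_diff)[seq_len(nb)] / N
    list(depth_grid = (0:(nb - 1)) * dz, downward = down, ballistic = ball,
         absorbed = absorbed / N, transmitted = transmitted / N,
         back_reflected = back / N, distance0 = down[1] + back / N,
         n_photons = N, seed = config$seed, mu_s = mu_s, mu_a = mu_a,
         g_phase = g, n_medium = n_med, ballistic_shortcut = FALSE)
  })
  class(res) <- "mc_result"
  res
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "<mc_result> %g photons, mu_s=%.4g mu_a=%.4g /mm, g=%.3f\n  absorbed %.4f | transmitted %.4f | back-reflected %.4f\n",
    x$n_photons, x$mu_s, x$mu_a, x$g_phase, x$absorbed, x$transmitted,
    x$back_reflected))
  invisible(x)
}

#' Relative intensity versus depth from a transport run
#'
#' Each depth plane's downward-crossing tally divided by the distance-0
#' reference (plane-0 crossings plus all back-reflected weight), times 100.
#' The first value is 100 by construction; it refers to a tally that
#' includes reflected light and so exceeds the incident power whenever any
#' light is reflected.
#'
#' @param result An \code{"mc_result"}.
#' @return Data frame with columns \code{depth} (mm) and \code{percent}.
#' @export
intensity_percent_curve <- function(result) {
  stopifnot(inherits(result, "mc_result"))
  ref <- result$distance0
  if (ref <= 0) stop("zero distance-0 tally", call. = FALSE)
  bins <- c(ref, result$downward[-1])
  data.frame(depth = result$depth_grid, percent = 100 * bins / ref)
}
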