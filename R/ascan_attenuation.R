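#' Rectangular region of interest
#'
#' Pixel-index ROI with a 0-based, inclusive-exclusive convention
#' \code{[min, max)}: x indexes lateral columns, y indexes axial rows. The
#' default (x 50-100, y 40-900) selects a 50 x 860 px region of a
#' 1000 x 1000 px B-scan.
#'
#' @param x_min,x_max Lateral pixel bounds, \code{0 <= x_min < x_max}.
#' @param y_min,y_max Axial pixel bounds, \code{0 <= y_min < y_max}.
#' @return An object of class \code{"roi_spec"}.
#' @export
roi_spec <- function(x_min = 50L, x_max = 100L, y_min = 40L, y_max = 900L) {
  x_min <- as.integer(x_min); x_max <- as.integer(x_max)
  y_min <- as.integer(y_min); y_max <- as.integer(y_max)
  if (x_min < 0L || y_min < 0L || x_min >= x_max || y_min >= y_max)
    stop("require 0 <= min < max for both ROI axes", call. = FALSE)
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
            class = "roi_spec")
}

#' Extract a rectangular ROI from a B-scan
#'
#' Returns the sub-image of shape \code{(y_max - y_min) x (x_max - x_min)}.
#' The axial offset of the ROI is retained (as \code{depth_origin}) so that
#' downstream depth coordinates stay absolute.
#'
#' @param x A \code{\link{bscan}}.
#' @param roi A \code{\link{roi_spec}}.
#' @return A \code{\link{bscan}} holding the sub-image.
#' @export
extract_roi <- function(x, roi) {
  stopifnot(inherits(x, "bscan"), inherits(roi, "roi_spec"))
  d <- dim(x$intensity)
  if (roi$y_max > d[1] || roi$x_max > d[2])
    stop("ROI exceeds image bounds (", d[1], " x ", d[2], " px)",
         call. = FALSE)
  sub <- x$intensity[(roi$y_min + 1L):roi$y_max,
                     (roi$x_min + 1L):roi$x_max, drop = FALSE]
  out <- bscan(sub, axial_pitch = x$axial_pitch,
               lateral_pitch = x$lateral_pitch, label = x$label)
  out$depth_origin <- (x$depth_origin %||% 0) + roi$y_min * x$axial_pitch
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sampled, normalised 1-D Gaussian kernel of s.d. sigma px (radius 4 sigma).
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution down the rows of m with symmetric-reflection padding
# (edge value repeated), kernel k of odd length.
conv_rows_reflect <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(m)
  top <- m[pmin(r:1, nr), , drop = FALSE]
  bot <- m[pmax(nr:(nr - r + 1L), 1L), , drop = FALSE]
  pad <- rbind(top, m, bot)
  out <- matrix(0, nr, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * pad[j:(j + nr - 1L), , drop = FALSE]
  out
}

#' Denoise a B-scan with an isotropic Gaussian filter
#'
#' Separable 2-D Gaussian convolution with symmetric-reflection boundary
#' handling; \code{sigma = 0} is the identity. The kernel is normalised, so
#' constant images pass through unchanged and total intensity is conserved
#' away from the borders.
#'
#' @param x A \code{\link{bscan}}.
#' @param sigma Kernel standard deviation in pixels (>= 0); default 1.
#' @return A \code{\link{bscan}}.
#' @export
denoise_gaussian <- function(x, sigma = 1) {
  stopifnot(inherits(x, "bscan"))
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(x)
  k <- gauss_kernel(sigma)
  m <- conv_rows_reflect(x$intensity, k)
  m <- t(conv_rows_reflect(t(m), k))
  out <- bscan(pmax(m, 0), axial_pitch = x$axial_pitch,
               lateral_pitch = x$lateral_pitch, label = x$label)
  out$depth_origin <- x$depth_origin %||% 0
  out
}

#' Laterally averaged depth A-scan of a B-scan
#'
#' Per-row arithmetic mean across the ROI width: averaging N independent
#' speckle realisations suppresses the multiplicative noise by sqrt(N)
#' while leaving the mean decay curve unchanged. The depth grid carries the
#' ROI's absolute axial offset.
#'
#' @param x A \code{\link{bscan}}.
#' @return An \code{\link{ascan}}.
#' @export
lateral_mean <- function(x) {
  stopifnot(inherits(x, "bscan"))
  if (length(x$intensity) == 0L) stop("empty image", call. = FALSE)
  z0 <- x$depth_origin %||% 0
  z <- z0 + (seq_len(nrow(x$intensity)) - 1L) * x$axial_pitch
  ascan(z, rowMeans(x$intensity))
}

#' Savitzky-Golay smoothing of an A-scan
#'
#' Local least-squares polynomial smoothing; any signal that is globally a
#' polynomial of degree <= \code{order} passes through unchanged.
#'
#' @param x An \code{\link{ascan}}.
#' @param window Odd window length in samples, > \code{order} and <= the
#'   signal length.
#' @param order Polynomial order.
#' @return An \code{\link{ascan}}.
#' @export
savgol_smooth <- function(x, window = 11L, order = 3L) {
  stopifnot(inherits(x, "ascan"))
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L || window <= order)
    stop("window must be odd and greater than order", call. = FALSE)
  if (window > length(x$intensity))
    stop("signal shorter than the smoothing window", call. = FALSE)
  ascan(x$depth, signal::sgolayfilt(x$intensity, p = order, n = window))
}

#' Set of detected backscatter peaks
#'
#' @param depths Peak depths in mm, strictly increasing.
#' @param intensities Intensities at the peaks (original scale).
#' @param indices 1-based sample indices of the peaks.
#' @param norm_const Normalisation constant used for the prominence
#'   threshold (the A-scan maximum).
#' @return An object of class \code{"peak_set"}.
#' @export
peak_set <- function(depths, intensities, indices, norm_const = 1) {
  if (length(depths) > 1L && any(diff(depths) <= 0))
    stop("peak depths must be strictly increasing", call. = FALSE)
  structure(list(depths = as.numeric(depths),
                 intensities = as.numeric(intensities),
                 indices = as.integer(indices),
                 norm_const = norm_const),
            class = "peak_set")
}

#' @export
length.peak_set <- function(x) length(x$depths)

# scipy-style topographic prominence of local maximum i in signal y.
peak_prominence_one <- function(y, i) {
  n <- length(y)
  lmin <- y[i]
  j <- i - 1L
  while (j >= 1L && y[j] <= y[i]) { if (y[j] < lmin) lmin <- y[j]; j <- j - 1L }
  left <- lmin
  lmin <- y[i]
  j <- i + 1L
  while (j <= n && y[j] <= y[i]) { if (y[j] < lmin) lmin <- y[j]; j <- j + 1L }
  y[i] - max(left, lmin)
}

#' Detect coherent backscatter peaks in an A-scan
#'
#' Local maxima of the max-normalised A-scan with a topographic prominence
#' threshold and a minimum peak spacing (higher peaks claim their
#' neighbourhood first; among equal peaks the shallower one is kept).
#' Detected peaks are sorted by depth and truncated at the valid depth
#' range.
#'
#' @param x An \code{\link{ascan}}.
#' @param min_spacing Minimum separation between retained peaks, in
#'   samples.
#' @param prominence Prominence threshold on the max-normalised signal.
#' @param valid_max Maximum absolute depth (mm) of retained peaks.
#' @return A \code{\link{peak_set}} (possibly empty).
#' @export
detect_peaks <- function(x, min_spacing = 20L, prominence = 0.005,
                         valid_max = 2.5) {
  stopifnot(inherits(x, "ascan"))
  y_raw <- x$intensity
  norm <- max(y_raw)
  if (norm <= 0)
    return(peak_set(numeric(0), numeric(0), integer(0), norm_const = 1))
  y <- y_raw / norm
  n <- length(y)
  # local maxima; on flat plateaus keep the first sample
  cand <- which(diff(c(-Inf, y)) > 0 & diff(c(y, -Inf)) <= 0)
  cand <- cand[cand > 1L & cand < n]
  if (length(cand)) {
    prom <- vapply(cand, function(i) peak_prominence_one(y, i), numeric(1))
    cand <- cand[prom >= prominence]
  }
  # enforce spacing: greedy by descending height, shallower first on ties
  if (length(cand) > 1L) {
    ord <- cand[order(-y[cand], cand)]
    kept <- integer(0)
    for (i in ord)
      if (!length(kept) || all(abs(kept - i) >= min_spacing))
        kept <- c(kept, i)
    cand <- sort(kept)
  }
  keep <- x$depth[cand] <= valid_max
  cand <- cand[keep]
  peak_set(x$depth[cand], y_raw[cand], cand, norm_const = norm)
}

#' Fit the two-way exponential decay model to detected peaks
#'
#' Constrained nonlinear least squares of
#' \eqn{I(z) = (I_0 - C)\exp(-2\mu(z - z_0)) + C} over \eqn{(I_0, C, \mu)},
#' with \eqn{z_0} fixed at the first peak's depth (the model is degenerate
#' in \eqn{(I_0, z_0)} jointly, and the first interface defines the surface
#' reference). The factor 2 accounts for the round-trip propagation of OCT
#' light; \code{two_way = FALSE} fits the single-pass model, whose fitted
#' \eqn{\mu} is exactly twice the two-way one. Bounds:
#' \eqn{\mu \in [0, 50]} 1/mm, \eqn{C \in [0, \min I]},
#' \eqn{I_0 \ge 0}. Starting values: \eqn{I_0} = first peak intensity,
#' C = half the minimum peak intensity, \eqn{\mu} from the log-slope
#' between the first and last peaks.
#'
#' @param peaks A \code{\link{peak_set}} with at least 3 peaks.
#' @param two_way Logical; use the round-trip factor 2 (default TRUE).
#' @return An object of class \code{"attenuation_fit"} with fields
#'   \code{mu} (1/mm), \code{i0}, \code{c0}, \code{z0} (mm), \code{r2},
#'   \code{n_peaks}.
#' @export
fit_two_way_decay <- function(peaks, two_way = TRUE) {
  stopifnot(inherits(peaks, "peak_set"))
  n <- length(peaks)
  if (n < 3L)
    stop("need at least 3 peaks to fit the decay model (got ", n, ")",
         call. = FALSE)
  z <- peaks$depths
  I <- peaks$intensities
  z0 <- z[1]
  fac <- if (two_way) 2 else 1
  imin <- min(I)
  # degenerate flat input: every mu fits equally once i0 = c0, so report
  # the zero-decay solution directly
  if (max(I) - imin <= 1e-12 * max(I, 1)) {
    return(structure(list(mu = 0, i0 = I[1], c0 = 0, z0 = z0, r2 = 1,
                          n_peaks = n, two_way = two_way),
                     class = "attenuation_fit"))
  }
  c_start <- imin / 2
  span <- z[n] - z[1]
  mu_start <- if (I[n] > 0 && I[1] > I[n] && span > 0)
    min(max(log(I[1] / I[n]) / (fac * span), 0), 50) else 0
  # at mu = 0 the model's C-derivative vanishes identically and the
  # Jacobian is singular; start at a small positive decay instead
  mu_start <- max(mu_start, 1e-3)
  df <- data.frame(z = z, I = I)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      I ~ (i0 - c0) * exp(-fac * mu * (z - z0)) + c0,
      data = df,
      start = list(i0 = I[1], c0 = c_start, mu = mu_start),
      lower = c(i0 = 0, c0 = 0, mu = 0),
      upper = c(i0 = Inf, c0 = imin, mu = 50),
      control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                           maxiter = 500)),
    error = function(e)
      stop("decay fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  p <- stats::coef(fit)
  pred <- (p["i0"] - p["c0"]) * exp(-fac * p["mu"] * (z - z0)) + p["c0"]
  ss_res <- sum((I - pred)^2)
  ss_tot <- sum((I - mean(I))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  structure(list(mu = unname(p["mu"]), i0 = unname(p["i0"]),
                 c0 = unname(p["c0"]), z0 = z0, r2 = r2, n_peaks = n,
                 two_way = two_way),
            class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf(
    "<attenuation_fit> mu = %.4f /mm (%s-way), I0 = %.4g, C = %.4g, z0 = %.4f mm, R2 = %.5f, %d peaks\n",
    x$mu, if (x$two_way) "two" else "one", x$i0, x$c0, x$z0, x$r2,
    x$n_peaks))
  if (!is.null(x$stages))
    cat("  pipeline:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}

#' Estimate the attenuation coefficient of a B-scan
#'
#' The full depth-decay pipeline: ROI extraction, Gaussian denoising,
#' lateral averaging, Savitzky-Golay smoothing, peak detection, and the
#' two-way exponential decay fit, with every constant taken from the
#' \code{\link{run_config}}. The returned fit records the stage order and
#' the peak-normalisation constant; intermediate products are attached when
#' \code{keep_intermediates} is TRUE.
#'
#' @param x A \code{\link{bscan}}.
#' @param config A \code{\link{run_config}}.
#' @param keep_intermediates Attach the ROI A-scans and peak set to the
#'   result.
#' @return An \code{"attenuation_fit"} with pipeline metadata.
#' @export
estimate_attenuation <- function(x, config = run_config(),
                                 keep_intermediates = FALSE) {
  stopifnot(inherits(x, "bscan"), inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  roi <- stage("extract_roi", extract_roi(x, config$roi))
  den <- stage("denoise_gaussian", denoise_gaussian(roi, config$gaussian_sigma))
  asc <- stage("lateral_mean", lateral_mean(den))
  sm <- stage("savgol_smooth",
              savgol_smooth(asc, config$savgol_window, config$savgol_order))
  pk <- stage("detect_peaks",
              detect_peaks(sm, config$peak_min_spacing,
                           config$peak_prominence, config$valid_depth_max))
  fit <- stage("fit_two_way_decay", fit_two_way_decay(pk))
  fit$stages <- c("extract_roi", "denoise_gaussian", "lateral_mean",
                  "savgol_smooth", "detect_peaks", "fit_two_way_decay")
  fit$norm_const <- pk$norm_const
  fit$config <- config
  if (keep_intermediates)
    fit$intermediates <- list(ascan_raw = asc, ascan_smooth = sm, peaks = pk)
  fit
}
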