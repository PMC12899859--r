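#' Construct a calibrated B-scan
#'
#' A B-scan is a two-dimensional cross-sectional OCT intensity image. Rows
#' index optical depth (row 1 is the zero-delay line at the top of the
#' image), columns index the lateral scan position. Depth in millimetres for
#' row \code{i} is \code{(i - 1) * axial_pitch}.
#'
#' @param intensity Numeric matrix of non-negative intensities
#'   (rows = axial/depth, columns = lateral).
#' @param axial_pitch Axial calibration, mm per pixel. Default 0.003 mm/px
#'   (a 3.0 mm imaging depth mapped onto a 1000-pixel axis).
#' @param lateral_pitch Lateral calibration, mm per pixel.
#' @param label Free-text label carried through reports.
#' @return An object of class \code{"bscan"}.
#' @export
bscan <- function(intensity, axial_pitch = 0.003, lateral_pitch = 0.004,
                  label = "") {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("intensity must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("intensity contains non-finite values", call. = FALSE)
  if (any(intensity < 0))
    stop("intensity must be non-negative", call. = FALSE)
  if (!is.numeric(axial_pitch) || length(axial_pitch) != 1L || axial_pitch <= 0)
    stop("axial_pitch must be a single positive number", call. = FALSE)
  if (!is.numeric(lateral_pitch) || length(lateral_pitch) != 1L ||
      lateral_pitch <= 0)
    stop("lateral_pitch must be a single positive number", call. = FALSE)
  structure(list(intensity = intensity,
                 axial_pitch = axial_pitch,
                 lateral_pitch = lateral_pitch,
                 label = as.character(label)[1L]),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<bscan> %d x %d px (%.3f x %.3f mm), axial pitch %g mm/px%s\n",
              d[1], d[2], d[1] * x$axial_pitch, d[2] * x$lateral_pitch,
              x$axial_pitch,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
dim.bscan <- function(x) dim(x$intensity)

#' Construct a depth A-scan
#'
#' One-dimensional backscattered intensity versus depth on a uniform grid.
#'
#' @param depth Strictly increasing, uniformly spaced depth grid in mm.
#' @param intensity Non-negative intensities, same length as \code{depth}.
#' @return An object of class \code{"ascan"}.
#' @export
ascan <- function(depth, intensity) {
  depth <- as.numeric(depth)
  intensity <- as.numeric(intensity)
  if (length(depth) != length(intensity))
    stop("depth and intensity must have the same length", call. = FALSE)
  if (length(depth) < 1L) stop("empty A-scan", call. = FALSE)
  if (length(depth) > 1L) {
    dd <- diff(depth)
    if (any(dd <= 0)) stop("depth must be strictly increasing", call. = FALSE)
    if (max(dd) - min(dd) > 1e-9 * max(dd))
      stop("depth grid must be uniform", call. = FALSE)
  }
  if (any(!is.finite(intensity)))
    stop("intensity contains non-finite values", call. = FALSE)
  structure(list(depth = depth, intensity = intensity), class = "ascan")
}

#' @export
print.ascan <- function(x, ...) {
  cat(sprintf("<ascan> %d samples, depth %.4f..%.4f mm\n",
              length(x$depth), x$depth[1], x$depth[length(x$depth)]))
  invisible(x)
}

#' Read a B-scan image or intensity matrix
#'
#' Reads a grayscale TIFF or PNG image, or a headerless CSV numeric matrix,
#' into a calibrated \code{\link{bscan}}. Row 1 of the file is the top of
#' the image (zero delay); image intensities from TIFF/PNG are returned on
#' the [0, 1] scale those readers use.
#'
#' @param path File path; format chosen by extension (.tif/.tiff, .png,
#'   anything else is treated as CSV).
#' @param axial_pitch,lateral_pitch Calibration in mm per pixel.
#' @param label Optional label; defaults to the file name.
#' @return A \code{\link{bscan}}.
#' @export
read_bscan <- function(path, axial_pitch = 0.003, lateral_pitch = 0.004,
                       label = basename(path)) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    {
      m <- as.matrix(utils::read.csv(path, header = FALSE))
      storage.mode(m) <- "double"
      m
    })
  if (is.array(img) && length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1L]
    else stop("'", path, "' is not grayscale (", dim(img)[3], " channels)",
              call. = FALSE)
  }
  if (!is.matrix(img) || nrow(img) < 2L || ncol(img) < 1L)
    stop("'", path, "' does not contain a 2-D intensity matrix",
         call. = FALSE)
  if (any(!is.finite(img)) || any(img < 0))
    stop("'", path, "' contains negative or non-finite intensities",
         call. = FALSE)
  bscan(img, axial_pitch = axial_pitch, lateral_pitch = lateral_pitch,
        label = label)
}

#' Write a B-scan to disk
#'
#' CSV writes the raw intensity matrix without header. TIFF/PNG require
#' intensities in [0, 1] (no rescaling is applied, so a write/read
#' round-trip preserves values up to bit depth).
#'
#' @param x A \code{\link{bscan}}.
#' @param path Output path; format chosen by extension.
#' @return \code{path}, invisibly.
#' @export
write_bscan <- function(x, path) {
  stopifnot(inherits(x, "bscan"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff", "png")) {
    if (max(x$intensity) > 1)
      stop("image formats require intensities in [0, 1]; rescale first",
           call. = FALSE)
    if (ext == "png") png::writePNG(x$intensity, path)
    else tiff::writeTIFF(x$intensity, path, bits.per.sample = 16L)
  } else {
    utils::write.table(x$intensity, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Construct a spectrophotometric thickness series
#'
#' Per-record sample thickness, wavelength, and fractional reflectance and
#' transmittance measured with an integrating-sphere spectrophotometer.
#' Energy conservation requires R + T <= 1 (the remainder is absorbed).
#'
#' @param thickness Sample thickness in mm (> 0).
#' @param wavelength Wavelength in nm.
#' @param reflectance,transmittance Fractions in [0, 1].
#' @return A data frame with class \code{"spectro_series"}.
#' @export
spectro_series <- function(thickness, wavelength, reflectance, transmittance) {
  df <- data.frame(thickness = as.numeric(thickness),
                   wavelength = as.numeric(wavelength),
                   reflectance = as.numeric(reflectance),
                   transmittance = as.numeric(transmittance))
  if (any(df$thickness <= 0)) stop("thickness must be > 0", call. = FALSE)
  if (any(df$reflectance < 0 | df$reflectance > 1))
    stop("reflectance must lie in [0, 1]", call. = FALSE)
  if (any(df$transmittance < 0 | df$transmittance > 1))
    stop("transmittance must lie in [0, 1]", call. = FALSE)
  if (any(df$reflectance + df$transmittance > 1 + 1e-9))
    stop("R + T exceeds 1: negative absorption is non-physical",
         call. = FALSE)
  class(df) <- c("spectro_series", "data.frame")
  df
}

#' Read a spectrophotometer thickness series from CSV
#'
#' Expects columns \code{thickness_mm}, \code{wavelength_nm},
#' \code{reflectance_percent}, \code{transmittance_percent}; percentages are
#' converted to fractions by dividing by 100.
#'
#' @param path CSV file path.
#' @return A \code{\link{spectro_series}}.
#' @export
read_spectro_series <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("thickness_mm", "wavelength_nm", "reflectance_percent",
            "transmittance_percent")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(df$reflectance_percent < 0 | df$reflectance_percent > 100))
    stop("reflectance_percent outside [0, 100]", call. = FALSE)
  if (any(df$transmittance_percent < 0 | df$transmittance_percent > 100))
    stop("transmittance_percent outside [0, 100]", call. = FALSE)
  spectro_series(df$thickness_mm, df$wavelength_nm,
                 df$reflectance_percent / 100,
                 df$transmittance_percent / 100)
}

#' Write a spectrophotometer thickness series to CSV
#'
#' Inverse of \code{\link{read_spectro_series}}: fractions are written as
#' percentages under the canonical column names.
#'
#' @param x A \code{\link{spectro_series}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_spectro_series <- function(x, path) {
  stopifnot(inherits(x, "spectro_series"))
  out <- data.frame(thickness_mm = x$thickness,
                    wavelength_nm = x$wavelength,
                    reflectance_percent = 100 * x$reflectance,
                    transmittance_percent = 100 * x$transmittance)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' All constants of the A-scan attenuation pipeline live here; defaults are
#' the reference recipe (ROI x = 50-100, y = 40-900 px, Gaussian sigma 1 px,
#' Savitzky-Golay window 11 / order 3, peak spacing 20 px, prominence 0.005
#' on the max-normalised A-scan, valid depth 0-2.5 mm, axial pitch 0.003
#' mm/px, anisotropy g = 0.9).
#'
#' @param roi List with \code{x_min}, \code{x_max}, \code{y_min},
#'   \code{y_max} (0-based, inclusive-exclusive), see \code{\link{roi_spec}}.
#' @param gaussian_sigma Denoising Gaussian s.d. in pixels.
#' @param savgol_window,savgol_order Savitzky-Golay parameters; the window
#'   must be odd and larger than the order.
#' @param peak_min_spacing Minimum peak separation in pixels.
#' @param peak_prominence Prominence threshold on the max-normalised A-scan.
#' @param valid_depth_max Maximum depth (mm) of peaks entering the fit.
#' @param axial_pitch Axial calibration in mm per pixel.
#' @param anisotropy_g Scattering anisotropy factor in [0, 1).
#' @param seed Integer seed for any stochastic stage.
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(roi = roi_spec(50, 100, 40, 900),
                       gaussian_sigma = 1,
                       savgol_window = 11L,
                       savgol_order = 3L,
                       peak_min_spacing = 20L,
                       peak_prominence = 0.005,
                       valid_depth_max = 2.5,
                       axial_pitch = 0.003,
                       anisotropy_g = 0.9,
                       seed = 1L) {
  savgol_window <- as.integer(savgol_window)
  savgol_order <- as.integer(savgol_order)
  if (savgol_window %% 2L == 0L || savgol_window <= savgol_order)
    stop("savgol_window must be odd and greater than savgol_order",
         call. = FALSE)
  if (anisotropy_g < 0 || anisotropy_g >= 1)
    stop("anisotropy_g must lie in [0, 1)", call. = FALSE)
  if (valid_depth_max <= 0) stop("valid_depth_max must be > 0", call. = FALSE)
  if (gaussian_sigma < 0) stop("gaussian_sigma must be >= 0", call. = FALSE)
  if (axial_pitch <= 0) stop("axial_pitch must be > 0", call. = FALSE)
  if (!inherits(roi, "roi_spec")) roi <- do.call(roi_spec, as.list(roi))
  structure(list(roi = roi, gaussian_sigma = gaussian_sigma,
                 savgol_window = savgol_window, savgol_order = savgol_order,
                 peak_min_spacing = as.integer(peak_min_spacing),
                 peak_prominence = peak_prominence,
                 valid_depth_max = valid_depth_max,
                 axial_pitch = axial_pitch,
                 anisotropy_g = anisotropy_g,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file path.
#' @return A \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Write a run configuration to JSON
#' @param config A \code{\link{run_config}}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$roi <- unclass(x$roi)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Package logging
#'
#' Messages are emitted to stderr when \code{options(octoquant.verbose)} is
#' TRUE; off by default so that pipelines stay quiet under test.
#'
#' @param fmt \code{sprintf} format string.
#' @param ... Values interpolated into \code{fmt}.
#' @return Invisibly, the formatted message.
#' @export
oq_log <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (isTRUE(getOption("octoquant.verbose", FALSE)))
    message("[octoquant] ", msg)
  invisible(msg)
}
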