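#' Jones-matrix tomogram volume
#'
#' Container for a polarization-sensitive OCT measurement: one complex 2x2
#' Jones matrix per voxel, describing the round-trip response of the sample,
#' plus the acquisition metadata needed to convert estimates to physical
#' units. Voxels are indexed `[z, x, y]` with depth index 1 at the
#' shallowest pixel; a single B-scan has `ny = 1`.
#'
#' The four matrix entries are stored as parallel complex arrays so that
#' whole-volume algebra stays vectorized.
#'
#' @param j11,j12,j21,j22 Complex arrays of identical dimension
#'   `[nz, nx, ny]` (or `[nz, nx]`, promoted to `ny = 1`); entry `jrc` is
#'   row `r`, column `c` of the per-voxel Jones matrix. Columns correspond
#'   to the two incident polarization channels.
#' @param axial_pitch Depth pixel separation in micrometers.
#' @param lateral_pitch Lateral pixel separation in micrometers.
#' @param center_wavelength Source center wavelength in micrometers.
#'
#' @return An object of class `jones_volume`.
#' @export
jones_volume <- function(j11, j12, j21, j22,
                         axial_pitch, lateral_pitch, center_wavelength) {
  promote <- function(a) {
    a <- as.array(a)
    if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1L)
    storage.mode(a) <- "complex"
    a
  }
  j11 <- promote(j11); j12 <- promote(j12)
  j21 <- promote(j21); j22 <- promote(j22)
  dm <- dim(j11)
  if (length(dm) != 3) stop("Jones entries must be [nz, nx, ny] arrays")
  if (!all(vapply(list(j12, j21, j22),
                  function(a) identical(dim(a), dm), logical(1))))
    stop("all four Jones entry arrays must share one shape")
  if (any(dm == 0)) stop("zero-size volume")
  if (!all(is.finite(Re(j11)) & is.finite(Im(j11))) ||
      !all(is.finite(Re(j22)) & is.finite(Im(j22))))
    stop("Jones entries must be finite")
  stopifnot(axial_pitch > 0, lateral_pitch > 0, center_wavelength > 0)
  structure(
    list(j11 = j11, j12 = j12, j21 = j21, j22 = j22,
         axial_pitch = axial_pitch, lateral_pitch = lateral_pitch,
         center_wavelength = center_wavelength),
    class = "jones_volume")
}

#' @export
dim.jones_volume <- function(x) dim(x$j11)

#' @export
print.jones_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<jones_volume> %d x %d x %d (z, x, y), pitch %.3g/%.3g um, lambda0 %.4g um\n",
    d[1], d[2], d[3], x$axial_pitch, x$lateral_pitch, x$center_wavelength))
  invisible(x)
}

#' Scalar contrast volume
#'
#' A single OCT contrast on the same voxel grid as the measurement it was
#' derived from: intensity (linear or dB), attenuation coefficient (1/mm),
#' local birefringence (dimensionless refractive-index difference), DOPU,
#' or estimator reliability. Undefined voxels (e.g. masked attenuation tail,
#' unreliable birefringence) are `NA`.
#'
#' @param data Numeric array `[nz, nx, ny]` (2-D input promoted to
#'   `ny = 1`).
#' @param units One of `"linear"`, `"dB"`, `"mm^-1"`, `"delta_n"`,
#'   `"dopu"`, `"reliability"`, `"rad"`.
#' @param contrast Free-text provenance label (e.g. `"intensity"`).
#' @param axial_pitch,lateral_pitch Pixel pitches in micrometers.
#'
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, units, contrast = units,
                          axial_pitch = NA_real_, lateral_pitch = NA_real_) {
  data <- as.array(data)
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3) stop("data must be [nz, nx, ny]")
  units <- match.arg(units,
                     c("linear", "dB", "mm^-1", "delta_n", "dopu",
                       "reliability", "rad"))
  v <- data[!is.na(data)]
  if (units == "dopu" && length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    stop("DOPU values must lie in [0, 1]")
  if (units == "reliability" && length(v) && (min(v) < 0 || max(v) > 1))
    stop("reliability values must lie in [0, 1]")
  structure(
    list(data = data, units = units, contrast = contrast,
         axial_pitch = axial_pitch, lateral_pitch = lateral_pitch),
    class = "scalar_volume")
}

#' @export
dim.scalar_volume <- function(x) dim(x$data)

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x)
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("<scalar_volume:%s> %d x %d x %d [%s], range [%.4g, %.4g]\n",
              x$contrast, d[1], d[2], d[3], x$units, rng[1], rng[2]))
  invisible(x)
}

#' @export
as.array.scalar_volume <- function(x, ...) x$data

# extract B-scan y as [nz, nx] matrix
#' Extract one B-scan plane
#'
#' @param x A `scalar_volume` or `jones_volume`.
#' @param y B-scan index (third dimension).
#' @return For a `scalar_volume`, a `[nz, nx]` matrix; for a
#'   `jones_volume`, a `jones_volume` with `ny = 1`.
#' @export
bscan <- function(x, y = 1) UseMethod("bscan")

#' @export
bscan.scalar_volume <- function(x, y = 1) x$data[, , y]

#' @export
bscan.jones_volume <- function(x, y = 1) {
  jones_volume(x$j11[, , y], x$j12[, , y], x$j21[, , y], x$j22[, , y],
               x$axial_pitch, x$lateral_pitch, x$center_wavelength)
}
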