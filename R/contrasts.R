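#' Scatter intensity from a Jones-matrix volume
#'
#' Averages the absolute-squared values of the four Jones matrix entries
#' (the four polarization channels) per voxel.
#'
#' @param jones A [jones_volume()].
#' @param db If `TRUE`, return `10*log10(I / reference)`.
#' @param reference dB reference in linear units; defaults to the maximum
#'   voxel intensity of the volume.
#' @return A [scalar_volume()] in `"linear"` or `"dB"` units.
#' @export
scatter_intensity <- function(jones, db = FALSE, reference = NULL) {
  stopifnot(inherits(jones, "jones_volume"))
  i <- (Mod(jones$j11)^2 + Mod(jones$j12)^2 +
        Mod(jones$j21)^2 + Mod(jones$j22)^2) / 4
  if (db) {
    reference <- reference %||% max(i)
    i <- 10 * log10(i / reference)
    units <- "dB"
  } else units <- "linear"
  scalar_volume(i, units, "intensity", jones$axial_pitch, jones$lateral_pitch)
}

#' Depth-resolved attenuation coefficient
#'
#' Per-voxel attenuation estimate by tail normalization: each pixel's
#' intensity is divided by twice the pixel pitch times the summed intensity
#' of all deeper pixels in the same A-line,
#' `mu(i) = I(i) / (2 * dz * sum_{j > i} I(j))`,
#' assuming the beam is fully attenuated within the recorded depth range.
#' The deepest pixel (empty tail) and any pixel with a non-positive tail
#' sum are returned as `NA`.
#'
#' @param intensity A [scalar_volume()] in linear units, non-negative.
#' @return A [scalar_volume()] in 1/mm.
#' @export
attenuation_depth_resolved <- function(intensity) {
  stopifnot(inherits(intensity, "scalar_volume"))
  if (intensity$units != "linear")
    stop("attenuation requires linear-scale intensity, not ", intensity$units)
  x <- intensity$data
  if (any(x < 0, na.rm = TRUE)) stop("intensity must be non-negative")
  if (is.na(intensity$axial_pitch)) stop("axial_pitch metadata required")
  dz_mm <- intensity$axial_pitch / 1000
  nz <- dim(x)[1]
  x0 <- x; x0[is.na(x0)] <- 0
  # tail(i) = sum over j > i, per A-line
  cs <- apply(x0, c(2, 3), cumsum)
  cs <- array(cs, dim(x))
  tail_sum <- rep(cs[nz, , , drop = FALSE], each = nz) - cs
  mu <- x / (2 * dz_mm * tail_sum)
  mu[tail_sum <= 0] <- NA_real_
  mu[nz, , ] <- NA_real_
  scalar_volume(mu, "mm^-1", "attenuation",
                intensity$axial_pitch, intensity$lateral_pitch)
}
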