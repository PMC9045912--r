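# Visualization composites: reliability-gated pseudo-color birefringence,
# intensity/DOPU overlays, and depth-windowed en-face projections.

#' @noRd
composite_image <- function(rgb, legend) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3,
            min(rgb, na.rm = TRUE) >= 0, max(rgb, na.rm = TRUE) <= 1)
  structure(list(rgb = rgb, legend = legend), class = "composite_image")
}

#' @export
print.composite_image <- function(x, ...) {
  cat(sprintf("<composite_image> %d x %d, contrast %s\n",
              dim(x$rgb)[1], dim(x$rgb)[2], x$legend$contrast))
  invisible(x)
}

# clip a dB image into [0, 1] brightness over display_range
#' @noRd
db_brightness <- function(intensity_db, display_range) {
  pmin(pmax((intensity_db - display_range[1]) /
              (display_range[2] - display_range[1]), 0), 1)
}

#' Reliability-gated pseudo-color birefringence tomogram
#'
#' Combines scatter intensity, birefringence and estimation reliability
#' into one image: where the estimate is reliable the birefringence sets
#' the color hue (over `value_range`) and the intensity the brightness;
#' elsewhere the pixel is a shade of gray at the same brightness.
#'
#' @param intensity_db Matrix, intensity B-scan in dB.
#' @param delta_n Matrix of birefringence values (NA treated as
#'   unreliable).
#' @param reliability Matrix in \[0, 1\].
#' @param threshold Reliability gate (default 0.7).
#' @param value_range Birefringence range mapped onto the hue scale.
#' @param hue_range HSV hue endpoints of the colormap (default blue to
#'   red).
#' @param display_range dB range mapped to brightness, relative to 0 dB
#'   max.
#' @return A `composite_image` (`$rgb` in \[0, 1\], `$legend` records the
#'   generating parameters).
#' @export
pseudo_color_birefringence <- function(intensity_db, delta_n, reliability,
                                       threshold = 0.7,
                                       value_range = c(0, 2e-3),
                                       hue_range = c(2 / 3, 0),
                                       display_range = c(-30, 0)) {
  stopifnot(all(dim(intensity_db) == dim(delta_n)),
            all(dim(intensity_db) == dim(reliability)))
  v <- db_brightness(intensity_db, display_range)
  t <- pmin(pmax((delta_n - value_range[1]) /
                   (value_range[2] - value_range[1]), 0), 1)
  reliable <- !is.na(delta_n) & reliability >= threshold
  hue <- hue_range[1] + t * (hue_range[2] - hue_range[1])
  sat <- ifelse(reliable, 1, 0)
  hue[is.na(hue)] <- 0
  col <- grDevices::hsv(h = hue, s = sat, v = v)
  rgb <- aperm(array(grDevices::col2rgb(col) / 255,
                     c(3, nrow(v), ncol(v))), c(2, 3, 1))
  composite_image(rgb, list(
    contrast = "birefringence", value_range = value_range,
    colormap = sprintf("hsv[%.3f,%.3f]", hue_range[1], hue_range[2]),
    reliability_threshold = threshold, display_range_db = display_range))
}

#' Intensity/DOPU composite image
#'
#' Pixels brighter than `intensity_floor` are colored by the DOPU value
#' (hue) with intensity-scaled brightness; background pixels stay gray, so
#' noise regions render as mostly gray.
#'
#' @param intensity_db Matrix, intensity B-scan in dB.
#' @param dopu Matrix of DOPU values in \[0, 1\].
#' @param intensity_floor dB threshold separating sample from background.
#' @param hue_range HSV hue endpoints mapped to DOPU 0..1.
#' @param display_range dB range mapped to brightness.
#' @return A `composite_image`.
#' @export
dopu_composite <- function(intensity_db, dopu, intensity_floor = -25,
                           hue_range = c(0, 1 / 3),
                           display_range = c(-30, 0)) {
  stopifnot(all(dim(intensity_db) == dim(dopu)))
  v <- db_brightness(intensity_db, display_range)
  fg <- intensity_db > intensity_floor & !is.na(dopu)
  t <- pmin(pmax(dopu, 0), 1)
  t[is.na(t)] <- 0
  hue <- hue_range[1] + t * (hue_range[2] - hue_range[1])
  col <- grDevices::hsv(h = hue, s = ifelse(fg, 1, 0), v = v)
  rgb <- aperm(array(grDevices::col2rgb(col) / 255,
                     c(3, nrow(v), ncol(v))), c(2, 3, 1))
  composite_image(rgb, list(
    contrast = "dopu", intensity_floor_db = intensity_floor,
    colormap = sprintf("hsv[%.3f,%.3f]", hue_range[1], hue_range[2]),
    display_range_db = display_range))
}

#' Depth-windowed en-face projection
#'
#' Projects a depth window of a volume onto the lateral plane, by mean or
#' maximum, ignoring undefined voxels.
#'
#' @param volume A [scalar_volume()].
#' @param z_range Inclusive depth pixel range `c(z0, z1)`, 1-based.
#' @param mode `"mean"` or `"max"`.
#' @return An `[nx, ny]` matrix (`NA` where the window is entirely
#'   undefined).
#' @export
enface_projection <- function(volume, z_range, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "scalar_volume"))
  nz <- dim(volume$data)[1]
  z0 <- z_range[1]; z1 <- z_range[2]
  if (z0 < 1 || z1 > nz || z0 > z1) stop("invalid z_range")
  slab <- volume$data[z0:z1, , , drop = FALSE]
  f <- if (mode == "mean") {
    function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  } else {
    function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  }
  out <- apply(slab, c(2, 3), f)
  matrix(out, dim(volume$data)[2], dim(volume$data)[3])
}
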