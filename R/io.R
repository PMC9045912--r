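# On-disk formats: multi-page 32-bit TIFF stacks with a JSON sidecar for
# volumes, 8-bit TIFF for masks, YAML/JSON for phantom specs.
#
# The TIFF backend stores 32-bit integer samples; values are mapped
# through an affine offset/scale recorded in the sidecar (relative
# round-trip error ~1e-9). Sample value 0 is reserved to encode NA.

#' @noRd
sidecar_path <- function(path) paste0(path, ".json")

#' Write a scalar volume to TIFF + JSON sidecar
#'
#' One TIFF page per B-scan (32-bit), plus `<path>.json` holding units,
#' contrast, pitches, dimensions and the value scaling.
#'
#' @param volume A [scalar_volume()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scalar_volume <- function(volume, path) {
  stopifnot(inherits(volume, "scalar_volume"))
  x <- volume$data
  fin <- x[!is.na(x)]
  lo <- if (length(fin)) min(fin) else 0
  hi <- if (length(fin)) max(fin) else 1
  scale <- if (hi > lo) hi - lo else 1
  eps <- 2^-20                                  # > 0 so 0 stays NA-only
  enc <- (x - lo) / scale * (1 - eps) + eps
  enc[is.na(x)] <- 0
  pages <- lapply(seq_len(dim(x)[3]), function(y) enc[, , y])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(type = "scalar_volume", units = volume$units,
         contrast = volume$contrast, dim = dim(x),
         axial_pitch = volume$axial_pitch,
         lateral_pitch = volume$lateral_pitch,
         offset = lo, scale = scale, eps = eps),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scalar volume written by [write_scalar_volume()]
#'
#' @param path TIFF path (the `.json` sidecar must sit next to it).
#' @return A [scalar_volume()].
#' @export
read_scalar_volume <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (!identical(meta$type, "scalar_volume")) stop("not a scalar_volume file")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dm <- as.integer(meta$dim)
  x <- array(NA_real_, dm)
  for (y in seq_len(dm[3])) x[, , y] <- pages[[y]]
  na <- x == 0
  x <- (x - meta$eps) / (1 - meta$eps) * meta$scale + meta$offset
  x[na] <- NA_real_
  scalar_volume(x, meta$units, meta$contrast,
                meta$axial_pitch, meta$lateral_pitch)
}

#' Write a Jones-matrix volume to TIFF + JSON sidecar
#'
#' Eight 32-bit pages per B-scan (real and imaginary parts of the four
#' matrix entries, in row-major entry order), page-interleaved by B-scan.
#'
#' @param volume A [jones_volume()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_jones_volume <- function(volume, path) {
  stopifnot(inherits(volume, "jones_volume"))
  dm <- dim(volume)
  chans <- list(Re(volume$j11), Im(volume$j11), Re(volume$j12),
                Im(volume$j12), Re(volume$j21), Im(volume$j21),
                Re(volume$j22), Im(volume$j22))
  lo <- min(vapply(chans, min, numeric(1)))
  hi <- max(vapply(chans, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  pages <- list()
  for (y in seq_len(dm[3]))
    for (ch in chans)
      pages[[length(pages) + 1]] <- (ch[, , y] - lo) / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(type = "jones_volume", dim = dm,
         axial_pitch = volume$axial_pitch,
         lateral_pitch = volume$lateral_pitch,
         center_wavelength = volume$center_wavelength,
         offset = lo, scale = scale),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Jones-matrix volume written by [write_jones_volume()]
#'
#' @param path TIFF path.
#' @return A [jones_volume()].
#' @export
read_jones_volume <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (!identical(meta$type, "jones_volume")) stop("not a jones_volume file")
  pages <- tiff::readTIFF(path, all = TRUE)
  dm <- as.integer(meta$dim)
  dec <- function(p) p * meta$scale + meta$offset
  ch <- vector("list", 8)
  for (k in 1:8) ch[[k]] <- array(0, dm)
  for (y in seq_len(dm[3]))
    for (k in 1:8)
      ch[[k]][, , y] <- dec(pages[[(y - 1) * 8 + k]])
  cpx <- function(re, im) array(complex(real = re, imaginary = im), dm)
  jones_volume(cpx(ch[[1]], ch[[2]]), cpx(ch[[3]], ch[[4]]),
               cpx(ch[[5]], ch[[6]]), cpx(ch[[7]], ch[[8]]),
               meta$axial_pitch, meta$lateral_pitch,
               meta$center_wavelength)
}

#' Write region masks as a labelled 8-bit TIFF
#'
#' One page per B-scan; voxel values are the 1-based label codes recorded
#' in the sidecar (0 = unlabelled).
#'
#' @param masks A [region_mask_set()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_region_masks <- function(masks, path) {
  stopifnot(inherits(masks, "region_mask_set"))
  labs <- names(masks$masks)
  dm <- dim(masks$masks[[1]])
  lab_vol <- array(0L, dm)
  for (i in seq_along(labs)) lab_vol[masks$masks[[i]]] <- i
  pages <- lapply(seq_len(dm[3]), function(y) lab_vol[, , y] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  jsonlite::write_json(
    list(type = "region_mask_set", dim = dm, labels = labs,
         volume_ref = masks$volume_ref),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read region masks written by [write_region_masks()]
#'
#' @param path TIFF path.
#' @return A [region_mask_set()].
#' @export
read_region_masks <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (!identical(meta$type, "region_mask_set"))
    stop("not a region_mask_set file")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dm <- as.integer(meta$dim)
  lab_vol <- array(0L, dm)
  for (y in seq_len(dm[3]))
    lab_vol[, , y] <- as.integer(round(pages[[y]] * 255))
  masks <- lapply(seq_along(meta$labels), function(i) lab_vol == i)
  names(masks) <- meta$labels
  region_mask_set(masks, volume_ref = meta$volume_ref)
}

#' Save / load a phantom specification as YAML or JSON
#'
#' @param spec A [phantom_spec()].
#' @param path Output path; extension `.json` selects JSON, anything else
#'   YAML.
#' @return `path` ([write_phantom_spec()]) or a [phantom_spec()]
#'   ([read_phantom_spec()]).
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  lst <- unclass(spec)
  lst$layers <- lapply(lst$layers, unclass)
  if (!is.finite(lst$snr_db)) lst$snr_db <- NULL   # Inf = noise-free default
  if (grepl("\\.json$", path))
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  lst <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  layers <- lapply(lst$layers, function(l) do.call(phantom_layer, l))
  phantom_spec(layers, lst$lateral_size, lst$axial_size, lst$n_bscans,
               lst$axial_pitch, lst$lateral_pitch, lst$center_wavelength,
               lst$snr_db %||% Inf, lst$seed)
}

#' Write a stats report to JSON plus a CSV of per-B-scan means
#'
#' @param report A `stats_report` from [quantify_regions()].
#' @param path Base path (no extension): writes `<path>.json` and
#'   `<path>_means.csv`.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(report, path) {
  stopifnot(inherits(report, "stats_report"))
  jsonlite::write_json(
    list(labels = report$labels, alpha = report$alpha,
         tests = report$tests,
         summaries = dplyr::mutate(
           report$summaries,
           outliers = purrr::map_chr(.data$outliers,
                                     ~paste(.x, collapse = ";")))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$means, paste0(path, "_means.csv"),
                   row.names = FALSE)
  invisible(path)
}
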