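# Spectral-domain OCT: forward fringe synthesis and reconstruction.

#' Synthesize raw SD-OCT spectral fringes
#'
#' Forward counterpart of [sdoct_reconstruct()]: each A-line spectrum is a
#' DC term plus one cosine fringe per reflector, `A * cos(2 k z + phi(k))`
#' with a polynomial dispersion phase
#' `phi(k) = a2 (k - k0)^2 + a3 (k - k0)^3`, sampled on a linear or mildly
#' nonlinear wavenumber grid, plus white detector noise.
#'
#' The linear-grid sample spacing is chosen so that the reconstructed
#' depth pixel pitch equals `axial_pitch`; reflector depths must stay
#' below the unambiguous range `n_samples / 2 * axial_pitch`.
#'
#' @param reflectors Two-column matrix or data frame `(depth_um,
#'   amplitude)`.
#' @param n_samples Spectral samples per A-line.
#' @param n_alines Number of A-lines.
#' @param axial_pitch Target reconstructed depth pitch in micrometers
#'   (default 2.5, an 840-nm spectrometer system).
#' @param center_wavelength Source center wavelength in micrometers.
#' @param dispersion Numeric `c(a2, a3)` phase coefficients in rad per
#'   (rad/um)^n.
#' @param k_warp Fractional sinusoidal warp of the k grid (0 = linear;
#'   values well below 1 keep the grid monotonic).
#' @param dc DC (reference arm) spectral level.
#' @param noise_sd Additive white noise standard deviation.
#' @param phase_jitter If `TRUE`, each A-line adds a random phase per
#'   reflector so fringes survive average-spectrum subtraction.
#' @param seed RNG seed.
#' @return A `spectral_frames` object: `spectra` `[n_alines, n_samples]`,
#'   `k_grid` (rad/um), `k0`, `dispersion`, `axial_pitch`.
#' @export
generate_fringes <- function(reflectors, n_samples, n_alines = 1,
                             axial_pitch = 2.5, center_wavelength = 0.84,
                             dispersion = c(0, 0), k_warp = 0, dc = 1,
                             noise_sd = 0, phase_jitter = FALSE, seed = 1) {
  reflectors <- as.matrix(reflectors)
  if (ncol(reflectors) != 2) stop("reflectors must be (depth, amplitude)")
  stopifnot(n_samples >= 8, n_alines >= 1, axial_pitch > 0)
  zmax <- n_samples / 2 * axial_pitch
  if (nrow(reflectors) && any(reflectors[, 1] >= zmax | reflectors[, 1] < 0))
    stop(sprintf("reflector depths must lie in [0, %.1f) um (Nyquist range)",
                 zmax))
  dk <- pi / (n_samples * axial_pitch)
  k0 <- 2 * pi / center_wavelength
  j <- seq_len(n_samples) - 1
  t <- j / (n_samples - 1)
  k <- k0 + dk * ((j - (n_samples - 1) / 2) +
                  k_warp * n_samples * sin(2 * pi * t) / (2 * pi))
  phi_d <- dispersion[1] * (k - k0)^2 + dispersion[2] * (k - k0)^3

  spectra <- with_seed(seed, {
    s <- matrix(dc, n_alines, n_samples)
    for (r in seq_len(nrow(reflectors))) {
      z <- reflectors[r, 1]; a <- reflectors[r, 2]
      ph <- if (phase_jitter) stats::runif(n_alines, 0, 2 * pi) else
        numeric(n_alines)
      s <- s + a * cos(outer(ph, 2 * k * z + phi_d, `+`))
    }
    if (noise_sd > 0)
      s <- s + matrix(stats::rnorm(n_alines * n_samples, sd = noise_sd),
                      n_alines, n_samples)
    s
  })
  structure(list(spectra = spectra, k_grid = k, k0 = k0,
                 dispersion = dispersion, axial_pitch = axial_pitch),
            class = "spectral_frames")
}

#' Reconstruction settings for SD-OCT
#'
#' @param window_width Gaussian spectral-shaping width (standard
#'   deviation, rad/um); default half the sampled wavenumber band.
#' @param resample_points Points of the uniform k grid; default the input
#'   sample count, must be at least half of it.
#' @param subtract_mean Subtract the across-A-line average spectrum
#'   (fixed-pattern / DC removal).
#' @param resample Apply k-linearization (disable for known-linear grids).
#' @return A `recon_settings` list.
#' @export
recon_settings <- function(window_width = NULL, resample_points = NULL,
                           subtract_mean = TRUE, resample = TRUE) {
  structure(list(window_width = window_width,
                 resample_points = resample_points,
                 subtract_mean = subtract_mean, resample = resample),
            class = "recon_settings")
}

#' Reconstruct SD-OCT intensity A-lines from spectral fringes
#'
#' Applies, in order: cubic-spline resampling to a uniform wavenumber
#' grid, Gaussian spectral shaping, numerical dispersion compensation
#' (`exp(-i (a2 (k-k0)^2 + a3 (k-k0)^3))` with the coefficients carried by
#' the frame set), average-spectrum subtraction, and Fourier
#' transformation; the squared modulus of the positive-frequency half is
#' returned.
#'
#' @param frames A `spectral_frames` object.
#' @param settings A [recon_settings()].
#' @return A [scalar_volume()] `[n_depth, n_alines, 1]` in linear units;
#'   its `axial_pitch` is derived from the resampled wavenumber span.
#' @export
sdoct_reconstruct <- function(frames, settings = recon_settings()) {
  stopifnot(inherits(frames, "spectral_frames"))
  k <- frames$k_grid
  s <- frames$spectra
  if (any(!is.finite(s))) stop("spectra contain non-finite values")
  if (any(diff(k) <= 0)) stop("k_grid must be strictly increasing")
  n_in <- ncol(s)
  np <- settings$resample_points %||% n_in
  if (np < n_in / 2) stop("resample_points must be >= half the sample count")
  if (settings$subtract_mean && nrow(s) < 2)
    stop("average-spectrum subtraction needs at least 2 A-lines")

  ku <- seq(k[1], k[length(k)], length.out = np)
  if (settings$resample) {
    s <- t(apply(s, 1, function(row)
      stats::spline(k, row, xout = ku, method = "natural")$y))
  } else {
    if (np != n_in) stop("resampling disabled but resample_points differs")
    ku <- k
  }
  kc <- (ku[1] + ku[length(ku)]) / 2
  w <- settings$window_width %||% ((ku[length(ku)] - ku[1]) / 2)
  win <- exp(-(ku - kc)^2 / (2 * w^2))
  s <- sweep(s, 2, win, `*`)
  comp <- exp(-1i * (frames$dispersion[1] * (ku - frames$k0)^2 +
                     frames$dispersion[2] * (ku - frames$k0)^3))
  s <- sweep(s, 2, comp, `*`)
  if (settings$subtract_mean) s <- sweep(s, 2, colMeans(s), `-`)
  ft <- t(stats::mvfft(t(s)))
  half <- seq_len(floor(np / 2))
  img <- t(Mod(ft[, half, drop = FALSE])^2)     # [depth, A-line]
  dku <- (ku[length(ku)] - ku[1]) / (np - 1)
  scalar_volume(array(img, c(length(half), nrow(s), 1)), "linear",
                "sdoct_intensity", axial_pitch = pi / (np * dku))
}
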