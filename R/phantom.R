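#' Describe one layer of a tissue phantom
#'
#' Layers are stacked along depth and parameterize the physical quantities
#' the analysis estimates: attenuation, birefringence (as a linear retarder
#' of given axis), polarization scrambling, and mean backscatter.
#'
#' @param thickness Layer thickness in depth pixels.
#' @param mu Attenuation coefficient in 1/mm (absorption + scattering).
#' @param delta_n Birefringence as a dimensionless refractive-index
#'   difference between the fast and slow axes.
#' @param axis Retarder axis orientation in radians.
#' @param scrambling Polarization scrambling index in \[0, 1\]: 0 preserves
#'   the polarization state, 1 randomizes it per speckle (fully
#'   depolarizing in the kernel-averaged sense).
#' @param reflectivity Mean backscattered power at the layer top (linear,
#'   arbitrary units).
#'
#' @return A `phantom_layer` list.
#' @export
phantom_layer <- function(thickness, mu = 0, delta_n = 0, axis = 0,
                          scrambling = 0, reflectivity = 1) {
  stopifnot(thickness >= 1, mu >= 0, delta_n >= 0,
            scrambling >= 0, scrambling <= 1, reflectivity >= 0)
  structure(list(thickness = as.integer(thickness), mu = mu,
                 delta_n = delta_n, axis = axis,
                 scrambling = scrambling, reflectivity = reflectivity),
            class = "phantom_layer")
}

#' Specify a layered JM-OCT phantom
#'
#' Ground-truth description of a speckled, layered, birefringent medium
#' imaged by a Jones-matrix OCT system. Defaults carry the acquisition
#' constants of a 1310-nm swept-source system with 7.24 um depth pixel
#' separation.
#'
#' @param layers List of [phantom_layer()]; thicknesses must tile the full
#'   depth `axial_size` exactly, in order from the surface down.
#' @param lateral_size Number of A-scans per B-scan.
#' @param axial_size Number of depth pixels.
#' @param n_bscans Number of B-scans (third dimension).
#' @param axial_pitch Depth pixel separation in micrometers.
#' @param lateral_pitch Lateral pixel separation in micrometers.
#' @param center_wavelength Source center wavelength in micrometers.
#' @param snr_db Detection signal-to-noise ratio in dB, defined against the
#'   mean backscattered power of the first layer; `Inf` disables additive
#'   noise.
#' @param seed Integer RNG seed; identical specs generate bit-identical
#'   volumes.
#'
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(layers, lateral_size, axial_size, n_bscans = 1,
                         axial_pitch = 7.24, lateral_pitch = 10,
                         center_wavelength = 1.31, snr_db = Inf, seed = 1) {
  if (inherits(layers, "phantom_layer")) layers <- list(layers)
  stopifnot(length(layers) >= 1,
            all(vapply(layers, inherits, logical(1), "phantom_layer")))
  if (lateral_size < 1 || axial_size < 1 || n_bscans < 1)
    stop("zero-size grids are not allowed")
  th <- vapply(layers, function(l) l$thickness, integer(1))
  if (sum(th) != axial_size)
    stop(sprintf("layer thicknesses sum to %d but axial_size is %d: layers must tile the depth range exactly",
                 sum(th), axial_size))
  stopifnot(axial_pitch > 0, lateral_pitch > 0, center_wavelength > 0,
            is.finite(snr_db) || identical(snr_db, Inf))
  structure(list(layers = layers, lateral_size = as.integer(lateral_size),
                 axial_size = as.integer(axial_size),
                 n_bscans = as.integer(n_bscans),
                 axial_pitch = axial_pitch, lateral_pitch = lateral_pitch,
                 center_wavelength = center_wavelength,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "phantom_spec")
}

# per-depth-pixel vectors of layer properties
#' @noRd
layer_profiles <- function(spec) {
  idx <- rep(seq_along(spec$layers),
             vapply(spec$layers, function(l) l$thickness, integer(1)))
  get <- function(f) vapply(spec$layers, function(l) l[[f]], numeric(1))[idx]
  list(mu = get("mu"), delta_n = get("delta_n"), axis = get("axis"),
       scrambling = get("scrambling"), reflectivity = get("reflectivity"))
}

#' Simulate a Jones-matrix OCT volume from a phantom description
#'
#' Forward model: per depth pixel the medium acts as a linear retarder with
#' single-pass retardation `2*pi*delta_n*axial_pitch/lambda0` at the layer
#' axis; the cumulative single-pass matrix down to depth z is the ordered
#' product of these, and the measured round-trip matrix is the reciprocal
#' form `t(J_cum) %*% J_cum`. Each voxel is scaled by a fully developed
#' speckle amplitude (circular complex Gaussian) whose mean power is the
#' layer reflectivity attenuated by `exp(-2 * integral of mu dz)`.
#' Scrambling replaces the deterministic round-trip matrix, per voxel with
#' probability equal to the scrambling index, by a random symmetric unitary
#' whose output polarization state is uniform on the Poincare sphere.
#' Additive complex white Gaussian detector noise is set by `snr_db`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (a [jones_volume()]) and
#'   `ground_truth` (list of `mu`, `delta_n`, `dopu_expected`
#'   [scalar_volume()] grids; expected DOPU is `1 - scrambling`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$axial_size; nx <- spec$lateral_size; ny <- spec$n_bscans
  prof <- layer_profiles(spec)
  phi <- 2 * pi * prof$delta_n * spec$axial_pitch / spec$center_wavelength

  # cumulative single-pass matrix and deterministic round trip, per depth
  q11 <- q12 <- q22 <- complex(nz)            # round trip is symmetric
  jc <- diag(2) + 0i
  for (z in seq_len(nz)) {
    jc <- retarder_matrix(phi[z], prof$axis[z]) %*% jc
    q <- t(jc) %*% jc
    q11[z] <- q[1, 1]; q12[z] <- q[1, 2]; q22[z] <- q[2, 2]
  }

  # mean backscattered power: reflectivity attenuated down to the voxel
  dz_mm <- spec$axial_pitch / 1000
  od <- c(0, cumsum(prof$mu * dz_mm))[seq_len(nz)]   # surface unattenuated
  pow <- prof$reflectivity * exp(-2 * od)

  nvox <- nz * nx * ny
  dm <- c(nz, nx, ny)
  with_seed(spec$seed, {
    amp <- array(cplx_normal(nvox), dm) * array(sqrt(pow), dm)

    j11 <- array(q11, dm); j12 <- array(q12, dm)
    j22 <- array(q22, dm)

    scram <- array(stats::runif(nvox) < prof$scrambling, dm)
    ns <- sum(scram)
    if (ns > 0) {
      v1 <- cplx_normal(ns); v2 <- cplx_normal(ns)
      nrm <- sqrt(Mod(v1)^2 + Mod(v2)^2)
      v1 <- v1 / nrm; v2 <- v2 / nrm
      # symmetric unitary with first column (v1, v2): off-diagonal v2,
      # second diagonal entry -conj(v1) v2 / conj(v2)
      j11[scram] <- v1
      j12[scram] <- v2
      j22[scram] <- -Conj(v1) * v2 / Conj(v2)
    }
    j21 <- j12                                  # reciprocity

    j11 <- j11 * amp; j12 <- j12 * amp; j21 <- j21 * amp; j22 <- j22 * amp

    if (is.finite(spec$snr_db)) {
      p0 <- spec$layers[[1]]$reflectivity
      nsd <- sqrt(p0 * 10^(-spec$snr_db / 10))
      j11 <- j11 + array(cplx_normal(nvox, nsd), dm)
      j12 <- j12 + array(cplx_normal(nvox, nsd), dm)
      j21 <- j21 + array(cplx_normal(nvox, nsd), dm)
      j22 <- j22 + array(cplx_normal(nvox, nsd), dm)
    }
  })

  vol <- jones_volume(j11, j12, j21, j22, spec$axial_pitch,
                      spec$lateral_pitch, spec$center_wavelength)
  gt <- list(
    mu = scalar_volume(array(prof$mu, dm), "mm^-1", "mu_true",
                       spec$axial_pitch, spec$lateral_pitch),
    delta_n = scalar_volume(array(prof$delta_n, dm), "delta_n",
                            "delta_n_true",
                            spec$axial_pitch, spec$lateral_pitch),
    dopu_expected = scalar_volume(array(1 - prof$scrambling, dm), "dopu",
                                  "dopu_expected",
                                  spec$axial_pitch, spec$lateral_pitch))
  list(volume = vol, ground_truth = gt)
}
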