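#' Synthetic tumor-versus-control JM-OCT dataset
#'
#' Generates a volume holding two laterally disjoint tissue regions with
#' per-B-scan masks: a muscle-like "control" region (high birefringence,
#' moderate polarization scrambling) and a "tumor" region whose optical
#' parameters are the control values plus configurable shifts. The default
#' effect lowers the tumor birefringence, lowers its scrambling (raising
#' DOPU homogeneity) and raises its attenuation - the direction of the
#' differences reported between cancer-affected and control tissue.
#'
#' @param effect Named list of tumor-minus-control parameter shifts:
#'   `delta_n`, `scrambling`, `mu` (any subset; missing entries default to
#'   the values below). Zero shifts give identical ground truths.
#' @param n_bscans B-scans per volume (default 32).
#' @param seed Integer RNG seed.
#' @param control Named list of control-tissue parameters
#'   (`delta_n`, `scrambling`, `mu`, `reflectivity`).
#' @param axial_size,lateral_size Volume dimensions; the two regions split
#'   the lateral extent.
#' @param snr_db Detection SNR (dB).
#' @return List: `volume` ([jones_volume()]), `masks`
#'   ([region_mask_set()] with labels `tumor`, `control`), `ground_truth`
#'   (as in [generate_phantom()]), `params` (resolved per-region
#'   parameters), `noise_floor` (linear intensity units).
#' @export
generate_tumor_control_dataset <- function(
    effect = list(delta_n = -1e-3, scrambling = -0.15, mu = 1.0),
    n_bscans = 32, seed = 1,
    control = list(delta_n = 1.5e-3, scrambling = 0.25, mu = 2.0,
                   reflectivity = 1),
    axial_size = 96, lateral_size = 96, snr_db = 25) {
  eff <- list(delta_n = 0, scrambling = 0, mu = 0)
  eff[names(effect)] <- effect
  tumor <- list(delta_n = control$delta_n + eff$delta_n,
                scrambling = control$scrambling + eff$scrambling,
                mu = control$mu + eff$mu,
                reflectivity = control$reflectivity)
  if (tumor$delta_n < 0 || tumor$scrambling < 0 || tumor$scrambling > 1 ||
      tumor$mu < 0)
    stop("effect shifts push tumor parameters out of their valid range")

  half <- lateral_size %/% 2
  mk_spec <- function(p, s) phantom_spec(
    phantom_layer(axial_size, mu = p$mu, delta_n = p$delta_n,
                  scrambling = p$scrambling,
                  reflectivity = p$reflectivity),
    lateral_size = half, axial_size = axial_size, n_bscans = n_bscans,
    snr_db = snr_db, seed = s)
  ph_c <- generate_phantom(mk_spec(control, seed))
  ph_t <- generate_phantom(mk_spec(tumor, seed + 1L))

  cat2 <- function(a, b) {
    out <- array(if (is.complex(a)) 0i else 0,
                 dim = c(dim(a)[1], dim(a)[2] + dim(b)[2], dim(a)[3]))
    out[, seq_len(dim(a)[2]), ] <- a
    out[, dim(a)[2] + seq_len(dim(b)[2]), ] <- b
    out
  }
  vc <- ph_c$volume; vt <- ph_t$volume
  vol <- jones_volume(cat2(vc$j11, vt$j11), cat2(vc$j12, vt$j12),
                      cat2(vc$j21, vt$j21), cat2(vc$j22, vt$j22),
                      vc$axial_pitch, vc$lateral_pitch,
                      vc$center_wavelength)
  gt <- purrr::map2(ph_c$ground_truth, ph_t$ground_truth, function(a, b)
    scalar_volume(cat2(a$data, b$data), a$units, a$contrast,
                  a$axial_pitch, a$lateral_pitch))

  # masks keep a margin from the surface, the attenuated tail and the seam
  dm <- dim(vol)
  zi <- seq(max(4, round(dm[1] * 0.05)), round(dm[1] * 0.85))
  mg <- max(2, round(half * 0.08))
  ctrl_x <- seq(mg, half - mg)
  tum_x <- seq(half + mg, 2 * half - mg)
  base <- array(FALSE, dm)
  m_ctrl <- base; m_ctrl[zi, ctrl_x, ] <- TRUE
  m_tum <- base; m_tum[zi, tum_x, ] <- TRUE
  masks <- region_mask_set(tumor = m_tum, control = m_ctrl,
                           volume_ref = "synthetic_tumor_control")

  noise_floor <- control$reflectivity * 10^(-snr_db / 10)
  list(volume = vol, masks = masks, ground_truth = gt,
       params = list(control = control, tumor = tumor, effect = eff),
       noise_floor = noise_floor)
}

#' Compute the four JM-OCT contrasts of a volume
#'
#' Convenience wrapper running [scatter_intensity()] (linear and dB),
#' [attenuation_depth_resolved()], [local_birefringence()] and [dopu()]
#' with shared defaults, returning the named list of contrasts that
#' [quantify_regions()] expects.
#'
#' @param jones A [jones_volume()].
#' @param noise_floor Passed to [local_birefringence()].
#' @param estimator Birefringence estimator (`"naive"` or `"map"`).
#' @param depth_sep,dopu_kernel Estimator geometry.
#' @return Named list of [scalar_volume()]s: `intensity_db`, `intensity`,
#'   `attenuation`, `birefringence`, `reliability`, `dopu`.
#' @export
compute_contrasts <- function(jones, noise_floor = NULL,
                              estimator = "naive", depth_sep = 2,
                              dopu_kernel = c(3, 5)) {
  ilin <- scatter_intensity(jones)
  bir <- local_birefringence(jones, depth_sep = depth_sep,
                             estimator = estimator,
                             noise_floor = noise_floor)
  list(intensity_db = scatter_intensity(jones, db = TRUE),
       intensity = ilin,
       attenuation = attenuation_depth_resolved(ilin),
       birefringence = bir$delta_n,
       reliability = bir$reliability,
       dopu = dopu(jones, kernel = dopu_kernel))
}
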