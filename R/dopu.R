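#' Degree of polarization uniformity (DOPU)
#'
#' For each incident polarization channel (column of the Jones matrix) the
#' per-voxel Stokes vector is formed, normalized by its intensity, and
#' averaged over a centered spatial kernel; the channel DOPU is the length
#' of that mean vector, and the output is the mean over the two channels.
#' A spatially uniform polarization state gives exactly 1; per-speckle
#' random states drive the kernel mean toward the resultant length of
#' isotropic unit vectors.
#'
#' With `(Eh, Ev)` the channel's field, the Stokes components are
#' `I = |Eh|^2 + |Ev|^2`, `Q = |Eh|^2 - |Ev|^2`, `U = 2 Re(Eh Ev*)`,
#' `V = -2 Im(Eh Ev*)`. Zero-intensity voxels are excluded from the kernel
#' mean; the kernel is truncated at volume borders.
#'
#' @param jones A [jones_volume()].
#' @param kernel Odd `(z, x)` kernel size in pixels; default `c(3, 5)`
#'   spans several speckles at the system pitches while limiting axial
#'   blur.
#' @return A [scalar_volume()] with values in \[0, 1\] (`NA` where the
#'   whole kernel has zero intensity).
#' @export
dopu <- function(jones, kernel = c(3, 5)) {
  stopifnot(inherits(jones, "jones_volume"), length(kernel) == 2)
  kz <- as.integer(kernel[1]); kx <- as.integer(kernel[2])
  if (kz < 1 || kx < 1 || kz %% 2 == 0 || kx %% 2 == 0)
    stop("kernel sizes must be odd and >= 1")
  dm <- dim(jones)
  if (kz > dm[1] || kx > dm[2]) stop("kernel larger than the volume")

  channel <- function(eh, ev) {
    s0 <- Mod(eh)^2 + Mod(ev)^2
    cross <- eh * Conj(ev)
    ok <- s0 > 0
    q <- u <- v <- array(NA_real_, dm)
    q[ok] <- ((Mod(eh)^2 - Mod(ev)^2) / s0)[ok]
    u[ok] <- (2 * Re(cross) / s0)[ok]
    v[ok] <- (-2 * Im(cross) / s0)[ok]
    sqrt(box_mean(q, kz, kx)^2 + box_mean(u, kz, kx)^2 +
         box_mean(v, kz, kx)^2)
  }
  d <- (channel(jones$j11, jones$j21) + channel(jones$j12, jones$j22)) / 2
  d <- pmin(d, 1)
  scalar_volume(array(d, dm), "dopu", "dopu",
                jones$axial_pitch, jones$lateral_pitch)
}
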