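# Independent oracles and fixture builders shared across test files.

# per-voxel brute-force intensity: mean of the four |entry|^2
oracle_intensity <- function(jv) {
  dm <- dim(jv)
  out <- array(NA_real_, dm)
  for (z in seq_len(dm[1])) for (x in seq_len(dm[2])) for (y in seq_len(dm[3]))
    out[z, x, y] <- (Mod(jv$j11[z, x, y])^2 + Mod(jv$j12[z, x, y])^2 +
                     Mod(jv$j21[z, x, y])^2 + Mod(jv$j22[z, x, y])^2) / 4
  out
}

# Monte-Carlo mean resultant length of n isotropic unit vectors in R^3
oracle_resultant_length <- function(n, reps = 4000) {
  mean(replicate(reps, {
    v <- matrix(rnorm(3 * n), nrow = 3)
    v <- v / rep(sqrt(colSums(v^2)), each = 3)
    sqrt(sum(rowMeans(v)^2))
  }))
}

# exact two-sided Mann-Whitney p by enumerating group assignments of the
# observed values and counting discordant pairs directly (independent of
# the rank-sum implementation)
oracle_mw_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  ustat <- function(x, y) sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  u_obs <- ustat(a, b)
  m <- n1 * n2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx)
    ustat(pooled[idx], pooled[-idx]))
  mean(abs(u_all - m / 2) >= abs(u_obs - m / 2) - 1e-12)
}

# one-way ANOVA F on |deviations from group centers|, coded from the
# sums-of-squares definition
oracle_levene_w <- function(a, b, center = mean) {
  z <- c(abs(a - center(a)), abs(b - center(b)))
  g <- factor(rep(1:2, c(length(a), length(b))))
  zbar <- mean(z)
  ssb <- sum(tapply(z, g, length) * (tapply(z, g, mean) - zbar)^2)
  ssw <- sum((z - ave(z, g))^2)
  (ssb / 1) / (ssw / (length(z) - 2))
}

# FWHM of a peaked profile with linear subpixel interpolation at the
# half-maximum crossings
profile_fwhm <- function(p) {
  m <- max(p)
  i0 <- which.max(p)
  half <- m / 2
  left <- i0
  while (left > 1 && p[left - 1] > half) left <- left - 1
  right <- i0
  while (right < length(p) && p[right + 1] > half) right <- right + 1
  xl <- if (left == 1) left else
    (left - 1) + (half - p[left - 1]) / (p[left] - p[left - 1])
  xr <- if (right == length(p)) right else
    right + (half - p[right]) / (p[right + 1] - p[right])
  xr - xl
}

# textured test scene with local spatial correlation (stitchable)
make_scene <- function(nr, nc, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc), nr, nc)
  m <- t(apply(m, 1, function(r) stats::filter(r, rep(1, 7), circular = TRUE)))
  m <- apply(m, 2, function(cc) stats::filter(cc, rep(1, 7), circular = TRUE))
  matrix(as.numeric(m), nr, nc)
}

# phantom whose round-trip retardation per depth_sep pixels equals delta
retarder_phantom <- function(delta, depth_sep = 2, nz = 32, nx = 8,
                             snr_db = Inf, seed = 1) {
  lambda0 <- 1.31; pitch <- 7.24
  dn <- delta * lambda0 / (4 * pi * depth_sep * pitch)
  phantom_spec(phantom_layer(nz, delta_n = dn), lateral_size = nx,
               axial_size = nz, snr_db = snr_db, seed = seed)
}
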