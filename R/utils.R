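# Internal helpers: vectorized 2x2 complex algebra, kernel means, RNG scoping.

# Jones volumes store the 2x2 matrix in four parallel complex arrays
# (j11, j12, j21, j22). All per-voxel algebra below is elementwise over
# arrays of identical shape, so a whole volume is processed per call.

#' @noRd
cplx_normal <- function(n, sd = 1) {
  complex(real = stats::rnorm(n, sd = sd / sqrt(2)),
          imaginary = stats::rnorm(n, sd = sd / sqrt(2)))
}

# matrix product C = A %*% B, elementwise over parallel entry arrays
#' @noRd
m22_mult <- function(a, b) {
  list(j11 = a$j11 * b$j11 + a$j12 * b$j21,
       j12 = a$j11 * b$j12 + a$j12 * b$j22,
       j21 = a$j21 * b$j11 + a$j22 * b$j21,
       j22 = a$j21 * b$j12 + a$j22 * b$j22)
}

#' @noRd
m22_transpose <- function(a) {
  list(j11 = a$j11, j12 = a$j21, j21 = a$j12, j22 = a$j22)
}

#' @noRd
m22_det <- function(a) a$j11 * a$j22 - a$j12 * a$j21

# inverse; caller handles det == 0
#' @noRd
m22_inv <- function(a) {
  d <- m22_det(a)
  list(j11 = a$j22 / d, j12 = -a$j12 / d,
       j21 = -a$j21 / d, j22 = a$j11 / d)
}

# eigenvalues of a 2x2 complex matrix, vectorized:
# lambda = (tr +- sqrt(tr^2 - 4 det)) / 2
#' @noRd
m22_eigenvalues <- function(a) {
  tr <- a$j11 + a$j22
  disc <- sqrt(as.complex(tr * tr - 4 * m22_det(a)))
  list(l1 = (tr + disc) / 2, l2 = (tr - disc) / 2)
}

# absolute eigen-phase difference wrapped to [0, pi]
#' @noRd
m22_eigenphase_diff <- function(a) {
  ev <- m22_eigenvalues(a)
  d <- Arg(ev$l1) - Arg(ev$l2)
  d <- (d + pi) %% (2 * pi) - pi
  abs(d)
}

# single-pass linear retarder: rotation(theta) diag(e^{i phi/2}, e^{-i phi/2})
# rotation(-theta); returns a plain 2x2 complex matrix
#' @noRd
retarder_matrix <- function(phi, theta = 0) {
  d <- diag(c(exp(1i * phi / 2), exp(-1i * phi / 2)))
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rot %*% d %*% t(rot)
}

# moving-average over a centered (kz x kx) window applied to every B-scan
# plane of a [nz, nx, ny] array; NA entries are excluded from each local
# mean (truncated window at the borders). Pure R separable implementation.
#' @noRd
box_mean <- function(x, kz, kx) {
  stopifnot(kz >= 1, kx >= 1, kz %% 2 == 1, kx %% 2 == 1)
  dm <- dim(x)
  if (is.null(dm)) dm <- c(length(x), 1L, 1L)
  if (length(dm) == 2) dm <- c(dm, 1L)
  x <- array(x, dm)
  w <- array(as.numeric(!is.na(x)), dm)
  x[is.na(x)] <- 0
  run1 <- function(a, k) {
    # running sum of window k along dim 1 via padded cumsum
    if (k == 1) return(a)
    h <- (k - 1L) / 2L
    n <- dim(a)[1]
    cs <- apply(a, c(2, 3), cumsum)
    cs <- array(cs, dim(a))
    pad <- array(0, c(1, dim(a)[2], dim(a)[3]))
    csp <- abind1(pad, cs)                       # csp[i+1,,] = sum(a[1..i])
    hi <- pmin(seq_len(n) + h, n)
    lo <- pmax(seq_len(n) - h, 1L)
    csp[hi + 1L, , , drop = FALSE] - csp[lo, , , drop = FALSE]
  }
  run2 <- function(a, k) aperm(run1(aperm(a, c(2, 1, 3)), k), c(2, 1, 3))
  s <- run2(run1(x, kz), kx)
  n <- run2(run1(w, kz), kx)
  out <- s / n
  out[n == 0] <- NA_real_
  out
}

# minimal abind along dim 1 for 3-d arrays
#' @noRd
abind1 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

# evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x
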