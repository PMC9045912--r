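# Tile registration and stitching for large field-of-view acquisitions.
#
# Tiles acquired on an x-y translation stage overlap laterally by a small
# fraction (5% by default). Pairwise integer-pixel offsets are recovered
# by phase correlation on en-face intensity projections, chained along the
# acquisition order into a global layout, and blended onto one canvas.

#' Register one image pair by phase correlation
#'
#' Computes the normalized cross-power spectrum of the two images and
#' takes the inverse-transform peak, restricted to
#' `expected_offset +- search_margin`. The returned offset `(dy, dx)`
#' places the origin of `b` in the coordinate frame of `a`: where the
#' images overlap, `b[i, j] == a[i + dy, j + dx]`.
#'
#' @param a,b Numeric matrices of identical shape (en-face projections).
#' @param expected_offset Integer `(dy, dx)` prior for the offset (e.g.
#'   from the stage position).
#' @param search_margin Integer `(dy, dx)` half-width of the search window
#'   around `expected_offset`.
#' @return A list with `offset` (integer vector) and `confidence` (ratio
#'   of the correlation peak to the strongest peak elsewhere; 0 for a
#'   flat, unregistrable input).
#' @export
register_pair <- function(a, b, expected_offset = c(0, 0),
                          search_margin = c(20, 20)) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  expected_offset <- as.integer(round(expected_offset))
  search_margin <- as.integer(abs(search_margin))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(offset = expected_offset, confidence = 0))
  n1 <- nrow(a); n2 <- ncol(a)
  cross <- Conj(stats::fft(a)) * stats::fft(b)
  mag <- Mod(cross)
  mag[mag == 0] <- 1
  r <- Re(stats::fft(cross / mag, inverse = TRUE)) / length(cross)

  # b[i,j] = a[i+dy, j+dx]  <=>  b shifted by -d  => correlation peak at
  # surface index (-d) mod n
  cand_y <- (expected_offset[1] - search_margin[1]):
            (expected_offset[1] + search_margin[1])
  cand_x <- (expected_offset[2] - search_margin[2]):
            (expected_offset[2] + search_margin[2])
  iy <- ((-cand_y) %% n1) + 1L
  ix <- ((-cand_x) %% n2) + 1L
  win <- r[iy, ix, drop = FALSE]
  pk <- arrayInd(which.max(win), dim(win))
  offset <- c(cand_y[pk[1]], cand_x[pk[2]])
  peak <- win[pk]

  # second peak: global surface outside a 3x3 neighborhood of the chosen one
  py <- ((-offset[1]) %% n1) + 1L
  px <- ((-offset[2]) %% n2) + 1L
  excl_y <- ((py - 2L):(py)) %% n1 + 1L
  excl_x <- ((px - 2L):(px)) %% n2 + 1L
  r2 <- r
  r2[excl_y, excl_x] <- -Inf
  second <- max(r2)
  confidence <- if (second <= 0) Inf else max(peak, 0) / second
  list(offset = as.integer(offset), confidence = confidence)
}

#' Build a mosaic layout by chaining pairwise registrations
#'
#' Registers consecutive tiles of a strip (or row-major grid) acquired
#' with a known nominal overlap and chains the pairwise offsets into
#' global positions; the first tile anchors the origin. Registration runs
#' on en-face mean projections when tiles are volumes.
#'
#' @param tiles List of numeric matrices or [scalar_volume()]s sharing one
#'   shape.
#' @param nominal_grid `(rows, cols)` of the acquisition;
#'   default a single row.
#' @param overlap_fraction Nominal lateral overlap between neighboring
#'   tiles (default 0.05).
#' @param search_margin Search half-width in pixels around the nominal
#'   offset.
#' @return A tibble (the mosaic layout) with columns `tile`, `dy`, `dx`,
#'   `confidence`.
#' @export
register_tiles <- function(tiles, nominal_grid = c(1, length(tiles)),
                           overlap_fraction = 0.05, search_margin = c(20, 20)) {
  imgs <- lapply(tiles, tile_enface)
  n <- length(imgs)
  stopifnot(prod(nominal_grid) == n, overlap_fraction > 0,
            overlap_fraction < 1)
  dmi <- dim(imgs[[1]])
  step_x <- round(ncol(imgs[[1]]) * (1 - overlap_fraction))
  step_y <- round(nrow(imgs[[1]]) * (1 - overlap_fraction))
  pos <- matrix(0L, n, 2)
  conf <- rep(NA_real_, n)
  conf[1] <- Inf
  for (i in seq_len(n)[-1]) {
    rc <- c((i - 1) %/% nominal_grid[2], (i - 1) %% nominal_grid[2])
    prev <- if (rc[2] == 0) i - nominal_grid[2] else i - 1
    expected <- if (rc[2] == 0) c(step_y, 0L) else c(0L, step_x)
    reg <- register_pair(imgs[[prev]], imgs[[i]], expected, search_margin)
    pos[i, ] <- pos[prev, ] + reg$offset
    conf[i] <- reg$confidence
  }
  tibble::tibble(tile = seq_len(n), dy = pos[, 1], dx = pos[, 2],
                 confidence = conf)
}

#' @noRd
tile_enface <- function(t) {
  if (inherits(t, "scalar_volume")) {
    d <- dim(t$data)
    m <- apply(t$data, c(2, 3), mean, na.rm = TRUE)
    if (d[3] == 1) matrix(m, d[2], 1) else m
  } else as.matrix(t)
}

#' Stitch registered tiles onto one canvas
#'
#' Places every tile at its layout offset and blends overlaps either by
#' feathering (linear cross-fade with per-pixel weights proportional to
#' the distance from the tile border, normalized to sum to 1) or by
#' overwrite (later tile wins). Volumes are stitched laterally, slice by
#' slice, with the same 2-D layout.
#'
#' @param tiles List of matrices or [scalar_volume()]s of one shape.
#' @param layout Tibble from [register_tiles()] (columns `tile`, `dy`,
#'   `dx`), or a two-column matrix of offsets.
#' @param blend `"feather"` or `"overwrite"`.
#' @return A matrix (or [scalar_volume()]) covering the offset envelope;
#'   canvas pixels covered by no tile are `NA`.
#' @export
stitch <- function(tiles, layout, blend = c("feather", "overwrite")) {
  blend <- match.arg(blend)
  is_vol <- inherits(tiles[[1]], "scalar_volume")
  if (is.data.frame(layout)) off <- cbind(layout$dy, layout$dx)
  else off <- as.matrix(layout)
  if (nrow(off) != length(tiles)) stop("layout must cover all tiles")
  off <- sweep(off, 2, apply(off, 2, min))      # anchor canvas at (0, 0)

  if (is_vol) {
    dm <- dim(tiles[[1]]$data)
    planes <- lapply(seq_len(dm[1]), function(z) {
      stitch(lapply(tiles, function(t)
        matrix(t$data[z, , ], dm[2], dm[3])), off, blend)
    })
    out <- array(NA_real_, c(dm[1], dim(planes[[1]])))
    for (z in seq_along(planes)) out[z, , ] <- planes[[z]]
    return(scalar_volume(out, tiles[[1]]$units, tiles[[1]]$contrast,
                         tiles[[1]]$axial_pitch, tiles[[1]]$lateral_pitch))
  }

  h <- nrow(tiles[[1]]); wd <- ncol(tiles[[1]])
  check_connected(off, h, wd)
  ch <- max(off[, 1]) + h
  cw <- max(off[, 2]) + wd
  acc <- matrix(0, ch, cw)
  wacc <- matrix(0, ch, cw)
  wy <- pmin(seq_len(h), h + 1 - seq_len(h))
  wx <- pmin(seq_len(wd), wd + 1 - seq_len(wd))
  wtile <- outer(wy, wx, pmin)                   # distance-to-border weight
  for (i in seq_along(tiles)) {
    t <- as.matrix(tiles[[i]])
    ri <- off[i, 1] + seq_len(h)
    ci <- off[i, 2] + seq_len(wd)
    if (blend == "feather") {
      acc[ri, ci] <- acc[ri, ci] + t * wtile
      wacc[ri, ci] <- wacc[ri, ci] + wtile
    } else {
      acc[ri, ci] <- t
      wacc[ri, ci] <- 1
    }
  }
  out <- acc / ifelse(wacc > 0, wacc, NA)
  if (blend == "overwrite") out <- acc
  out[wacc == 0] <- NA_real_
  out
}

# tiles whose bounding boxes neither overlap nor touch any other tile make
# the canvas disconnected
#' @noRd
check_connected <- function(off, h, w) {
  n <- nrow(off)
  if (n == 1) return(invisible(TRUE))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    adj[i, j] <- adj[j, i] <-
      abs(off[i, 1] - off[j, 1]) <= h && abs(off[i, 2] - off[j, 2]) <= w
  }
  seen <- rep(FALSE, n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    nb <- which(adj[cur, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen)) stop("tile offsets produce a disconnected canvas")
  invisible(TRUE)
}
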