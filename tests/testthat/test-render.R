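test_that("zero reliability renders a pure grayscale intensity image", {
  set.seed(30)
  idb <- matrix(runif(60, -30, 0), 10, 6)
  dn <- matrix(runif(60, 0, 2e-3), 10, 6)
  rel <- matrix(0, 10, 6)
  img <- pseudo_color_birefringence(idb, dn, rel)
  v <- pmin(pmax((idb + 30) / 30, 0), 1)
  expect_equal(img$rgb[, , 1], img$rgb[, , 2])
  expect_equal(img$rgb[, , 2], img$rgb[, , 3])
  expect_equal(img$rgb[, , 1], v, tolerance = 1 / 255)
})

test_that("reliable pixels map range endpoints to the colormap endpoints", {
  idb <- matrix(0, 1, 2)                       # full brightness
  dn <- matrix(c(0, 2e-3), 1, 2)               # range min and max
  rel <- matrix(1, 1, 2)
  img <- pseudo_color_birefringence(idb, dn, rel, threshold = 0.7,
                                    value_range = c(0, 2e-3),
                                    hue_range = c(2 / 3, 0))
  first <- grDevices::col2rgb(grDevices::hsv(2 / 3, 1, 1)) / 255
  last <- grDevices::col2rgb(grDevices::hsv(0, 1, 1)) / 255
  expect_equal(as.vector(img$rgb[1, 1, ]), as.vector(first))
  expect_equal(as.vector(img$rgb[1, 2, ]), as.vector(last))
})

test_that("pseudo-color output equals a pixel-wise scalar reference", {
  set.seed(31)
  idb <- matrix(runif(48, -35, 0), 8, 6)
  dn <- matrix(runif(48, -5e-4, 3e-3), 8, 6)
  rel <- matrix(runif(48), 8, 6)
  img <- pseudo_color_birefringence(idb, dn, rel, threshold = 0.6)
  ref_pixel <- function(i, d, r) {
    v <- min(max((i + 30) / 30, 0), 1)
    t <- min(max(d / 2e-3, 0), 1)
    if (!is.na(d) && r >= 0.6)
      grDevices::col2rgb(grDevices::hsv(2 / 3 * (1 - t), 1, v)) / 255
    else rep(v, 3)
  }
  for (i in c(1, 4, 8)) for (j in c(1, 3, 6))
    expect_equal(as.vector(img$rgb[i, j, ]),
                 as.vector(ref_pixel(idb[i, j], dn[i, j], rel[i, j])),
                 tolerance = 1 / 255)
})

test_that("DOPU composite grays out the background below the floor", {
  idb <- matrix(-29, 4, 4)
  dp <- matrix(0.8, 4, 4)
  img <- dopu_composite(idb, dp, intensity_floor = -25)
  expect_equal(img$rgb[, , 1], img$rgb[, , 2])
  expect_equal(img$rgb[, , 2], img$rgb[, , 3])
  fg <- dopu_composite(matrix(-5, 4, 4), matrix(1, 4, 4))
  # uniform DOPU foreground: one hue everywhere
  expect_equal(length(unique(as.vector(fg$rgb[, , 1]))), 1)
  expect_false(isTRUE(all.equal(fg$rgb[, , 1], fg$rgb[, , 2])))
})

test_that("legend parameters re-run to a bit-identical image", {
  set.seed(32)
  idb <- matrix(runif(40, -30, 0), 8, 5)
  dn <- matrix(runif(40, 0, 2e-3), 8, 5)
  rel <- matrix(runif(40), 8, 5)
  a <- pseudo_color_birefringence(idb, dn, rel, threshold = 0.55,
                                  value_range = c(1e-4, 1.8e-3))
  b <- pseudo_color_birefringence(idb, dn, rel,
                                  threshold = a$legend$reliability_threshold,
                                  value_range = a$legend$value_range)
  expect_identical(a$rgb, b$rgb)
})

test_that("en-face projections match brute force and handle single slices", {
  set.seed(33)
  x <- array(rnorm(9 * 7 * 5), c(9, 7, 5))
  x[sample(length(x), 20)] <- NA
  vol <- scalar_volume(x, "linear")
  expect_equal(enface_projection(vol, c(4, 4), "mean"),
               matrix(x[4, , ], 7, 5))
  for (mode in c("mean", "max")) {
    got <- enface_projection(vol, c(2, 6), mode)
    f <- if (mode == "mean") mean else max
    for (i in 1:7) for (j in 1:5) {
      v <- x[2:6, i, j]; v <- v[!is.na(v)]
      expect_equal(got[i, j], if (length(v)) f(v) else NA_real_)
    }
  }
  const <- scalar_volume(array(1.5, c(4, 3, 2)), "linear")
  expect_equal(enface_projection(const, c(1, 4), "mean"),
               matrix(1.5, 3, 2))
  expect_error(enface_projection(vol, c(0, 3)), "z_range")
  expect_error(enface_projection(vol, c(5, 20)), "z_range")
})

test_that("permuting lateral positions permutes the rendering identically", {
  set.seed(34)
  idb <- matrix(runif(60, -30, 0), 6, 10)
  dn <- matrix(runif(60, 0, 2e-3), 6, 10)
  rel <- matrix(runif(60), 6, 10)
  perm <- sample(10)
  a <- pseudo_color_birefringence(idb, dn, rel)
  b <- pseudo_color_birefringence(idb[, perm], dn[, perm], rel[, perm])
  expect_identical(a$rgb[, perm, ], b$rgb)
})
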