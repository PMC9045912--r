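test_that("Mann-Whitney handles the canonical small-sample cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p, 0.1)             # 2 of the 20 rank assignments
  expect_equal(r$method, "exact")

  same <- mann_whitney_u(c(2, 5, 9, 9), c(5, 2, 9, 9))
  expect_equal(same$u, 8)            # n1*n2/2 for identical multisets
  expect_equal(same$p, 1)

  degen <- mann_whitney_u(rep(3, 5), rep(3, 4))
  expect_equal(degen$p, 1)
})

test_that("exact p equals the enumeration oracle for tie-free n1, n2 <= 7", {
  set.seed(14)
  for (n1 in c(1, 2, 3, 5, 7)) for (n2 in c(1, 3, 4, 7)) {
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    got <- mann_whitney_u(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p, oracle_mw_exact_p(x, y),
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("the approximate path agrees with wilcox.test on larger samples", {
  set.seed(15)
  x <- rnorm(25); y <- rnorm(30, 0.5)
  got <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(got$u, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  # with ties
  xt <- round(rnorm(20), 1); yt <- round(rnorm(22, 0.3), 1)
  gt <- mann_whitney_u(xt, yt)
  rt <- stats::wilcox.test(xt, yt, correct = TRUE, exact = FALSE)
  expect_equal(gt$p, rt$p.value, tolerance = 1e-10)
})

test_that("Mann-Whitney p is invariant under strictly monotone transforms", {
  set.seed(16)
  x <- rexp(12); y <- rexp(15) * 1.6
  p0 <- mann_whitney_u(x, y)$p
  expect_equal(mann_whitney_u(log(x), log(y))$p, p0)
  expect_equal(mann_whitney_u(x^3, y^3)$p, p0)
  expect_equal(mann_whitney_u(exp(x), exp(y))$p, p0)
})

test_that("null rejection rate stays inside the binomial 99% band", {
  set.seed(17)
  reps <- 2000
  rej <- logical(reps)
  for (i in seq_len(reps))
    rej[i] <- mann_whitney_u(rnorm(20), rnorm(20))$p < 0.05
  band <- stats::qbinom(c(0.005, 0.995), reps, 0.05) / reps
  rate <- mean(rej)
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})

test_that("Levene test matches its definition and the car implementation", {
  expect_equal(levene_test(c(1, 2, 3, 4), c(1, 2, 3, 4))$w, 0)
  expect_equal(levene_test(c(1, 2, 3, 4), c(1, 2, 3, 4))$p, 1)

  set.seed(18)
  a <- rnorm(12); b <- rnorm(15)
  got <- levene_test(a, b)
  expect_equal(got$w, oracle_levene_w(a, b), tolerance = 1e-10)
  ref <- car::leveneTest(c(a, b), factor(rep(1:2, c(12, 15))),
                         center = mean)
  expect_equal(got$w, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(got$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)

  gmed <- levene_test(a, b, center = "median")
  refm <- car::leveneTest(c(a, b), factor(rep(1:2, c(12, 15))),
                          center = median)
  expect_equal(gmed$w, refm[["F value"]][1], tolerance = 1e-10)
})

test_that("Levene p decreases as the scale ratio grows", {
  set.seed(19)
  a <- rnorm(20)
  ps <- vapply(c(1.5, 3, 6, 12), function(s) levene_test(a, s * a)$p,
               numeric(1))
  expect_gt(levene_test(a, 10 * a)$w, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("box summaries follow the 1.5 IQR whisker rule", {
  b <- box_summary(1:5)
  expect_equal(b$median, 3); expect_equal(b$q25, 2); expect_equal(b$q75, 4)
  expect_equal(b$whisker_lo, 1); expect_equal(b$whisker_hi, 5)
  expect_equal(lengths(b$outliers), 0L, ignore_attr = TRUE)

  const <- box_summary(rep(2.5, 8))
  expect_equal(const$median, 2.5)
  expect_equal(const$whisker_lo, 2.5)
  expect_equal(const$whisker_hi, 2.5)
  expect_equal(lengths(const$outliers), 0L, ignore_attr = TRUE)

  far <- box_summary(c(1:9, 100))
  expect_equal(far$outliers[[1]], 100)
  expect_equal(far$whisker_hi, 9)
})

test_that("region means equal a per-voxel brute-force loop", {
  set.seed(20)
  x <- array(rnorm(10 * 8 * 4), c(10, 8, 4))
  x[sample(length(x), 25)] <- NA
  vol <- scalar_volume(x, "linear", axial_pitch = 7.24)
  m1 <- array(runif(length(x)) < 0.3, dim(x))
  m2 <- array(runif(length(x)) < 0.3, dim(x)) & !m1
  masks <- region_mask_set(tumor = m1, control = m2)
  got <- region_means_per_bscan(vol, masks)
  for (row in seq_len(nrow(got))) {
    lab <- got$label[row]; y <- got$bscan[row]
    m <- if (lab == "tumor") m1 else m2
    acc <- c()
    for (z in 1:10) for (xx in 1:8)
      if (m[z, xx, y] && !is.na(x[z, xx, y])) acc <- c(acc, x[z, xx, y])
    expect_equal(got$mean[row], mean(acc))
    expect_equal(got$n_voxels[row], length(acc))
  }
  # single-voxel mask returns that voxel
  single <- array(FALSE, dim(x)); single[4, 5, 2] <- TRUE
  other <- array(FALSE, dim(x)); other[1, 1, 1] <- TRUE
  ms <- region_mask_set(a = single, b = other)
  rm1 <- region_means_per_bscan(vol, ms)
  expect_equal(rm1$mean[rm1$label == "a"], x[4, 5, 2])
})

test_that("constant volumes give constant region means", {
  x <- array(2.25, c(6, 6, 3))
  vol <- scalar_volume(x, "linear")
  m1 <- array(FALSE, dim(x)); m1[2:4, 2:3, ] <- TRUE
  m2 <- array(FALSE, dim(x)); m2[2:4, 5:6, ] <- TRUE
  got <- region_means_per_bscan(vol, region_mask_set(t = m1, c = m2))
  expect_equal(unique(got$mean), 2.25)
  expect_equal(nrow(got), 6)
})

test_that("mask sets enforce naming, shape and disjointness", {
  m <- array(TRUE, c(2, 2, 1))
  expect_error(region_mask_set(m, m), "named")
  expect_error(region_mask_set(a = m, b = m), "disjoint")
  m2 <- array(FALSE, c(2, 3, 1))
  expect_error(region_mask_set(a = m, b = m2), "shape")
})

test_that("quantify_regions wires means, summaries, tests and tidiers together", {
  set.seed(22)
  dm <- c(12, 20, 10)
  base <- array(rnorm(prod(dm), 5), dm)
  eff <- base; eff[, 1:10, ] <- eff[, 1:10, ] - 2
  vols <- list(c1 = scalar_volume(eff, "linear"),
               c2 = scalar_volume(base, "linear"))
  mt <- array(FALSE, dm); mt[, 1:10, ] <- TRUE
  mc <- array(FALSE, dm); mc[, 11:20, ] <- TRUE
  rep <- quantify_regions(vols, region_mask_set(tumor = mt, control = mc),
                          animal_id = rep(1:2, each = 5))
  td <- generics::tidy(rep)
  expect_true(all(c("pooled", "animal:1", "animal:2") %in% td$scope))
  pooled <- td[td$scope == "pooled", ]
  expect_true(pooled$significant_mw[pooled$contrast == "c1"])
  expect_false(pooled$significant_mw[pooled$contrast == "c2"])
  expect_match(pooled$direction[pooled$contrast == "c1"], "tumor < control")
  gl <- generics::glance(rep)
  expect_equal(gl$n_bscans, 10)
  expect_equal(gl$n_contrasts, 2)
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
})
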