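test_that("zero spectra reconstruct to a zero image", {
  fr <- generate_fringes(matrix(numeric(0), 0, 2), n_samples = 256,
                         n_alines = 3, dc = 0, seed = 1)
  expect_equal(max(abs(fr$spectra)), 0)
  rec <- sdoct_reconstruct(fr)
  expect_equal(max(rec$data), 0)
})

test_that("a 0.5-mm reflector lands on depth pixel 200 at 2.5-um pitch", {
  fr <- generate_fringes(cbind(500, 1), n_samples = 1024, n_alines = 1,
                         axial_pitch = 2.5, dc = 0, seed = 1)
  rec <- sdoct_reconstruct(fr, recon_settings(subtract_mean = FALSE))
  expect_equal(rec$axial_pitch, 2.5, tolerance = 1e-9)
  expect_lte(abs((which.max(rec$data[, 1, 1]) - 1) - 200), 1)
})

test_that("matched dispersion compensation restores the peak width", {
  base <- generate_fringes(cbind(500.8, 1), 1024, dc = 0, seed = 2)
  rec0 <- sdoct_reconstruct(base, recon_settings(subtract_mean = FALSE))
  f0 <- profile_fwhm(rec0$data[, 1, 1])

  disp <- generate_fringes(cbind(500.8, 1), 1024, dispersion = c(200, 0),
                           dc = 0, seed = 2)
  rec_c <- sdoct_reconstruct(disp, recon_settings(subtract_mean = FALSE))
  fc <- profile_fwhm(rec_c$data[, 1, 1])
  expect_lt(abs(fc - f0) / f0, 0.10)

  uncomp <- disp
  uncomp$dispersion <- c(0, 0)       # reconstruct ignoring the true a2
  rec_u <- sdoct_reconstruct(uncomp, recon_settings(subtract_mean = FALSE))
  expect_gt(profile_fwhm(rec_u$data[, 1, 1]), fc)
})

test_that("average-spectrum subtraction nulls any static common component", {
  set.seed(6)
  fr <- generate_fringes(cbind(320, 1), 512, n_alines = 8, dc = 0,
                         phase_jitter = TRUE, seed = 6)
  rec1 <- sdoct_reconstruct(fr)
  fr2 <- fr
  static <- sin(seq(0, 40, length.out = 512)) + 2
  fr2$spectra <- sweep(fr2$spectra, 2, static, `+`)
  rec2 <- sdoct_reconstruct(fr2)
  expect_equal(rec1$data, rec2$data, tolerance = 1e-10)
})

test_that("linear-k input reconstructs identically with resampling on or off", {
  fr <- generate_fringes(cbind(410.3, 1), 512, dc = 1, k_warp = 0, seed = 4)
  on <- sdoct_reconstruct(fr, recon_settings(subtract_mean = FALSE,
                                             resample = TRUE))
  off <- sdoct_reconstruct(fr, recon_settings(subtract_mean = FALSE,
                                              resample = FALSE))
  expect_equal(on$data, off$data, tolerance = 1e-6)
})

test_that("a warped k grid still reconstructs a sharp peak after k-linearization", {
  fr <- generate_fringes(cbind(500.8, 1), 1024, k_warp = 0.3, dc = 0,
                         seed = 5)
  rec <- sdoct_reconstruct(fr, recon_settings(subtract_mean = FALSE))
  lin <- generate_fringes(cbind(500.8, 1), 1024, k_warp = 0, dc = 0,
                          seed = 5)
  rec_lin <- sdoct_reconstruct(lin, recon_settings(subtract_mean = FALSE))
  expect_equal(which.max(rec$data[, 1, 1]), which.max(rec_lin$data[, 1, 1]))
  expect_lt(profile_fwhm(rec$data[, 1, 1]),
            1.2 * profile_fwhm(rec_lin$data[, 1, 1]))
})

test_that("input validation rejects bad grids, NaNs and Nyquist violations", {
  expect_error(generate_fringes(cbind(2000, 1), n_samples = 256), "Nyquist")
  fr <- generate_fringes(cbind(100, 1), 256, dc = 0, seed = 1)
  fr$spectra[1, 5] <- NaN
  expect_error(sdoct_reconstruct(fr, recon_settings(subtract_mean = FALSE)),
               "finite")
  fr2 <- generate_fringes(cbind(100, 1), 256, dc = 0, seed = 1)
  fr2$k_grid <- rev(fr2$k_grid)
  expect_error(sdoct_reconstruct(fr2, recon_settings(subtract_mean = FALSE)),
               "increasing")
  fr3 <- generate_fringes(cbind(100, 1), 256, dc = 0, seed = 1)
  expect_error(sdoct_reconstruct(fr3, recon_settings(subtract_mean = TRUE)),
               "A-lines")
  expect_error(sdoct_reconstruct(fr3, recon_settings(subtract_mean = FALSE,
                                                     resample_points = 100)),
               "half")
})

test_that("output energy does not exceed the windowed input energy", {
  fr <- generate_fringes(cbind(300.6, 2), 512, dc = 0, noise_sd = 0.2,
                         seed = 9)
  rec <- sdoct_reconstruct(fr, recon_settings(subtract_mean = FALSE))
  # recompute the windowed spectrum energy the same way the pipeline does
  k <- fr$k_grid
  kc <- (k[1] + k[length(k)]) / 2
  w <- (k[length(k)] - k[1]) / 2
  win <- exp(-(k - kc)^2 / (2 * w^2))
  e_in <- sum(sweep(fr$spectra, 2, win, `*`)^2) * 512
  expect_lte(sum(rec$data), e_in)
})
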