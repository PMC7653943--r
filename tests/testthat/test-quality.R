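test_that("VOI SNR matches hand arithmetic and flags degenerate inputs", {
  vol <- volume_image(array(c(8, 12, 8, 12, 8, 12, 8, 12), c(2, 2, 2)), c(1, 1, 1))
  v <- voi(center = c(1.5, 1.5, 1.5), extents = c(2, 2, 2))
  expect_equal(snr_voi(vol, v), 10 * log10(5), tolerance = 1e-12)

  const <- volume_image(array(3, c(4, 4, 4)), c(1, 1, 1))
  vc <- voi(c(2.5, 2.5, 2.5), c(4, 4, 4))
  expect_error(snr_voi(const, vc), class = "gateopt_infinite_snr")

  neg <- volume_image(array(-1, c(4, 4, 4)), c(1, 1, 1))
  expect_error(snr_voi(neg, vc), class = "gateopt_undefined_snr")

  outside <- voi(c(2, 2, 2), c(40, 4, 4))
  expect_error(snr_voi(const, outside), class = "gateopt_bounds_error")
})

test_that("Poisson voxels give SNR near 5 log10(lambda)", {
  lambda <- 100
  withr::with_seed(31, {
    vol <- volume_image(array(rpois(17^3, lambda), c(17, 17, 17)), c(1, 1, 1))
  })
  v <- voi(c(9, 9, 9), c(17, 17, 17))
  expect_lt(abs(snr_voi(vol, v) - 5 * log10(lambda)), 0.3)
})

test_that("SNR is invariant under positive scaling of the image", {
  withr::with_seed(32, {
    vol <- volume_image(array(rpois(1000, 50), c(10, 10, 10)), c(1, 1, 1))
  })
  v <- voi(c(5.5, 5.5, 5.5), c(8, 8, 8))
  scaled <- vol
  scaled$voxels <- vol$voxels * 12.5
  expect_equal(snr_voi(scaled, v), snr_voi(vol, v))
})

test_that("scheme SNR works on the summed image and needs noise", {
  cfg <- small_config(noise = TRUE, invalid_fraction = 0, seed = 14)
  sc <- test_scanner(c(48, 48, 47))
  set <- simulate_gated_acquisition(cfg, sc, gate_scheme(1, 1), duration_s = 60)
  v <- voi(mm_to_index_for_test(set$volumes[[1]], c(0, 0, 0)), c(9, 9, 9))
  expect_equal(scheme_snr(set, v), snr_voi(set$volumes[[1]], v))

  flat <- volume_image(array(2, dim(set$volumes[[1]]$voxels)),
                       set$volumes[[1]]$voxel_size_mm)
  const_set <- gated_image_set(gate_scheme(1, 1), list(r1_c1 = flat),
                               tibble::tibble(resp_gate = 1L, card_gate = 1L,
                                              fraction = 1))
  expect_error(scheme_snr(const_set, v), class = "gateopt_infinite_snr")
})

test_that("the SNR curve fit is exact on log-law data and rejects one point", {
  exact <- fit_snr_curve(data.frame(n_total = c(1, 10, 100),
                                    snr_db = c(20, 15, 10)))
  expect_equal(exact$a, 20, tolerance = 1e-10)
  expect_equal(exact$b, -5, tolerance = 1e-10)
  expect_equal(exact$rmse_db, 0, tolerance = 1e-10)

  two <- fit_snr_curve(data.frame(n_total = c(2, 20), snr_db = c(14, 11)))
  expect_equal(two$rmse_db, 0, tolerance = 1e-10)

  expect_error(fit_snr_curve(data.frame(n_total = c(4, 4), snr_db = c(1, 2))),
               class = "gateopt_degenerate_fit")
})

test_that("the 3 dB rule accepts the reference loss and rejects larger ones", {
  expect_true(snr_criterion(20, 18.3))
  expect_false(snr_criterion(20, 16.9))
  expect_true(snr_criterion(15, 15))
})

test_that("profiles interpolate trilinearly along the segment", {
  const <- volume_image(array(4, c(10, 10, 10)), c(2, 2, 2))
  prof <- extract_profile(const, c(-5, 0, 0), c(5, 0, 0))
  expect_true(all(abs(prof$values - 4) < 1e-12))

  blob <- volume_image(array(0, c(21, 21, 21)), c(2, 2, 2))
  xs <- seq(-20, 20, by = 2)
  blob$voxels <- exp(-outer(outer(xs^2, xs^2, "+"), xs^2, "+") / (2 * 36))
  p <- extract_profile(blob, c(-16, 0, 0), c(16, 0, 0), spacing_mm = 0.5)
  peak_at <- p$positions_mm[which.max(p$values)]
  expect_lt(abs(peak_at - 16), p$spacing_mm)
  expect_equal(p$values, rev(p$values), tolerance = 1e-9)

  expect_error(extract_profile(const, c(0, 0, 0), c(0, 0, 0)),
               class = "gateopt_bounds_error")
  expect_error(extract_profile(const, c(-50, 0, 0), c(5, 0, 0)),
               class = "gateopt_bounds_error")
})

test_that("FWHM matches linear geometry and the Gaussian identity", {
  triangle <- c(0, 2, 4, 6, 8, 10, 8, 6, 4, 2, 0)
  expect_equal(fwhm(triangle, spacing_mm = 1), 5)

  x <- seq(-20, 20, by = 0.05)
  gauss <- exp(-x^2 / (2 * 9))
  expect_lt(abs(fwhm(gauss, spacing_mm = 0.05) - 2.3548 * 3) / (2.3548 * 3), 0.02)

  expect_error(fwhm(c(1, 2, 3, 4), spacing_mm = 1), class = "gateopt_open_profile")
})

test_that("FWHM is affine-intensity invariant and spatially equivariant", {
  x <- seq(-15, 15, by = 0.1)
  prof <- exp(-x^2 / (2 * 4)) + 0.2
  w <- fwhm(prof, spacing_mm = 0.1)
  expect_equal(fwhm(5 * prof + 3, spacing_mm = 0.1), w, tolerance = 1e-9)
  expect_equal(fwhm(prof, spacing_mm = 0.2), 2 * w, tolerance = 1e-9)
})

test_that("relative FWHM difference matches the printed arithmetic", {
  expect_equal(relative_fwhm_difference(27, 35), -22.857, tolerance = 1e-4)
  expect_equal(relative_fwhm_difference(10, 10), 0)
  expect_equal(relative_fwhm_difference(76, 100), -24)
  expect_error(relative_fwhm_difference(10, 0), class = "gateopt_input_error")
})
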