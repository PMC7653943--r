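make_blob_volume <- function(centre_mm, sigma = 4, shape = c(32, 32, 24),
                             voxel = c(2, 2, 3), background = 0) {
  vol <- volume_image(array(background, shape), voxel)
  xs <- vol$origin_mm[1] + (seq_len(shape[1]) - 1) * voxel[1]
  ys <- vol$origin_mm[2] + (seq_len(shape[2]) - 1) * voxel[2]
  zs <- vol$origin_mm[3] + (seq_len(shape[3]) - 1) * voxel[3]
  vol$voxels <- vol$voxels +
    exp(-outer(outer((xs - centre_mm[1])^2, (ys - centre_mm[2])^2, "+"),
               (zs - centre_mm[3])^2, "+") / (2 * sigma^2))
  vol
}

test_that("hot-spot localisation is exact for a bright voxel and sub-voxel for blobs", {
  v <- volume_image(array(0, c(9, 9, 9)), c(2, 2, 2))
  v$voxels[5, 6, 4] <- 1
  expect_equal(locate_hotspot(v, "local_max"),
               c(5 - 5, 6 - 5, 4 - 5) * 2)

  truth <- c(1.3, -2.1, 0.8) # off-grid centre
  blob <- make_blob_volume(truth)
  p <- locate_hotspot(blob, "weighted90")
  expect_lt(max(abs(p - truth) / blob$voxel_size_mm), 0.25)

  two <- make_blob_volume(c(-10, 0, 0))
  two$voxels <- two$voxels + 0.6 * make_blob_volume(c(10, 0, 0))$voxels
  pa <- locate_hotspot(two, "weighted90")
  expect_lt(abs(pa[1] + 10), 1)

  flat <- volume_image(array(1, c(5, 5, 5)), c(2, 2, 2))
  expect_error(locate_hotspot(flat), class = "gateopt_localisation_failure")
})

test_that("search regions confine the locator", {
  two <- make_blob_volume(c(-10, 0, 0))
  two$voxels <- two$voxels + 0.6 * make_blob_volume(c(10, 0, 0))$voxels
  region <- list(lo = c(20, 1, 1), hi = c(32, 32, 24))
  p <- locate_hotspot(two, "weighted90", search_region = region)
  expect_lt(abs(p[1] - 10), 1.5)
})

test_that("myocardium extraction recovers the generator's shell", {
  cfg <- phantom_config(seed = 5)
  sc <- test_scanner(c(48, 48, 47))
  ax <- c(30, 30, 30)
  v <- gen_myocardium_volume(0.5, 0, cfg, sc, semiaxes_mm = ax,
                             wall_thickness_mm = 10)
  mask <- extract_myocardium(v, 0.5)

  # ground-truth shell membership at voxel centres
  xs <- v$origin_mm[1] + (seq_len(dim(v$voxels)[1]) - 1) * v$voxel_size_mm[1]
  ys <- v$origin_mm[2] + (seq_len(dim(v$voxels)[2]) - 1) * v$voxel_size_mm[2]
  zs <- v$origin_mm[3] + (seq_len(dim(v$voxels)[3]) - 1) * v$voxel_size_mm[3]
  r <- sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))
  truth <- r <= ax[1] & r >= ax[1] - 10
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gt(dice, 0.95)

  # monotone shrinkage with threshold
  expect_lt(sum(extract_myocardium(v, 0.9)), sum(mask))
  zero <- volume_image(array(0, c(5, 5, 5)), c(2, 2, 2))
  expect_error(extract_myocardium(zero, 0.5),
               class = "gateopt_extraction_failure")
  expect_error(extract_myocardium(v, 1.5), class = "gateopt_input_error")
})

test_that("centre of mass is symmetric, translation-equivariant and scale-invariant", {
  blob <- make_blob_volume(c(0, 0, 0))
  expect_lt(max(abs(cma(blob))), 1e-6)

  shifted <- make_blob_volume(c(0, 0, 12))
  d <- cma(shifted) - cma(blob)
  expect_lt(max(abs(d - c(0, 0, 12))), max(blob$voxel_size_mm) / 2)

  doubled <- blob
  doubled$voxels <- doubled$voxels * 2
  expect_equal(cma(doubled), cma(blob))
  expect_error(cma(volume_image(array(0, c(4, 4, 4)), c(1, 1, 1))),
               class = "gateopt_input_error")
})

test_that("axis-collapsed averages behave like unweighted means", {
  cfg <- small_config(noise = FALSE, invalid_fraction = 0, seed = 6)
  sc <- test_scanner(c(48, 48, 47))
  set <- simulate_gated_acquisition(cfg, sc, gate_scheme(3, 1), duration_s = 60)
  collapsed <- average_over_cardiac(set)
  for (i in 1:3) {
    expect_identical(collapsed[[i]]$voxels, set$volumes[[sprintf("r%d_c1", i)]]$voxels)
  }
  resp_avg <- average_over_respiratory(set)
  manual <- (set$volumes[["r1_c1"]]$voxels + set$volumes[["r2_c1"]]$voxels +
               set$volumes[["r3_c1"]]$voxels) / 3
  expect_equal(resp_avg[[1]]$voxels, manual)
})

test_that("averaging over gates suppresses noise variance as 1/p", {
  cfg <- small_config(noise = TRUE, invalid_fraction = 0, seed = 13,
                      total_counts = 2e6)
  clean_cfg <- small_config(noise = FALSE, invalid_fraction = 0, seed = 13,
                            total_counts = 2e6)
  sc <- test_scanner(c(48, 48, 47))
  set <- simulate_gated_acquisition(cfg, sc, gate_scheme(1, 4), duration_s = 120)
  clean <- simulate_gated_acquisition(clean_cfg, sc, gate_scheme(1, 4),
                                      duration_s = 120)
  core <- function(vox) vox[20:28, 20:28, 20:28]
  resid_var <- function(noisy_vol, clean_vol) {
    stats::var(as.numeric(core(noisy_vol$voxels) - core(clean_vol$voxels)))
  }
  gate_vars <- vapply(1:4, function(j) {
    resid_var(gate_volume(set, 1, j), gate_volume(clean, 1, j))
  }, numeric(1))
  avg_var <- resid_var(average_over_cardiac(set)[[1]],
                       average_over_cardiac(clean)[[1]])
  ratio <- mean(gate_vars) / avg_var
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 6)
})

test_that("identical images measure zero motion", {
  blob <- make_blob_volume(c(0, 0, 0))
  expect_equal(measure_extreme_motion(list(blob, blob, blob)), 0)
  expect_equal(measure_extreme_motion(list(blob, blob), mode = "mid_cycle"), 0)
})

test_that("motion measurement is invariant under global intensity scaling", {
  a <- make_blob_volume(c(0, 0, -8), background = 0.05)
  b <- make_blob_volume(c(0, 0, 8), background = 0.05)
  m1 <- measure_extreme_motion(list(a, b))
  a2 <- a; a2$voxels <- a$voxels * 7.3
  b2 <- b; b2$voxels <- b$voxels * 7.3
  expect_equal(measure_extreme_motion(list(a2, b2)), m1)
  expect_lt(abs(m1 - 16), max(a$voxel_size_mm) / 2)
})

test_that("a single degenerate scheme yields one zero-motion sample", {
  cfg <- small_config(noise = FALSE, invalid_fraction = 0, seed = 6)
  sc <- test_scanner(c(48, 48, 47))
  set <- simulate_gated_acquisition(cfg, sc, gate_scheme(1, 1), duration_s = 60)
  samples <- build_motion_samples(list(set))
  expect_equal(nrow(samples), 1)
  expect_equal(samples$motion_mm, 0)
})
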