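test_that("respiratory signal generation is deterministic with the configured shape", {
  cfg <- phantom_config(resp_jitter = 0, invalid_fraction = 0, seed = 2)
  sig <- gen_resp_signal(cfg, 60)
  expect_equal(nrow(sig), 60 * 25 + 1)
  expect_equal(range(sig$amplitude), c(0, 20))
  # 15 complete 4-second cycles: the trace returns to baseline at each cycle end
  zero_crossings <- sum(abs(sig$amplitude) < 1e-9)
  expect_equal(zero_crossings, 16) # includes t = 0 and t = 60
  expect_identical(sig, gen_resp_signal(cfg, 60))

  jit <- phantom_config(resp_jitter = 0.1, invalid_fraction = 0, seed = 3)
  sigj <- gen_resp_signal(jit, 1200)
  # cycle lengths from successive minima: CV should track the configured jitter
  mins <- which(diff(sign(diff(sigj$amplitude))) > 0) + 1
  cycles <- diff(sigj$time_s[mins])
  cycles <- cycles[cycles > 1] # ignore flat-sample double minima
  cv <- stats::sd(cycles) / mean(cycles)
  expect_lt(abs(cv - 0.1), 0.02)
})

test_that("R-peak generation matches the configured rate and jitter", {
  cfg <- phantom_config(rr_jitter = 0, seed = 2)
  peaks <- gen_rpeaks(cfg, 60)
  expect_equal(peaks$rpeak_time_s, 0:59)
  expect_identical(peaks, gen_rpeaks(cfg, 60))

  jit <- phantom_config(rr_jitter = 0.05, seed = 9)
  pk <- gen_rpeaks(jit, 1800)$rpeak_time_s
  rr <- diff(pk)
  se <- stats::sd(rr) / sqrt(2 * (length(rr) - 1))
  expect_lt(abs(stats::sd(rr) - 0.05 * jit$mean_rr_s), 2 * se + 0.002)
  expect_error(gen_rpeaks(cfg, 0.5), class = "gateopt_input_error")
})

test_that("rendering is a pure function with the configured motion amplitudes", {
  cfg <- phantom_config(seed = 1)
  sc <- test_scanner()
  v0 <- render_phase(0, 0, cfg, sc)
  expect_identical(v0$voxels, render_phase(0, 0, cfg, sc)$voxels)
  expect_error(render_phase(-0.1, 0, cfg, sc), class = "gateopt_input_error")

  # respiratory extremes displace the tracked hot spot by the full 20 mm
  p0 <- locate_hotspot(v0, "weighted90")
  p1 <- locate_hotspot(render_phase(1, 0, cfg, sc), "weighted90")
  d <- sqrt(sum((p1 - p0)^2))
  expect_lt(abs(d - cfg$resp_amplitude_mm), sc$voxel_size_mm[3] / 2)

  # peak contraction moves the free-pole hot spot by the 7 mm diameter change
  pc <- locate_hotspot(render_phase(0, 0.5, cfg, sc), "weighted90")
  dc <- sqrt(sum((pc - p0)^2))
  expect_lt(abs(dc - cfg$card_diameter_change_mm), max(sc$voxel_size_mm))
})

test_that("gated acquisition conserves expected counts and dwell fractions", {
  cfg <- small_config(noise = FALSE, invalid_fraction = 0.1, seed = 6)
  sc <- test_scanner(c(48, 48, 47))
  set <- simulate_gated_acquisition(cfg, sc, gate_scheme(3, 2), duration_s = 120)
  expect_equal(sum(set$gate_fractions$fraction), 1 - set$rejected_pct / 100,
               tolerance = 1e-12)

  noisy_cfg <- small_config(noise = TRUE, invalid_fraction = 0.1, seed = 6)
  noisy <- simulate_gated_acquisition(noisy_cfg, sc, gate_scheme(3, 2),
                                      duration_s = 120)
  # activity-calibrated noisy gates fluctuate around the noiseless truth
  rel <- vapply(names(set$volumes), function(k) {
    sum(noisy$volumes[[k]]$voxels) / sum(set$volumes[[k]]$voxels)
  }, numeric(1))
  expect_true(all(abs(rel - 1) < 0.02))

  # same seed, same acquisition
  rerun <- simulate_gated_acquisition(noisy_cfg, sc, gate_scheme(3, 2),
                                      duration_s = 120)
  expect_identical(noisy$volumes[["r1_c1"]]$voxels, rerun$volumes[["r1_c1"]]$voxels)
})

test_that("a single-gate scheme reproduces the time-averaged phantom", {
  cfg <- small_config(noise = FALSE, invalid_fraction = 0, seed = 6)
  sc <- test_scanner(c(48, 48, 47))
  set <- simulate_gated_acquisition(cfg, sc, gate_scheme(1, 1), duration_s = 60)
  expect_equal(measure_extreme_motion(list(set$volumes[[1]]), "hotspot_weighted90"), 0)
  # phantom centre of mass sits at mid-excursion of the 20 mm translation
  com <- cma(set$volumes[[1]], extract_myocardium(set$volumes[[1]], 0.3))
  expect_lt(abs(com[3]), 1)
})

test_that("gate-averaged hot-spot displacement follows the capture law", {
  cfg <- small_config(noise = FALSE, invalid_fraction = 0, seed = 6)
  sc <- test_scanner(c(48, 48, 47))
  signals <- list(resp = gen_resp_signal(cfg, 240), rpeaks = gen_rpeaks(cfg, 240))
  cache <- new.env(parent = emptyenv())
  for (r in c(2, 5)) {
    set <- simulate_gated_acquisition(cfg, sc, gate_scheme(r, 1), 240,
                                      signals = signals, render_cache = cache)
    m <- measure_extreme_motion(average_over_cardiac(set), "hotspot_weighted90")
    expect_lt(abs(m - 20 * (r - 1) / r), sc$voxel_size_mm[3])
  }
})

test_that("empty gates warn and return zero volumes", {
  cfg <- small_config(noise = FALSE, invalid_fraction = 0, seed = 6,
                      mean_rr_s = 1, rr_jitter = 0)
  sc <- test_scanner(c(48, 48, 47))
  # 40 cardiac gates at 25 Hz sampling leave some phase bins empty
  w <- capture_warnings(
    set <- simulate_gated_acquisition(cfg, sc, gate_scheme(1, 40), duration_s = 30)
  )
  expect_true(any(grepl("no samples", w)))
  expect_true(any(vapply(set$volumes, function(v) all(v$voxels == 0), logical(1))))
})

test_that("myocardium volume translates with respiration and is reproducible", {
  cfg <- phantom_config(seed = 5)
  sc <- test_scanner(c(48, 48, 47))
  v0 <- gen_myocardium_volume(0, 0, cfg, sc, semiaxes_mm = c(30, 30, 30))
  v1 <- gen_myocardium_volume(1, 0, cfg, sc, semiaxes_mm = c(30, 30, 30))
  expect_identical(v0$voxels, gen_myocardium_volume(0, 0, cfg, sc,
                                                    semiaxes_mm = c(30, 30, 30))$voxels)
  c0 <- cma(v0, extract_myocardium(v0, 0.5))
  c1 <- cma(v1, extract_myocardium(v1, 0.5))
  d <- sqrt(sum((c1 - c0)^2))
  expect_lt(abs(d - cfg$resp_amplitude_mm), sc$voxel_size_mm[3] / 2)
})

test_that("wall profile FWHM reflects the configured thickness after blur", {
  cfg <- phantom_config(seed = 5, psf_fwhm_mm = 5.2)
  sc <- test_scanner(c(48, 48, 47))
  v <- gen_myocardium_volume(0.5, 0, cfg, sc, semiaxes_mm = c(30, 30, 30),
                             wall_thickness_mm = 10)
  centre_z <- 0 # mid-excursion translation
  prof <- extract_profile(v, c(0, 0, centre_z), c(40, 0, centre_z),
                          spacing_mm = 0.25)
  sigma <- 5.2 / (2 * sqrt(2 * log(2)))
  expected <- oracle_box_gauss_fwhm(10, sigma)
  expect_lt(abs(fwhm(prof) - expected), min(sc$voxel_size_mm))
})

test_that("phantom configurations round-trip through YAML", {
  cfg <- phantom_config(seed = 42, resp_amplitude_mm = 18, noise = FALSE)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_config(cfg, path)
  back <- read_phantom_config(path)
  expect_equal(back, cfg)
})
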