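# Shared phantom fixtures. End-to-end studies run on a 64 x 64 x 47 grid
# (the reconstruction's voxel size with a reduced transaxial FOV that still
# contains the phantom through its full motion) and 10-minute simulated
# acquisitions; results are memoised so several test files can share them.

test_scanner <- function(shape = c(64, 64, 47)) {
  scanner_spec(volume_shape = shape)
}

# small phantom for cheap unit tests (fits a 48 x 48 x 47 grid)
small_config <- function(...) {
  phantom_config(
    balloon_radii_mm = c(15, 22),
    hotspot_positions = list(c(1, 0, 0)),
    hotspot_intensity = 1,
    ...
  )
}

mm_to_index_for_test <- function(vol, pos_mm) {
  (pos_mm - vol$origin_mm) / vol$voxel_size_mm + 1
}

.study_cache <- new.env(parent = emptyenv())

phantom_study_fixture <- function(noise) {
  key <- if (noise) "noisy" else "noiseless"
  if (is.null(.study_cache[[key]])) {
    cfg <- phantom_config(noise = noise, seed = 1)
    .study_cache[[key]] <- run_phantom_study(cfg, test_scanner(),
                                             duration_s = 600)
  }
  .study_cache[[key]]
}
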