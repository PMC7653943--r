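#' Moving heart phantom configuration
#'
#' Parameters of the synthetic two-balloon heart phantom: a water-filled
#' outer balloon (uniform activity) carrying small hot spots that emulate
#' coronary plaques, translated axially by respiration and inflating/deflating
#' with the cardiac cycle. Defaults follow the reference phantom: 20 mm
#' respiratory translation, 7 mm maximal change of the outer-balloon diameter,
#' 3 mm hot spots, 5.2 mm system PSF, 25 Hz respiratory signal sampling.
#'
#' The balloon inflates from an anchored mounting pole on the -x axis, so the
#' free (+x) pole — where the most active hot spot sits — moves by the full
#' diameter change over the cardiac cycle. Respiratory translation is along
#' the axial (z) axis, orthogonal to the cardiac motion.
#'
#' The default respiratory waveform is triangular (constant-speed excursion),
#' so the breathing amplitude is uniformly distributed and equal-height
#' amplitude gates contain equal motion intervals — the premise of the
#' gate-count motion models. A raised-cosine waveform (`"raised_cosine"`,
#' with realistic dwell at the motion extremes) is available to study how
#' uneven dwell biases amplitude gating.
#'
#' Gate images are activity-calibrated. With `noise = TRUE`, per-gate counts
#' are drawn as scaled Poisson deviates whose variance scales as
#' `mu^recon_noise_exponent`, emulating the noise amplification of iterative
#' reconstruction at low counts; this reproduces an `a + b log10(n)` SNR decay
#' with slope `-5 (1 - recon_noise_exponent)` dB per decade of gates
#' (about 2 dB loss at 20 gates with the default 0.7).
#' `recon_noise_exponent = 1` gives pure Poisson counting noise.
#'
#' @param resp_amplitude_mm Peak-to-peak axial respiratory translation (mm).
#' @param card_diameter_change_mm Maximal change of the outer-balloon
#'   diameter over the cardiac cycle (mm).
#' @param hotspot_diameter_mm Hot-spot size (FWHM of the activity blob, mm).
#' @param hotspot_positions List of direction 3-vectors (normalised
#'   internally); each hot spot rides on the outer-balloon surface along its
#'   direction. The first entry is the most active spot.
#' @param hotspot_intensity Relative intensity of each hot spot.
#' @param balloon_radii_mm Inner and outer balloon radii (mm); the inner
#'   radius bounds the homogeneous core used for SNR VOIs. The default outer
#'   radius gives a heart-sized (9 cm) balloon whose core comfortably holds
#'   the published 13 x 13 x 13-voxel VOI throughout the motion cycle.
#' @param activity_ratio Named intensities `hotspot` (unblurred blob peak),
#'   `balloon` and `background`.
#' @param resp_period_s Mean respiratory period (s).
#' @param resp_jitter Coefficient of variation of the cycle length.
#' @param resp_waveform `"triangular"` or `"raised_cosine"`.
#' @param invalid_fraction Fraction of respiratory samples flagged invalid
#'   (in contiguous segments), emulating spirometry signal dropout.
#' @param mean_rr_s Mean R-R interval (s).
#' @param rr_jitter Coefficient of variation of the R-R interval.
#' @param total_counts Expected total detected counts over the acquisition.
#' @param psf_fwhm_mm Isotropic Gaussian PSF FWHM (mm).
#' @param noise Draw count noise? (Noiseless sets carry exact gate-average
#'   activity.)
#' @param recon_noise_exponent Exponent `beta` of the per-gate count variance
#'   law `mu^beta` (1 = Poisson).
#' @param card_phase_bins Number of cardiac phase bins used to discretise the
#'   renderer input when averaging gates.
#' @param seed Integer seed; all phantom randomness derives from it.
#' @return An object of class `phantom_config`.
#' @examples
#' phantom_config(seed = 7)
#' @export
phantom_config <- function(resp_amplitude_mm = 20,
                           card_diameter_change_mm = 7,
                           hotspot_diameter_mm = 3,
                           hotspot_positions = list(c(1, 0, 0), c(0, 1, 0), c(0, -1, 0)),
                           hotspot_intensity = c(1, 0.6, 0.4),
                           balloon_radii_mm = c(32, 45),
                           activity_ratio = c(hotspot = 40, balloon = 1, background = 0.1),
                           resp_period_s = 4,
                           resp_jitter = 0.05,
                           resp_waveform = c("triangular", "raised_cosine"),
                           invalid_fraction = 0.15,
                           mean_rr_s = 1,
                           rr_jitter = 0.05,
                           total_counts = 1e7,
                           psf_fwhm_mm = 5.2,
                           noise = TRUE,
                           recon_noise_exponent = 0.7,
                           card_phase_bins = 16L,
                           seed = 1L) {
  resp_waveform <- rlang::arg_match(resp_waveform)
  if (resp_amplitude_mm < 0 || card_diameter_change_mm < 0) {
    abort_gateopt("Motion amplitudes must be non-negative.", "gateopt_input_error")
  }
  if (total_counts <= 0) {
    abort_gateopt("`total_counts` must be positive.", "gateopt_input_error")
  }
  if (balloon_radii_mm[1] >= balloon_radii_mm[2]) {
    abort_gateopt("Inner balloon radius must be smaller than the outer radius.",
                  "gateopt_input_error")
  }
  if (length(hotspot_intensity) != length(hotspot_positions)) {
    abort_gateopt("`hotspot_intensity` must match `hotspot_positions` in length.",
                  "gateopt_input_error")
  }
  structure(
    list(
      resp_amplitude_mm = resp_amplitude_mm,
      card_diameter_change_mm = card_diameter_change_mm,
      hotspot_diameter_mm = hotspot_diameter_mm,
      hotspot_positions = lapply(hotspot_positions,
                                 function(d) d / sqrt(sum(d^2))),
      hotspot_intensity = hotspot_intensity,
      balloon_radii_mm = balloon_radii_mm,
      activity_ratio = activity_ratio,
      resp_period_s = resp_period_s,
      resp_jitter = resp_jitter,
      resp_waveform = resp_waveform,
      invalid_fraction = invalid_fraction,
      mean_rr_s = mean_rr_s,
      rr_jitter = rr_jitter,
      total_counts = total_counts,
      psf_fwhm_mm = psf_fwhm_mm,
      noise = noise,
      recon_noise_exponent = recon_noise_exponent,
      card_phase_bins = as.integer(card_phase_bins),
      seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  cat(sprintf("  respiratory: %.1f mm axial, %s waveform, period %.1f s (CV %.0f%%)\n",
              x$resp_amplitude_mm, x$resp_waveform, x$resp_period_s,
              100 * x$resp_jitter))
  cat(sprintf("  cardiac: %.1f mm diameter change, RR %.2f s (CV %.0f%%)\n",
              x$card_diameter_change_mm, x$mean_rr_s, 100 * x$rr_jitter))
  cat(sprintf("  %d hot spot(s) of %.1f mm, balloon radii %.0f/%.0f mm\n",
              length(x$hotspot_positions), x$hotspot_diameter_mm,
              x$balloon_radii_mm[1], x$balloon_radii_mm[2]))
  cat(sprintf("  counts %.3g, PSF %.1f mm, noise %s (exponent %.2f), seed %d\n",
              x$total_counts, x$psf_fwhm_mm, x$noise, x$recon_noise_exponent,
              x$seed))
  invisible(x)
}

resp_waveform_value <- function(phase, waveform) {
  switch(waveform,
    triangular = 1 - abs(2 * phase - 1),
    raised_cosine = sin(pi * phase)^2
  )
}

# cardiac contraction weight over the cycle: 0 at the R-peak, 1 mid-cycle
card_waveform_value <- function(phase) sin(pi * phase)^2

#' Generate a respiratory volume signal
#'
#' Emulates a spirometry-derived lung-volume trace sampled at 25 Hz: cycles of
#' jittered length following the configured waveform, scaled so the signal
#' equals the respiratory displacement in mm (0 = end-expiration), with a
#' configurable fraction of samples flagged invalid in contiguous segments.
#' Deterministic for a given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @param duration_s Signal duration in seconds.
#' @return A tibble with columns `time_s`, `amplitude`, `valid`.
#' @examples
#' sig <- gen_resp_signal(phantom_config(resp_jitter = 0, invalid_fraction = 0), 60)
#' range(sig$amplitude)
#' @export
gen_resp_signal <- function(config, duration_s) {
  stopifnot(inherits(config, "phantom_config"))
  if (duration_s <= 0) {
    abort_gateopt("`duration_s` must be positive.", "gateopt_input_error")
  }
  withr::with_seed(derive_seed(config$seed, 1), {
    times <- seq(0, duration_s, by = 1 / 25)
    n_cycles <- ceiling(duration_s / config$resp_period_s * 2) + 10
    lengths <- config$resp_period_s *
      pmax(0.3, 1 + config$resp_jitter * stats::rnorm(n_cycles))
    starts <- c(0, cumsum(lengths))
    cycle <- findInterval(times, starts)
    phase <- (times - starts[cycle]) / lengths[cycle]
    amplitude <- config$resp_amplitude_mm *
      resp_waveform_value(phase, config$resp_waveform)
    valid <- rep(TRUE, length(times))
    if (config$invalid_fraction > 0) {
      target <- config$invalid_fraction * length(times)
      guard <- 0
      while (sum(!valid) < target && guard < 1000) {
        seg_start <- stats::runif(1, 0, duration_s)
        seg_len <- 0.5 + stats::rexp(1, 1 / 2.5)
        valid[times >= seg_start & times < seg_start + seg_len] <- FALSE
        guard <- guard + 1
      }
    }
    tibble::tibble(time_s = times, amplitude = amplitude, valid = valid)
  })
}

#' Generate ECG R-peak times
#'
#' Emulates ECG triggers: strictly increasing R-peak times with mean interval
#' `mean_rr_s` and Gaussian jitter of coefficient of variation `rr_jitter`.
#' Deterministic for a given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @param duration_s Acquisition duration in seconds (must exceed the mean
#'   R-R interval).
#' @return A tibble with column `rpeak_time_s`.
#' @examples
#' gen_rpeaks(phantom_config(rr_jitter = 0), 5)
#' @export
gen_rpeaks <- function(config, duration_s) {
  stopifnot(inherits(config, "phantom_config"))
  if (duration_s <= config$mean_rr_s) {
    abort_gateopt("`duration_s` must exceed the mean R-R interval.",
                  "gateopt_input_error")
  }
  withr::with_seed(derive_seed(config$seed, 2), {
    n <- ceiling(duration_s / config$mean_rr_s * 2) + 10
    rr <- config$mean_rr_s * pmax(0.3, 1 + config$rr_jitter * stats::rnorm(n))
    t <- c(0, cumsum(rr))
    tibble::tibble(rpeak_time_s = t[t < duration_s])
  })
}

#' Render the phantom at a single motion state
#'
#' Noiseless activity map of the phantom at respiratory phase `resp_phase`
#' (fraction of the axial translation) and cardiac phase `card_phase`
#' (fraction of the R-R interval), blurred by the isotropic Gaussian PSF. The
#' PSF is applied in closed form: balloon edges as Gaussian error-function
#' profiles, hot spots as Gaussian blobs of combined width
#' `sqrt(spot^2 + psf^2)`. A pure function: identical inputs give identical
#' volumes.
#'
#' @param resp_phase,card_phase Phases in `[0, 1]`.
#' @param config A [phantom_config()].
#' @param scanner A [scanner_spec()] fixing grid and voxel size.
#' @return A [volume_image()].
#' @examples
#' vol <- render_phase(0, 0, phantom_config(), scanner_spec(volume_shape = c(48, 48, 47)))
#' max(vol$voxels)
#' @export
render_phase <- function(resp_phase, card_phase, config, scanner) {
  stopifnot(inherits(config, "phantom_config"), inherits(scanner, "scanner_spec"))
  if (any(c(resp_phase, card_phase) < 0) || any(c(resp_phase, card_phase) > 1)) {
    abort_gateopt("Phases must lie in [0, 1].", "gateopt_input_error")
  }
  shape <- scanner$volume_shape
  vs <- scanner$voxel_size_mm
  vol <- volume_image(array(0, shape), vs)
  x <- axis_coords(vol, 1)
  y <- axis_coords(vol, 2)
  z <- axis_coords(vol, 3)

  r_outer <- config$balloon_radii_mm[2]
  w <- card_waveform_value(card_phase)
  radius <- r_outer - config$card_diameter_change_mm / 2 * w
  centre <- c(radius - r_outer,              # anchored -x pole
              0,
              -config$resp_amplitude_mm / 2 + resp_phase * config$resp_amplitude_mm)

  sigma_psf <- max(config$psf_fwhm_mm * FWHM_TO_SIGMA, 1e-6)
  act <- config$activity_ratio
  dx2 <- (x - centre[1])^2
  dy2 <- (y - centre[2])^2
  dz2 <- (z - centre[3])^2
  d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  voxels <- act[["background"]] +
    (act[["balloon"]] - act[["background"]]) *
    stats::pnorm((radius - d) / sigma_psf)

  sigma_spot <- config$hotspot_diameter_mm * FWHM_TO_SIGMA
  sigma_blob <- sqrt(sigma_spot^2 + sigma_psf^2)
  peak_scale <- (sigma_spot / sigma_blob)^3
  for (k in seq_along(config$hotspot_positions)) {
    pos <- centre + radius * config$hotspot_positions[[k]]
    amp <- act[["hotspot"]] * config$hotspot_intensity[k] * peak_scale
    ix <- which(abs(x - pos[1]) < 4 * sigma_blob)
    iy <- which(abs(y - pos[2]) < 4 * sigma_blob)
    iz <- which(abs(z - pos[3]) < 4 * sigma_blob)
    if (!length(ix) || !length(iy) || !length(iz)) next
    blob <- amp * exp(-outer(outer((x[ix] - pos[1])^2, (y[iy] - pos[2])^2, "+"),
                             (z[iz] - pos[3])^2, "+") / (2 * sigma_blob^2))
    voxels[ix, iy, iz] <- voxels[ix, iy, iz] + blob
  }
  vol$voxels <- voxels
  vol
}

#' Render a patient-like myocardium volume
#'
#' A hollow spherical/ellipsoidal shell (myocardium wall) over a faint lung
#' background: translated axially by the respiratory phase, and contracting
#' with wall thickening over the cardiac cycle. Edges are PSF-blurred in
#' closed form. Used as the patient-like object for centre-of-mass and
#' wall-FWHM analyses.
#'
#' @inheritParams render_phase
#' @param semiaxes_mm Outer semi-axes of the wall (mm).
#' @param wall_thickness_mm Wall thickness at rest (mm).
#' @param contraction Fractional reduction of the outer semi-axes at peak
#'   contraction (wall thickness grows by the same relative amount).
#' @return A [volume_image()].
#' @export
gen_myocardium_volume <- function(resp_phase, card_phase, config, scanner,
                                  semiaxes_mm = c(40, 40, 40),
                                  wall_thickness_mm = 10,
                                  contraction = 0.1) {
  stopifnot(inherits(config, "phantom_config"), inherits(scanner, "scanner_spec"))
  if (any(c(resp_phase, card_phase) < 0) || any(c(resp_phase, card_phase) > 1)) {
    abort_gateopt("Phases must lie in [0, 1].", "gateopt_input_error")
  }
  vol <- volume_image(array(0, scanner$volume_shape), scanner$voxel_size_mm)
  x <- axis_coords(vol, 1)
  y <- axis_coords(vol, 2)
  z <- axis_coords(vol, 3)
  w <- card_waveform_value(card_phase)
  outer_ax <- semiaxes_mm * (1 - contraction * w)
  thick <- wall_thickness_mm * (1 + contraction * w)
  inner_ax <- pmax(outer_ax - thick, 1)
  centre <- c(0, 0, -config$resp_amplitude_mm / 2 +
                resp_phase * config$resp_amplitude_mm)
  sigma_psf <- max(config$psf_fwhm_mm * FWHM_TO_SIGMA, 1e-6)

  # signed mm distance outside an ellipsoid, via the gradient-normalised
  # level-set of rho = sqrt(sum((x_i - c_i)^2 / s_i^2)); exact for spheres
  signed_dist <- function(ax) {
    q <- outer(outer((x - centre[1])^2 / ax[1]^2, (y - centre[2])^2 / ax[2]^2, "+"),
               (z - centre[3])^2 / ax[3]^2, "+")
    g <- outer(outer((x - centre[1])^2 / ax[1]^4, (y - centre[2])^2 / ax[2]^4, "+"),
               (z - centre[3])^2 / ax[3]^4, "+")
    rho <- sqrt(q)
    (rho - 1) * rho / sqrt(pmax(g, 1e-12))
  }
  inside_outer <- stats::pnorm(-signed_dist(outer_ax) / sigma_psf)
  inside_inner <- stats::pnorm(-signed_dist(inner_ax) / sigma_psf)
  act <- config$activity_ratio
  vol$voxels <- act[["background"]] +
    (act[["balloon"]] - act[["background"]]) * (inside_outer - inside_inner)
  vol
}

phantom_signals <- function(config, duration_s) {
  list(resp = gen_resp_signal(config, duration_s),
       rpeaks = gen_rpeaks(config, duration_s))
}

shift_z <- function(arr, off) {
  if (off == 0) return(arr)
  d <- dim(arr)
  out <- array(0, d)
  if (abs(off) >= d[3]) return(out)
  if (off > 0) {
    out[, , (off + 1):d[3]] <- arr[, , 1:(d[3] - off)]
  } else {
    out[, , 1:(d[3] + off)] <- arr[, , (1 - off):d[3]]
  }
  out
}

render_base_volumes <- function(config, scanner, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  K <- config$card_phase_bins
  lapply(seq_len(K), function(k) {
    key <- sprintf("card%03d", k)
    if (is.null(cache[[key]])) {
      cache[[key]] <- render_phase(0, (k - 0.5) / K, config, scanner)
    }
    cache[[key]]
  })
}

#' Simulate a dual-gated phantom acquisition
#'
#' Generates (or reuses) respiratory and ECG signals, assigns every time
#' sample to a dual gate, and builds each gate's activity image as the
#' dwell-weighted average of the phantom rendered over that gate's motion
#' states (cardiac states discretised into `config$card_phase_bins` bins;
#' respiratory translation applied as a sub-voxel axial shift). With
#' `config$noise`, per-gate counts are drawn from the scaled-Poisson
#' reconstruction-noise model and returned as activity-calibrated images.
#' Expected counts across gates sum to `total_counts` times the accepted data
#' fraction. Fully deterministic per `config$seed`.
#'
#' @param config A [phantom_config()].
#' @param scanner A [scanner_spec()].
#' @param scheme A [gate_scheme()].
#' @param duration_s Acquisition duration in seconds.
#' @param signals Optional precomputed signals from an earlier call (list with
#'   elements `resp`, `rpeaks`) so several schemes share one acquisition.
#' @param render_cache Optional environment reused across calls to avoid
#'   re-rendering cardiac phase bins.
#' @return A [gated_image_set()].
#' @examples
#' cfg <- phantom_config(noise = FALSE, invalid_fraction = 0, seed = 2)
#' sc <- scanner_spec(volume_shape = c(48, 48, 47))
#' set <- simulate_gated_acquisition(cfg, sc, gate_scheme(2, 1), duration_s = 60)
#' set$gate_fractions
#' @export
simulate_gated_acquisition <- function(config, scanner, scheme,
                                       duration_s = 1800,
                                       signals = NULL,
                                       render_cache = NULL) {
  stopifnot(inherits(config, "phantom_config"),
            inherits(scanner, "scanner_spec"),
            inherits(scheme, "gate_scheme"))
  if (is.null(signals)) signals <- phantom_signals(config, duration_s)
  resp <- signals$resp
  rpeaks <- signals$rpeaks$rpeak_time_s

  resp_idx <- assign_resp_amplitude(resp, scheme$n_resp)
  card_idx <- assign_card_phase(rpeaks, scheme$n_card, resp$time_s)
  labels <- combine_dual(resp_idx, card_idx)
  rejected_pct <- rejected_fraction(labels)
  accepted <- !is.na(labels$resp_gate)

  phase <- card_phase_of(resp$time_s, rpeaks)
  K <- config$card_phase_bins
  card_bin <- pmin.int(as.integer(floor(phase * K)) + 1L, K)
  z_shift <- resp$amplitude / scanner$voxel_size_mm[3]

  base <- render_base_volumes(config, scanner, render_cache)
  template <- base[[1]]
  n_total <- nrow(resp)

  volumes <- list()
  fractions <- tidyr::expand_grid(resp_gate = seq_len(scheme$n_resp),
                                  card_gate = seq_len(scheme$n_card)) |>
    dplyr::mutate(fraction = 0)
  for (row in seq_len(nrow(fractions))) {
    i <- fractions$resp_gate[row]
    j <- fractions$card_gate[row]
    sel <- accepted & labels$resp_gate == i & labels$card_gate == j
    n_sel <- sum(sel)
    fractions$fraction[row] <- n_sel / n_total
    key <- gate_key(i, j)
    if (n_sel == 0) {
      rlang::warn(sprintf("Gate (%d,%d) received no samples; returning zeros.", i, j))
      volumes[[key]] <- volume_image(array(0, dim(template$voxels)),
                                     template$voxel_size_mm, template$origin_mm)
      next
    }
    # weights over (cardiac phase bin, integer z offset): fractional shifts
    # split linearly between neighbouring offsets, preserving the centroid.
    # only the phantom (activity above the static background) is shifted.
    zv <- z_shift[sel]
    f0 <- floor(zv)
    wts <- tibble::tibble(
      k = rep(card_bin[sel], 2),
      off = c(f0, f0 + 1),
      w = c(1 - (zv - f0), zv - f0)
    ) |>
      dplyr::filter(.data$w > 0) |>
      dplyr::summarise(w = sum(.data$w), .by = c("k", "off"))
    bg <- config$activity_ratio[["background"]]
    acc <- array(bg, dim(template$voxels))
    for (q in seq_len(nrow(wts))) {
      acc <- acc + (wts$w[q] / n_sel) *
        shift_z(base[[wts$k[q]]]$voxels - bg, as.integer(wts$off[q]))
    }
    volumes[[key]] <- volume_image(acc, template$voxel_size_mm,
                                   template$origin_mm)
  }

  if (config$noise) {
    accepted_frac <- 1 - rejected_pct / 100
    if (accepted_frac <= 0) {
      abort_gateopt("All data rejected; cannot scale counts.", "gateopt_empty_signal")
    }
    activity_mass <- sum(purrr::map2_dbl(
      fractions$fraction, seq_len(nrow(fractions)),
      function(f, row) f * sum(volumes[[gate_key(fractions$resp_gate[row],
                                                 fractions$card_gate[row])]]$voxels)
    ))
    W <- activity_mass / accepted_frac
    beta <- config$recon_noise_exponent
    withr::with_seed(
      derive_seed(config$seed, 10000 + scheme$n_resp * 100 + scheme$n_card), {
        for (row in seq_len(nrow(fractions))) {
          f <- fractions$fraction[row]
          if (f == 0) next
          key <- gate_key(fractions$resp_gate[row], fractions$card_gate[row])
          calib <- f * config$total_counts / W
          mu <- volumes[[key]]$voxels * calib
          m_g <- sum(mu^2) / sum(mu)
          s <- m_g^(beta - 1)
          counts <- s * stats::rpois(length(mu), mu / s)
          volumes[[key]]$voxels <- array(counts / calib, dim(mu))
        }
      })
  }

  gated_image_set(scheme, volumes, fractions, rejected_pct = rejected_pct)
}

#' Simulate one acquisition gated under several schemes
#'
#' Shares one pair of respiratory/ECG signals and one render cache across all
#' schemes, mirroring how a single list-mode acquisition is re-gated offline
#' under different gate counts.
#'
#' @inheritParams simulate_gated_acquisition
#' @param schemes List of [gate_scheme()] objects.
#' @return A named list of [gated_image_set()] objects (names like `"5x4"`).
#' @export
simulate_phantom_study <- function(config, scanner, schemes,
                                   duration_s = 1800) {
  signals <- phantom_signals(config, duration_s)
  cache <- new.env(parent = emptyenv())
  sets <- lapply(schemes, function(sch) {
    simulate_gated_acquisition(config, scanner, sch, duration_s,
                               signals = signals, render_cache = cache)
  })
  names(sets) <- vapply(schemes, function(sch) {
    sprintf("%dx%d", sch$n_resp, sch$n_card)
  }, character(1))
  sets
}

#' Read and write phantom configurations as YAML
#'
#' Serialises every field of a [phantom_config()] so a simulation setup can be
#' version-controlled and passed to the command-line tools.
#'
#' @param config A [phantom_config()].
#' @param path File path.
#' @return `read_phantom_config()` returns a [phantom_config()];
#'   `write_phantom_config()` returns `path` invisibly.
#' @export
write_phantom_config <- function(config, path) {
  stopifnot(inherits(config, "phantom_config"))
  out <- unclass(config)
  out$activity_ratio <- as.list(out$activity_ratio)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$activity_ratio <- unlist(raw$activity_ratio)
  raw$hotspot_positions <- lapply(raw$hotspot_positions, as.numeric)
  raw$hotspot_intensity <- as.numeric(raw$hotspot_intensity)
  do.call(phantom_config, raw)
}
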