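#' Locate a hot spot in an activity volume
#'
#' `"local_max"` returns the centre of the brightest voxel in the search
#' region. `"weighted90"` refines it to the intensity-weighted centroid of
#' the voxels reaching at least 90% of that maximum, restricted to a
#' neighbourhood of three scanner FWHM around the maximum so neighbouring hot
#' spots do not contaminate the centroid.
#'
#' @param vol A [volume_image()].
#' @param method `"weighted90"` (default) or `"local_max"`.
#' @param search_region Optional list with voxel-index vectors `lo` and `hi`
#'   restricting the search box.
#' @param neighbourhood_mm Radius of the weighted-centroid neighbourhood
#'   (defaults to three PSF widths).
#' @param psf_fwhm_mm Scanner resolution used for the default neighbourhood.
#' @return Numeric length-3 position in mm.
#' @examples
#' v <- volume_image(array(0, c(9, 9, 9)), c(2, 2, 2))
#' v$voxels[5, 5, 5] <- 1
#' locate_hotspot(v, method = "local_max")
#' @export
locate_hotspot <- function(vol, method = c("weighted90", "local_max"),
                           search_region = NULL,
                           neighbourhood_mm = 3 * psf_fwhm_mm,
                           psf_fwhm_mm = 5.2) {
  stopifnot(inherits(vol, "volume_image"))
  method <- rlang::arg_match(method)
  vox <- vol$voxels
  d <- dim(vox)
  lo <- c(1L, 1L, 1L)
  hi <- d
  if (!is.null(search_region)) {
    lo <- pmax(as.integer(search_region$lo), 1L)
    hi <- pmin(as.integer(search_region$hi), d)
    if (any(lo > hi)) {
      abort_gateopt("`search_region` lies outside the volume.", "gateopt_bounds_error")
    }
  }
  sub <- vox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  vmax <- max(sub)
  if (!is.finite(vmax) || vmax <= min(sub) + 1e-12) {
    abort_gateopt("Region is flat: no unique maximum above background.",
                  "gateopt_localisation_failure")
  }
  peak_sub <- arrayInd(which.max(sub), dim(sub))
  peak <- as.integer(peak_sub) + lo - 1L
  peak_mm <- index_to_mm(vol, peak)
  if (method == "local_max") {
    return(peak_mm)
  }
  # centroid of the >= 90% region evaluated on a trilinearly upsampled
  # neighbourhood (quarter-voxel sampling) so the position is sub-voxel even
  # though the 90% isocontour of a PSF-sized blob spans only a voxel or two
  half <- pmin(c(6, 6, 12), neighbourhood_mm)
  grid_mm <- lapply(1:3, function(ax) {
    coords <- axis_coords(vol, ax)
    step <- vol$voxel_size_mm[ax] / 4
    seq(max(peak_mm[ax] - half[ax], coords[1]),
        min(peak_mm[ax] + half[ax], coords[length(coords)]), by = step)
  })
  pts <- as.matrix(expand.grid(grid_mm[[1]], grid_mm[[2]], grid_mm[[3]]))
  vals <- trilinear_interp(vol, pts)
  vmax_i <- max(vals)
  peak_i <- pts[which.max(vals), ]
  dist2 <- (pts[, 1] - peak_i[1])^2 + (pts[, 2] - peak_i[2])^2 +
    (pts[, 3] - peak_i[3])^2
  keep <- vals >= 0.9 * vmax_i & dist2 <= neighbourhood_mm^2
  w <- vals[keep]
  c(sum(w * pts[keep, 1]), sum(w * pts[keep, 2]), sum(w * pts[keep, 3])) / sum(w)
}

# 6-connected components of a logical 3-D mask; returns integer labels
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx_all <- which(mask)
  if (length(idx_all) == 0) return(lab)
  coords <- arrayInd(idx_all, d)
  in_mask <- array(FALSE, d)
  in_mask[idx_all] <- TRUE
  visited <- array(FALSE, d)
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  current <- 0L
  for (seed in idx_all) {
    if (visited[seed]) next
    current <- current + 1L
    frontier <- seed
    visited[seed] <- TRUE
    lab[seed] <- current
    while (length(frontier) > 0) {
      fc <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (o in seq_len(nrow(offsets))) {
        nb <- fc + rep(offsets[o, ], each = nrow(fc))
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] + (nb[ok, 3] - 1) * d[1] * d[2]
        lin <- lin[in_mask[lin] & !visited[lin]]
        if (length(lin)) {
          lin <- unique(lin)
          visited[lin] <- TRUE
          lab[lin] <- current
          nxt <- c(nxt, lin)
        }
      }
      frontier <- nxt
    }
  }
  lab
}

#' Extract the myocardium (or phantom body) by thresholded components
#'
#' Thresholds the volume at a fraction of its maximum and keeps the largest
#' 6-connected component, a simple automatic stand-in for myocardium
#' segmentation prior to centre-of-mass analysis.
#'
#' @param vol A [volume_image()].
#' @param threshold_fraction Fraction of the volume maximum in (0, 1).
#' @return A logical 3-D array (class `myocardium_mask` attribute-free) of
#'   the same shape as the volume.
#' @examples
#' cfg <- phantom_config()
#' sc <- scanner_spec(volume_shape = c(40, 40, 31))
#' vol <- gen_myocardium_volume(0.5, 0, cfg, sc)
#' mask <- extract_myocardium(vol, 0.5)
#' sum(mask) > 0
#' @export
extract_myocardium <- function(vol, threshold_fraction = 0.5) {
  stopifnot(inherits(vol, "volume_image"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    abort_gateopt("`threshold_fraction` must lie in (0, 1).", "gateopt_input_error")
  }
  vmax <- max(vol$voxels)
  mask <- vol$voxels >= threshold_fraction * vmax & vol$voxels > 0
  if (!any(mask)) {
    abort_gateopt("Thresholding produced an empty mask.",
                  "gateopt_extraction_failure")
  }
  lab <- label_components_3d(mask)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Centre of mass of activity
#'
#' Intensity-weighted mean position (mm) over the masked voxels — the CMA
#' used to track myocardial displacement between gates. Invariant under
#' global intensity scaling.
#'
#' @param vol A [volume_image()].
#' @param mask Optional logical array (e.g. from [extract_myocardium()]);
#'   defaults to the whole volume.
#' @return Numeric length-3 position in mm.
#' @export
cma <- function(vol, mask = NULL) {
  stopifnot(inherits(vol, "volume_image"))
  vox <- vol$voxels
  if (is.null(mask)) mask <- array(TRUE, dim(vox))
  if (!any(mask)) {
    abort_gateopt("Mask is empty.", "gateopt_input_error")
  }
  w <- vox * mask
  total <- sum(w)
  if (total <= 0) {
    abort_gateopt("Zero total intensity inside the mask.", "gateopt_input_error")
  }
  xs <- axis_coords(vol, 1)
  ys <- axis_coords(vol, 2)
  zs <- axis_coords(vol, 3)
  c(sum(w * slice.index(w, 1)) / total,
    sum(w * slice.index(w, 2)) / total,
    sum(w * slice.index(w, 3)) / total) |>
    (\(idx) index_to_mm(vol, idx))()
}

average_volumes <- function(vols) {
  acc <- Reduce(`+`, lapply(vols, function(v) v$voxels)) / length(vols)
  volume_image(acc, vols[[1]]$voxel_size_mm, vols[[1]]$origin_mm)
}

#' Collapse a gated set over one gating axis
#'
#' `average_over_cardiac()` averages all cardiac gates within each
#' respiratory gate (one volume per respiratory gate, used for respiratory
#' motion measurement); `average_over_respiratory()` is the cardiac analogue.
#' Averages are unweighted voxelwise means.
#'
#' @param set A [gated_image_set()].
#' @return A list of [volume_image()] objects, ordered by gate index.
#' @export
average_over_cardiac <- function(set) {
  stopifnot(inherits(set, "gated_image_set"))
  lapply(seq_len(set$scheme$n_resp), function(i) {
    average_volumes(lapply(seq_len(set$scheme$n_card),
                           function(j) gate_volume(set, i, j)))
  })
}

#' @rdname average_over_cardiac
#' @export
average_over_respiratory <- function(set) {
  stopifnot(inherits(set, "gated_image_set"))
  lapply(seq_len(set$scheme$n_card), function(j) {
    average_volumes(lapply(seq_len(set$scheme$n_resp),
                           function(i) gate_volume(set, i, j)))
  })
}

locate_position <- function(vol, locator, psf_fwhm_mm, search_region = NULL) {
  switch(locator,
    hotspot_local_max = locate_hotspot(vol, "local_max",
                                       search_region = search_region,
                                       psf_fwhm_mm = psf_fwhm_mm),
    hotspot_weighted90 = locate_hotspot(vol, "weighted90",
                                        search_region = search_region,
                                        psf_fwhm_mm = psf_fwhm_mm),
    cma = cma(vol, extract_myocardium(vol, 0.5))
  )
}

#' Motion between the extreme gates of an image series
#'
#' For respiratory series (`mode = "extremes"`): the Euclidean distance
#' between the located position in the first (end-expiration) and last
#' (peak-inspiration) image. For cardiac series (`mode = "mid_cycle"`): the
#' distance between the average of the first and last (systolic/diastolic)
#' positions and the mid-series (mid-diastolic) position; for an even number
#' of gates the later of the two middle gates is the mid-series image.
#'
#' @param images Ordered list of [volume_image()] objects (>= 2, or 1 for a
#'   degenerate series whose motion is 0).
#' @param locator `"hotspot_weighted90"`, `"hotspot_local_max"` or `"cma"`.
#' @param mode `"extremes"` (respiratory) or `"mid_cycle"` (cardiac).
#' @param psf_fwhm_mm Scanner resolution forwarded to the hot-spot locator.
#' @param track With a hot-spot locator, first locate the spot on the series
#'   average and then search each gate only inside a box around that
#'   reference (`track_box_mm` half-extents), so the same spot is followed
#'   through all gates even when another spot fluctuates brighter.
#' @param track_box_mm Half-extents (mm) of the tracking box.
#' @return Motion in mm.
#' @export
measure_extreme_motion <- function(images,
                                   locator = c("hotspot_weighted90",
                                               "hotspot_local_max", "cma"),
                                   mode = c("extremes", "mid_cycle"),
                                   psf_fwhm_mm = 5.2,
                                   track = TRUE,
                                   track_box_mm = c(12, 12, 18)) {
  locator <- rlang::arg_match(locator)
  mode <- rlang::arg_match(mode)
  n <- length(images)
  if (n < 1) {
    abort_gateopt("`images` must contain at least one volume.", "gateopt_input_error")
  }
  if (n == 1) return(0)
  region <- NULL
  if (track && locator != "cma") {
    ref <- average_volumes(images)
    ref_pos <- locate_hotspot(ref, "local_max", psf_fwhm_mm = psf_fwhm_mm)
    lo <- floor(mm_to_index(ref, ref_pos - track_box_mm))
    hi <- ceiling(mm_to_index(ref, ref_pos + track_box_mm))
    region <- list(lo = pmax(lo, 1), hi = pmin(hi, dim(ref$voxels)))
  }
  pos <- lapply(images, locate_position, locator = locator,
                psf_fwhm_mm = psf_fwhm_mm, search_region = region)
  if (mode == "extremes") {
    sqrt(sum((pos[[n]] - pos[[1]])^2))
  } else {
    mid <- pos[[floor(n / 2) + 1]]
    ends <- (pos[[1]] + pos[[n]]) / 2
    sqrt(sum((mid - ends)^2))
  }
}

#' Build model-ready motion samples from gated image sets
#'
#' For each gating scheme, measures respiratory motion between the extreme
#' respiratory gates of the cardiac-averaged images and cardiac motion
#' between the cardiac extremes and mid-cycle of the respiratory-averaged
#' images; the scheme's total motion is their sum. The result feeds
#' [fit_dual_model()] directly.
#'
#' @param sets List of [gated_image_set()] objects (>= 1).
#' @param locator Position locator, as in [measure_extreme_motion()].
#' @param psf_fwhm_mm Scanner resolution forwarded to the locator.
#' @return A tibble with columns `n_resp`, `n_card`, `resp_mm`, `card_mm`,
#'   `motion_mm` (total).
#' @export
build_motion_samples <- function(sets,
                                 locator = c("hotspot_weighted90",
                                             "hotspot_local_max", "cma"),
                                 psf_fwhm_mm = 5.2) {
  locator <- rlang::arg_match(locator)
  if (length(sets) < 1) {
    abort_gateopt("`sets` must contain at least one gated image set.",
                  "gateopt_input_error")
  }
  purrr::map_dfr(sets, function(set) {
    resp_mm <- measure_extreme_motion(average_over_cardiac(set), locator,
                                      mode = "extremes",
                                      psf_fwhm_mm = psf_fwhm_mm)
    card_mm <- measure_extreme_motion(average_over_respiratory(set), locator,
                                      mode = "mid_cycle",
                                      psf_fwhm_mm = psf_fwhm_mm)
    tibble::tibble(n_resp = set$scheme$n_resp, n_card = set$scheme$n_card,
                   resp_mm = resp_mm, card_mm = card_mm,
                   motion_mm = resp_mm + card_mm)
  })
}

#' Read and write motion-sample tables
#'
#' Dual-gating tables use columns `n_resp,n_card,motion_mm`; single-mode
#' tables use `n,motion_mm`.
#'
#' @param data A data frame of motion samples.
#' @param path File path.
#' @return `read_motion_samples()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
write_motion_samples <- function(data, path) {
  if (!all(c("n_resp", "n_card", "motion_mm") %in% names(data)) &&
      !all(c("n", "motion_mm") %in% names(data))) {
    abort_gateopt("Motion tables need columns n_resp,n_card,motion_mm or n,motion_mm.",
                  "gateopt_input_error")
  }
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_motion_samples
#' @export
read_motion_samples <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("n_resp", "n_card", "motion_mm") %in% names(out)) &&
      !all(c("n", "motion_mm") %in% names(out))) {
    abort_gateopt("Motion tables need columns n_resp,n_card,motion_mm or n,motion_mm.",
                  "gateopt_input_error")
  }
  out
}
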