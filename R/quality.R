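#' Volume of interest
#'
#' A box- or ellipsoid-shaped VOI given in voxel coordinates, used for SNR
#' measurement in a homogeneous region (the inner-balloon core of the
#' phantom, or a lung region in patients). Published sizes are 13 x 13 x 13
#' voxels (phantom) and 10 x 15 x 15 voxels (patient).
#'
#' @param center Voxel-index centre (length 3, may be fractional).
#' @param extents Full extents in voxels along each axis (length 3).
#' @param shape `"box"` or `"ellipsoid"`.
#' @return An object of class `voi`.
#' @examples
#' voi(center = c(32, 32, 24), extents = c(13, 13, 13))
#' @export
voi <- function(center, extents = c(13, 13, 13), shape = c("box", "ellipsoid")) {
  shape <- rlang::arg_match(shape)
  if (length(center) != 3 || length(extents) != 3 || any(extents < 1)) {
    abort_gateopt("`center` and `extents` must be length-3, extents >= 1 voxel.",
                  "gateopt_input_error")
  }
  structure(list(center = as.numeric(center), extents = as.numeric(extents),
                 shape = shape),
            class = "voi")
}

voi_values <- function(vol, v) {
  stopifnot(inherits(vol, "volume_image"), inherits(v, "voi"))
  d <- dim(vol$voxels)
  lo <- ceiling(v$center - v$extents / 2 + 0.5 - 1e-9)
  hi <- floor(v$center + v$extents / 2 - 0.5 + 1e-9)
  if (any(lo < 1) || any(hi > d)) {
    abort_gateopt("VOI extends outside the volume.", "gateopt_bounds_error")
  }
  block <- vol$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (v$shape == "box") {
    return(as.numeric(block))
  }
  ii <- slice.index(block, 1) + lo[1] - 1
  jj <- slice.index(block, 2) + lo[2] - 1
  kk <- slice.index(block, 3) + lo[3] - 1
  inside <- ((ii - v$center[1]) / (v$extents[1] / 2))^2 +
    ((jj - v$center[2]) / (v$extents[2] / 2))^2 +
    ((kk - v$center[3]) / (v$extents[3] / 2))^2 <= 1
  block[inside]
}

#' Signal-to-noise ratio over a VOI
#'
#' `10 log10(mean / SD)` of the voxel intensities inside a homogeneous VOI,
#' in dB. The default SD is the population standard deviation (divisor `N`);
#' `sd_type = "sample"` uses `N - 1`.
#'
#' @param vol A [volume_image()].
#' @param v A [voi()] fully inside the volume, covering >= 2 voxels.
#' @param sd_type `"population"` or `"sample"`.
#' @return SNR in dB.
#' @examples
#' vol <- volume_image(array(c(8, 12), c(2, 2, 2)), c(1, 1, 1))
#' snr_voi(vol, voi(c(1.5, 1.5, 1.5), c(2, 2, 2)))
#' @export
snr_voi <- function(vol, v, sd_type = c("population", "sample")) {
  sd_type <- rlang::arg_match(sd_type)
  vals <- voi_values(vol, v)
  n <- length(vals)
  if (n < 2) {
    abort_gateopt("VOI must cover at least 2 voxels.", "gateopt_input_error")
  }
  m <- mean(vals)
  if (m <= 0) {
    abort_gateopt("VOI mean is not positive; SNR undefined.",
                  "gateopt_undefined_snr")
  }
  ss <- sum((vals - m)^2)
  s <- if (sd_type == "population") sqrt(ss / n) else sqrt(ss / (n - 1))
  if (s == 0) {
    abort_gateopt("VOI standard deviation is zero; SNR infinite.",
                  "gateopt_infinite_snr")
  }
  10 * log10(m / s)
}

#' SNR of a gating scheme's summed image
#'
#' Sums all gate volumes of the set voxelwise and evaluates [snr_voi()] on
#' the sum — the per-scheme SNR used to monitor image-quality loss as the
#' gate count grows.
#'
#' @param set A [gated_image_set()].
#' @param v A [voi()].
#' @inheritParams snr_voi
#' @return SNR in dB.
#' @export
scheme_snr <- function(set, v, sd_type = c("population", "sample")) {
  stopifnot(inherits(set, "gated_image_set"))
  total <- Reduce(`+`, lapply(set$volumes, function(x) x$voxels))
  vol1 <- set$volumes[[1]]
  snr_voi(volume_image(total, vol1$voxel_size_mm, vol1$origin_mm), v,
          sd_type = sd_type)
}

#' Fit the SNR-versus-gate-count curve
#'
#' Least-squares fit of `snr = a + b log10(n)` to per-scheme SNR
#' measurements, with the residual RMSE in dB.
#'
#' @param data A data frame with columns `n_total` (total gates) and
#'   `snr_db`.
#' @return An object of class `snr_curve_fit` with elements `a`, `b`,
#'   `rmse_db`, `data` and `fitted`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' fit_snr_curve(data.frame(n_total = c(1, 10, 100), snr_db = c(20, 15, 10)))
#' @export
fit_snr_curve <- function(data) {
  check_columns(data, c("n_total", "snr_db"), "`data`")
  n <- as.numeric(data$n_total)
  y <- as.numeric(data$snr_db)
  if (any(n < 1)) {
    abort_gateopt("`n_total` must be >= 1.", "gateopt_invalid_gate_count")
  }
  if (length(unique(n)) < 2) {
    abort_gateopt("At least two distinct gate counts are required.",
                  "gateopt_degenerate_fit")
  }
  fit <- stats::lm(y ~ log10(n))
  fitted <- stats::fitted(fit)
  structure(
    list(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
         rmse_db = sqrt(mean(stats::resid(fit)^2)),
         data = tibble::tibble(n_total = n, snr_db = y),
         fitted = fitted),
    class = "snr_curve_fit"
  )
}

#' @export
print.snr_curve_fit <- function(x, ...) {
  cat(sprintf("<snr_curve_fit> SNR(n) = %.2f %+.2f * log10(n) dB, RMSE %.3f dB\n",
              x$a, x$b, x$rmse_db))
  invisible(x)
}

#' Acceptable SNR loss criterion
#'
#' TRUE when the SNR of the optimally gated image is within 3 dB of the
#' non-gated image — the image-quality bound accompanying the motion
#' criterion.
#'
#' @param snr_nongated_db,snr_optimal_db SNRs in dB.
#' @param max_loss_db Allowed loss (default 3 dB).
#' @return Logical.
#' @examples
#' snr_criterion(20, 18.3)
#' @export
snr_criterion <- function(snr_nongated_db, snr_optimal_db, max_loss_db = 3) {
  if (!is.finite(snr_nongated_db) || !is.finite(snr_optimal_db)) {
    abort_gateopt("SNR inputs must be finite.", "gateopt_input_error")
  }
  (snr_nongated_db - snr_optimal_db) <= max_loss_db
}

trilinear_interp <- function(vol, pts) {
  d <- dim(vol$voxels)
  idx <- sweep(sweep(pts, 2, vol$origin_mm, "-"), 2, vol$voxel_size_mm, "/") + 1
  if (any(idx < 1 - 1e-9) || any(sweep(idx, 2, d, "-") > 1e-9)) {
    abort_gateopt("Profile endpoints lie outside the volume.",
                  "gateopt_bounds_error")
  }
  idx <- pmin(pmax(idx, 1), matrix(d, nrow(idx), 3, byrow = TRUE))
  f0 <- pmin(floor(idx), matrix(d - 1, nrow(idx), 3, byrow = TRUE))
  fr <- idx - f0
  vals <- numeric(nrow(idx))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    lin <- (f0[, 1] + dx) + (f0[, 2] + dy - 1) * d[1] +
      (f0[, 3] + dz - 1) * d[1] * d[2]
    vals <- vals + w * vol$voxels[lin]
  }
  vals
}

#' Extract a line profile from a volume
#'
#' Samples the volume by trilinear interpolation at uniform spacing along the
#' segment from `p0` to `p1` (positions in mm).
#'
#' @param vol A [volume_image()].
#' @param p0,p1 Segment endpoints in mm (inside the volume).
#' @param spacing_mm Sampling step; defaults to half the smallest voxel
#'   dimension.
#' @return An object of class `line_profile` with elements `values`,
#'   `spacing_mm`, `positions_mm` (distance along the segment) and
#'   `endpoints`.
#' @export
extract_profile <- function(vol, p0, p1,
                            spacing_mm = min(vol$voxel_size_mm) / 2) {
  stopifnot(inherits(vol, "volume_image"))
  p0 <- as.numeric(p0)
  p1 <- as.numeric(p1)
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) {
    abort_gateopt("Profile segment has zero length.", "gateopt_bounds_error")
  }
  n <- max(3, floor(len / spacing_mm) + 1)
  t <- seq(0, 1, length.out = n)
  pts <- cbind(p0[1] + t * (p1[1] - p0[1]),
               p0[2] + t * (p1[2] - p0[2]),
               p0[3] + t * (p1[3] - p0[3]))
  structure(
    list(values = trilinear_interp(vol, pts),
         spacing_mm = len / (n - 1),
         positions_mm = t * len,
         endpoints = list(p0 = p0, p1 = p1)),
    class = "line_profile"
  )
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples @ %.3f mm, range [%.3g, %.3g]\n",
              length(x$values), x$spacing_mm, min(x$values), max(x$values)))
  invisible(x)
}

#' Full width at half maximum of a line profile
#'
#' Width in mm between the two half-maximum crossings nearest the profile
#' peak, each located by linear interpolation between bracketing samples.
#' The half-maximum level is measured above the profile minimum (baseline).
#' The peak must lie strictly inside the profile and the half level must be
#' crossed on both sides.
#'
#' @param profile A [extract_profile()] result, or a numeric vector combined
#'   with `spacing_mm`.
#' @param spacing_mm Sample spacing when `profile` is a bare numeric vector.
#' @return FWHM in mm.
#' @examples
#' prof <- c(0, 2, 4, 6, 8, 10, 8, 6, 4, 2, 0)
#' fwhm(prof, spacing_mm = 1) # symmetric triangle: 5 mm
#' @export
fwhm <- function(profile, spacing_mm = NULL) {
  if (inherits(profile, "line_profile")) {
    values <- profile$values
    spacing_mm <- profile$spacing_mm
  } else {
    values <- as.numeric(profile)
    if (is.null(spacing_mm)) {
      abort_gateopt("`spacing_mm` is required for a bare numeric profile.",
                    "gateopt_input_error")
    }
  }
  n <- length(values)
  if (n < 3) {
    abort_gateopt("Profile needs at least 3 samples.", "gateopt_input_error")
  }
  peak <- which.max(values)
  base <- min(values)
  if (peak == 1 || peak == n || values[peak] <= base) {
    abort_gateopt("Profile has no strict interior maximum above its baseline.",
                  "gateopt_open_profile")
  }
  half <- base + (values[peak] - base) / 2

  cross_left <- NA_real_
  for (i in seq(peak - 1, 1)) {
    if (values[i] <= half) {
      cross_left <- i + (half - values[i]) / (values[i + 1] - values[i])
      break
    }
  }
  cross_right <- NA_real_
  for (i in seq(peak + 1, n)) {
    if (values[i] <= half) {
      cross_right <- (i - 1) + (half - values[i - 1]) / (values[i] - values[i - 1])
      break
    }
  }
  if (is.na(cross_left) || is.na(cross_right)) {
    abort_gateopt("Profile does not cross half maximum on both sides.",
                  "gateopt_open_profile")
  }
  (cross_right - cross_left) * spacing_mm
}

#' Relative FWHM difference between gated and non-gated images
#'
#' `(FWHM_dual_gated - FWHM_non_gated) / FWHM_non_gated * 100`; negative
#' values mean the gated image is sharper.
#'
#' @param fwhm_dg FWHM measured in the dual-gated image (mm).
#' @param fwhm_ng FWHM measured in the non-gated image (mm, > 0).
#' @return Percentage change.
#' @examples
#' relative_fwhm_difference(27, 35)
#' @export
relative_fwhm_difference <- function(fwhm_dg, fwhm_ng) {
  if (any(fwhm_ng <= 0)) {
    abort_gateopt("Reference FWHM must be positive.", "gateopt_input_error")
  }
  (fwhm_dg - fwhm_ng) / fwhm_ng * 100
}
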