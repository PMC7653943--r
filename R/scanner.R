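#' Scanner specification
#'
#' Describes the PET system whose images are analysed: its effective spatial
#' resolution (the system FWHM `s`, which drives the optimal-gate-count rules:
#' motion is considered compensated once captured to within `s/2`) and the
#' reconstructed image geometry.
#'
#' Defaults correspond to a whole-body PET/CT system with 5.2 mm effective
#' resolution reconstructing 192 x 192 x 47 volumes at
#' 1.82 x 1.82 x 3.27 mm voxels (35 cm transaxial field of view).
#'
#' @param resolution_fwhm_mm Effective scanner resolution (FWHM) in mm.
#' @param voxel_size_mm Numeric length-3 vector of voxel edge lengths in mm
#'   (x, y, z with z the axial direction).
#' @param volume_shape Integer length-3 vector giving the reconstructed image
#'   dimensions.
#'
#' @return An object of class `scanner_spec`.
#' @examples
#' scanner_spec()
#' scanner_spec(volume_shape = c(64, 64, 47))
#' @export
scanner_spec <- function(resolution_fwhm_mm = 5.2,
                         voxel_size_mm = c(1.82, 1.82, 3.27),
                         volume_shape = c(192L, 192L, 47L)) {
  if (length(resolution_fwhm_mm) != 1 || !is.finite(resolution_fwhm_mm) ||
      resolution_fwhm_mm <= 0) {
    abort_gateopt("`resolution_fwhm_mm` must be a single positive length.",
                  "gateopt_input_error")
  }
  if (length(voxel_size_mm) != 3 || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    abort_gateopt("`voxel_size_mm` must be three positive lengths.",
                  "gateopt_input_error")
  }
  if (length(volume_shape) != 3 || any(volume_shape < 1) ||
      any(abs(volume_shape - round(volume_shape)) > 1e-8)) {
    abort_gateopt("`volume_shape` must be three positive integers.",
                  "gateopt_input_error")
  }
  structure(
    list(
      resolution_fwhm_mm = as.numeric(resolution_fwhm_mm),
      voxel_size_mm = as.numeric(voxel_size_mm),
      volume_shape = as.integer(round(volume_shape))
    ),
    class = "scanner_spec"
  )
}

#' @export
print.scanner_spec <- function(x, ...) {
  cat("<scanner_spec>\n")
  cat(sprintf("  resolution (FWHM): %.2f mm\n", x$resolution_fwhm_mm))
  cat(sprintf("  volume: %s voxels @ %s mm\n",
              paste(x$volume_shape, collapse = " x "),
              paste(format(x$voxel_size_mm), collapse = " x ")))
  invisible(x)
}

#' Gating scheme
#'
#' A pair of gate counts: `n_resp` amplitude-based respiratory gates and
#' `n_card` phase-based cardiac gates, giving `n_resp * n_card` dual gates.
#'
#' @param n_resp Number of respiratory gates (integer >= 1).
#' @param n_card Number of cardiac gates (integer >= 1).
#' @return An object of class `gate_scheme` with fields `n_resp`, `n_card`
#'   and `total`.
#' @examples
#' gate_scheme(5, 4)
#' @export
gate_scheme <- function(n_resp, n_card) {
  n_resp <- check_gate_count(n_resp, "n_resp")
  n_card <- check_gate_count(n_card, "n_card")
  structure(
    list(n_resp = n_resp, n_card = n_card, total = n_resp * n_card),
    class = "gate_scheme"
  )
}

#' @export
print.gate_scheme <- function(x, ...) {
  cat(sprintf("<gate_scheme> %d respiratory x %d cardiac = %d dual gates\n",
              x$n_resp, x$n_card, x$total))
  invisible(x)
}

#' @export
format.gate_scheme <- function(x, ...) {
  sprintf("(%d,%d)", x$n_resp, x$n_card)
}
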