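#' 3-D activity volume
#'
#' A 3-D grid of non-negative voxel intensities with its voxel geometry. The
#' third array axis is axial (z); positions are in mm at voxel centres, with
#' the default origin placing the grid centre at (0, 0, 0).
#'
#' @param voxels Numeric 3-D array of intensities.
#' @param voxel_size_mm Length-3 vector of voxel edge lengths in mm.
#' @param origin_mm Position (mm) of the centre of voxel `[1, 1, 1]`; default
#'   centres the grid on the coordinate origin.
#' @return An object of class `volume_image`.
#' @examples
#' v <- volume_image(array(0, c(8, 8, 4)), c(2, 2, 3))
#' dim(v$voxels)
#' @export
volume_image <- function(voxels, voxel_size_mm, origin_mm = NULL) {
  if (length(dim(voxels)) != 3) {
    abort_gateopt("`voxels` must be a 3-D array.", "gateopt_input_error")
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3 || any(voxel_size_mm <= 0)) {
    abort_gateopt("`voxel_size_mm` must be three positive lengths.",
                  "gateopt_input_error")
  }
  if (is.null(origin_mm)) {
    origin_mm <- -(dim(voxels) - 1) / 2 * voxel_size_mm
  }
  structure(
    list(voxels = voxels, voxel_size_mm = voxel_size_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels @ %s mm, intensity range [%.3g, %.3g]\n",
              paste(dim(x$voxels), collapse = " x "),
              paste(format(x$voxel_size_mm), collapse = " x "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

# voxel-centre coordinates (mm) along one axis
axis_coords <- function(vol, axis) {
  vol$origin_mm[axis] + (seq_len(dim(vol$voxels)[axis]) - 1) * vol$voxel_size_mm[axis]
}

# mm position -> fractional voxel index (1-based)
mm_to_index <- function(vol, pos_mm) {
  (pos_mm - vol$origin_mm) / vol$voxel_size_mm + 1
}

index_to_mm <- function(vol, idx) {
  vol$origin_mm + (idx - 1) * vol$voxel_size_mm
}

#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers around RNifti preserving the voxel size; volumes are written
#' as 32-bit float.
#'
#' @param vol A [volume_image()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a [volume_image()]; `write_volume()`
#'   returns `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  arr <- vol$voxels
  attr(arr, "pixdim") <- vol$voxel_size_mm
  attr(arr, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  volume_image(array(as.numeric(img), dim(img)),
               RNifti::pixdim(img)[seq_len(3)])
}

#' Gated image set
#'
#' The result of a dual-gated acquisition: one activity volume per
#' (respiratory, cardiac) gate plus each gate's dwell-time fraction (its share
#' of valid acquisition time; the fractions sum to at most 1, the remainder
#' being rejected data).
#'
#' @param scheme A [gate_scheme()].
#' @param volumes List of [volume_image()] objects, one per dual gate, named
#'   `"r<resp>_c<card>"`.
#' @param gate_fractions Tibble with columns `resp_gate`, `card_gate`,
#'   `fraction`.
#' @param rejected_pct Percentage of rejected acquisition samples.
#' @return An object of class `gated_image_set`.
#' @seealso [simulate_gated_acquisition()]
#' @export
gated_image_set <- function(scheme, volumes, gate_fractions, rejected_pct = 0) {
  stopifnot(inherits(scheme, "gate_scheme"))
  expected <- gate_key(rep(seq_len(scheme$n_resp), each = scheme$n_card),
                       rep(seq_len(scheme$n_card), scheme$n_resp))
  if (!setequal(names(volumes), expected)) {
    abort_gateopt("`volumes` must contain every cell of the scheme.",
                  "gateopt_input_error")
  }
  structure(
    list(scheme = scheme, volumes = volumes,
         gate_fractions = tibble::as_tibble(gate_fractions),
         rejected_pct = rejected_pct),
    class = "gated_image_set"
  )
}

gate_key <- function(resp, card) sprintf("r%d_c%d", resp, card)

#' @export
print.gated_image_set <- function(x, ...) {
  cat(sprintf("<gated_image_set> scheme %s, %d volumes, %.1f%% rejected data\n",
              format(x$scheme), length(x$volumes), x$rejected_pct))
  invisible(x)
}

gate_volume <- function(set, resp, card) {
  set$volumes[[gate_key(resp, card)]]
}

#' Write and read a gated image set
#'
#' Writes one NIfTI-1 volume per gate plus a JSON sidecar recording the
#' scheme, the gate-file mapping, dwell fractions and rejected-data
#' percentage.
#'
#' @param set A [gated_image_set()].
#' @param dir Output directory (created if needed).
#' @return `read_gated_set()` returns a [gated_image_set()];
#'   `write_gated_set()` returns `dir` invisibly.
#' @export
write_gated_set <- function(set, dir) {
  stopifnot(inherits(set, "gated_image_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (key in names(set$volumes)) {
    f <- file.path(dir, paste0(key, ".nii.gz"))
    write_volume(set$volumes[[key]], f)
    files[key] <- basename(f)
  }
  sidecar <- list(
    scheme = list(n_resp = set$scheme$n_resp, n_card = set$scheme$n_card),
    rejected_pct = set$rejected_pct,
    gate_fractions = set$gate_fractions,
    files = as.list(files),
    voxel_size_mm = set$volumes[[1]]$voxel_size_mm,
    origin_mm = set$volumes[[1]]$origin_mm
  )
  jsonlite::write_json(sidecar, file.path(dir, "gates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_gated_set
#' @export
read_gated_set <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "gates.json"),
                                 simplifyVector = TRUE)
  volumes <- lapply(sidecar$files, function(f) {
    vol <- read_volume(file.path(dir, f))
    vol$origin_mm <- as.numeric(sidecar$origin_mm)
    vol
  })
  gated_image_set(
    gate_scheme(sidecar$scheme$n_resp, sidecar$scheme$n_card),
    volumes,
    tibble::as_tibble(sidecar$gate_fractions),
    rejected_pct = sidecar$rejected_pct
  )
}
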