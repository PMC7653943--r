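#' Gate grid of measured total motion
#'
#' A matrix of total measured motion (mm) indexed by respiratory and cardiac
#' gate counts, the object on which the minimal-product grid search for the
#' optimal scheme operates.
#'
#' @param resp_counts Ordered integer vector of respiratory gate counts.
#' @param card_counts Ordered integer vector of cardiac gate counts.
#' @param motion_mm Numeric matrix of motion values, `length(card_counts)`
#'   rows by `length(resp_counts)` columns, all entries >= 0.
#' @return An object of class `gate_grid`. `as_tibble()` gives the long form
#'   with columns `n_resp`, `n_card`, `motion_mm`.
#' @examples
#' grid <- phantom_motion_grid()
#' optimal_from_grid(grid, threshold_mm = 12.7)
#' @export
gate_grid <- function(resp_counts, card_counts, motion_mm) {
  resp_counts <- check_gate_count(resp_counts, "resp_counts")
  card_counts <- check_gate_count(card_counts, "card_counts")
  motion_mm <- as.matrix(motion_mm)
  if (nrow(motion_mm) != length(card_counts) ||
      ncol(motion_mm) != length(resp_counts)) {
    abort_gateopt("`motion_mm` must be a [card x resp] matrix matching the count lists.",
                  "gateopt_input_error")
  }
  if (anyNA(motion_mm) || any(motion_mm < 0)) {
    abort_gateopt("Grid motion values must be non-negative.", "gateopt_input_error")
  }
  dimnames(motion_mm) <- list(card_counts, resp_counts)
  structure(
    list(resp_counts = resp_counts, card_counts = card_counts,
         motion_mm = motion_mm),
    class = "gate_grid"
  )
}

#' @export
print.gate_grid <- function(x, ...) {
  cat(sprintf("<gate_grid> total motion (mm), %d cardiac x %d respiratory gate counts\n",
              length(x$card_counts), length(x$resp_counts)))
  print(x$motion_mm)
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.gate_grid <- function(x, ...) {
  tidyr::expand_grid(n_card = x$card_counts, n_resp = x$resp_counts) |>
    dplyr::mutate(motion_mm = as.vector(t(x$motion_mm))) |>
    dplyr::select("n_resp", "n_card", "motion_mm")
}

#' Minimal-product optimal scheme from a gate grid
#'
#' Among grid cells whose measured total motion reaches `threshold_mm`,
#' returns the scheme minimising the total number of gates
#' `n_resp * n_card`. Ties are broken towards fewer cardiac gates, then fewer
#' respiratory gates (ECG gating discards less data than respiratory gating).
#'
#' @param grid A [gate_grid()].
#' @param threshold_mm Motion the scheme must capture, in mm (see
#'   [threshold_from_motion()]).
#' @return A [gate_scheme()].
#' @examples
#' optimal_from_grid(phantom_motion_grid(), 12.7)
#' @export
optimal_from_grid <- function(grid, threshold_mm) {
  stopifnot(inherits(grid, "gate_grid"))
  threshold_mm <- check_nonneg_scalar(threshold_mm, "threshold_mm")
  cells <- as_tibble(grid) |>
    dplyr::filter(.data$motion_mm >= threshold_mm - 1e-9) |>
    dplyr::mutate(product = .data$n_resp * .data$n_card) |>
    dplyr::arrange(.data$product, .data$n_card, .data$n_resp)
  if (nrow(cells) == 0) {
    abort_gateopt(
      sprintf("No gating scheme in the grid captures %.2f mm (grid maximum %.2f mm).",
              threshold_mm, max(grid$motion_mm)),
      "gateopt_no_feasible_scheme"
    )
  }
  gate_scheme(cells$n_resp[1], cells$n_card[1])
}

#' Read and write gate grids as CSV
#'
#' The CSV layout has cardiac gate counts in the first column and respiratory
#' gate counts as the header of the remaining columns, matching the printed
#' grid layout.
#'
#' @param path File path.
#' @param grid A [gate_grid()].
#' @return `read_gate_grid()` returns a [gate_grid()]; `write_gate_grid()`
#'   returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_gate_grid(phantom_motion_grid(), path)
#' read_gate_grid(path)
#' @export
read_gate_grid <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (ncol(raw) < 2) {
    abort_gateopt("Gate-grid CSV needs a cardiac-count column plus motion columns.",
                  "gateopt_input_error")
  }
  resp_counts <- as.integer(names(raw)[-1])
  if (anyNA(resp_counts)) {
    abort_gateopt("Gate-grid CSV header must list respiratory gate counts.",
                  "gateopt_input_error")
  }
  gate_grid(resp_counts, as.integer(raw[[1]]),
            as.matrix(raw[, -1, drop = FALSE]))
}

#' @rdname read_gate_grid
#' @export
write_gate_grid <- function(grid, path) {
  stopifnot(inherits(grid, "gate_grid"))
  out <- data.frame(n_card = grid$card_counts, grid$motion_mm,
                    check.names = FALSE)
  names(out) <- c("n_card", grid$resp_counts)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Measured phantom motion grid
#'
#' The published measured total motion (mm) of the moving heart phantom as a
#' function of respiratory (1-6) and cardiac (1, 4, 6, 8, 10) gate counts,
#' shipped as a CSV fixture. At the phantom's 12.7 mm motion-minimisation
#' threshold its minimal-product optimum is 5 respiratory and 4 cardiac gates.
#'
#' @return A [gate_grid()].
#' @examples
#' phantom_motion_grid()
#' @export
phantom_motion_grid <- function() {
  read_gate_grid(system.file("extdata", "phantom_motion_grid.csv",
                             package = "gateopt", mustWork = TRUE))
}
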