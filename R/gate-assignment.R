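#' Amplitude-based respiratory gate assignment
#'
#' Splits the amplitude range of the valid samples of a lung-volume signal
#' into `r` bins of equal height and labels each valid sample with its bin
#' (1 = lowest amplitude, end-expiration). Values exactly on an interior
#' boundary go to the higher bin; the range maximum goes to bin `r`. Invalid
#' samples are labelled `NA` (rejected). The labelling is invariant under
#' affine rescaling of the amplitude signal because only the valid-sample
#' range enters.
#'
#' @param signal A data frame with columns `time_s`, `amplitude` and logical
#'   `valid` (see [gen_resp_signal()]), or a numeric amplitude vector (all
#'   samples then count as valid).
#' @param r Number of respiratory gates (integer >= 1).
#' @return An integer vector of gate indices in `[1, r]`, `NA` for rejected
#'   samples.
#' @examples
#' assign_resp_amplitude(c(0, 0.25, 0.5, 0.75, 1), r = 2)
#' @export
assign_resp_amplitude <- function(signal, r) {
  r <- check_gate_count(r, "r")
  if (is.numeric(signal)) {
    signal <- tibble::tibble(time_s = seq_along(signal), amplitude = signal,
                             valid = TRUE)
  }
  check_columns(signal, c("amplitude", "valid"), "`signal`")
  amp <- as.numeric(signal$amplitude)
  valid <- as.logical(signal$valid) & is.finite(amp)
  if (!any(valid)) {
    abort_gateopt("Signal contains no valid samples.", "gateopt_empty_signal")
  }
  lo <- min(amp[valid])
  hi <- max(amp[valid])
  idx <- rep(NA_integer_, length(amp))
  if (hi == lo) {
    idx[valid] <- 1L
    return(idx)
  }
  breaks <- seq(lo, hi, length.out = r + 1)
  # findInterval: breaks[i] <= x < breaks[i+1] -> boundary values go up
  bin <- findInterval(amp[valid], breaks)
  idx[valid] <- pmin.int(bin, r)
  idx
}

# cardiac phase in [0, 1) within the enclosing RR interval; NA outside coverage
card_phase_of <- function(times, rpeak_times) {
  i <- findInterval(times, rpeak_times)
  inside <- i >= 1 & i < length(rpeak_times)
  phase <- rep(NA_real_, length(times))
  ii <- i[inside]
  phase[inside] <- (times[inside] - rpeak_times[ii]) /
    (rpeak_times[ii + 1] - rpeak_times[ii])
  phase
}

#' Phase-based cardiac gate assignment
#'
#' Divides each R-to-R interval into `p` gates of equal time fraction. A time
#' `t` inside `[R_i, R_(i+1))` receives gate `floor(p * phase) + 1` where
#' `phase` is its relative position in the interval; a time exactly on an
#' R-peak starts gate 1 of the new cycle. Times before the first or at/after
#' the last R-peak are rejected (`NA`).
#'
#' @param rpeak_times Strictly increasing R-peak times in seconds (numeric
#'   vector or a data frame with column `rpeak_time_s`); at least 2 peaks.
#' @param p Number of cardiac gates (integer >= 1).
#' @param times Sample times in seconds.
#' @return An integer vector of gate indices in `[1, p]`, `NA` for rejected
#'   samples.
#' @examples
#' assign_card_phase(c(0, 1), p = 4, times = c(0, 0.3, 0.8, 1.2))
#' @export
assign_card_phase <- function(rpeak_times, p, times) {
  p <- check_gate_count(p, "p")
  if (is.data.frame(rpeak_times)) {
    check_columns(rpeak_times, "rpeak_time_s", "`rpeak_times`")
    rpeak_times <- rpeak_times$rpeak_time_s
  }
  rpeak_times <- as.numeric(rpeak_times)
  if (length(rpeak_times) < 2 || any(diff(rpeak_times) <= 0)) {
    abort_gateopt("At least 2 strictly increasing R-peaks are required.",
                  "gateopt_insufficient_triggers")
  }
  phase <- card_phase_of(as.numeric(times), rpeak_times)
  idx <- ifelse(is.na(phase), NA_integer_,
                pmin.int(as.integer(floor(phase * p)) + 1L, p))
  as.integer(idx)
}

#' Combine respiratory and cardiac gate labels into dual-gate labels
#'
#' Pairs the per-sample respiratory and cardiac gate indices; a sample is
#' rejected (both components `NA`) when either component is rejected.
#'
#' @param resp_idx,card_idx Integer gate-index vectors of equal length (`NA`
#'   = rejected), as returned by [assign_resp_amplitude()] and
#'   [assign_card_phase()].
#' @return A tibble with columns `resp_gate` and `card_gate`.
#' @examples
#' combine_dual(c(1L, 2L), c(3L, NA))
#' @export
combine_dual <- function(resp_idx, card_idx) {
  if (length(resp_idx) != length(card_idx)) {
    abort_gateopt("`resp_idx` and `card_idx` must have equal length.",
                  "gateopt_input_error")
  }
  rejected <- is.na(resp_idx) | is.na(card_idx)
  tibble::tibble(
    resp_gate = ifelse(rejected, NA_integer_, as.integer(resp_idx)),
    card_gate = ifelse(rejected, NA_integer_, as.integer(card_idx))
  )
}

#' Fraction of rejected samples
#'
#' The percentage of samples whose dual-gate label is rejected, combining
#' invalid respiratory-signal samples and samples outside ECG coverage.
#'
#' @param labels A tibble from [combine_dual()], or any vector/data frame
#'   whose `NA` rows count as rejected.
#' @return Percentage in `[0, 100]`.
#' @examples
#' rejected_fraction(combine_dual(c(1L, NA, 2L, 1L), c(1L, 1L, NA, 2L)))
#' @export
rejected_fraction <- function(labels) {
  if (is.data.frame(labels)) {
    if (nrow(labels) == 0) {
      abort_gateopt("`labels` is empty.", "gateopt_input_error")
    }
    rejected <- !stats::complete.cases(labels)
  } else {
    if (length(labels) == 0) {
      abort_gateopt("`labels` is empty.", "gateopt_input_error")
    }
    rejected <- is.na(labels)
  }
  100 * mean(rejected)
}

#' Write and read dual-gate labels as CSV
#'
#' Labels are stored as `time_s,resp_gate,card_gate` with `-1` marking
#' rejected samples.
#'
#' @param labels A tibble with columns `resp_gate`, `card_gate` (and
#'   optionally `time_s`).
#' @param times Sample times written alongside the labels (defaults to the
#'   `time_s` column when present).
#' @param path File path.
#' @return `read_gate_labels()` returns a tibble with `NA` for rejected
#'   samples; `write_gate_labels()` returns `path` invisibly.
#' @export
write_gate_labels <- function(labels, path, times = NULL) {
  check_columns(labels, c("resp_gate", "card_gate"), "`labels`")
  if (is.null(times)) {
    times <- if ("time_s" %in% names(labels)) labels$time_s else seq_len(nrow(labels))
  }
  out <- tibble::tibble(
    time_s = times,
    resp_gate = dplyr::coalesce(as.integer(labels$resp_gate), -1L),
    card_gate = dplyr::coalesce(as.integer(labels$card_gate), -1L)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_gate_labels
#' @export
read_gate_labels <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           time_s = readr::col_double(),
                           resp_gate = readr::col_integer(),
                           card_gate = readr::col_integer()
                         ))
  out |>
    dplyr::mutate(
      resp_gate = dplyr::if_else(.data$resp_gate < 0, NA_integer_, .data$resp_gate),
      card_gate = dplyr::if_else(.data$card_gate < 0, NA_integer_, .data$card_gate)
    )
}
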