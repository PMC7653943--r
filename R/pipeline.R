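#' Default phantom-study gating schemes
#'
#' The gate-count coverage used in the reference phantom protocol: 1-6
#' respiratory gates crossed with 1, 4, 6, 8 and 10 cardiac gates.
#'
#' @param resp_counts,card_counts Gate-count vectors to cross.
#' @return A list of [gate_scheme()] objects.
#' @examples
#' length(default_schemes())
#' @export
default_schemes <- function(resp_counts = 1:6, card_counts = c(1, 4, 6, 8, 10)) {
  grid <- tidyr::expand_grid(r = resp_counts, p = card_counts)
  purrr::map2(grid$r, grid$p, gate_scheme)
}

#' Run the full phantom gating study
#'
#' The end-to-end workflow: simulate one acquisition and gate it under every
#' scheme, measure respiratory/cardiac motion per scheme, fit the dual motion
#' model, derive the optimal scheme both from the model inversion and from a
#' minimal-product search over the measured motion grid, and evaluate image
#' quality (per-scheme SNR with the log-law fit and the 3 dB rule; hot-spot
#' FWHM of the optimal scheme's most statistics-rich gate versus the
#' non-gated image). Volumes are discarded after measurement so memory stays
#' bounded; only the non-gated image and the optimal scheme's last gate are
#' kept for the profile analysis.
#'
#' @param config A [phantom_config()]; its `noise` flag controls whether SNR
#'   and FWHM are evaluated on noisy data (SNR requires noise).
#' @param scanner A [scanner_spec()].
#' @param schemes List of [gate_scheme()]s (default [default_schemes()]).
#' @param duration_s Acquisition duration in seconds.
#' @param locator Motion locator (see [measure_extreme_motion()]).
#' @return A list of class `phantom_study` with elements `samples` (motion
#'   tibble), `fit` (dual `motion_model_fit`), `threshold_mm`,
#'   `optimal_model` and `optimal_grid` ([gate_scheme()]s), `grid`
#'   ([gate_grid()]), `snr` (tibble + `snr_fit` when noise is on),
#'   `quality` (FWHM comparison) and `config`/`scanner`/`seed` provenance.
#' @export
run_phantom_study <- function(config = phantom_config(),
                              scanner = scanner_spec(),
                              schemes = default_schemes(),
                              duration_s = 1800,
                              locator = "hotspot_weighted90") {
  signals <- phantom_signals(config, duration_s)
  cache <- new.env(parent = emptyenv())

  rows <- list()
  snr_rows <- list()
  nongated_sum <- NULL
  optimal_last_gate <- NULL
  voi_spec <- NULL

  measure_one <- function(sch) {
    set <- simulate_gated_acquisition(config, scanner, sch, duration_s,
                                      signals = signals, render_cache = cache)
    sample <- build_motion_samples(list(set), locator = locator,
                                   psf_fwhm_mm = config$psf_fwhm_mm)
    out <- list(sample = sample)
    if (config$noise) {
      if (is.null(voi_spec)) {
        voi_spec <<- phantom_voi(config, scanner)
      }
      out$snr <- scheme_snr(set, voi_spec)
    }
    if (sch$total == 1) {
      nongated_sum <<- set$volumes[[1]]
    }
    out
  }

  for (sch in schemes) {
    res <- measure_one(sch)
    rows[[length(rows) + 1]] <- res$sample
    if (config$noise) {
      snr_rows[[length(snr_rows) + 1]] <-
        tibble::tibble(n_resp = sch$n_resp, n_card = sch$n_card,
                       n_total = sch$total, snr_db = res$snr)
    }
  }
  samples <- dplyr::bind_rows(rows)

  fit <- fit_dual_model(samples)
  threshold_mm <- threshold_from_motion(fit$coef[["a"]], fit$coef[["b"]], scanner)
  optimal_model <- optimal_gates(fit, scanner)

  grid <- samples_to_grid(samples)
  optimal_grid <- tryCatch(
    optimal_from_grid(grid, threshold_mm),
    gateopt_no_feasible_scheme = function(e) NULL
  )

  snr <- NULL
  snr_fit <- NULL
  quality <- NULL
  if (config$noise) {
    snr <- dplyr::bind_rows(snr_rows)
    snr_fit <- fit_snr_curve(snr)
    target <- if (!is.null(optimal_grid)) optimal_grid else optimal_model
    in_study <- any(samples$n_resp == target$n_resp &
                      samples$n_card == target$n_card)
    if (in_study && !is.null(nongated_sum)) {
      opt_set <- simulate_gated_acquisition(config, scanner, target, duration_s,
                                            signals = signals,
                                            render_cache = cache)
      last_gate <- gate_volume(opt_set, target$n_resp, target$n_card)
      quality <- hotspot_quality(nongated_sum, last_gate, config)
      snr_nongated <- snr$snr_db[snr$n_total == 1][1]
      snr_opt <- snr$snr_db[snr$n_resp == target$n_resp &
                              snr$n_card == target$n_card][1]
      quality$snr_nongated_db <- snr_nongated
      quality$snr_optimal_db <- snr_opt
      quality$snr_within_3db <- snr_criterion(snr_nongated, snr_opt)
    }
  }

  structure(
    list(samples = samples, fit = fit, threshold_mm = threshold_mm,
         optimal_model = optimal_model, optimal_grid = optimal_grid,
         grid = grid, snr = snr, snr_fit = snr_fit, quality = quality,
         config = config, scanner = scanner, seed = config$seed),
    class = "phantom_study"
  )
}

# VOI centred in the balloon core at mid respiratory excursion
phantom_voi <- function(config, scanner, extents = c(13, 13, 13)) {
  tmp <- volume_image(array(0, scanner$volume_shape), scanner$voxel_size_mm)
  centre_mm <- c(0, 0, 0) # balloon centre at mid excursion
  voi(center = mm_to_index(tmp, centre_mm), extents = extents, shape = "box")
}

# axial profile through the most active hot spot in both images
hotspot_quality <- function(nongated, gated, config) {
  prof_for <- function(vol) {
    peak <- locate_hotspot(vol, "local_max", psf_fwhm_mm = config$psf_fwhm_mm)
    zmin <- axis_coords(vol, 3)[1]
    zmax <- axis_coords(vol, 3)[length(axis_coords(vol, 3))]
    extract_profile(vol, c(peak[1], peak[2], zmin), c(peak[1], peak[2], zmax))
  }
  f_ng <- fwhm(prof_for(nongated))
  f_dg <- fwhm(prof_for(gated))
  list(fwhm_nongated_mm = f_ng, fwhm_gated_mm = f_dg,
       fwhm_change_pct = relative_fwhm_difference(f_dg, f_ng))
}

# motion-sample tibble -> gate_grid of total motion
samples_to_grid <- function(samples) {
  resp_counts <- sort(unique(samples$n_resp))
  card_counts <- sort(unique(samples$n_card))
  m <- matrix(NA_real_, length(card_counts), length(resp_counts))
  for (k in seq_len(nrow(samples))) {
    i <- match(samples$n_card[k], card_counts)
    j <- match(samples$n_resp[k], resp_counts)
    m[i, j] <- samples$motion_mm[k]
  }
  if (anyNA(m)) {
    abort_gateopt("Motion samples do not cover a full scheme grid.",
                  "gateopt_input_error")
  }
  gate_grid(resp_counts, card_counts, pmax(m, 0))
}

#' @export
print.phantom_study <- function(x, ...) {
  cat("<phantom_study>\n")
  cat(sprintf("  fitted amplitudes: a = %.2f mm respiratory, b = %.2f mm cardiac\n",
              x$fit$coef[["a"]], x$fit$coef[["b"]]))
  cat(sprintf("  threshold %.2f mm; optimal scheme %s (model), %s (grid)\n",
              x$threshold_mm, format(x$optimal_model),
              if (is.null(x$optimal_grid)) "none" else format(x$optimal_grid)))
  if (!is.null(x$snr_fit)) {
    cat(sprintf("  SNR(n) = %.1f %+.2f log10(n) dB (rmse %.2f dB)\n",
                x$snr_fit$a, x$snr_fit$b, x$snr_fit$rmse_db))
  }
  if (!is.null(x$quality)) {
    cat(sprintf("  hot-spot FWHM %.1f -> %.1f mm (%.0f%%)\n",
                x$quality$fwhm_nongated_mm, x$quality$fwhm_gated_mm,
                x$quality$fwhm_change_pct))
  }
  invisible(x)
}

#' Serialise study results
#'
#' Writes a JSON report (fit parameters, threshold, chosen schemes, SNR fit,
#' quality metrics, seed) plus CSV tables of the motion samples and SNR
#' measurements.
#'
#' @param study A `phantom_study` from [run_phantom_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "phantom_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    seed = study$seed,
    fit = list(kind = study$fit$kind, coef = as.list(study$fit$coef),
               m_est = study$fit$m_est),
    threshold_mm = study$threshold_mm,
    optimal_model = list(n_resp = study$optimal_model$n_resp,
                         n_card = study$optimal_model$n_card),
    optimal_grid = if (is.null(study$optimal_grid)) NULL else
      list(n_resp = study$optimal_grid$n_resp,
           n_card = study$optimal_grid$n_card),
    snr_fit = if (is.null(study$snr_fit)) NULL else
      list(a = study$snr_fit$a, b = study$snr_fit$b,
           rmse_db = study$snr_fit$rmse_db),
    quality = study$quality
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(study$samples, file.path(dir, "motion_samples.csv"))
  if (!is.null(study$snr)) {
    readr::write_csv(study$snr, file.path(dir, "snr.csv"))
  }
  write_gate_grid(study$grid, file.path(dir, "motion_grid.csv"))
  invisible(dir)
}

#' Optimal gates from a motion table, grid or component amplitudes
#'
#' One-stop wrapper mirroring the command-line `optimize` verb: fit the
#' requested model to a motion table (CSV path or data frame) and invert it,
#' search a measured grid, or evaluate the published general lines at given
#' amplitudes.
#'
#' @param input A data frame / CSV path of motion samples (modes `"model1"`,
#'   `"model2"`), a [gate_grid()] / grid CSV path (mode `"grid"`), or a
#'   numeric `c(resp, card)` motion pair in mm (mode `"general"`).
#' @param mode One of `"model1"`, `"model2"`, `"grid"`, `"general"`.
#' @param scanner A [scanner_spec()].
#' @param threshold_mm Grid-search threshold (mode `"grid"`); defaults to the
#'   reference 12.7 mm when the input grid is the shipped phantom grid.
#' @return A list with the chosen scheme and the supporting fit/values.
#' @export
optimize_gates <- function(input, mode = c("model2", "model1", "grid", "general"),
                           scanner = scanner_spec(), threshold_mm = NULL) {
  mode <- rlang::arg_match(mode)
  if (mode == "general") {
    m <- as.numeric(input)
    if (length(m) != 2) {
      abort_gateopt("Mode 'general' needs c(respiratory, cardiac) motion in mm.",
                    "gateopt_input_error")
    }
    n_total <- eval_gate_count_line(gate_count_models$dual, sum(m), "up")
    n_resp <- eval_gate_count_line(gate_count_models$respiratory, m[1], "nearest")
    scheme <- resolve_gate_combination(n_total, n_resp)
    return(list(scheme = scheme, n_total = n_total, n_resp = n_resp,
                motion_mm = m, mode = mode))
  }
  if (mode == "grid") {
    grid <- if (inherits(input, "gate_grid")) input else read_gate_grid(input)
    if (is.null(threshold_mm)) {
      abort_gateopt("Mode 'grid' needs `threshold_mm`.", "gateopt_input_error")
    }
    scheme <- optimal_from_grid(grid, threshold_mm)
    return(list(scheme = scheme, threshold_mm = threshold_mm, mode = mode))
  }
  samples <- if (is.data.frame(input)) input else read_motion_samples(input)
  if (mode == "model1") {
    fit <- fit_single_model(samples)
    scheme <- optimal_gates(fit, scanner)
  } else {
    fit <- fit_dual_model(samples)
    scheme <- optimal_gates(fit, scanner)
  }
  list(scheme = scheme, fit = fit, mode = mode)
}
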