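#' Linear gate-count models
#'
#' A `gate_count_line` maps a motion amplitude `m` (mm) to a number of gates
#' through `slope * m + intercept`. Lines of this form summarise, across a
#' patient group, how many gates the half-resolution criterion implies for a
#' given motion amplitude, so that new studies only need a motion estimate.
#'
#' @param slope Gates per mm of motion.
#' @param intercept Gates at zero motion.
#' @param r_squared Goodness of fit (squared Pearson correlation of fitted and
#'   observed gate counts), in `[0, 1]`, or `NA` when unknown.
#' @param domain_min_mm Smallest motion amplitude (mm) the line is valid for.
#' @return An object of class `gate_count_line`.
#' @seealso [gate_count_models] for published coefficient sets,
#'   [fit_gate_count_line()] to fit a new line.
#' @examples
#' line <- gate_count_line(0.35, 1.005)
#' eval_gate_count_line(line, m = 12, rounding = "nearest")
#' @export
gate_count_line <- function(slope, intercept, r_squared = NA_real_,
                            domain_min_mm = 0) {
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    abort_gateopt("`r_squared` must lie in [0, 1].", "gateopt_input_error")
  }
  structure(
    list(slope = as.numeric(slope), intercept = as.numeric(intercept),
         r_squared = as.numeric(r_squared),
         domain_min_mm = as.numeric(domain_min_mm)),
    class = "gate_count_line"
  )
}

#' @export
print.gate_count_line <- function(x, ...) {
  cat(sprintf("<gate_count_line> n(m) = %.3f * m %+.3f", x$slope, x$intercept))
  if (!is.na(x$r_squared)) cat(sprintf("  (R^2 = %.3f)", x$r_squared))
  if (x$domain_min_mm > 0) cat(sprintf("  [m >= %g mm]", x$domain_min_mm))
  cat("\n")
  invisible(x)
}

#' Published general gate-count lines
#'
#' Named [gate_count_line()] objects with the published coefficients of the
#' general linear models relating motion amplitude to gate count:
#'
#' * `respiratory`: respiratory gates vs respiratory motion,
#'   `n = 0.350 m + 1.005` (R^2 = 0.978).
#' * `cardiac`: cardiac gates vs cardiac motion,
#'   `n = 0.356 m + 0.718` (R^2 = 0.926).
#' * `dual`: total dual gates vs summed motion, `n = 1.717 m - 18.730`
#'   (R^2 = 0.951), valid for `m >= 12` mm.
#' * `dawood_respiratory`: the earlier published respiratory line,
#'   `n = 0.488 m - 0.869`.
#' * `respiratory_dawood_form`: the respiratory line refitted in that same
#'   convention, `n = 0.407 m - 0.408`.
#'
#' @format A named list of `gate_count_line` objects.
#' @examples
#' eval_gate_count_line(gate_count_models$dual, m = 22, rounding = "up")
#' @export
gate_count_models <- list(
  respiratory = gate_count_line(0.350, 1.005, r_squared = 0.978),
  cardiac = gate_count_line(0.356, 0.718, r_squared = 0.926),
  dual = gate_count_line(1.717, -18.730, r_squared = 0.951, domain_min_mm = 12),
  dawood_respiratory = gate_count_line(0.488, -0.869),
  respiratory_dawood_form = gate_count_line(0.407, -0.408)
)

#' Evaluate a linear gate-count model
#'
#' Evaluates `slope * m + intercept`, optionally rounding the result to an
#' integer gate count. Rounding `"up"` (ceiling) reproduces the published
#' usage for total dual-gate counts; `"nearest"` (half away from zero)
#' reproduces the per-mode usage; `"none"` returns the raw value.
#'
#' @param line A [gate_count_line()].
#' @param m Motion amplitude in mm; must be at least `line$domain_min_mm`.
#' @param rounding One of `"none"`, `"nearest"`, `"up"`.
#' @return A number of gates (numeric for `"none"`, integer otherwise).
#' @examples
#' eval_gate_count_line(gate_count_models$dual, 22, "up") # 20 dual gates
#' eval_gate_count_line(gate_count_models$respiratory, 12, "nearest") # 5
#' @export
eval_gate_count_line <- function(line, m, rounding = c("none", "nearest", "up")) {
  stopifnot(inherits(line, "gate_count_line"))
  rounding <- rlang::arg_match(rounding)
  if (any(!is.finite(m)) || any(m < line$domain_min_mm)) {
    abort_gateopt(
      sprintf("`m` must be finite and >= the line's domain minimum (%g mm).",
              line$domain_min_mm),
      "gateopt_domain_error"
    )
  }
  value <- line$slope * m + line$intercept
  switch(rounding,
    none = value,
    nearest = as.integer(floor(value + 0.5)),
    up = as.integer(ceiling(value))
  )
}

#' Fit a linear gate-count model
#'
#' Ordinary least squares of gate count on motion amplitude, with goodness of
#' fit reported as the squared Pearson correlation between fitted and observed
#' gate counts.
#'
#' @param data A data frame with columns `motion_mm` and `n_gates`.
#' @param domain_min_mm Stored domain restriction of the resulting line.
#' @return A [gate_count_line()] with an additional `data` attribute.
#' @examples
#' fit_gate_count_line(data.frame(motion_mm = c(0, 10), n_gates = c(1, 5)))
#' @export
fit_gate_count_line <- function(data, domain_min_mm = 0) {
  check_columns(data, c("motion_mm", "n_gates"), "`data`")
  m <- as.numeric(data$motion_mm)
  n <- as.numeric(data$n_gates)
  if (length(m) < 2 || length(unique(m)) < 2) {
    abort_gateopt("At least two points with distinct motion values are required.",
                  "gateopt_degenerate_fit")
  }
  fit <- stats::lm(n ~ m)
  fitted <- stats::fitted(fit)
  r2 <- if (stats::var(n) == 0) 1 else stats::cor(fitted, n)^2
  line <- gate_count_line(stats::coef(fit)[["m"]], stats::coef(fit)[["(Intercept)"]],
                          r_squared = r2, domain_min_mm = domain_min_mm)
  attr(line, "data") <- tibble::tibble(motion_mm = m, n_gates = n,
                                       fitted = fitted)
  line
}
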