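# Internal helpers shared across the package.

#' @importFrom rlang .data
NULL

abort_gateopt <- function(message, class) {
  rlang::abort(message, class = c(class, "gateopt_error"))
}

# gate counts must be whole numbers >= 1
check_gate_count <- function(n, name = "n") {
  if (length(n) == 0 || anyNA(n) || any(!is.finite(n)) ||
      any(n < 1) || any(abs(n - round(n)) > 1e-8)) {
    abort_gateopt(
      sprintf("`%s` must contain whole gate counts >= 1.", name),
      "gateopt_invalid_gate_count"
    )
  }
  as.integer(round(n))
}

check_nonneg_scalar <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 0) {
    abort_gateopt(sprintf("`%s` must be a single non-negative number.", name),
                  "gateopt_input_error")
  }
  as.numeric(x)
}

check_columns <- function(data, cols, what) {
  if (!is.data.frame(data) || !all(cols %in% names(data))) {
    abort_gateopt(
      sprintf("%s must be a data frame with columns %s.",
              what, paste0("`", cols, "`", collapse = ", ")),
      "gateopt_input_error"
    )
  }
  invisible(data)
}

# FWHM of a Gaussian <-> its standard deviation
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

# deterministic sub-seed derivation; keeps results within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629)
}
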