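#' Gate-count motion models
#'
#' Predicted total motion captured by a gated acquisition, as a function of the
#' number of gates. The single-mode model assumes a cyclic motion of amplitude
#' `c` divided into `n` gates whose midpoints span `n - 1` of the `n` equal
#' motion intervals, so the motion visible between the extreme gates is
#' `c * (n - 1) / n`; it satisfies `f(1) = 0` (a single gate captures no
#' motion) and approaches `c` as `n` grows. The dual model sums independent
#' respiratory and cardiac components:
#' `g(r, p) = a * (r - 1) / r + b * (p - 1) / p`.
#'
#' `dawood_motion()` evaluates the earlier empirical respiratory model
#' `a + b * exp(c / r)`, which does not vanish at `r = 1`.
#'
#' @param c,a,b Motion amplitudes in mm (`c` single-mode; `a` respiratory and
#'   `b` cardiac for the dual model; for the Dawood model `a` is the offset and
#'   `b` the scale).
#' @param n,r,p Gate counts (integers >= 1, vectorised).
#' @param c_daw Dimensionless exponent of the Dawood model.
#' @return Motion in mm, vectorised over the gate counts.
#' @examples
#' single_gate_motion(20, 2) # half the amplitude with two gates
#' dual_gate_motion(14.1, 3.8, r = 5, p = 4)
#' dawood_motion(0, 1, 1, r = 1) # e: nonzero even with a single gate
#' @export
single_gate_motion <- function(c, n) {
  c <- check_nonneg_scalar(c, "c")
  n <- check_gate_count(n, "n")
  c * (n - 1) / n
}

#' @rdname single_gate_motion
#' @export
dual_gate_motion <- function(a, b, r, p) {
  a <- check_nonneg_scalar(a, "a")
  b <- check_nonneg_scalar(b, "b")
  r <- check_gate_count(r, "r")
  p <- check_gate_count(p, "p")
  a * (r - 1) / r + b * (p - 1) / p
}

#' @rdname single_gate_motion
#' @export
dawood_motion <- function(a, b, c_daw, r) {
  r <- check_gate_count(r, "r")
  a + b * exp(c_daw / r)
}

new_motion_model_fit <- function(kind, coef, m_est, data, fitted) {
  structure(
    list(kind = kind, coef = coef, m_est = m_est,
         data = tibble::as_tibble(data), fitted = fitted),
    class = "motion_model_fit"
  )
}

clamp_motion_coef <- function(value, name) {
  if (value < 0) {
    rlang::warn(sprintf(
      "Fitted %s is negative (%.3f mm); clamped to 0 (motion amplitudes are physical lengths).",
      name, value))
    value <- 0
  }
  value
}

#' Fit gate-count motion models to measured motion
#'
#' Least-squares fits of the models in [single_gate_motion()] to motion
#' measured from gated images. The single-mode and dual models are linear in
#' their parameters, so closed-form (QR) least squares is used; the Dawood
#' model is fitted by Levenberg-Marquardt nonlinear least squares from the
#' fixed start `a = max(motion)`, `b = -a`, `c = -1` (at most 500 iterations).
#' Negative fitted amplitudes are clamped to zero with a warning.
#'
#' The asymptotic motion estimate `m_est` is the model limit for infinitely
#' many gates: `c` for the single model, `a + b` for the dual and Dawood
#' models.
#'
#' @param data For `fit_single_model()` and `fit_dawood_model()`, a data frame
#'   with columns `n` (gate count) and `motion_mm`; for `fit_dual_model()`,
#'   columns `n_resp`, `n_card` and `motion_mm`.
#' @param mode Which motion the single-mode fit describes (affects only the
#'   stored `kind`).
#' @return A `motion_model_fit` with elements `kind`, `coef` (named parameter
#'   vector), `m_est`, the input `data` and `fitted` values. Supports
#'   [generics::tidy()], [generics::glance()], [predict()] and
#'   [ggplot2::autoplot()].
#' @examples
#' fit_single_model(data.frame(n = 2:4, motion_mm = c(6, 8, 9)))
#' samples <- expand.grid(n_resp = 1:5, n_card = c(1, 4, 6))
#' samples$motion_mm <- dual_gate_motion(12, 10, samples$n_resp, samples$n_card)
#' fit_dual_model(samples)
#' @export
fit_single_model <- function(data, mode = c("respiratory", "cardiac")) {
  mode <- rlang::arg_match(mode)
  check_columns(data, c("n", "motion_mm"), "`data`")
  n <- check_gate_count(data$n, "data$n")
  y <- as.numeric(data$motion_mm)
  if (!any(n >= 2)) {
    abort_gateopt("At least one sample with n >= 2 is required to identify `c`.",
                  "gateopt_unidentifiable")
  }
  w <- (n - 1) / n
  c_hat <- sum(w * y) / sum(w^2)
  c_hat <- clamp_motion_coef(c_hat, "c")
  kind <- if (mode == "respiratory") "single_resp" else "single_card"
  new_motion_model_fit(kind, c(c = c_hat), m_est = c_hat,
                       data = data, fitted = c_hat * w)
}

#' @rdname fit_single_model
#' @export
fit_dual_model <- function(data) {
  check_columns(data, c("n_resp", "n_card", "motion_mm"), "`data`")
  r <- check_gate_count(data$n_resp, "data$n_resp")
  p <- check_gate_count(data$n_card, "data$n_card")
  y <- as.numeric(data$motion_mm)
  X <- cbind(resp = (r - 1) / r, card = (p - 1) / p)
  if (qr(X)$rank < 2) {
    abort_gateopt(
      "Design is rank deficient: need samples with n_resp >= 2 and with n_card >= 2.",
      "gateopt_unidentifiable"
    )
  }
  beta <- qr.solve(X, y)
  a_hat <- clamp_motion_coef(beta[["resp"]], "a")
  b_hat <- clamp_motion_coef(beta[["card"]], "b")
  new_motion_model_fit("dual", c(a = a_hat, b = b_hat), m_est = a_hat + b_hat,
                       data = data,
                       fitted = drop(X %*% c(a_hat, b_hat)))
}

#' @rdname fit_single_model
#' @export
fit_dawood_model <- function(data) {
  check_columns(data, c("n", "motion_mm"), "`data`")
  n <- check_gate_count(data$n, "data$n")
  y <- as.numeric(data$motion_mm)
  if (length(unique(n)) < 3) {
    abort_gateopt("At least 3 samples at distinct gate counts are required.",
                  "gateopt_unidentifiable")
  }
  df <- data.frame(n = n, y = y)
  a0 <- max(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a + b * exp(cdaw / n),
      data = df,
      start = list(a = a0, b = -a0, cdaw = -1),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      abort_gateopt(
        paste0("Dawood model fit failed to converge: ", conditionMessage(e)),
        "gateopt_fit_failure"
      )
    }
  )
  cf <- stats::coef(fit)
  new_motion_model_fit(
    "dawood",
    c(a = unname(cf["a"]), b = unname(cf["b"]), c_daw = unname(cf["cdaw"])),
    m_est = unname(cf["a"] + cf["b"]),
    data = data,
    fitted = stats::fitted(fit)
  )
}

#' @export
predict.motion_model_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(object$fitted)
  }
  cf <- object$coef
  switch(object$kind,
    single_resp = ,
    single_card = single_gate_motion(cf[["c"]], newdata$n),
    dual = dual_gate_motion(cf[["a"]], cf[["b"]], newdata$n_resp, newdata$n_card),
    dawood = dawood_motion(cf[["a"]], cf[["b"]], cf[["c_daw"]], newdata$n)
  )
}

#' @export
print.motion_model_fit <- function(x, ...) {
  cat(sprintf("<motion_model_fit> kind: %s\n", x$kind))
  cat("  coefficients:",
      paste(sprintf("%s = %.3f", names(x$coef), x$coef), collapse = ", "), "\n")
  cat(sprintf("  asymptotic motion m_est = %.3f mm (n = %d samples)\n",
              x$m_est, nrow(x$data)))
  invisible(x)
}

half_resolution_gate_count <- function(m, s) {
  # smallest n with m * (n - 1) / n >= m - s / 2; one gate when the whole
  # amplitude is already within half the scanner resolution
  if (m <= s / 2) {
    return(1L)
  }
  as.integer(ceiling(2 * m / s - 1e-9))
}

#' Optimal number of gates from a fitted motion model
#'
#' Inverts a fitted gate-count motion model at the target capture level
#' `m_est - s/2` (motion compensated to within half the scanner resolution
#' `s`) and takes the ceiling. For a single-mode fit this is
#' `ceiling(2 c / s)`; for a dual fit the rule is applied componentwise to the
#' respiratory amplitude `a` and cardiac amplitude `b`. Amplitudes not
#' exceeding `s/2` need no gating and yield 1 gate.
#'
#' @param fit A `motion_model_fit` of kind `single_resp`, `single_card` or
#'   `dual`.
#' @param scanner A [scanner_spec()] providing the resolution `s`.
#' @return An integer gate count for single-mode fits; a [gate_scheme()] for
#'   dual fits.
#' @examples
#' fit <- fit_single_model(data.frame(n = 2:6, motion_mm = single_gate_motion(14.1, 2:6)))
#' optimal_gates(fit, scanner_spec())
#' @export
optimal_gates <- function(fit, scanner = scanner_spec()) {
  stopifnot(inherits(fit, "motion_model_fit"), inherits(scanner, "scanner_spec"))
  s <- scanner$resolution_fwhm_mm
  switch(fit$kind,
    single_resp = ,
    single_card = half_resolution_gate_count(fit$coef[["c"]], s),
    dual = gate_scheme(
      half_resolution_gate_count(fit$coef[["a"]], s),
      half_resolution_gate_count(fit$coef[["b"]], s)
    ),
    abort_gateopt("`optimal_gates()` requires a single-mode or dual fit.",
                  "gateopt_input_error")
  )
}

#' Motion-minimisation threshold from component amplitudes
#'
#' The residual motion that gating should remove: each component amplitude
#' less half the scanner resolution (floored at zero), summed. With the
#' reference phantom amplitudes (14.1 mm respiratory, 3.8 mm cardiac) and a
#' 5.2 mm scanner this is 14.1 - 2.6 + 3.8 - 2.6 = 12.7 mm.
#'
#' @param m_r,m_p Respiratory and cardiac motion amplitudes in mm.
#' @param scanner A [scanner_spec()].
#' @return Threshold in mm.
#' @examples
#' threshold_from_motion(14.1, 3.8)
#' @export
threshold_from_motion <- function(m_r, m_p, scanner = scanner_spec()) {
  m_r <- check_nonneg_scalar(m_r, "m_r")
  m_p <- check_nonneg_scalar(m_p, "m_p")
  s <- scanner$resolution_fwhm_mm
  max(m_r - s / 2, 0) + max(m_p - s / 2, 0)
}

#' Mean absolute difference and root-mean-square error
#'
#' Agreement metrics between measured and model-estimated motion series:
#' `md()` is the mean absolute difference and `rmse()` the root-mean-square
#' error. `rmse(x, y) >= md(x, y)` always.
#'
#' @param x,y Numeric vectors of equal, nonzero length.
#' @return A single number.
#' @examples
#' md(c(0, 0), c(1, 3)) # 2
#' rmse(c(0, 0), c(1, 3)) # sqrt(5)
#' @export
md <- function(x, y) {
  check_paired_series(x, y)
  mean(abs(x - y))
}

#' @rdname md
#' @export
rmse <- function(x, y) {
  check_paired_series(x, y)
  sqrt(mean((x - y)^2))
}

check_paired_series <- function(x, y) {
  if (length(x) == 0 || length(x) != length(y) ||
      anyNA(x) || anyNA(y)) {
    abort_gateopt("`x` and `y` must be complete numeric vectors of equal, nonzero length.",
                  "gateopt_input_error")
  }
  invisible(NULL)
}

#' Split a total dual-gate count into respiratory and cardiac gates
#'
#' Given a total number of dual gates and a chosen respiratory gate count,
#' the cardiac count is the ceiling of their quotient, so the scheme provides
#' at least the requested total. The reference worked example resolves 20
#' total gates with 5 respiratory gates into a (5, 4) scheme.
#'
#' @param n_total Total number of dual gates (integer >= 1).
#' @param n_resp Number of respiratory gates (integer in `[1, n_total]`).
#' @return A [gate_scheme()].
#' @examples
#' resolve_gate_combination(20, 5)
#' @export
resolve_gate_combination <- function(n_total, n_resp) {
  n_total <- check_gate_count(n_total, "n_total")
  n_resp <- check_gate_count(n_resp, "n_resp")
  if (n_resp > n_total) {
    abort_gateopt("`n_resp` cannot exceed `n_total`.",
                  "gateopt_invalid_combination")
  }
  gate_scheme(n_resp, ceiling(n_total / n_resp))
}
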