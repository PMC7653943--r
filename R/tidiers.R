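#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted motion model
#'
#' @param x A `motion_model_fit`.
#' @param ... Unused.
#' @return One row per parameter with columns `term` and `estimate`.
#' @export
tidy.motion_model_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @rdname tidy.motion_model_fit
#' @export
glance.motion_model_fit <- function(x, ...) {
  obs <- x$data$motion_mm
  tibble::tibble(
    kind = x$kind,
    m_est = x$m_est,
    n_samples = nrow(x$data),
    rmse = rmse(obs, x$fitted),
    md = md(obs, x$fitted)
  )
}

#' @export
tidy.gate_count_line <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$slope, x$intercept))
}

#' @export
glance.gate_count_line <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, domain_min_mm = x$domain_min_mm)
}

#' @export
tidy.snr_curve_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @export
glance.snr_curve_fit <- function(x, ...) {
  tibble::tibble(rmse_db = x$rmse_db, n_points = nrow(x$data))
}

#' Plot a fitted motion model against its samples
#'
#' For single-mode and Dawood fits: measured motion versus gate count with
#' the fitted curve and the asymptote `m_est`. For dual fits: measured versus
#' fitted motion per scheme.
#'
#' @param object A `motion_model_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motion_model_fit <- function(object, ...) {
  if (object$kind == "dual") {
    df <- dplyr::mutate(object$data, fitted = object$fitted)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$motion_mm)) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
        ggplot2::geom_point() +
        ggplot2::labs(x = "Model total motion (mm)",
                      y = "Measured total motion (mm)",
                      title = sprintf("Dual model: a = %.1f, b = %.1f mm",
                                      object$coef[["a"]], object$coef[["b"]])) +
        ggplot2::theme_minimal()
    )
  }
  grid <- tibble::tibble(n = seq(1, max(object$data$n) + 2, by = 0.1))
  grid$motion_mm <- switch(object$kind,
    dawood = dawood_motion(object$coef[["a"]], object$coef[["b"]],
                           object$coef[["c_daw"]], pmax(1, round(grid$n))),
    single_gate_motion(object$coef[["c"]], 1) * 0 +
      object$coef[["c"]] * (grid$n - 1) / grid$n
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$n, y = .data$motion_mm)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$m_est, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Number of gates", y = "Motion (mm)",
                  title = sprintf("%s fit: m_est = %.1f mm",
                                  object$kind, object$m_est)) +
    ggplot2::theme_minimal()
}

#' Plot an SNR-versus-gates curve fit
#'
#' @param object An `snr_curve_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snr_curve_fit <- function(object, ...) {
  grid <- tibble::tibble(
    n_total = exp(seq(log(min(object$data$n_total)),
                      log(max(object$data$n_total)), length.out = 100))
  )
  grid$snr_db <- object$a + object$b * log10(grid$n_total)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$n_total, y = .data$snr_db)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Total number of gates", y = "SNR (dB)",
                  title = sprintf("SNR(n) = %.1f %+.1f log10(n) dB",
                                  object$a, object$b)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a gate grid
#'
#' Total measured motion as a function of respiratory and cardiac gate
#' counts, optionally marking cells reaching a capture threshold.
#'
#' @param object A [gate_grid()].
#' @param threshold_mm Optional threshold; cells at or above it are outlined.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gate_grid <- function(object, threshold_mm = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n_resp),
                                        y = factor(.data$n_card),
                                        fill = .data$motion_mm)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$motion_mm)),
                       colour = "white", size = 3) +
    ggplot2::labs(x = "Respiratory gates", y = "Cardiac gates",
                  fill = "Motion (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold_mm)) {
    hit <- dplyr::filter(df, .data$motion_mm >= threshold_mm - 1e-9)
    p <- p + ggplot2::geom_tile(data = hit, fill = NA, colour = "red",
                                linewidth = 0.8)
  }
  p
}
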