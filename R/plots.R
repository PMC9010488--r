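#' Plot a muscle-ROI CrCEST time series
#'
#' Baseline and post-exercise frames with, optionally, the fitted exponential
#' recovery overlaid.
#'
#' @param object A `crcest_roi_series`.
#' @param fit Optional `crcest_kinetics` fit to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot crcest_roi_series
#' @export
autoplot.crcest_roi_series <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$value_pct)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "Time after exercise (s)", y = "CrCEST (% asymmetry)",
                  title = object$muscle[1])
  if (!is.null(fit) && fit$status != "fit_failed") {
    tt <- seq(0, max(object$time_s), length.out = 200)
    curve <- tibble::tibble(
      time_s = tt,
      value_pct = fit$asymptote_pct + fit$amp_pct * exp(-tt / fit$tau_s))
    p <- p + ggplot2::geom_line(data = curve, colour = "firebrick") +
      ggplot2::labs(subtitle = sprintf("tauCr = %.0f s", fit$tau_s))
  }
  p
}

#' @describeIn fit_tau Plot the series with the fitted recovery curve.
#' @param object,... Fit object and unused arguments.
#' @method autoplot crcest_kinetics
#' @export
autoplot.crcest_kinetics <- function(object, ...) {
  autoplot(object$series, fit = object)
}

#' Plot one frame of an asymmetry map series
#'
#' @param object A `crcest_asym_series`.
#' @param frame Frame index to display.
#' @param ... Unused.
#' @return A ggplot raster of MTR_asym in %.
#' @method autoplot crcest_asym_series
#' @export
autoplot.crcest_asym_series <- function(object, frame = 1, ...) {
  d <- dim(object$maps)
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(object$maps[, , frame])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "MTR_asym (%)",
                  title = sprintf("t = %g s", object$frame_times_s[frame]))
}

#' Forest plot of model coefficients
#'
#' @param object A `crcest_model_result`.
#' @param ... Unused.
#' @return A ggplot of estimates with 95% CIs by term, faceted by model and
#'   muscle scope.
#' @method autoplot crcest_model_result
#' @export
autoplot.crcest_model_result <- function(object, ...) {
  df <- object[object$term != "(Intercept)", ]
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2) +
    ggplot2::facet_grid(muscle_scope ~ model) +
    ggplot2::labs(x = "Estimate (95% CI)", y = NULL)
}

#' @describeIn fit_mixed_model Model results are already tidy; returns the
#'   underlying tibble.
#' @param x,... Result object and unused arguments.
#' @method tidy crcest_model_result
#' @export
tidy.crcest_model_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @describeIn fit_mixed_model One-row model summary (outcome, n).
#' @method glance crcest_model_result
#' @export
glance.crcest_model_result <- function(x, ...) {
  dplyr::distinct(tibble::as_tibble(x),
                  .data$outcome, .data$model, .data$muscle_scope,
                  .data$n_subjects, .data$n_observations)
}
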