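#' Trimmed-mean gradient scatter along the posterior-anterior axis
#'
#' One point per ROI: the trimmed mean of the response across participants
#' against the ROI centroid Y coordinate, coloured by Z.
#'
#' @param cohort cohort tibble with `roi_id`, `y`, `z` and the response.
#' @param response response column.
#' @param trim_proportion trimmed-mean proportion per tail.
#' @return A ggplot.
#' @export
plot_pf_gradient <- function(cohort, response = "pf",
                             trim_proportion = 0.1) {
  roi_mean <- cohort |>
    dplyr::group_by(.data$roi_id, .data$y, .data$z) |>
    dplyr::summarise(value = trimmed_mean(.data[[response]],
                                          trim_proportion),
                     .groups = "drop")
  ggplot2::ggplot(roi_mean,
                  ggplot2::aes(x = .data$y, y = .data$value,
                               colour = .data$z)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::scale_colour_viridis_c(name = "Z (mm)") +
    ggplot2::labs(x = "Y, posterior → anterior (mm)",
                  y = paste("trimmed-mean", response)) +
    ggplot2::theme_minimal()
}

#' Spectrum with aperiodic fit and detected peaks
#'
#' Log-log power spectrum with the fitted 1/f line and markers at detected
#' peak frequencies.
#'
#' @param spectrum tibble (`frequency`, `power`).
#' @param fit optional [fit_aperiodic()] result.
#' @param peaks optional [detect_peaks()] result.
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum, fit = NULL, peaks = NULL) {
  sp <- dplyr::filter(spectrum, .data$frequency > 0, .data$power > 0)
  p <- ggplot2::ggplot(sp, ggplot2::aes(x = .data$frequency,
                                        y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power (au²/Hz)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    line <- tibble::tibble(frequency = fit$frequencies,
                           power = 10^(fit$offset +
                                         fit$slope * log10(fit$frequencies)))
    p <- p + ggplot2::geom_line(data = line, colour = "steelblue",
                                linetype = "dashed")
  }
  if (!is.null(peaks) && nrow(peaks) > 0) {
    pk <- tibble::tibble(frequency = peaks$frequency,
                         power = peaks$original_power)
    p <- p + ggplot2::geom_point(data = pk, colour = "firebrick", size = 2)
  }
  p
}

#' Pooled peak-frequency histogram with band boundaries
#'
#' @param peak_frequencies numeric vector of detected peak frequencies.
#' @param bands optional band tibble (`label`, `f_low`, `f_high`) whose
#'   boundaries are drawn.
#' @param bin_width histogram bin width, Hz.
#' @return A ggplot.
#' @export
plot_peak_histogram <- function(peak_frequencies, bands = NULL,
                                bin_width = 0.5) {
  df <- tibble::tibble(frequency = peak_frequencies[
    is.finite(peak_frequencies)])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency)) +
    ggplot2::geom_histogram(binwidth = bin_width, fill = "grey35") +
    ggplot2::labs(x = "peak frequency (Hz)", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(bands)) {
    edges <- sort(unique(c(bands$f_low, bands$f_high)))
    p <- p + ggplot2::geom_vline(xintercept = edges, colour = "firebrick",
                                 linetype = "dotted")
  }
  p
}

#' Coefficient plot for a mixed-model fit
#'
#' Fixed-effect estimates with confidence bounds, intercept excluded.
#'
#' @param object an `lmem_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lmem_fit <- function(object, ...) {
  tt <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(tt, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "estimate", y = NULL) +
    ggplot2::theme_minimal()
}
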