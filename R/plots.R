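# autoplot() methods for the package's result objects.

#' Plot a Welch spectrum
#'
#' @param object A `welch_spectrum`.
#' @param log Use log10 axes.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.welch_spectrum <- function(object, log = TRUE, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power spectral density")
  if (log) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Plot a spectral parameterization (data, aperiodic and full fit)
#'
#' @param object A `spectral_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectral_fit <- function(object, ...) {
  df <- tibble::tibble(freq = object$freqs,
                       data = object$log_power,
                       full = object$fitted,
                       aperiodic = object$aperiodic_fit)
  df <- tidyr::pivot_longer(df, -"freq", names_to = "component",
                            values_to = "log_power")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$log_power,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "log10 power")
}

#' Plot a coherogram
#'
#' @param object A `coherogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coherogram <- function(object, ...) {
  df <- tidyr::expand_grid(freq = object$freqs, time = object$times)
  df$coherence <- as.numeric(t(object$coherence))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$coherence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Time from event (s)", y = "Frequency (Hz)",
                  fill = "PLV")
}

#' Plot a phase-binned coupling profile
#'
#' @param object A `coupling_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coupling_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$phase, y = .data$magnitude)) +
    ggplot2::geom_col(width = 2 * pi / object$n_bins) +
    ggplot2::geom_vline(xintercept = object$preferred_phase,
                        linetype = "dashed") +
    ggplot2::labs(x = "Theta phase (rad)", y = "Normalised magnitude")
}

#' Plot a temporal response function
#'
#' @param object A `trf_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trf_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$lag, y = .data$weight,
                               colour = .data$feature)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Lag (s)", y = "Weight")
}

#' Plot a phase-locked average with its surrogate band
#'
#' @param object A `phase_locked_average`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phase_locked_average <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$phase)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$null_lo,
                                      ymax = .data$null_hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_vline(xintercept = seq(-8, 6, by = 2) * pi,
                        linetype = "dotted", colour = "grey50") +
    ggplot2::labs(x = "Unwrapped theta phase (rad)", y = object$signal)
}

#' Plot phase-resolved decoding accuracy
#'
#' @param object A `decoding_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decoding_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$null_lo,
                                      ymax = .data$null_hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$accuracy)) +
    ggplot2::geom_point(data = df[which(df$significant), ],
                        ggplot2::aes(y = .data$accuracy),
                        colour = "orange") +
    ggplot2::geom_hline(yintercept = object$chance, linetype = "dashed") +
    ggplot2::labs(x = "Warped theta phase (rad)", y = "Accuracy")
}
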