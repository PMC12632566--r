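# broom-style tidy()/glance() methods for the package's result objects.

#' Tidy a Welch spectrum
#'
#' @param x A `welch_spectrum`.
#' @param ... Unused.
#' @return Tibble with `freq` and `power`.
#' @export
tidy.welch_spectrum <- function(x, ...) {
  tibble::tibble(freq = x$freqs, power = x$power)
}

#' Tidy a spectral parameterization (one row per fitted peak)
#'
#' @param x A `spectral_fit`.
#' @param ... Unused.
#' @return Tibble with `center`, `height`, `width`.
#' @export
tidy.spectral_fit <- function(x, ...) x$peaks

#' One-row summary of a spectral parameterization
#'
#' @param x A `spectral_fit`.
#' @param ... Unused.
#' @return Tibble with offset, exponent, number of peaks, and R-squared.
#' @export
glance.spectral_fit <- function(x, ...) {
  tibble::tibble(aperiodic_offset = x$aperiodic_offset,
                 aperiodic_exponent = x$aperiodic_exponent,
                 n_peaks = nrow(x$peaks), r_squared = x$r_squared)
}

#' Tidy a coupling result (one row per phase bin)
#'
#' @param x A `coupling_result`.
#' @param ... Unused.
#' @return Tibble with `phase` (bin centre) and `magnitude` (normalised).
#' @export
tidy.coupling_result <- function(x, ...) {
  tibble::tibble(phase = x$bin_centers, magnitude = x$profile)
}

#' One-row summary of a coupling result
#'
#' @param x A `coupling_result`.
#' @param ... Unused.
#' @return Tibble with `mi`, `preferred_phase`, `p_value`, `n_surrogates`.
#' @export
glance.coupling_result <- function(x, ...) {
  tibble::tibble(mi = x$mi, preferred_phase = x$preferred_phase,
                 preferred_phase_deg = rad2deg(x$preferred_phase),
                 p_value = x$p_value, n_surrogates = x$n_surrogates)
}

#' Tidy a temporal response function model (long weights)
#'
#' @param x A `trf_model`.
#' @param ... Unused.
#' @return Tibble with `feature`, `lag`, `weight`.
#' @export
tidy.trf_model <- function(x, ...) {
  tibble::tibble(
    feature = rep(x$features, times = ncol(x$weights)),
    lag = rep(x$lags, each = nrow(x$weights)),
    weight = as.numeric(x$weights))
}

#' One-row summary of a temporal response function model
#'
#' @param x A `trf_model`.
#' @param ... Unused.
#' @return Tibble with `ridge_lambda`, `cv_r2`, `n_features`, `n_lags`.
#' @export
glance.trf_model <- function(x, ...) {
  tibble::tibble(ridge_lambda = x$ridge_lambda, cv_r2 = x$cv_r2,
                 n_features = nrow(x$weights), n_lags = ncol(x$weights))
}

#' Tidy a decoding result (one row per phase bin)
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return Tibble with bin centre, accuracy, null band, p and significance.
#' @export
tidy.decoding_result <- function(x, ...) {
  tibble::tibble(phase = x$bin_centers, accuracy = x$accuracy,
                 null_mean = x$null_mean, null_lo = x$null_lo,
                 null_hi = x$null_hi, p = x$p,
                 significant = x$significant)
}

#' Tidy a phase-locked average (one row per phase point)
#'
#' @param x A `phase_locked_average`.
#' @param ... Unused.
#' @return Tibble with phase, mean, and null band.
#' @export
tidy.phase_locked_average <- function(x, ...) {
  tibble::tibble(phase = x$phase_axis, mean = x$mean,
                 null_lo = x$null_lo, null_hi = x$null_hi,
                 null_mean = x$null_mean)
}

#' Tidy a periodicity result (the autocorrelation function)
#'
#' @param x A `periodicity_result`.
#' @param ... Unused.
#' @return Tibble with `lag_s` and `r`.
#' @export
tidy.periodicity_result <- function(x, ...) x$acf
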