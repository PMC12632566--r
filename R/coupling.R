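# Tort modulation-index coupling between a phase series and a magnitude
# series, with circular-shift surrogate inference and FDR control.

#' Tort modulation index
#'
#' Bins the phase series into `n_bins` equal bins over `[0, 2*pi)`, averages
#' the magnitude within each bin, normalises the profile to sum to one, and
#' returns the Kullback-Leibler divergence from uniformity divided by
#' `log(n_bins)` (so MI lies in `[0, 1]`).
#'
#' @param phase Phase per sample (radians, any wrapping).
#' @param magnitude Non-negative magnitude per sample.
#' @param n_bins Number of phase bins (default 24, i.e. 15-degree bins).
#' @return A `coupling_result` with `mi`, `profile`, `bin_centers`,
#'   `preferred_phase`, `n_bins`.
#' @export
tort_mi <- function(phase, magnitude, n_bins = 24) {
  if (length(phase) != length(magnitude))
    stopf("`phase` and `magnitude` must have equal length")
  if (any(magnitude < 0)) stopf("`magnitude` must be non-negative")
  bins <- bin_index(phase, n_bins)
  counts <- tabulate(bins, n_bins)
  if (any(counts == 0L))
    stopf("insufficient data: phase bin %d is empty",
          which(counts == 0L)[1])
  prof <- as.numeric(rowsum(magnitude, bins)[, 1]) / counts
  centers <- (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  structure(list(mi = mi_from_profile(prof),
                 profile = prof / sum(prof),
                 bin_centers = centers,
                 preferred_phase = if (sum(prof) > 0 &&
                                       circ_resultant(centers, prof) > 1e-12)
                   preferred_phase(prof, centers) else NA_real_,
                 n_bins = n_bins, p_value = NA_real_,
                 n_surrogates = 0L, surrogate_mi = numeric(0)),
            class = "coupling_result")
}

bin_index <- function(phase, n_bins) {
  b <- floor(wrap_2pi(phase) / (2 * pi) * n_bins) + 1L
  pmin(b, n_bins)
}

mi_from_profile <- function(prof) {
  p <- prof / sum(prof)
  nz <- p > 0
  kl <- sum(p[nz] * log(p[nz] * length(p)))
  kl / log(length(p))
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result> MI = %.4g", x$mi))
  if (!is.na(x$preferred_phase))
    cat(sprintf(", preferred phase = %.1f deg", rad2deg(x$preferred_phase)))
  if (!is.na(x$p_value))
    cat(sprintf(", p = %.4g (%d surrogates)", x$p_value, x$n_surrogates))
  cat("\n")
  invisible(x)
}

#' Circular-shift surrogate test for the modulation index
#'
#' Circularly shifts the phase series by amounts drawn uniformly outside
#' `+/- min_shift_s`, recomputes the MI for each surrogate, and returns the
#' add-one permutation p-value
#' `p = (1 + #\{surrogate MI >= observed\}) / (1 + n_surrogates)`.
#'
#' @param phase,magnitude As in [tort_mi()].
#' @param fs Sampling rate (Hz) of the series.
#' @param n_surrogates Number of circular shifts (>= 50).
#' @param min_shift_s Minimum shift magnitude (s), default 1.
#' @param n_bins Phase bins.
#' @param seed Integer seed.
#' @return A `coupling_result` with `p_value`, `n_surrogates`,
#'   `surrogate_mi` filled in.
#' @export
circular_shift_surrogates <- function(phase, magnitude, fs,
                                      n_surrogates = 200, min_shift_s = 1,
                                      n_bins = 24, seed = 1L) {
  n <- length(phase)
  if (n_surrogates < 50L) stopf("`n_surrogates` must be at least 50")
  if (min_shift_s >= n / fs / 2)
    stopf("`min_shift_s` must be below half the series duration")
  if (n < 4 * min_shift_s * fs)
    stopf("series shorter than 4 * `min_shift_s`")
  obs <- tort_mi(phase, magnitude, n_bins)
  min_k <- ceiling(min_shift_s * fs)
  bins <- bin_index(phase, n_bins)
  sur <- with_seed(seed, {
    shifts <- sample(seq(min_k, n - min_k), n_surrogates, replace = TRUE)
    vapply(shifts, function(k) {
      sb <- c(bins[(k + 1L):n], bins[1:k])
      counts <- tabulate(sb, n_bins)
      if (any(counts == 0L)) return(NA_real_)
      mi_from_profile(as.numeric(rowsum(magnitude, sb)[, 1]) / counts)
    }, numeric(1))
  })
  sur <- sur[!is.na(sur)]
  obs$p_value <- (1 + sum(sur >= obs$mi)) / (1 + length(sur))
  obs$n_surrogates <- length(sur)
  obs$surrogate_mi <- sur
  obs
}

#' Preferred phase of a binned magnitude profile
#'
#' Circular mean of the bin centres weighted by the profile, reported in
#' `[0, 2*pi)`.
#'
#' @param profile Per-bin non-negative magnitudes.
#' @param bin_centers Bin centre phases (radians); defaults to equal bins
#'   over `[0, 2*pi)`.
#' @return Preferred phase in radians.
#' @export
preferred_phase <- function(profile,
                            bin_centers = (seq_along(profile) - 0.5) *
                              2 * pi / length(profile)) {
  if (any(profile < 0)) stopf("`profile` must be non-negative")
  if (circ_resultant(bin_centers, profile) < 1e-12)
    stopf("preferred phase undefined for a uniform profile")
  wrap_2pi(circ_mean(bin_centers, profile))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q`.
#'
#' @param p_values Vector of p-values in `(0, 1]`.
#' @param q FDR level.
#' @return List with `significant` (logical) and `adjusted` p-values.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (!length(p_values))
    return(list(significant = logical(0), adjusted = numeric(0)))
  if (any(p_values <= 0 | p_values > 1)) stopf("p-values must lie in (0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  list(significant = adj <= q, adjusted = adj)
}

#' Phase-magnitude coupling with surrogate inference
#'
#' Convenience wrapper: computes the Tort MI, the preferred phase and the
#' circular-shift surrogate p-value in one call, optionally restricted to a
#' sample mask (shifts are applied before masking so surrogate phase series
#' keep their autocorrelation).
#'
#' @inheritParams circular_shift_surrogates
#' @param mask Optional logical vector selecting samples (e.g. speech).
#' @return A `coupling_result`.
#' @export
phase_coupling <- function(phase, magnitude, fs, mask = NULL,
                           n_surrogates = 200, min_shift_s = 1,
                           n_bins = 24, seed = 1L) {
  n <- length(phase)
  if (is.null(mask)) mask <- rep(TRUE, n)
  obs <- tort_mi(phase[mask], magnitude[mask], n_bins)
  min_k <- ceiling(min_shift_s * fs)
  if (n < 4 * min_shift_s * fs) stopf("series shorter than 4 * `min_shift_s`")
  sur <- with_seed(seed, {
    shifts <- sample(seq(min_k, n - min_k), n_surrogates, replace = TRUE)
    vapply(shifts, function(k) {
      ph <- c(phase[(k + 1L):n], phase[1:k])[mask]
      bins <- bin_index(ph, n_bins)
      counts <- tabulate(bins, n_bins)
      if (any(counts == 0L)) return(NA_real_)
      mi_from_profile(as.numeric(rowsum(magnitude[mask], bins)[, 1]) /
                        counts)
    }, numeric(1))
  })
  sur <- sur[!is.na(sur)]
  obs$p_value <- (1 + sum(sur >= obs$mi)) / (1 + length(sur))
  obs$n_surrogates <- length(sur)
  obs$surrogate_mi <- sur
  obs
}
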