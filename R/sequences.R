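# Relating each electrode's peri-AC activation latency to its theta phase:
# cross-correlogram latencies, circular-linear correlation, pairwise
# lag-phase correlation, and a state-space trajectory summary.

#' Cross-correlogram peak latency
#'
#' Lag (within `+/- max_lag_s`) maximising the normalised cross-correlation
#' between an electrode's lag-resolved activation profile and a reference
#' profile on the same lag grid. Ties are broken toward the smallest
#' absolute lag.
#'
#' @param profile,reference_profile Numeric vectors on a common lag grid.
#' @param dt Grid step (s).
#' @param max_lag_s Maximum latency searched (s), default 0.3.
#' @return Latency in seconds (positive = `profile` lags the reference).
#' @export
xcorr_latency <- function(profile, reference_profile, dt,
                          max_lag_s = 0.3) {
  if (length(profile) != length(reference_profile))
    stopf("profiles must share the lag grid")
  if (sd(profile) == 0 || sd(reference_profile) == 0)
    stopf("undefined latency for a flat profile")
  x <- profile - mean(profile)
  r <- reference_profile - mean(reference_profile)
  max_k <- min(round(max_lag_s / dt), length(x) - 2L)
  lags <- -max_k:max_k
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      a <- x[(1 + k):length(x)]
      b <- r[1:(length(r) - k)]
    } else {
      a <- x[1:(length(x) + k)]
      b <- r[(1 - k):length(r)]
    }
    if (sd(a) == 0 || sd(b) == 0) return(-Inf)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  best <- which(cc == max(cc))
  best <- best[which.min(abs(lags[best]))]
  lags[best] * dt
}

#' Circular-linear correlation
#'
#' Correlation between a circular variable and a linear one, computed as the
#' multiple correlation of the linear variable on `(cos(phi), sin(phi))`.
#' Significance is reported both by permutation and by the asymptotic
#' chi-squared (2 df) approximation for `n * rho^2`.
#'
#' @param phases Angles (radians).
#' @param latencies Linear values, same length.
#' @param n_perm Number of permutations (>= 1000 recommended).
#' @param seed Integer seed.
#' @return List with `rho`, `p_perm`, `p_asymptotic`, `n`.
#' @export
circ_linear_corr <- function(phases, latencies, n_perm = 1000, seed = 1L) {
  n <- length(phases)
  if (n < 6L) stopf("at least 6 observations are required")
  if (!all(is.finite(latencies))) stopf("latencies must be finite")
  if (var(latencies) == 0) stopf("zero latency variance")
  rho <- cl_rho(phases, latencies)
  p_asym <- stats::pchisq(n * rho^2, df = 2, lower.tail = FALSE)
  p_perm <- with_seed(seed, {
    cnt <- sum(vapply(seq_len(n_perm), function(i)
      cl_rho(phases, sample(latencies)) >= rho, logical(1)))
    (1 + cnt) / (1 + n_perm)
  })
  list(rho = rho, p_perm = p_perm, p_asymptotic = p_asym, n = n)
}

cl_rho <- function(phases, x) {
  rxc <- cor(x, cos(phases))
  rxs <- cor(x, sin(phases))
  rcs <- cor(cos(phases), sin(phases))
  sqrt(max(0, (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)))
}

#' Pairwise lag-difference versus phase-difference correlation
#'
#' Pearson correlation, over all unordered electrode pairs, between the
#' latency difference and the wrapped theta-phase difference. Because pairs
#' share electrodes, significance is assessed by permuting electrode phase
#' labels.
#'
#' @param table Tibble with columns `latency_s` and `phase_rad` (one row
#'   per electrode).
#' @param n_perm Number of electrode-label permutations.
#' @param seed Integer seed.
#' @return List with `r`, `p_value`, `n_electrodes`, `n_pairs`.
#' @export
pairwise_lag_phase_corr <- function(table, n_perm = 1000, seed = 1L) {
  n <- nrow(table)
  if (n < 3L) stopf("insufficient data: at least 3 electrodes required")
  lat <- table$latency_s
  ph <- table$phase_rad
  pair_r <- function(ph) {
    ij <- utils::combn(n, 2)
    dlat <- lat[ij[1, ]] - lat[ij[2, ]]
    dph <- wrap_pi(ph[ij[1, ]] - ph[ij[2, ]])
    cor(dlat, dph)
  }
  r <- pair_r(ph)
  p <- with_seed(seed, {
    cnt <- sum(vapply(seq_len(n_perm), function(i)
      abs(pair_r(sample(ph))) >= abs(r), logical(1)))
    (1 + cnt) / (1 + n_perm)
  })
  list(r = r, p_value = p, n_electrodes = n, n_pairs = n * (n - 1) / 2)
}

#' State-space trajectory of peri-AC activation
#'
#' Projects the electrode x lag activation profiles onto their first two
#' principal components (each lag is one point in electrode space) and, at
#' each lag, reports the circular mean theta phase of the most active
#' electrodes.
#'
#' @param profiles Electrode x lag matrix.
#' @param phases Theta phase per electrode (radians).
#' @param top_fraction Fraction of electrodes deemed "most active" per lag.
#' @return List with `trajectory` (tibble: lag index, pc1, pc2,
#'   mean_phase), `explained` (variance fractions), `n_top`.
#' @export
activation_state_space <- function(profiles, phases, top_fraction = 0.10) {
  profiles <- as.matrix(profiles)
  ne <- nrow(profiles)
  nl <- ncol(profiles)
  if (ne < 3L || nl < 3L) stopf("need at least 3 electrodes and 3 lags")
  pc <- prcomp(t(profiles), center = TRUE, scale. = FALSE)
  if (ncol(pc$x) < 2L)
    rlang::warn("profiles have rank < 2; second component is degenerate")
  n_top <- max(1L, round(top_fraction * ne))
  mean_ph <- vapply(seq_len(nl), function(l) {
    top <- order(abs(profiles[, l]), decreasing = TRUE)[seq_len(n_top)]
    circ_mean(phases[top])
  }, numeric(1))
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(trajectory = tibble::tibble(
         lag_index = seq_len(nl),
         pc1 = pc$x[, 1],
         pc2 = if (ncol(pc$x) >= 2L) pc$x[, 2] else rep(0, nl),
         mean_phase = mean_ph),
       explained = expl, n_top = n_top)
}

#' Latency-phase table for a set of electrodes
#'
#' Builds the per-electrode table relating peri-AC activation latency
#' (cross-correlogram peak against the grand-average profile) to theta
#' phase relative to a reference electrode.
#'
#' @param profiles Electrode x lag matrix of peri-AC activation.
#' @param dt Lag-grid step (s).
#' @param phases Theta phase per electrode (radians, relative to the
#'   reference site).
#' @param electrode Optional electrode names.
#' @param max_lag_s Latency search range (s).
#' @return Tibble: `electrode`, `latency_s`, `phase_rad`.
#' @export
latency_phase_table <- function(profiles, dt, phases, electrode = NULL,
                                max_lag_s = 0.3) {
  profiles <- as.matrix(profiles)
  if (is.null(electrode)) electrode <- sprintf("e%03d", seq_len(nrow(profiles)))
  grand <- colMeans(profiles)
  lat <- vapply(seq_len(nrow(profiles)), function(i)
    xcorr_latency(profiles[i, ], grand, dt, max_lag_s), numeric(1))
  tibble::tibble(electrode = electrode, latency_s = lat,
                 phase_rad = wrap_pi(phases))
}
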