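# Internal numerical helpers shared across modules.
#
# Phase convention used throughout the package: the instantaneous phase is
# the argument of the analytic signal, so phase 0 falls on the waveform
# positive peak and +/- pi on the trough.

stopf <- function(...) rlang::abort(sprintf(...))

#' Wrap angles
#'
#' `wrap_pi()` maps angles to `(-pi, pi]`; `wrap_2pi()` maps to `[0, 2*pi)`.
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector of wrapped angles.
#' @export
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' @rdname wrap_pi
#' @export
wrap_2pi <- function(x) x %% (2 * pi)

#' Circular mean and resultant length
#'
#' Weighted first trigonometric moment of a sample of angles.
#'
#' @param x Angles in radians.
#' @param w Optional non-negative weights.
#' @return `circ_mean()` returns the mean direction in `(-pi, pi]`;
#'   `circ_resultant()` the mean resultant length in `[0, 1]`.
#' @export
circ_mean <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  Arg(sum(w * exp(1i * x)) / sum(w))
}

#' @rdname circ_mean
#' @export
circ_resultant <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  Mod(sum(w * exp(1i * x)) / sum(w))
}

#' Signed circular distance
#'
#' Shortest signed angular difference `a - b`, wrapped to `(-pi, pi]`.
#'
#' @param a,b Angles in radians.
#' @return Numeric vector of differences in radians.
#' @export
circ_dist <- function(a, b) wrap_pi(a - b)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Analytic signal via the frequency domain
#'
#' Computes the discrete analytic signal (Hilbert-transform based) whose real
#' part equals the input and whose argument is the instantaneous phase.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 4L) stopf("analytic_signal() needs at least 4 samples")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Zero-phase band-pass by frequency-domain windowing with raised-cosine
# transitions; group delay is identically zero.
fft_bandpass <- function(x, fs, band, transition = 1) {
  n <- length(x)
  # detrend so the periodic-extension step does not leak into the band
  idx <- seq_len(n)
  slope <- (x[n] - x[1]) / (n - 1)
  x <- x - (x[1] + slope * (idx - 1))
  f <- seq(0, fs - fs / n, length.out = n)
  f <- pmin(f, fs - f) # two-sided -> folded frequency magnitude
  H <- raised_cosine_response(f, band, transition)
  Re(fft(fft(x) * H, inverse = TRUE) / n)
}

raised_cosine_response <- function(f, band, transition) {
  lo <- band[1]
  hi <- band[2]
  H <- numeric(length(f))
  inb <- f >= lo & f <= hi
  H[inb] <- 1
  rise <- f < lo & f > lo - transition
  H[rise] <- 0.5 * (1 + cos(pi * (lo - f[rise]) / transition))
  fall <- f > hi & f < hi + transition
  H[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / transition))
  if (lo <= transition) H[f <= max(lo, 0)] <- ifelse(lo <= 0, 1, H[f <= lo])
  H
}

fft_lowpass <- function(x, fs, cutoff, transition = 2) {
  n <- length(x)
  # remove the linear trend first: FFT filtering assumes periodicity, and
  # the wrap-around step of a drifting series leaks across all frequencies
  idx <- seq_len(n)
  slope <- (x[n] - x[1]) / (n - 1)
  trend <- x[1] + slope * (idx - 1)
  xd <- x - trend
  f <- seq(0, fs - fs / n, length.out = n)
  f <- pmin(f, fs - f)
  H <- numeric(n)
  H[f <= cutoff] <- 1
  fall <- f > cutoff & f < cutoff + transition
  H[fall] <- 0.5 * (1 + cos(pi * (f[fall] - cutoff) / transition))
  Re(fft(fft(xd) * H, inverse = TRUE) / n) + trend
}

# Gaussian smoothing kernel applied by convolution (edges renormalised).
gauss_smooth <- function(x, fs, sigma_s) {
  if (sigma_s <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_s * fs))
  t <- (-half:half) / fs
  k <- exp(-t^2 / (2 * sigma_s^2))
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  stats::filter(xp, k, sides = 2)[(half + 1L):(half + n)]
}

# Morlet wavelet transform at one frequency; returns complex coefficients.
morlet_transform <- function(x, fs, freq, n_cycles = 6) {
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(4 * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sigma_t^2))
  w <- w / sqrt(sum(Mod(w)^2)) # unit-energy normalisation
  conv_same(x, w)
}

# Linear convolution trimmed to the length/alignment of x (FFT-based).
conv_same <- function(x, k) {
  n <- length(x)
  m <- length(k)
  L <- nextn(n + m - 1L, 2L)
  X <- fft(c(x, rep(0, L - n)))
  K <- fft(c(k, rep(0, L - m)))
  full <- fft(X * K, inverse = TRUE) / L
  off <- (m - 1L) %/% 2L
  full[(off + 1L):(off + n)]
}

# Unwrap a phase series (radians).
unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

# Local maxima indices of a numeric vector (strict on the left, >= right).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

# Peak picking with threshold and minimum separation (greedy by height).
find_peaks <- function(x, min_height = -Inf, min_sep = 1L) {
  idx <- local_maxima(x)
  idx <- idx[x[idx] >= min_height]
  if (length(idx) == 0L) return(integer(0))
  ord <- idx[order(x[idx], decreasing = TRUE)]
  keep <- integer(0)
  for (i in ord) {
    if (all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

# Seeded RNG evaluation that restores the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a finite numeric scalar", name)
  if (positive && x <= 0) stopf("`%s` must be positive", name)
  invisible(x)
}

check_proportion <- function(x, name) {
  check_scalar(x, name)
  if (x < 0 || x > 1) stopf("`%s` must lie in [0, 1]", name)
  invisible(x)
}
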