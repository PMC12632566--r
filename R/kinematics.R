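# Articulatory Change statistic, pulse/interval analysis, and lagged ridge
# (mTRF) encoding models with unique-variance attribution.

#' Articulatory Change (AC)
#'
#' The sum of squared velocities (total squared speed) across tract
#' variables: trajectories are low-passed, differentiated by central
#' differences, squared, summed across variables, then smoothed with a
#' Gaussian kernel.
#'
#' @param kin A [tract_kinematics()] object or a samples x variables matrix.
#' @param fs Sampling rate (Hz); taken from `kin` when available.
#' @param smooth_ms Gaussian smoothing sigma (ms), default 15.
#' @param lowpass_hz Trajectory low-pass cutoff (Hz), default 20; `Inf`
#'   disables it.
#' @return Non-negative numeric AC series with attribute `fs`.
#' @export
articulatory_change <- function(kin, fs = NULL, smooth_ms = 15,
                                lowpass_hz = 20) {
  if (inherits(kin, "tract_kinematics")) {
    fs <- kin$fs
    mat <- kin$data
  } else {
    mat <- as.matrix(kin)
    if (is.null(fs)) stopf("`fs` is required for matrix input")
  }
  n <- nrow(mat)
  if (n < 3L) stopf("at least 3 samples are required")
  if (ncol(mat) < 1L) stopf("at least one tract variable is required")
  ac <- numeric(n)
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    if (is.finite(lowpass_hz) && lowpass_hz < fs / 2)
      x <- fft_lowpass(x, fs, lowpass_hz, transition = lowpass_hz / 2)
    v <- numeric(n)
    v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
    v[1] <- v[2]
    v[n] <- v[n - 1L]
    ac <- ac + v^2
  }
  if (smooth_ms > 0) ac <- gauss_smooth(ac, fs, smooth_ms / 1000)
  ac <- pmax(ac, 0)
  attr(ac, "fs") <- fs
  ac
}

#' AC pulse and inter-peak-interval analysis
#'
#' Detects local AC maxima above a threshold (default: the within-utterance
#' median of AC) with a minimum separation, restricted to utterance spans,
#' and summarises inter-peak intervals and per-utterance pulse rates.
#'
#' @param ac AC series (from [articulatory_change()]).
#' @param fs Sampling rate (Hz); taken from `ac`'s attribute if `NULL`.
#' @param utterances Event table (rows with `tier == "utterance"`), or a
#'   tibble with `onset_s`/`offset_s` columns.
#' @param threshold Absolute pulse threshold; `NULL` for the
#'   within-utterance median.
#' @param min_sep_s Minimum peak separation (s), default 0.06.
#' @return List with `pulse_times`, `ipi` (s), `rates` tibble
#'   (utterance_id, n_pulses, duration_s, rate), `median_rate` (pulses/s),
#'   `threshold`.
#' @export
ac_pulse_analysis <- function(ac, fs = NULL, utterances,
                              threshold = NULL, min_sep_s = 0.06) {
  if (is.null(fs)) fs <- attr(ac, "fs")
  if (is.null(fs)) stopf("`fs` is required")
  if (any(ac < 0)) stopf("`ac` must be non-negative")
  if ("tier" %in% names(utterances))
    utterances <- utterances[utterances$tier == "utterance", ]
  if (nrow(utterances) == 0L) stopf("`utterances` must be non-empty")
  n <- length(ac)
  inmask <- logical(n)
  for (i in seq_len(nrow(utterances))) {
    a <- max(1L, floor(utterances$onset_s[i] * fs) + 1L)
    b <- min(n, ceiling(utterances$offset_s[i] * fs))
    inmask[a:b] <- TRUE
  }
  if (is.null(threshold)) {
    # scale-free default: during speech the AC alternates between pulse
    # peaks and valleys, so the within-utterance median separates them
    threshold <- median(ac[inmask])
  }
  idx <- find_peaks(as.numeric(ac), min_height = threshold,
                    min_sep = max(1L, round(min_sep_s * fs)))
  idx <- idx[inmask[idx]]
  times <- (idx - 1L) / fs
  rates <- purrr::map_dfr(seq_len(nrow(utterances)), function(i) {
    dur <- utterances$offset_s[i] - utterances$onset_s[i]
    np <- sum(times >= utterances$onset_s[i] & times <= utterances$offset_s[i])
    uid <- if ("utterance_id" %in% names(utterances))
      utterances$utterance_id[i] else i
    tibble::tibble(utterance_id = uid, n_pulses = np, duration_s = dur,
                   rate = np / dur)
  })
  ipi <- unlist(lapply(seq_len(nrow(utterances)), function(i) {
    tu <- times[times >= utterances$onset_s[i] &
                  times <= utterances$offset_s[i]]
    diff(tu)
  }))
  list(pulse_times = times, ipi = ipi, rates = rates,
       median_rate = median(rates$rate), threshold = threshold)
}

# Lag-expanded design matrix: column (j, l) holds feature j delayed by
# lag_samples[l] (positive lag = feature leads the target).
lag_design <- function(features, lag_samples) {
  n <- nrow(features)
  p <- ncol(features)
  X <- matrix(0, n, p * length(lag_samples))
  for (l in seq_along(lag_samples)) {
    k <- lag_samples[l]
    src <- seq_len(n) - k
    ok <- src >= 1L & src <= n
    X[ok, (l - 1L) * p + seq_len(p)] <- features[src[ok], , drop = FALSE]
  }
  X
}

ridge_solve <- function(X, y, lambda) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  A <- crossprod(Xc)
  diag(A) <- diag(A) + lambda
  w <- solve(A, crossprod(Xc, y - ym))
  list(w = w, intercept = ym - sum(xm * w))
}

blocked_folds <- function(n, k) {
  cut(seq_len(n), breaks = k, labels = FALSE)
}

#' Multivariate temporal response function (mTRF) by ridge regression
#'
#' Time-lagged ridge regression of a target series on one or more feature
#' series (impulse trains or continuous), with the ridge penalty chosen by
#' blocked cross-validated R-squared.
#'
#' @param features Samples x features matrix (or vector / data frame).
#' @param target Numeric target series, equal length.
#' @param fs Sampling rate (Hz).
#' @param lags Lag range (s pair), default `c(-0.6, 0.6)`; positive lags
#'   mean the feature precedes the target.
#' @param lambda Ridge penalty grid, default `10^(-2:6)`.
#' @param cv_folds Number of contiguous (blocked) folds, >= 2.
#' @param seed Integer seed (kept for interface stability; folds are
#'   deterministic blocks).
#' @return A `trf_model`: `lags` (s), `weights` (feature x lag),
#'   `intercept`, `ridge_lambda`, `cv_r2`, `cv_table`, `features`.
#' @export
fit_mtrf <- function(features, target, fs, lags = c(-0.6, 0.6),
                     lambda = 10^(-2:6), cv_folds = 5, seed = 1L) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (nrow(features) != length(target))
    stopf("`features` and `target` must have equal length")
  if (cv_folds < 2L) stopf("`cv_folds` must be at least 2")
  lag_samples <- seq(round(lags[1] * fs), round(lags[2] * fs))
  X <- lag_design(features, lag_samples)
  y <- as.numeric(target)
  folds <- blocked_folds(length(y), cv_folds)
  cv <- vapply(lambda, function(lam) {
    r2 <- vapply(seq_len(cv_folds), function(k) {
      tr <- folds != k
      fit <- tryCatch(ridge_solve(X[tr, , drop = FALSE], y[tr], lam),
                      error = function(e) NULL)
      if (is.null(fit)) return(-Inf)
      pred <- X[!tr, , drop = FALSE] %*% fit$w + fit$intercept
      1 - sum((y[!tr] - pred)^2) / sum((y[!tr] - mean(y[tr]))^2)
    }, numeric(1))
    mean(r2)
  }, numeric(1))
  if (all(!is.finite(cv)))
    stopf("ridge fit failed for every lambda; try lambda > 0")
  best <- which.max(cv)
  fit <- tryCatch(ridge_solve(X, y, lambda[best]), error = function(e)
    stopf("rank-deficient design with lambda = %g; use lambda > 0",
          lambda[best]))
  W <- matrix(fit$w, ncol(features), length(lag_samples))
  rownames(W) <- colnames(features)
  structure(list(lags = lag_samples / fs, weights = W,
                 intercept = fit$intercept,
                 ridge_lambda = lambda[best], cv_r2 = cv[best],
                 cv_table = tibble::tibble(lambda = lambda, cv_r2 = cv),
                 features = colnames(features), fs = fs,
                 lag_range = lags, cv_folds = cv_folds),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf(
    "<trf_model> %d features x %d lags (%g..%g s), lambda = %g, cv R^2 = %.3f\n",
    nrow(x$weights), ncol(x$weights), x$lag_range[1], x$lag_range[2],
    x$ridge_lambda, x$cv_r2))
  invisible(x)
}

#' @export
predict.trf_model <- function(object, features, ...) {
  features <- as.matrix(features)
  lag_samples <- round(object$lags * object$fs)
  X <- lag_design(features, lag_samples)
  # lag_design columns are lag-major (features within lag), matching the
  # column-major layout of the feature x lag weight matrix
  as.numeric(X %*% as.numeric(object$weights) + object$intercept)
}

#' Unique variance explained by one feature
#'
#' Cross-validated R-squared of the full model minus that of the model with
#' the feature removed, using the same blocked folds and lambda-selection
#' protocol.
#'
#' @inheritParams fit_mtrf
#' @param feature Name or index of the feature to ablate.
#' @return List with `delta_r2`, `full` and `reduced` `trf_model`s.
#' @export
unique_variance <- function(features, target, fs, feature,
                            lags = c(-0.6, 0.6), lambda = 10^(-2:6),
                            cv_folds = 5, seed = 1L) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (is.character(feature)) feature <- match(feature, colnames(features))
  if (is.na(feature) || feature < 1 || feature > ncol(features))
    stopf("`feature` not found in the design")
  if (ncol(features) < 2L)
    stopf("removing the feature would empty the design")
  full <- fit_mtrf(features, target, fs, lags, lambda, cv_folds, seed)
  reduced <- fit_mtrf(features[, -feature, drop = FALSE], target, fs,
                      lags, lambda, cv_folds, seed)
  list(delta_r2 = full$cv_r2 - reduced$cv_r2, full = full,
       reduced = reduced)
}

#' Lag-resolved response profile of one feature
#'
#' Returns the weight-versus-lag curve of a fitted feature with its peak
#' lags annotated (local maxima above `peak_frac` of the curve maximum).
#'
#' @param model A `trf_model`.
#' @param feature Feature name or index.
#' @param peak_frac Fraction of the maximum weight a local maximum must
#'   exceed to count as a peak.
#' @return Tibble (`lag`, `weight`) with attribute `peaks` (lag values).
#' @export
trf_response_profile <- function(model, feature, peak_frac = 0.35) {
  stopifnot(inherits(model, "trf_model"))
  if (is.character(feature)) feature <- match(feature, model$features)
  if (is.na(feature) || feature < 1 || feature > nrow(model$weights))
    stopf("unknown feature")
  w <- model$weights[feature, ]
  out <- tibble::tibble(lag = model$lags, weight = as.numeric(w))
  if (max(w) > 0) {
    idx <- find_peaks(as.numeric(w), min_height = peak_frac * max(w),
                      min_sep = 2L)
    attr(out, "peaks") <- model$lags[idx]
  } else attr(out, "peaks") <- numeric(0)
  out
}

#' Peri-event average of a series
#'
#' Averages a sampled series in a lag window around a set of event times,
#' e.g. the articulatory-change profile around vowel nuclei, or predicted
#' AC around phoneme onsets.
#'
#' @param series Numeric series.
#' @param fs Sampling rate (Hz).
#' @param times Event times (s).
#' @param window Lag window (s pair).
#' @param dt Lag step (s), default one sample.
#' @return Tibble with `lag` and `mean`.
#' @export
peri_event_profile <- function(series, fs, times, window = c(-0.45, 0.45),
                               dt = 1 / fs) {
  lags <- seq(window[1], window[2], by = dt)
  n <- length(series)
  mean_at <- vapply(lags, function(lg) {
    idx <- round((times + lg) * fs) + 1L
    mean(series[idx[idx >= 1L & idx <= n]])
  }, numeric(1))
  tibble::tibble(lag = lags, mean = mean_at)
}

#' Phoneme impulse-train design from an event table
#'
#' Builds consonant / vowel onset impulse trains on the kinematic grid, for
#' the phoneme-to-AC encoding model.
#'
#' @param events Event table with a `phoneme` tier labelled `"C:..."` /
#'   `"V:..."`.
#' @param fs Sampling rate (Hz).
#' @param n Number of samples.
#' @return Samples x 2 matrix with columns `consonant`, `vowel`.
#' @export
phoneme_design <- function(events, fs, n) {
  ph <- events[events$tier == "phoneme", ]
  X <- matrix(0, n, 2, dimnames = list(NULL, c("consonant", "vowel")))
  for (i in seq_len(nrow(ph))) {
    s <- round(ph$onset_s[i] * fs) + 1L
    if (s < 1L || s > n) next
    j <- if (startsWith(ph$label[i], "V")) 2L else 1L
    X[s, j] <- X[s, j] + 1
  }
  X
}
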