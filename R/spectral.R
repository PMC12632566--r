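# Spectral characterisation: Welch power spectra, 1/f-corrected peak
# detection, parametric aperiodic+peak decomposition, and peri-event
# wavelet spectrograms with relative / baseline normalisation.

#' Event-locked Welch power spectral density
#'
#' Averaged modified-periodogram (Hann taper, 50% overlap) estimate over
#' event-locked epochs, or over the whole signal when `events` is `NULL`.
#' Default 2-s segments give 0.5 Hz resolution. The one-sided density is
#' scaled so that its integral equals the signal variance.
#'
#' @param signal Numeric waveform.
#' @param fs Sampling rate (Hz).
#' @param events `NULL`, a numeric vector of event times (s), or an event
#'   table whose `utterance` onsets are used.
#' @param window Two-element window (s) relative to each event, default
#'   `c(-1, 5)`.
#' @param segment_s Welch segment length (s).
#' @param overlap Segment overlap fraction.
#' @return A `welch_spectrum` with fields `freqs`, `power`, `n_segments`,
#'   `window_s`.
#' @export
welch_psd <- function(signal, fs, events = NULL, window = c(-1, 5),
                      segment_s = 2, overlap = 0.5) {
  check_scalar(fs, "fs", positive = TRUE)
  if (is.data.frame(events))
    events <- events$onset_s[events$tier == "utterance"]
  seg_n <- round(segment_s * fs)
  if (is.null(events)) {
    epochs <- list(signal)
  } else {
    if (length(events) < 1L) stopf("at least one event is required")
    if (diff(window) * fs < seg_n)
      stopf("`window` is shorter than one Welch segment")
    n <- length(signal)
    epochs <- list()
    for (tt in events) {
      a <- round((tt + window[1]) * fs) + 1L
      b <- round((tt + window[2]) * fs)
      if (a >= 1L && b <= n) epochs[[length(epochs) + 1L]] <- signal[a:b]
    }
    if (!length(epochs)) stopf("no event window lies inside the recording")
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_n) / (seg_n + 1)) # Hann
  step <- max(1L, round(seg_n * (1 - overlap)))
  acc <- NULL
  n_seg <- 0L
  for (ep in epochs) {
    if (length(ep) < seg_n) next
    starts <- seq(1L, length(ep) - seg_n + 1L, by = step)
    for (s in starts) {
      x <- ep[s:(s + seg_n - 1L)]
      X <- fft((x - mean(x)) * w)
      half <- floor(seg_n / 2)
      p <- (Mod(X)^2 / (fs * sum(w^2)))[1:(half + 1L)]
      p[2:(half + ifelse(seg_n %% 2L == 0L, 0L, 1L))] <-
        2 * p[2:(half + ifelse(seg_n %% 2L == 0L, 0L, 1L))]
      acc <- if (is.null(acc)) p else acc + p
      n_seg <- n_seg + 1L
    }
  }
  if (n_seg == 0L) stopf("no complete Welch segment available")
  freqs <- (0:(length(acc) - 1L)) * fs / seg_n
  structure(list(freqs = freqs, power = acc / n_seg, n_segments = n_seg,
                 window_s = segment_s),
            class = "welch_spectrum")
}

#' @export
print.welch_spectrum <- function(x, ...) {
  cat(sprintf("<welch_spectrum> %d bins, df = %g Hz, %d segments\n",
              length(x$freqs), diff(x$freqs[1:2]), x$n_segments))
  invisible(x)
}

# Robust log-log linear aperiodic fit; returns intercept/slope of
# log10 power ~ log10 f, down-weighting peak bins.
aperiodic_linfit <- function(freqs, power) {
  keep <- freqs > 0 & power > 0
  lf <- log10(freqs[keep])
  lp <- log10(power[keep])
  flat <- rep(TRUE, length(lf))
  fit <- lm(lp ~ lf)
  # iteratively trim bins sitting on peaks (strong positive outliers only,
  # so the line is not biased low on peak-free spectra)
  for (i in 1:4) {
    fit <- lm(lp[flat] ~ lf[flat])
    r <- lp - (coef(fit)[1] + coef(fit)[2] * lf)
    new_flat <- r <= 2.5 * sd(r[flat])
    if (identical(new_flat, flat)) break
    flat <- new_flat
  }
  # sanity fallback: an implausible slope means the "background" being
  # tracked is a spectral peak's skirt (e.g. a near-line spectrum with no
  # real 1/f component); fit the floor bins instead
  if (-coef(fit)[2] < -1 || -coef(fit)[2] > 5) {
    floor_bins <- lp <= quantile(lp, 0.25)
    fit <- lm(lp[floor_bins] ~ lf[floor_bins])
  }
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       keep = keep)
}

#' Detect a 1/f-corrected spectral peak
#'
#' Removes a log-log linear aperiodic trend, z-scores the residual over the
#' fit range, and returns the highest local maximum inside `band` if its
#' prominence exceeds `z_threshold` standard deviations (default 3), else
#' `NULL`.
#'
#' @param spectrum A `welch_spectrum`.
#' @param band Frequency band (Hz pair) to search.
#' @param fit_range Range (Hz) over which the aperiodic trend and residual
#'   SD are estimated.
#' @param z_threshold Prominence threshold in residual SDs.
#' @return `NULL`, or a list with `freq`, `z`, `power`.
#' @export
detect_spectral_peak <- function(spectrum, band, fit_range = c(3, 30),
                                 z_threshold = 3) {
  stopifnot(inherits(spectrum, "welch_spectrum"))
  f <- spectrum$freqs
  in_fit <- f >= fit_range[1] & f <= fit_range[2] & spectrum$power > 0
  if (sum(f >= band[1] & f <= band[2]) < 5L)
    stopf("`band` spans fewer than 5 frequency bins")
  ap <- aperiodic_linfit(f[in_fit], spectrum$power[in_fit])
  resid <- log10(spectrum$power[in_fit]) -
    (ap$intercept + ap$slope * log10(f[in_fit]))
  z <- (resid - mean(resid)) / sd(resid)
  fv <- f[in_fit]
  cand <- local_maxima(z)
  cand <- cand[fv[cand] >= band[1] & fv[cand] <= band[2]]
  cand <- cand[z[cand] > z_threshold]
  if (!length(cand)) return(NULL)
  best <- cand[which.max(z[cand])]
  list(freq = fv[best], z = z[best],
       power = spectrum$power[in_fit][best])
}

gauss_peak <- function(f, center, height, width)
  height * exp(-(f - center)^2 / (2 * width^2))

#' Parametric aperiodic + periodic spectral decomposition
#'
#' Models `log10(power)` as an aperiodic component `offset - exponent *
#' log10(f)` plus Gaussian peaks. The aperiodic line is fitted robustly
#' (iterative trimming of peak bins); peaks are then extracted largest
#' first from the 1/f-corrected log residual, until `max_peaks` or until
#' the residual maximum drops below `peak_threshold` residual SDs. Each
#' peak's centre and width are measured as background-subtracted moments
#' in linear power, where an oscillatory component is an additive
#' symmetric bump (a log-space Gaussian fit is skewed wherever the peak
#' meets the sloping background); the height is the log-residual at the
#' peak.
#'
#' @param spectrum A `welch_spectrum`.
#' @param fit_range Frequency range (Hz) of the fit, default 3-30 Hz.
#' @param max_peaks Maximum number of Gaussian peaks (default 4).
#' @param peak_threshold Residual threshold (SD units) for accepting a peak.
#' @param min_peak_height Minimum peak height (log10-power units).
#' @param knee Use a knee-parameterised aperiodic model.
#' @return A `spectral_fit` with `aperiodic_offset`, `aperiodic_exponent`,
#'   `peaks` (tibble: center, height, width), `fit_range`, `r_squared`.
#' @export
parameterize_spectrum <- function(spectrum, fit_range = c(3, 30),
                                  max_peaks = 4, peak_threshold = 2,
                                  min_peak_height = 0.1, knee = FALSE) {
  stopifnot(inherits(spectrum, "welch_spectrum"))
  sel <- spectrum$freqs >= fit_range[1] & spectrum$freqs <= fit_range[2]
  f <- spectrum$freqs[sel]
  p <- spectrum$power[sel]
  if (any(p <= 0)) stopf("power must be positive over `fit_range`")
  lp <- log10(p)
  min_w <- diff(f[1:2])
  ap_fun <- function(par, f) {
    if (knee) par[1] - log10(pmax(par[3], 0) + f^par[2])
    else par[1] - par[2] * log10(f)
  }
  fit_aperiodic <- function(target) {
    ap <- aperiodic_linfit(f, 10^target)
    par0 <- c(offset = ap$intercept, exponent = -ap$slope,
              if (knee) c(knee = 0))
    if (!knee) return(par0)
    opt <- optim(par0, function(par) sum((target - ap_fun(par, f))^2),
                 method = "Nelder-Mead", control = list(maxit = 1000))
    opt$par
  }
  # Peaks are detected on the 1/f-corrected log residual, but their centre
  # and width are measured by background-subtracted moments in *linear*
  # power, where an oscillatory component is an additive, symmetric bump:
  # log-space Gaussian fits are skewed wherever the peak meets the sloping
  # background, whereas linear-power moments are not.
  extract_peaks <- function(resid) {
    peaks <- list()
    for (i in seq_len(max_peaks)) {
      # detect on a lightly smoothed residual so single-bin sampling
      # fluctuations of the periodogram do not register as peaks
      sm <- stats::filter(resid, rep(1 / 3, 3), sides = 2)
      sm[is.na(sm)] <- resid[is.na(sm)]
      if (max(sm) < max(peak_threshold * sd(sm), min_peak_height)) break
      ctr_i <- which.max(sm)
      hgt <- resid[ctr_i]
      if (hgt <= min_peak_height) break
      # half-height run of the log residual delimits the peak region
      above <- resid >= 0.5 * hgt
      lo <- ctr_i
      while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
      hi <- ctr_i
      while (hi < length(resid) && above[hi + 1L]) hi <- hi + 1L
      pad <- max(2L, hi - lo)
      win <- max(1L, lo - pad):min(length(f), hi + pad)
      # local linear background in power space through the window edges
      e1 <- win[1:min(2L, length(win))]
      e2 <- win[max(1L, length(win) - 1L):length(win)]
      f1 <- mean(f[e1]); f2 <- mean(f[e2])
      q1 <- mean(p[e1]); q2 <- mean(p[e2])
      bg <- q1 + (q2 - q1) * (f[win] - f1) / max(f2 - f1, min_w)
      d <- pmax(p[win] - bg, 0)
      if (sum(d) <= 0) break
      ctr <- sum(f[win] * d) / sum(d)
      wdt <- sqrt(sum((f[win] - ctr)^2 * d) / sum(d))
      wdt <- min(max(wdt, min_w / 2), f[length(f)] - f[1])
      # always deflate the residual so the loop advances; keep the peak
      # only if it is not an edge artefact of the fit range
      resid <- resid - gauss_peak(f, ctr, hgt, wdt)
      if (ctr > fit_range[1] + min_w && ctr < fit_range[2] - min_w)
        peaks[[length(peaks) + 1L]] <- c(ctr, hgt, wdt)
    }
    # overlap guard: Gaussians closer than their combined widths are one
    # peak; keep the taller
    if (length(peaks) > 1L) {
      ord <- order(vapply(peaks, `[`, numeric(1), 2), decreasing = TRUE)
      kept <- list()
      for (j in ord) {
        pj <- peaks[[j]]
        clash <- any(vapply(kept, function(q)
          abs(q[1] - pj[1]) < 0.8 * (q[3] + pj[3]), logical(1)))
        if (!clash) kept[[length(kept) + 1L]] <- pj
      }
      peaks <- kept
    }
    peaks
  }
  peak_sum <- function(peaks) {
    y <- numeric(length(f))
    for (q in peaks) y <- y + gauss_peak(f, q[1], q[2], q[3])
    y
  }
  ap_par <- fit_aperiodic(lp)
  peaks <- extract_peaks(lp - ap_fun(ap_par, f))
  pk <- if (length(peaks)) {
    tibble::tibble(center = vapply(peaks, `[`, numeric(1), 1),
                   height = vapply(peaks, `[`, numeric(1), 2),
                   width = vapply(peaks, `[`, numeric(1), 3))
  } else {
    tibble::tibble(center = numeric(0), height = numeric(0),
                   width = numeric(0))
  }
  pk <- pk[order(pk$height, decreasing = TRUE), ]
  yhat <- ap_fun(ap_par, f) + peak_sum(peaks)
  structure(
    list(aperiodic_offset = unname(ap_par[1]),
         aperiodic_exponent = unname(ap_par[2]),
         knee = if (knee) unname(ap_par[3]) else NA_real_,
         peaks = pk, fit_range = fit_range,
         r_squared = 1 - sum((lp - yhat)^2) / sum((lp - mean(lp))^2),
         freqs = f, log_power = lp, fitted = yhat,
         aperiodic_fit = ap_fun(ap_par, f)),
    class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf(
    "<spectral_fit> exponent %.2f, %d peak(s), R^2 = %.3f\n",
    x$aperiodic_exponent, nrow(x$peaks), x$r_squared))
  if (nrow(x$peaks)) print(x$peaks)
  invisible(x)
}

#' Largest fitted peak within a band
#'
#' @param fit A `spectral_fit`.
#' @param band Frequency band (Hz pair).
#' @return One-row tibble (center, height, width) or zero rows if no peak
#'   falls inside `band`.
#' @export
peak_in_band <- function(fit, band = c(5, 11)) {
  pk <- fit$peaks[fit$peaks$center >= band[1] & fit$peaks$center <= band[2], ]
  if (nrow(pk)) pk[which.max(pk$height), ] else pk
}

#' Peri-event Morlet spectrogram with two normalisations
#'
#' Morlet-wavelet power (6 cycles) averaged over event-locked epochs.
#' `relative` normalisation divides each time column by its total power
#' across frequencies (columns sum to 1); `baseline` expresses power as dB
#' change versus the mean over the `baseline` window.
#'
#' @param signal Numeric waveform.
#' @param fs Sampling rate (Hz).
#' @param events Event times (s) or an event table (`utterance` onsets).
#' @param freqs Frequency grid (Hz), default 20 log-spaced values 3-50 Hz.
#' @param normalization `"relative"` or `"baseline"`.
#' @param window Epoch window (s) relative to events.
#' @param baseline Baseline window (s), must precede the event.
#' @param n_cycles Morlet cycles.
#' @return A `peri_spectrogram` with `times`, `freqs`, `power`
#'   (frequency x time), `normalization`, `n_events`, `n_dropped`.
#' @export
peri_event_spectrogram <- function(signal, fs, events,
                                   freqs = exp(seq(log(3), log(50),
                                                   length.out = 20)),
                                   normalization = c("relative", "baseline"),
                                   window = c(-1.5, 3),
                                   baseline = c(-1, 0), n_cycles = 6) {
  normalization <- match.arg(normalization)
  if (is.data.frame(events))
    events <- events$onset_s[events$tier == "utterance"]
  if (max(freqs) >= fs / 2) stopf("`freqs` must lie below Nyquist")
  if (normalization == "baseline" && baseline[2] > 0)
    stopf("`baseline` window must precede the event")
  n <- length(signal)
  pow_full <- vapply(freqs, function(fr)
    Mod(morlet_transform(signal, fs, fr, n_cycles))^2, numeric(n))
  rel_t <- seq(window[1], window[2], by = 1 / fs)
  acc <- matrix(0, length(freqs), length(rel_t))
  used <- 0L
  dropped <- 0L
  for (tt in events) {
    idx <- round((tt + rel_t) * fs) + 1L
    if (idx[1] < 1L || idx[length(idx)] > n) {
      dropped <- dropped + 1L
      next
    }
    acc <- acc + t(pow_full[idx, , drop = FALSE])
    used <- used + 1L
  }
  if (dropped > 0L)
    rlang::warn(sprintf("%d event(s) too close to the recording edge dropped",
                        dropped))
  if (used == 0L) stopf("no usable events")
  avg <- acc / used
  if (normalization == "relative") {
    out <- sweep(avg, 2, colSums(avg), "/")
  } else {
    bsel <- rel_t >= baseline[1] & rel_t <= baseline[2]
    bmean <- rowMeans(avg[, bsel, drop = FALSE])
    out <- 10 * log10(sweep(avg, 1, bmean, "/"))
  }
  structure(list(times = rel_t, freqs = freqs, power = out,
                 normalization = normalization, n_events = used,
                 n_dropped = dropped),
            class = "peri_spectrogram")
}
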