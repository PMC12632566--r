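# Band-limited analytic signals and inter-site phase coherence.
#
# Phase convention (used everywhere downstream): 0 = waveform positive
# peak, +/- pi = trough.

#' Band-limited analytic signal
#'
#' Zero-phase band-pass (frequency-domain filter with raised-cosine
#' transitions, group delay identically zero) followed by the analytic
#' amplitude and phase.
#'
#' @param signal Numeric waveform.
#' @param fs Sampling rate (Hz).
#' @param band Band edges (Hz pair), increasing and below Nyquist.
#' @param transition Transition width (Hz), default 1.
#' @return A `band_signal` with `amplitude`, `phase` (radians in
#'   `(-pi, pi]`), `filtered`, `band`, `fs`.
#' @export
band_analytic <- function(signal, fs, band, transition = 1) {
  if (band[1] >= band[2]) stopf("`band` must be increasing")
  if (band[2] >= fs / 2) stopf("`band` must lie below Nyquist")
  if (length(signal) < 3 * fs / transition)
    stopf("signal shorter than 3 filter lengths for this transition width")
  filt <- fft_bandpass(signal, fs, band, transition)
  z <- analytic_signal(filt)
  structure(list(amplitude = Mod(z), phase = Arg(z), filtered = filt,
                 band = band, fs = fs),
            class = "band_signal")
}

#' @export
print.band_signal <- function(x, ...) {
  cat(sprintf("<band_signal> %g-%g Hz, %d samples @ %g Hz\n",
              x$band[1], x$band[2], length(x$phase), x$fs))
  invisible(x)
}

#' Sliding-window phase-locking coherogram
#'
#' For every (window, frequency) cell, computes the mean resultant length of
#' the within-window instantaneous phase differences between two signals
#' (Morlet phase, 6 cycles), averaged across event-locked epochs. The
#' alternative `estimator = "across_trials"` computes, per time point and
#' frequency, the resultant length of the phase difference across trials.
#'
#' @param x,y Numeric waveforms (equal sampling rate), or `band_signal`
#'   objects for a single-band computation.
#' @param fs Sampling rate (Hz); ignored when band signals are supplied.
#' @param events Event times (s) or an event table (`utterance` onsets).
#' @param freqs Frequency grid (Hz); default 16 log-spaced 4-50 Hz.
#' @param window_s Sliding window length (s), default 0.5.
#' @param step_s Window step (s), default 0.05.
#' @param epoch_window Epoch span (s) relative to each event.
#' @param estimator `"within_window"` (default) or `"across_trials"`.
#' @param min_cycles Minimum cycles of the lowest frequency per window.
#' @return A `coherogram` with `times`, `freqs`, `coherence` in `[0, 1]`,
#'   `n_events`, `baseline_window` unset (`NULL`).
#' @export
sliding_plv_coherogram <- function(x, y, fs = NULL, events,
                                   freqs = exp(seq(log(4), log(50),
                                                   length.out = 16)),
                                   window_s = 0.5, step_s = 0.05,
                                   epoch_window = c(-1.5, 3),
                                   estimator = c("within_window",
                                                 "across_trials"),
                                   min_cycles = 2) {
  estimator <- match.arg(estimator)
  if (inherits(x, "band_signal")) {
    fs <- x$fs
    freqs <- mean(x$band)
    phx <- matrix(x$phase, ncol = 1)
    phy <- matrix(y$phase, ncol = 1)
  } else {
    if (is.null(fs)) stopf("`fs` is required for raw signals")
    if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
    phx <- vapply(freqs, function(fr) Arg(morlet_transform(x, fs, fr)),
                  numeric(length(x)))
    phy <- vapply(freqs, function(fr) Arg(morlet_transform(y, fs, fr)),
                  numeric(length(y)))
  }
  if (window_s < min_cycles / min(freqs))
    stopf("window shorter than %g cycles of the lowest frequency",
          min_cycles)
  if (is.data.frame(events))
    events <- events$onset_s[events$tier == "utterance"]
  n <- nrow(phx)
  centers <- seq(epoch_window[1] + window_s / 2,
                 epoch_window[2] - window_s / 2, by = step_s)
  halfw <- round(window_s * fs / 2)
  dphi <- exp(1i * (phx - phy))
  keep <- vapply(events, function(tt) {
    a <- round((tt + epoch_window[1]) * fs) + 1L
    b <- round((tt + epoch_window[2]) * fs) + 1L
    a >= 1L && b <= n
  }, logical(1))
  events <- events[keep]
  if (!length(events)) stopf("no event epoch lies inside the recording")
  if (estimator == "within_window") {
    coh <- matrix(0, length(centers), ncol(phx))
    for (tt in events) {
      for (ci in seq_along(centers)) {
        ctr <- round((tt + centers[ci]) * fs) + 1L
        idx <- max(1L, ctr - halfw):min(n, ctr + halfw)
        coh[ci, ] <- coh[ci, ] + Mod(colMeans(dphi[idx, , drop = FALSE]))
      }
    }
    coh <- coh / length(events)
  } else {
    idx0 <- round(centers * fs)
    coh <- matrix(0, length(centers), ncol(phx))
    samp <- vapply(events, function(tt) round(tt * fs) + 1L, numeric(1))
    for (ci in seq_along(centers)) {
      rows <- samp + idx0[ci]
      coh[ci, ] <- Mod(colMeans(dphi[rows, , drop = FALSE]))
    }
  }
  structure(list(times = centers, freqs = freqs, coherence = t(coh),
                 n_events = length(events), n_pairs = 1L,
                 baseline_window = NULL),
            class = "coherogram")
}

#' @export
print.coherogram <- function(x, ...) {
  cat(sprintf("<coherogram> %d freqs x %d windows, %d events\n",
              length(x$freqs), length(x$times), x$n_events))
  invisible(x)
}

#' Speech-related coherence change with hierarchical statistics
#'
#' For each pair's coherogram, subtracts the per-frequency baseline mean;
#' pairs are then averaged within subject and a one-sample t-test across
#' subjects is run per (time, frequency) cell, with Benjamini-Hochberg
#' control over all cells.
#'
#' @param coherograms List of `coherogram` objects (one per electrode pair)
#'   sharing time/frequency grids.
#' @param subjects Grouping label per coherogram.
#' @param baseline_window Baseline interval (s), default `c(-1, 0)`.
#' @param q FDR level.
#' @return List with `effect` (freq x time mean change), `t`, `p`,
#'   `p_adjusted`, `significant` (freq x time logical), `times`, `freqs`,
#'   `n_subjects`.
#' @export
coherence_change_stats <- function(coherograms, subjects,
                                   baseline_window = c(-1, 0), q = 0.05) {
  if (length(unique(subjects)) < 2L)
    stopf("at least two subjects' worth of pairs are required")
  times <- coherograms[[1]]$times
  freqs <- coherograms[[1]]$freqs
  bsel <- times >= baseline_window[1] & times <= baseline_window[2]
  if (!any(bsel)) stopf("no time points fall in the baseline window")
  changes <- lapply(coherograms, function(cg) {
    cg$coherence - rowMeans(cg$coherence[, bsel, drop = FALSE])
  })
  subj_means <- lapply(unique(subjects), function(s) {
    Reduce(`+`, changes[subjects == s]) / sum(subjects == s)
  })
  ns <- length(subj_means)
  arr <- simplify2array(subj_means) # freq x time x subject
  mu <- apply(arr, c(1, 2), mean)
  se <- apply(arr, c(1, 2), sd) / sqrt(ns)
  tstat <- mu / pmax(se, .Machine$double.eps)
  p <- 2 * stats::pt(-abs(tstat), df = ns - 1)
  adj <- matrix(p.adjust(p, "BH"), nrow(p), ncol(p))
  list(effect = mu, t = tstat, p = p, p_adjusted = adj,
       significant = adj < q, times = times, freqs = freqs,
       n_subjects = ns)
}

#' Per-channel theta phase offsets relative to a reference site
#'
#' Circular mean of the instantaneous phase difference to the reference
#' channel over speech samples, classified as near-zero (within 45 degrees
#' of 0), antiphase (within 45 degrees of 180), or other. Channels closer
#' than `min_dist_mm` to the reference are flagged excluded (volume
#' conduction guard).
#'
#' @param band_signals Named list of `band_signal` objects, one per channel.
#' @param reference_channel Name of the reference channel.
#' @param coords Tibble with `name`, `x`, `y`, `z` (mm) for every channel.
#' @param min_dist_mm Exclusion radius around the reference (mm).
#' @param speech_mask Logical vector of speech samples.
#' @return Tibble: `channel`, `offset` (radians in `(-pi, pi]`),
#'   `offset_deg`, `plv`, `class`, `distance_mm`, `excluded`.
#' @export
phase_offset_map <- function(band_signals, reference_channel, coords,
                             min_dist_mm = 15, speech_mask = NULL) {
  if (!reference_channel %in% names(band_signals))
    stopf("reference channel `%s` missing from `band_signals`",
          reference_channel)
  if (!all(names(band_signals) %in% coords$name))
    stopf("coordinates missing for some channels")
  ref <- band_signals[[reference_channel]]
  if (is.null(speech_mask)) speech_mask <- rep(TRUE, length(ref$phase))
  rc <- coords[match(reference_channel, coords$name), ]
  purrr::map_dfr(names(band_signals), function(ch) {
    bs <- band_signals[[ch]]
    d <- circ_dist(bs$phase[speech_mask], ref$phase[speech_mask])
    mu <- circ_mean(d)
    plv <- circ_resultant(d)
    cc <- coords[match(ch, coords$name), ]
    dist <- sqrt((cc$x - rc$x)^2 + (cc$y - rc$y)^2 + (cc$z - rc$z)^2)
    cls <- if (abs(wrap_pi(mu)) <= pi / 4) "near-zero"
           else if (abs(abs(wrap_pi(mu)) - pi) <= pi / 4) "antiphase"
           else "other"
    tibble::tibble(channel = ch, offset = mu, offset_deg = rad2deg(mu),
                   plv = plv, class = cls, distance_mm = dist,
                   excluded = ch != reference_channel & dist < min_dist_mm)
  })
}
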