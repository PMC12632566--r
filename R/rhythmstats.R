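# Rhythm periodicity (ACF) and its relation to speaking rate; matched-trial
# resampling and coupling contrasts for fluent versus error speech; shared
# circular statistical tests.

#' Theta-band autocorrelation periodicity
#'
#' Band-filters the signal, computes the (unbiased-normalised)
#' autocorrelation, and reports the first local maximum at a lag beyond
#' half a cycle of the band centre - the "secondary ACF peak" whose
#' magnitude indexes rhythm periodicity. A pure sinusoid gives a secondary
#' peak of 1 at lag `1/f`.
#'
#' @param signal Numeric waveform.
#' @param fs Sampling rate (Hz).
#' @param band Band (Hz pair), default `c(6, 10)`.
#' @param max_lag_s Longest lag examined (s).
#' @param filter Band-filter first (set `FALSE` if already filtered).
#' @return A `periodicity_result`: `acf` tibble (lag_s, r),
#'   `secondary_peak`, `secondary_peak_lag_s`, `band_power`, `found`.
#' @export
acf_periodicity <- function(signal, fs, band = c(6, 10), max_lag_s = 0.5,
                            filter = TRUE) {
  fc <- mean(band)
  if (length(signal) / fs < 10 / fc)
    stopf("signal shorter than 10 cycles of the band centre")
  x <- if (filter) fft_bandpass(signal, fs, band) else signal
  x <- x - mean(x)
  max_k <- round(max_lag_s * fs)
  a <- stats::acf(x, lag.max = max_k, plot = FALSE,
                  demean = FALSE)$acf[, 1, 1]
  n <- length(x)
  r <- a * n / (n - seq_along(a) + 1) # unbiased normalisation
  lag_s <- (seq_along(r) - 1L) / fs
  half_cycle <- 0.5 / fc
  cand <- local_maxima(r)
  cand <- cand[lag_s[cand] > half_cycle]
  found <- length(cand) > 0L
  if (found) {
    best <- cand[1] # first local maximum beyond half a cycle
    sp <- r[best]
    sl <- lag_s[best]
  } else {
    sp <- 0
    sl <- NA_real_
  }
  structure(list(acf = tibble::tibble(lag_s = lag_s, r = r),
                 secondary_peak = sp, secondary_peak_lag_s = sl,
                 band_power = mean(x^2), found = found, band = band),
            class = "periodicity_result")
}

#' @export
print.periodicity_result <- function(x, ...) {
  cat(sprintf(
    "<periodicity_result> secondary ACF peak %.3f at %.3f s (band %g-%g Hz)\n",
    x$secondary_peak, x$secondary_peak_lag_s, x$band[1], x$band[2]))
  invisible(x)
}

#' Rhythm periodicity versus speaking rate across subjects
#'
#' Median-splits subjects into slow and fast speakers by syllable rate,
#' compares periodicity between halves by rank-sum test, and reports the
#' Spearman correlation (exact p for small n).
#'
#' @param periodicity Per-subject periodicity values.
#' @param rates Per-subject mean syllable rates (syl/s).
#' @return List with `split` tibble (subject, rate, periodicity, group),
#'   `rank_sum_p`, `spearman_rho`, `spearman_p`, `tie_flagged`.
#' @export
rate_periodicity_analysis <- function(periodicity, rates) {
  n <- length(periodicity)
  if (n < 6L) stopf("at least 6 subjects are required")
  if (length(rates) != n) stopf("inputs must have equal length")
  med <- median(rates)
  tie_flagged <- any(rates == med) && n %% 2L == 0L
  ord <- order(rates, seq_len(n)) # stable order resolves ties
  group <- character(n)
  group[ord[seq_len(floor(n / 2))]] <- "slow"
  group[ord[(floor(n / 2) + 1L):n]] <- "fast"
  ws <- wilcox.test(periodicity[group == "fast"],
                    periodicity[group == "slow"], exact = FALSE)
  sp <- suppressWarnings(cor.test(rates, periodicity, method = "spearman",
                                  exact = n <= 10))
  list(split = tibble::tibble(subject = seq_len(n), rate = rates,
                              periodicity = periodicity, group = group),
       rank_sum_p = ws$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       tie_flagged = tie_flagged)
}

#' Covariate-matched resampling of fluent trials
#'
#' For each resample, draws (without replacement within the resample) a
#' fluent control set matching the error trials in sample size and, by
#' nearest-neighbour draw on standardised covariates, in syllable rate and
#' duration. Subjects with fewer than `min_error_trials` error trials are
#' flagged excluded.
#'
#' @param error_trials,fluent_trials Tibbles of trials with the matching
#'   covariates.
#' @param covariates Covariate column names, default
#'   `c("syllable_rate", "duration_s")`.
#' @param n_resamples Number of resamples, default 200.
#' @param min_error_trials Exclusion threshold, default 10.
#' @param n_candidates Nearest neighbours sampled from, per draw.
#' @param seed Integer seed.
#' @return List with `excluded` flag; if not excluded: `resamples` (list of
#'   fluent row-index vectors), `n_resamples`, `covariate_medians` tibble
#'   (per covariate: error median and median of matched-set medians).
#' @export
matched_trial_resample <- function(error_trials, fluent_trials,
                                   covariates = c("syllable_rate",
                                                  "duration_s"),
                                   n_resamples = 200,
                                   min_error_trials = 10,
                                   n_candidates = 1, seed = 1L) {
  ne <- nrow(error_trials)
  if (ne < min_error_trials)
    return(list(excluded = TRUE, n_error_trials = ne,
                reason = sprintf("fewer than %d error trials",
                                 min_error_trials)))
  if (nrow(fluent_trials) < ne)
    stopf("insufficient data: fluent pool smaller than the error set")
  E <- as.matrix(error_trials[, covariates])
  F_ <- as.matrix(fluent_trials[, covariates])
  mu <- colMeans(rbind(E, F_))
  sg <- pmax(apply(rbind(E, F_), 2, sd), 1e-12)
  Ez <- sweep(sweep(E, 2, mu), 2, sg, "/")
  Fz <- sweep(sweep(F_, 2, mu), 2, sg, "/")
  res <- with_seed(seed, {
    lapply(seq_len(n_resamples), function(r) {
      avail <- rep(TRUE, nrow(Fz))
      picked <- integer(ne)
      for (i in sample(ne)) {
        d <- colSums((t(Fz) - Ez[i, ])^2)
        d[!avail] <- Inf
        cand <- order(d)[seq_len(min(n_candidates, sum(avail)))]
        j <- cand[sample.int(length(cand), 1)]
        picked[i] <- j
        avail[j] <- FALSE
      }
      picked
    })
  })
  med_tbl <- purrr::map_dfr(covariates, function(cv) {
    matched_meds <- vapply(res, function(idx)
      median(fluent_trials[[cv]][idx]), numeric(1))
    tibble::tibble(covariate = cv,
                   error_median = median(error_trials[[cv]]),
                   matched_median = median(matched_meds))
  })
  list(excluded = FALSE, resamples = res, n_resamples = n_resamples,
       covariate_medians = med_tbl, n_error_trials = ne)
}

#' Fluent-versus-error theta-movement coupling contrast
#'
#' Computes, per electrode and group, the Tort MI and preferred phase of
#' theta-AC coupling from concatenated trials; tests the MI reduction on
#' error trials (paired Wilcoxon across electrodes), and compares the
#' across-electrode consistency of preferred phases - fluent odd versus
#' even halves against fluent versus error - with a concentration
#' (dispersion) test of the two samples of phase differences.
#'
#' @param trials Tibble with columns `electrode`, `group` (`"fluent"` /
#'   `"error"`), and list-columns `phase` and `magnitude` (per-trial
#'   series).
#' @param n_bins Phase bins for the MI.
#' @param n_perm Permutations for the dispersion test.
#' @param seed Integer seed.
#' @return List with `per_electrode` tibble (electrode, mi_fluent,
#'   mi_error, pref_fluent, pref_error), `mi_difference` (median fluent -
#'   error), `mi_p` (paired one-sided Wilcoxon), `consistency_fluent`
#'   (odd/even resultant length), `consistency_error` (fluent/error
#'   resultant length), `dispersion_p`, `dropped`.
#' @export
fluency_coupling_contrast <- function(trials, n_bins = 24, n_perm = 1000,
                                      seed = 1L) {
  stopifnot(all(c("electrode", "group", "phase", "magnitude") %in%
                  names(trials)))
  if (!all(c("fluent", "error") %in% trials$group))
    stopf("both groups must be non-empty")
  electrodes <- unique(trials$electrode)
  dropped <- character(0)
  rows <- list()
  halves <- list()
  for (el in electrodes) {
    sub <- trials[trials$electrode == el, ]
    grp <- function(g) {
      s <- sub[sub$group == g, ]
      list(phase = unlist(s$phase), mag = unlist(s$magnitude), n = nrow(s))
    }
    fl <- grp("fluent")
    er <- grp("error")
    mi_of <- function(g) tryCatch(tort_mi(g$phase, g$mag, n_bins),
                                  error = function(e) NULL)
    rf <- mi_of(fl)
    re <- mi_of(er)
    if (is.null(rf) || is.null(re) || is.na(rf$preferred_phase) ||
        is.na(re$preferred_phase)) {
      dropped <- c(dropped, el)
      next
    }
    # fluent odd/even split for the consistency benchmark
    sfl <- sub[sub$group == "fluent", ]
    odd <- seq_len(nrow(sfl)) %% 2L == 1L
    ph_odd <- tryCatch(tort_mi(unlist(sfl$phase[odd]),
                               unlist(sfl$magnitude[odd]),
                               n_bins)$preferred_phase,
                       error = function(e) NA_real_)
    ph_even <- tryCatch(tort_mi(unlist(sfl$phase[!odd]),
                                unlist(sfl$magnitude[!odd]),
                                n_bins)$preferred_phase,
                        error = function(e) NA_real_)
    halves[[el]] <- c(ph_odd, ph_even)
    rows[[el]] <- tibble::tibble(
      electrode = el, mi_fluent = rf$mi, mi_error = re$mi,
      pref_fluent = rf$preferred_phase, pref_error = re$preferred_phase)
  }
  if (!length(rows)) stopf("no electrode with defined preferred phases")
  tbl <- dplyr::bind_rows(rows)
  mi_test <- wilcox.test(tbl$mi_fluent, tbl$mi_error, paired = TRUE,
                         alternative = "greater", exact = FALSE)
  d_oddeven <- vapply(tbl$electrode, function(el) {
    h <- halves[[el]]
    if (any(is.na(h))) NA_real_ else circ_dist(h[1], h[2])
  }, numeric(1))
  d_oddeven <- d_oddeven[!is.na(d_oddeven)]
  d_flerr <- circ_dist(tbl$pref_fluent, tbl$pref_error)
  list(per_electrode = tbl,
       mi_difference = median(tbl$mi_fluent - tbl$mi_error),
       mi_p = mi_test$p.value,
       consistency_fluent = circ_resultant(d_oddeven),
       consistency_error = circ_resultant(d_flerr),
       dispersion_p = fisher_dispersion_test(d_oddeven, d_flerr,
                                             n_perm = n_perm,
                                             seed = seed)$p_value,
       dropped = dropped)
}

#' Two-sample circular concentration (dispersion) test
#'
#' Tests whether two samples of angles share a common concentration, using
#' the difference in mean resultant lengths with a permutation null
#' (Fisher's two-sample concentration comparison, permutation form).
#'
#' @param a,b Angle samples (radians).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `statistic` (R_a - R_b), `p_value` (two-sided).
#' @export
fisher_dispersion_test <- function(a, b, n_perm = 1000, seed = 1L) {
  na <- length(a)
  stat <- circ_resultant(a) - circ_resultant(b)
  pool <- c(a, b)
  p <- with_seed(seed, {
    cnt <- sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample(length(pool), na)
      abs(circ_resultant(pool[idx]) - circ_resultant(pool[-idx])) >=
        abs(stat)
    }, logical(1)))
    (1 + cnt) / (1 + n_perm)
  })
  list(statistic = stat, p_value = p)
}

#' Circular uniformity and two-sample tests
#'
#' Mean resultant length with the Rayleigh uniformity test; when a second
#' sample is supplied, adds the two-sample Watson U-squared test with a
#' permutation p-value.
#'
#' @param angles Angles (radians), n >= 5.
#' @param angles2 Optional second sample.
#' @param n_perm Permutations for the Watson test.
#' @param seed Integer seed.
#' @return List with `mrl`, `mean_direction`, `rayleigh_p`, and (two-sample
#'   case) `watson_u2`, `watson_p`.
#' @export
circ_tests <- function(angles, angles2 = NULL, n_perm = 1000, seed = 1L) {
  n <- length(angles)
  if (n < 5L) stopf("insufficient data: n >= 5 angles required")
  R <- circ_resultant(angles)
  Z <- n * R^2
  # Rayleigh p with the standard finite-n correction
  p_ray <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                        (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) /
                          (288 * n^2))
  p_ray <- min(max(p_ray, .Machine$double.xmin), 1)
  out <- list(mrl = R, mean_direction = circ_mean(angles),
              rayleigh_p = p_ray, n = n)
  if (!is.null(angles2)) {
    if (length(angles2) < 5L)
      stopf("insufficient data: n >= 5 angles required in each sample")
    u2 <- watson_u2_stat(angles, angles2)
    pool <- c(angles, angles2)
    na <- length(angles)
    p <- with_seed(seed, {
      cnt <- sum(vapply(seq_len(n_perm), function(i) {
        idx <- sample(length(pool), na)
        watson_u2_stat(pool[idx], pool[-idx]) >= u2
      }, logical(1)))
      (1 + cnt) / (1 + n_perm)
    })
    out$watson_u2 <- u2
    out$watson_p <- p
  }
  out
}

# Watson's two-sample U^2 statistic.
watson_u2_stat <- function(a, b) {
  a <- sort(wrap_2pi(a))
  b <- sort(wrap_2pi(b))
  n <- length(a)
  m <- length(b)
  all_v <- sort(c(a, b))
  ca <- vapply(all_v, function(v) sum(a <= v), numeric(1)) / n
  cb <- vapply(all_v, function(v) sum(b <= v), numeric(1)) / m
  d <- ca - cb
  N <- n + m
  (n * m / N^2) * (sum(d^2) - sum(d)^2 / N)
}

#' Conversational articulation rate excluding pauses
#'
#' Syllables divided by total voiced time, where a pause is any
#' inter-syllable gap longer than `pause_gap_s`.
#'
#' @param syllable_times Syllable nucleus times (s), sorted or not.
#' @param pause_gap_s Gap defining a pause, default 0.15 s.
#' @return Articulation rate (syl/s).
#' @export
articulation_rate <- function(syllable_times, pause_gap_s = 0.15) {
  tt <- sort(syllable_times)
  if (length(tt) < 2L) return(NA_real_)
  gaps <- diff(tt)
  voiced <- sum(pmin(gaps, pause_gap_s))
  length(tt) / voiced
}
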