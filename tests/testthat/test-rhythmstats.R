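test_that("ACF periodicity has the sinusoid limit and bandwidth monotonicity", {
  fs <- 500
  x <- cos(2 * pi * 8 * seq(0, 10, by = 1 / fs))
  pr <- acf_periodicity(x, fs, band = c(6, 10), filter = FALSE)
  expect_gt(pr$secondary_peak, 0.99)
  expect_lt(abs(pr$secondary_peak_lag_s - 0.125), 0.004)
  sp <- vapply(c(0.4, 1, 2, 3), function(bw)
    acf_periodicity(theta_carrier(fs, 30, 8.2, bw, seed = 5),
                    fs)$secondary_peak, numeric(1))
  expect_true(all(diff(sp) < 0))
  expect_error(acf_periodicity(x[1:300], fs), "cycles")
})

test_that("periodicity is amplitude-invariant and noise sits at the filter floor", {
  fs <- 500
  x <- theta_carrier(fs, 20, 8.2, 1.5, seed = 6)
  a <- acf_periodicity(x, fs)$secondary_peak
  b <- acf_periodicity(10 * x, fs)$secondary_peak
  expect_equal(a, b, tolerance = 1e-12)
  # white noise: secondary peak below the Monte-Carlo 95th percentile of
  # the filter-only null... and well below an oscillatory signal
  nulls <- thetaspeech:::with_seed(7, vapply(1:20, function(i)
    acf_periodicity(rnorm(20 * fs), fs)$secondary_peak, numeric(1)))
  expect_lt(quantile(nulls, 0.95), a)
})

test_that("rate_periodicity_analysis splits, correlates, and flags ties", {
  per <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9)
  rate <- seq(2.5, 6, length.out = 8)
  res <- rate_periodicity_analysis(per, rate)
  expect_equal(sum(res$split$group == "fast"), 4)
  expect_equal(res$spearman_rho, 1)
  expect_lt(res$spearman_p, 0.01)
  expect_lt(res$rank_sum_p, 0.05)
  expect_error(rate_periodicity_analysis(per[1:4], rate[1:4]), "6")
})

test_that("rate-periodicity test is calibrated under independence", {
  ps <- thetaspeech:::with_seed(8, vapply(1:200, function(i)
    rate_periodicity_analysis(rnorm(12), rnorm(12))$spearman_p,
    numeric(1)))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("matched resampling matches covariates without trial reuse", {
  err <- tibble::tibble(syllable_rate = with_seed_rnorm(1, 15) * 0.3 + 4,
                        duration_s = with_seed_rnorm(2, 15) * 0.2 + 2)
  flu <- tibble::tibble(syllable_rate = with_seed_rnorm(3, 90) * 0.5 + 4.2,
                        duration_s = with_seed_rnorm(4, 90) * 0.4 + 2.1)
  mr <- matched_trial_resample(err, flu, n_resamples = 200, seed = 2)
  expect_false(mr$excluded)
  expect_equal(mr$n_resamples, 200)
  expect_true(all(vapply(mr$resamples, function(i) !any(duplicated(i)),
                         logical(1))))
  expect_true(all(lengths(mr$resamples) == nrow(err)))
  pooled_sd <- sd(c(err$syllable_rate, flu$syllable_rate))
  dev <- abs(mr$covariate_medians$matched_median[1] -
               mr$covariate_medians$error_median[1])
  expect_lt(dev, 0.1 * pooled_sd)
  # identical covariates: matched medians equal the error medians
  mr2 <- matched_trial_resample(err, err, n_resamples = 20, seed = 3)
  expect_equal(mr2$covariate_medians$matched_median,
               mr2$covariate_medians$error_median, tolerance = 1e-9)
  # exclusion and insufficiency rules
  expect_true(matched_trial_resample(err[1:9, ], flu, seed = 1)$excluded)
  expect_error(matched_trial_resample(err, flu[1:10, ], seed = 1),
               "insufficient")
})

test_that("fluency contrast detects jittered, unlocked error trials", {
  s <- get_session("err")
  fs <- s$recording$fs
  fsk <- s$kinematics$fs
  ac <- articulatory_change(s$kinematics)
  utts <- s$events[s$events$tier == "utterance", ]
  rows <- list()
  for (ch in setdiff(colnames(s$recording$data),
                     s$ground_truth$reference_channel)) {
    th <- band_analytic(s$recording$data[, ch], fs, c(6, 10))
    phk <- approx((seq_len(nrow(s$recording$data)) - 1) / fs,
                  thetaspeech:::unwrap_phase(th$phase),
                  xout = (seq_along(ac) - 1) / fsk, rule = 2)$y
    for (i in seq_len(nrow(utts))) {
      a <- round(utts$onset_s[i] * fsk) + 1
      b <- round(utts$offset_s[i] * fsk)
      rows[[length(rows) + 1]] <- tibble::tibble(
        electrode = ch, trial = i,
        group = ifelse(utts$fluent[i], "fluent", "error"),
        phase = list(phk[a:b]), magnitude = list(as.numeric(ac[a:b])))
    }
  }
  fc <- fluency_coupling_contrast(dplyr::bind_rows(rows), n_perm = 500,
                                  seed = 5)
  expect_gt(fc$mi_difference, 0)
  expect_lt(fc$mi_p, 0.05)
  expect_gt(fc$consistency_fluent, fc$consistency_error)
  expect_lt(fc$dispersion_p, 0.05)
})

test_that("identical groups give zero contrast and full consistency", {
  ph <- thetaspeech:::with_seed(9, runif(3000, 0, 2 * pi))
  mag <- 1 + 0.5 * cos(ph - 2)
  rows <- purrr::map_dfr(c("e1", "e2", "e3"), function(el)
    purrr::map_dfr(1:6, function(tr) tibble::tibble(
      electrode = el, trial = tr,
      group = c("fluent", "error")[tr %% 2 + 1],
      phase = list(ph[1:500 + 500 * (tr - 1)]),
      magnitude = list(mag[1:500 + 500 * (tr - 1)]))))
  fc <- fluency_coupling_contrast(rows, n_perm = 200, seed = 6)
  expect_lt(abs(fc$mi_difference), 0.02)
  expect_gt(fc$consistency_error, 0.95)
})

test_that("circular tests behave at their limits and under uniformity", {
  expect_equal(circ_tests(rep(1.3, 8))$mrl, 1, tolerance = 1e-12)
  big <- thetaspeech:::with_seed(10, runif(3000, 0, 2 * pi))
  ct <- circ_tests(big)
  expect_lt(ct$mrl, 0.05)
  expect_gt(ct$rayleigh_p, 0.05)
  expect_error(circ_tests(c(1, 2)), "n >= 5")
  # von Mises concentration is detected with high power
  vm <- thetaspeech:::with_seed(11, {
    vapply(1:50, function(i) {
      th <- runif(50, -pi, pi)
      keep <- runif(50) < exp(2 * (cos(th) - 1)) # rejection sample kappa=2
      ang <- th[keep]
      while (length(ang) < 50) {
        th <- runif(50, -pi, pi)
        ang <- c(ang, th[runif(50) < exp(2 * (cos(th) - 1))])
      }
      circ_tests(ang[1:50])$rayleigh_p < 0.05
    }, logical(1))
  })
  expect_gt(mean(vm), 0.95)
})

test_that("Rayleigh test is calibrated under uniformity", {
  rej <- thetaspeech:::with_seed(12, vapply(1:300, function(i)
    circ_tests(runif(40, 0, 2 * pi))$rayleigh_p < 0.05, logical(1)))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("two-sample Watson test separates shifted distributions", {
  a <- thetaspeech:::with_seed(13, wrap_2pi(rnorm(40, 1, 0.4)))
  b <- thetaspeech:::with_seed(14, wrap_2pi(rnorm(40, 2.5, 0.4)))
  ct <- circ_tests(a, b, n_perm = 300, seed = 1)
  expect_lt(ct$watson_p, 0.05)
  same <- circ_tests(a, a + 0, n_perm = 300, seed = 2)
  expect_gt(same$watson_p, 0.5)
})

test_that("dispersion test separates concentrated from dispersed samples", {
  tight <- thetaspeech:::with_seed(15, wrap_2pi(rnorm(30, 1, 0.1)))
  loose <- thetaspeech:::with_seed(16, runif(30, 0, 2 * pi))
  ft <- fisher_dispersion_test(tight, loose, n_perm = 500, seed = 3)
  expect_lt(ft$p_value, 0.05)
  # calibration: equal concentration rejects at ~alpha
  rej <- thetaspeech:::with_seed(17, vapply(1:100, function(i) {
    a <- wrap_2pi(rnorm(25, 0, 0.5))
    b <- wrap_2pi(rnorm(25, 2, 0.5))
    fisher_dispersion_test(a, b, n_perm = 99, seed = i)$p_value < 0.05
  }, logical(1)))
  expect_lt(mean(rej), 0.12)
})

test_that("articulation rate excludes pauses", {
  # 10 syllables at 8/s with one 2-s pause: pause time is capped
  tt <- c(seq(0, 4 / 8, by = 1 / 8), seq(3, 3.5, by = 1 / 8))
  r <- articulation_rate(tt, pause_gap_s = 0.15)
  expect_gt(r, 6)
  expect_true(is.na(articulation_rate(1)))
})
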