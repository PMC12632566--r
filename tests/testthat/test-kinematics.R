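test_that("articulatory change obeys its closed forms", {
  fs <- 100
  # constant trajectories -> 0
  const <- matrix(5, 300, 3)
  expect_true(all(articulatory_change(const, fs = fs) < 1e-18))
  # linear ramp with slope v -> v^2 in the interior
  v <- 3.2
  ramp <- matrix(v * (0:299) / fs, ncol = 1)
  ac <- articulatory_change(ramp, fs = fs)
  interior <- 60:240
  expect_equal(unname(ac[interior]), rep(v^2, length(interior)),
               tolerance = 1e-6)
  expect_error(articulatory_change(matrix(1, 1, 1), fs = fs), "samples")
})

test_that("AC equals the manual per-variable sum of squared velocities", {
  fs <- 100
  mat <- matrix(with_seed_rnorm(3, 600 * 6), 600, 6)
  ac <- articulatory_change(mat, fs = fs, smooth_ms = 0, lowpass_hz = Inf)
  manual <- numeric(600)
  for (j in 1:6) {
    x <- mat[, j]
    vv <- numeric(600)
    vv[2:599] <- (x[3:600] - x[1:598]) * fs / 2
    vv[1] <- vv[2]; vv[600] <- vv[599]
    manual <- manual + vv^2
  }
  expect_lt(max(abs(ac - manual)), 1e-9)
})

test_that("AC is offset-invariant and scales quadratically with velocity", {
  fs <- 100
  mat <- matrix(with_seed_rnorm(4, 400 * 2), 400, 2)
  a <- articulatory_change(mat, fs = fs)
  b <- articulatory_change(sweep(mat, 2, c(10, -3), "+"), fs = fs)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-9)
  c2 <- articulatory_change(2 * mat, fs = fs)
  expect_equal(as.numeric(c2), 4 * as.numeric(a), tolerance = 1e-9)
})

test_that("pulse analysis recovers a strict 8 Hz train exactly", {
  fs <- 100
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  ac <- numeric(length(t))
  for (ct in seq(0.5, 19.5, by = 0.125))
    ac <- ac + exp(-(t - ct)^2 / (2 * 0.01^2))
  utts <- tibble::tibble(onset_s = 1, offset_s = 19)
  pa <- ac_pulse_analysis(ac, fs, utts)
  expect_equal(pa$median_rate, 8, tolerance = 0.1)
  expect_true(all(abs(pa$ipi - 0.125) < 0.011))
  # threshold above the maximum: nothing detected
  pa0 <- ac_pulse_analysis(ac, fs, utts, threshold = max(ac) * 2)
  expect_equal(length(pa0$pulse_times), 0L)
  # all-zero AC: zero pulses, not an error
  expect_equal(length(ac_pulse_analysis(numeric(2000), fs,
                                        utts)$pulse_times), 0L)
})

test_that("pulse-rate estimator recovers generator rates", {
  s <- make_session(session_config(duration_s = 160, seed = 1,
                                   utterance_dur_s = 8, gap_s = 1.5))
  pa <- ac_pulse_analysis(articulatory_change(s$kinematics),
                          utterances = s$events)
  expect_lt(abs(pa$median_rate - 7.3), 0.2)
})

test_that("mTRF recovers a known convolution kernel", {
  fs <- 100
  n <- 3000
  x <- matrix(0, n, 1)
  x[thetaspeech:::with_seed(2, sample(n - 100, 60)) + 50, 1] <- 1
  kern <- stats::dnorm(seq(-0.2, 0.2, by = 1 / fs), 0, 0.05)
  y <- Re(thetaspeech:::conv_same(x[, 1], kern))
  m <- fit_mtrf(x, y, fs, lags = c(-0.3, 0.3), lambda = c(1e-4, 1e-2, 1))
  kern_grid <- stats::dnorm(m$lags, 0, 0.05)
  expect_lt(max(abs(m$weights[1, ] - kern_grid)) / max(kern_grid), 0.01)
})

test_that("ridge limit and permuted-target behaviour", {
  fs <- 100
  n <- 1500
  x <- matrix(with_seed_rnorm(5, n), ncol = 1)
  y <- Re(thetaspeech:::conv_same(x[, 1], c(0.5, 1, 0.5)))
  big <- fit_mtrf(x, y, fs, lags = c(-0.1, 0.1), lambda = 1e9)
  expect_lt(max(abs(big$weights)), 1e-4)
  # permuted target: held-out R^2 is not positive (mean over permutations)
  r2 <- vapply(1:10, function(i) {
    yp <- thetaspeech:::with_seed(100 + i, sample(y))
    fit_mtrf(x, yp, fs, lags = c(-0.1, 0.1),
             lambda = c(0.01, 1, 100))$cv_r2
  }, numeric(1))
  expect_lte(mean(r2), 0.005)
})

test_that("unique variance isolates informative features", {
  fs <- 100
  n <- 2000
  f1 <- with_seed_rnorm(6, n)
  noise <- with_seed_rnorm(7, n)
  y <- Re(thetaspeech:::conv_same(f1, c(0.3, 1, 0.3))) + 0.1 * noise
  # duplicated feature: its unique contribution is ~0
  X <- cbind(a = f1, b = f1, c = with_seed_rnorm(8, n))
  uv <- unique_variance(X, y, fs, "a", lags = c(-0.1, 0.1),
                        lambda = c(1, 100))
  expect_lt(abs(uv$delta_r2), 0.02)
  # sole informative feature: unique contribution ~ full R^2
  X2 <- cbind(a = f1, c = with_seed_rnorm(9, n))
  uv2 <- unique_variance(X2, y, fs, "a", lags = c(-0.1, 0.1),
                         lambda = c(0.01, 1))
  expect_gt(uv2$delta_r2, 0.8 * uv2$full$cv_r2)
  expect_gt(uv2$full$cv_r2, 0.8)
  expect_error(unique_variance(X2[, 1, drop = FALSE], y, fs, 1,
                               lags = c(-0.1, 0.1)), "empty")
})

test_that("unique variance grows with the injected effect size", {
  fs <- 100
  n <- 2000
  a <- with_seed_rnorm(10, n)
  b <- with_seed_rnorm(11, n)
  dr <- vapply(c(0, 0.5, 1.5), function(g) {
    y <- b + g * a + 0.5 * with_seed_rnorm(12, n)
    unique_variance(cbind(a = a, b = b), y, fs, "a", lags = c(-0.05, 0.05),
                    lambda = c(1, 100))$delta_r2
  }, numeric(1))
  expect_true(all(diff(dr) > 0))
})

test_that("response profiles expose the syllable pulse structure", {
  s <- get_session("long4")
  ac <- articulatory_change(s$kinematics)
  X <- phoneme_design(s$events, s$kinematics$fs, length(ac))
  mv <- fit_mtrf(X[, "vowel", drop = FALSE], as.numeric(ac),
                 s$kinematics$fs, lags = c(-0.6, 0.6))
  pv <- trf_response_profile(mv, 1, peak_frac = 0.15)
  pk <- attr(pv, "peaks")
  expect_gte(length(pk), 3)
  w <- pv$weight[match(pk, pv$lag)]
  top3 <- sort(pk[order(w, decreasing = TRUE)][1:3])
  # vowel flanked by consonant gestures one theta cycle apart
  expect_lt(abs(mean(diff(top3)) - 0.125), 0.015)
  # full model: the consonant kernel has one dominant peak at zero lag
  m2 <- fit_mtrf(X, as.numeric(ac), s$kinematics$fs, lags = c(-0.6, 0.6))
  pc <- trf_response_profile(m2, "consonant")
  expect_lt(abs(pc$lag[which.max(pc$weight)]), 0.015)
  pkc_i <- thetaspeech:::find_peaks(pc$weight, min_height = 0, min_sep = 3)
  ww <- sort(pc$weight[pkc_i], decreasing = TRUE)
  expect_lt(ww[2] / ww[1], 0.6)
  # flat model yields a flat profile, unknown features error
  m0 <- mv; m0$weights[] <- 0
  expect_true(all(trf_response_profile(m0, 1)$weight == 0))
  expect_error(trf_response_profile(mv, "nope"), "feature")
})

test_that("pulse rate regresses on syllable rate across a cohort", {
  # faster speakers skip fewer theta cycles, so their gesture rate sits
  # closer to the theta frequency; pulse rate then tracks syllable rate
  syl <- c(3, 3.6, 4.2, 4.8, 5.4)
  skip <- c(0.30, 0.22, 0.14, 0.07, 0.01)
  rates <- purrr::map_dfr(seq_along(syl), function(i) {
    s <- make_session(session_config(duration_s = 40, seed = 300 + i,
                                     syllable_rate = syl[i],
                                     cycle_skip_prob = skip[i],
                                     utterance_dur_s = 4))
    pa <- ac_pulse_analysis(articulatory_change(s$kinematics),
                            utterances = s$events)
    tibble::tibble(syl = mean(s$ground_truth$trials$syllable_rate),
                   pulse = pa$median_rate)
  })
  fit <- lm(pulse ~ syl, data = rates)
  expect_gt(summary(fit)$r.squared, 0.8)
  expect_gt(coef(fit)[2], 0)
})
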