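test_that("band_analytic recovers amplitude and phase of a tone", {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- 2.5 * cos(2 * pi * 8 * t)
  bs <- band_analytic(x, fs, c(6, 10))
  mid <- seq(2 * fs, 18 * fs)
  expect_lt(max(abs(bs$amplitude[mid] - 2.5)) / 2.5, 0.02)
  # phase 0 at waveform peaks
  peaks <- which(diff(sign(diff(x))) < 0) + 1L
  peaks <- peaks[peaks > 2 * fs & peaks < 18 * fs]
  expect_lt(max(abs(circ_dist(bs$phase[peaks], 0))), 0.08)
  expect_error(band_analytic(x, fs, c(10, 6)), "increasing")
  expect_error(band_analytic(x, fs, c(6, 300)), "Nyquist")
})

test_that("chirp phase unwraps monotonically", {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- cos(2 * pi * (6 * t + 0.1 * t^2)) # 6 -> 10 Hz over 20 s
  bs <- band_analytic(x, fs, c(5, 11))
  u <- thetaspeech:::unwrap_phase(bs$phase[(2 * fs):(18 * fs)])
  expect_true(all(diff(u) > 0))
})

test_that("out-of-band energy does not leak into the band amplitude", {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  solo <- band_analytic(cos(2 * pi * 8 * t), fs, c(6, 10))
  both <- band_analytic(cos(2 * pi * 8 * t) + 2 * cos(2 * pi * 40 * t),
                        fs, c(6, 10))
  mid <- seq(2 * fs, 18 * fs)
  rel <- abs(both$amplitude[mid] - solo$amplitude[mid]) /
    solo$amplitude[mid]
  expect_lt(max(rel), 0.05)
})

test_that("PLV is exact for identical and constantly offset phases", {
  fs <- 200
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  x <- cos(2 * pi * 8 * t)
  bx <- band_analytic(x, fs, c(6, 10))
  by <- bx
  cg <- sliding_plv_coherogram(bx, by, events = c(10, 20, 30),
                               epoch_window = c(-1, 1))
  expect_true(all(abs(cg$coherence - 1) < 1e-9))
  # constant offset pi/3
  y <- cos(2 * pi * 8 * t - pi / 3)
  byo <- band_analytic(y, fs, c(6, 10))
  cg2 <- sliding_plv_coherogram(bx, byo, events = c(10, 20, 30),
                                epoch_window = c(-1, 1))
  expect_true(all(cg2$coherence > 0.999))
  md <- circ_mean(circ_dist(bx$phase[2000:6000], byo$phase[2000:6000]))
  expect_angle_near(md, pi / 3, 2)
})

test_that("null PLV matches the small-sample bias of the estimator", {
  # iid uniform phase differences, 100-sample windows: compare the
  # estimator with a direct Monte-Carlo of the within-window resultant
  fs <- 200
  n <- 60 * fs
  mkbs <- function(seed) {
    ph <- thetaspeech:::with_seed(seed, runif(n, -pi, pi))
    structure(list(amplitude = rep(1, n), phase = ph, filtered = NULL,
                   band = c(6, 10), fs = fs), class = "band_signal")
  }
  cg <- sliding_plv_coherogram(mkbs(1), mkbs(2), events = seq(5, 55, 2),
                               window_s = 0.5, epoch_window = c(-1, 1))
  nwin <- round(0.5 * fs) * 2 %/% 2 + 1
  mc <- thetaspeech:::with_seed(3, {
    mean(vapply(1:2000, function(i)
      Mod(mean(exp(1i * runif(101, -pi, pi)))), numeric(1)))
  })
  expect_lt(abs(mean(cg$coherence) - mc), 0.01)
})

test_that("PLV is invariant to a common phase rotation", {
  fs <- 200
  n <- 20 * fs
  ph1 <- thetaspeech:::with_seed(4, runif(n, -pi, pi))
  ph2 <- thetaspeech:::with_seed(5, runif(n, -pi, pi))
  mk <- function(p) structure(list(amplitude = rep(1, n), phase = wrap_pi(p),
                                   filtered = NULL, band = c(6, 10),
                                   fs = fs), class = "band_signal")
  a <- sliding_plv_coherogram(mk(ph1), mk(ph2), events = c(5, 10, 15),
                              epoch_window = c(-1, 1))
  b <- sliding_plv_coherogram(mk(ph1 + 1.1), mk(ph2 + 1.1),
                              events = c(5, 10, 15),
                              epoch_window = c(-1, 1))
  expect_equal(a$coherence, b$coherence, tolerance = 1e-9)
})

test_that("coherogram rejects windows shorter than two cycles", {
  fs <- 200
  x <- with_seed_rnorm(1, 30 * fs)
  expect_error(
    sliding_plv_coherogram(x, x, fs, events = 10, freqs = c(3, 8),
                           window_s = 0.5),
    "cycles")
})

test_that("coherence_change_stats: baseline against itself is zero", {
  mk <- function(seed) {
    co <- matrix(thetaspeech:::with_seed(seed, runif(10 * 41, 0.2, 0.4)),
                 10, 41)
    structure(list(times = seq(-1, 1, by = 0.05), freqs = 4:13,
                   coherence = co, n_events = 20, n_pairs = 1,
                   baseline_window = NULL), class = "coherogram")
  }
  cohs <- lapply(1:4, mk)
  st <- coherence_change_stats(cohs, subjects = c(1, 1, 2, 2),
                               baseline_window = c(-1, 1))
  # mean change over the whole (baseline = full) window is zero per row
  expect_lt(max(abs(rowMeans(st$effect))), 1e-12)
})

test_that("null coherograms are calibrated before FDR", {
  # per-cell one-sample t over subjects on exchangeable noise: the
  # uncorrected rejection rate should sit near alpha
  mk <- function(seed) {
    co <- matrix(thetaspeech:::with_seed(seed, runif(8 * 41, 0.2, 0.4)),
                 8, 41)
    structure(list(times = seq(-1, 1, by = 0.05), freqs = 4:11,
                   coherence = co, n_events = 20, n_pairs = 1,
                   baseline_window = NULL), class = "coherogram")
  }
  cohs <- lapply(1:12, mk)
  st <- coherence_change_stats(cohs, subjects = rep(1:6, each = 2))
  post <- st$times > 0
  rate <- mean(st$p[, post] < 0.05)
  # binomial CI is wide because cells are not fully independent
  expect_lt(rate, 0.12)
  expect_error(coherence_change_stats(cohs, subjects = rep(1, 12)),
               "subjects")
})

test_that("phase_offset_map classifies offsets and applies the 15-mm rule", {
  fs <- 200
  n <- 20 * fs
  base <- thetaspeech:::with_seed(6, runif(n, -pi, pi))
  mk <- function(off) structure(
    list(amplitude = rep(1, n), phase = wrap_pi(base + off),
         filtered = NULL, band = c(6, 10), fs = fs),
    class = "band_signal")
  bs <- list(ref = mk(0), same = mk(0), anti = mk(pi), oth = mk(pi / 2),
             near = mk(0.1))
  coords <- tibble::tibble(name = names(bs),
                           x = c(0, 30, 60, 90, 5),
                           y = 0, z = 0)
  pom <- phase_offset_map(bs, "ref", coords, min_dist_mm = 15)
  expect_equal(pom$class[pom$channel == "same"], "near-zero")
  expect_equal(pom$class[pom$channel == "anti"], "antiphase")
  expect_equal(pom$class[pom$channel == "oth"], "other")
  expect_true(pom$excluded[pom$channel == "near"])
  expect_false(pom$excluded[pom$channel == "same"])
  expect_equal(pom$offset[pom$channel == "ref"], 0)
  expect_equal(pom$plv[pom$channel == "ref"], 1)
  expect_error(phase_offset_map(bs, "missing", coords), "reference")
})

test_that("antiphase fraction is recovered from a generated session", {
  s <- make_session(session_config(duration_s = 30, seed = 9,
                                   n_channels = 20,
                                   antiphase_fraction = 0.25))
  fs <- s$recording$fs
  bs <- lapply(colnames(s$recording$data), function(ch)
    band_analytic(s$recording$data[, ch], fs, c(6, 10)))
  names(bs) <- colnames(s$recording$data)
  msk <- speech_mask(s$events, fs, nrow(s$recording$data))
  pom <- phase_offset_map(bs, s$ground_truth$reference_channel,
                          s$recording$channels, speech_mask = msk)
  expect_equal(sum(pom$class == "antiphase"),
               sum(s$ground_truth$channels$antiphase))
})
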