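test_that("locate_anchor_trough finds the nearest trough with tie rule", {
  fs <- 500
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- cos(2 * pi * 8.2 * t)
  bs <- band_analytic(x, fs, c(6, 10))
  idx <- locate_anchor_trough(bs, 5)
  # within half a cycle of the anchor
  expect_lt(abs(t[idx] - 5), 0.5 / 8.2 + 1 / fs)
  # phase at the returned sample is the trough (pi)
  expect_lt(abs(abs(bs$phase[idx]) - pi), 0.1)
  expect_error(locate_anchor_trough(bs, 99), "outside")
  # anchor exactly between two troughs: earlier trough wins. Use 10 Hz at
  # fs 500 so troughs fall on exact samples and the midpoint ties.
  x10 <- cos(2 * pi * 10 * t)
  bs10 <- band_analytic(x10, fs, c(8, 12))
  t1 <- t[locate_anchor_trough(bs10, 4.05)]
  t2 <- t[locate_anchor_trough(bs10, 4.05 + 0.1)]
  idx2 <- locate_anchor_trough(bs10, (t1 + t2) / 2)
  expect_equal(t[idx2], t1)
})

test_that("warping a constant-frequency signal equals time resampling", {
  fs <- 500
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  f0 <- 8
  phase <- wrap_pi(2 * pi * f0 * t) # trough pi at t = (k + 1/2)/f0
  sig <- sin(2 * pi * 1.3 * t) # arbitrary smooth signal
  anchor <- which.min(abs(t - (16 + 0.5) / f0)) # a trough mid-signal
  ep <- phase_warp_epochs(list(phase), list(s = list(sig)), anchor, fs,
                          n_points = 160)
  expect_equal(ep$phase_axis[1], -9 * pi)
  expect_equal(ep$phase_axis[160], 7 * pi)
  # psi = 2*pi*f0*(t - t_anchor): warped signal equals signal at
  # t_anchor + psi/(2*pi*f0)
  expected <- approx(t, sig,
                     xout = t[anchor] + ep$phase_axis / (2 * pi * f0))$y
  got <- ep$signals$s[1, ]
  ok <- !is.na(expected) & !is.na(got)
  expect_gt(sum(ok), 100)
  expect_lt(max(abs(got[ok] - expected[ok])), 1e-6)
})

test_that("trials with long phase slips are dropped and logged", {
  fs <- 100
  good <- seq(0, 40, length.out = 400)
  bad <- good
  bad[200:280] <- bad[200] - 0.5 # 0.8 s of decreasing phase
  ep <- phase_warp_epochs(list(good, bad),
                          list(s = list(sin(good), sin(bad))),
                          c(200, 200), fs, n_points = 80)
  expect_equal(ep$dropped, 2L)
  expect_equal(nrow(ep$signals$s), 1L)
  # a 30 ms slip is repaired instead
  small <- good
  small[200:202] <- small[199]
  ep2 <- phase_warp_epochs(list(small), list(s = list(sin(small))),
                           c(200), fs, n_points = 80)
  expect_equal(length(ep2$dropped), 0L)
})

test_that("phase-locked average flags locking and keeps nulls flat", {
  s <- get_session("s60")
  ep <- session_phase_epochs(s)
  expect_gt(nrow(ep$signals$ac), 20)
  pla <- phase_locked_average(ep, "ac", n_surrogates = 50, seed = 2)
  expect_equal(sum(pla$peak_hist$probability), 1, tolerance = 1e-9)
  # significant at the injected phase in at least 2 consecutive cycles
  tgt <- wrap_2pi(s$config$ac_preferred_phase - pi) # psi of pulses
  ax <- pla$phase_axis
  sig_cycles <- vapply(-3:2, function(cyc) {
    pos <- tgt + 2 * pi * cyc
    if (pos < min(ax) + 0.3 || pos > max(ax) - 0.3) return(NA)
    any((pla$mean > pla$null_hi)[abs(ax - pos) < 0.7], na.rm = TRUE)
  }, logical(1))
  runs <- rle(sig_cycles[!is.na(sig_cycles)])
  expect_gte(max(runs$lengths[runs$values]), 2)
  expect_error(phase_locked_average(ep, "nope"), "not present")
})

test_that("an unlocked signal stays inside the surrogate band", {
  axis <- seq(-9 * pi, 7 * pi, length.out = 160)
  M <- matrix(with_seed_rnorm(3, 40 * 160), 40, 160)
  ep <- structure(list(phase_axis = axis, signals = list(ac = M),
                       anchor_phase = pi, labels = NULL,
                       dropped = integer(0)), class = "phase_epochs")
  pla <- phase_locked_average(ep, "ac", n_surrogates = 50, seed = 4)
  inside <- pla$mean >= pla$null_lo & pla$mean <= pla$null_hi
  expect_gt(mean(inside), 0.9)
})

test_that("post-skip movements still occur at the preferred phase", {
  s <- get_session("s60")
  truth <- s$ground_truth$pulses
  skipped <- s$ground_truth$skipped_cycles
  expect_gt(length(skipped), 3)
  # for every skipped cycle, the next realised pulse keeps the phase
  nxt <- vapply(skipped, function(ts) {
    after <- truth$time[truth$time > ts]
    if (!length(after)) NA_real_ else truth$phase[truth$time == min(after)][1]
  }, numeric(1))
  nxt <- nxt[!is.na(nxt)]
  expect_true(all(abs(circ_dist(nxt, s$config$ac_preferred_phase)) < 0.05))
})

test_that("decoder recovers class structure at the injected phase", {
  ep <- simulate_phase_epochs(n_classes = 4, trials_per_class = 12,
                              n_electrodes = 10, pattern_phase = 0.5,
                              effect_size = 2, seed = 3)
  dr <- sliding_phase_decoder(ep, ep$labels$syllable,
                              phase_range = c(-pi, pi),
                              n_shuffles = 300, seed = 5)
  best <- dr$bin_centers[which.max(dr$accuracy)]
  expect_lt(abs(best - 0.5), 0.3)
  expect_gt(max(dr$accuracy, na.rm = TRUE), 0.8)
  # shuffle null sits at chance
  expect_equal(mean(dr$null_mean, na.rm = TRUE), 1 / 4, tolerance = 0.02)
  # pattern-free epochs: no bin beats its null
  ep0 <- simulate_phase_epochs(n_classes = 4, trials_per_class = 25,
                               n_electrodes = 10, effect_size = 0,
                               seed = 6)
  dr0 <- sliding_phase_decoder(ep0, ep0$labels$syllable,
                               phase_range = c(-pi, pi),
                               n_shuffles = 300, seed = 7)
  expect_false(any(dr0$significant))
  expect_true(all(abs(dr0$accuracy - 0.25) < 0.18, na.rm = TRUE))
})

test_that("classes below the repetition floor are dropped with a warning", {
  ep <- simulate_phase_epochs(n_classes = 3, trials_per_class = 12,
                              n_electrodes = 6, seed = 8)
  lab <- as.character(ep$labels$syllable)
  lab[lab == "syl03"][1:8] <- "syl01" # leaves syl03 with 4 trials
  expect_warning(
    dr <- sliding_phase_decoder(ep, lab, phase_range = c(0, 1),
                                n_shuffles = 60, seed = 9),
    "dropping")
  expect_equal(dr$n_classes, 2L)
})

test_that("combine_significant_bins weights and degenerates correctly", {
  ep <- simulate_phase_epochs(n_classes = 4, trials_per_class = 12,
                              n_electrodes = 10, pattern_phase = 0.5,
                              effect_size = 2, seed = 3)
  dr <- sliding_phase_decoder(ep, ep$labels$syllable,
                              phase_range = c(-pi, pi),
                              n_shuffles = 300, seed = 5)
  expect_gt(sum(dr$significant), 0)
  cmb <- combine_significant_bins(dr)
  expect_true(cmb$combined_accuracy > 0.7)
  expect_equal(sum(cmb$confusion), sum(!is.na(dr$predictions[, which(
    dr$significant)[1]])))
  # single significant bin: combined equals that bin's accuracy
  dr1 <- dr
  keep <- which(dr$significant)[1]
  dr1$significant[] <- FALSE
  dr1$significant[keep] <- TRUE
  cmb1 <- combine_significant_bins(dr1)
  expect_equal(cmb1$combined_accuracy, dr$accuracy[keep], tolerance = 1e-9)
  # equal weights match accuracy weights when accuracies are equal
  dr2 <- dr1
  dr2$accuracy[] <- 0.5
  expect_equal(combine_significant_bins(dr2, "equal")$combined_accuracy,
               combine_significant_bins(dr2, "accuracy")$combined_accuracy)
  # no significant bins: explicit status
  dr3 <- dr
  dr3$significant[] <- FALSE
  expect_equal(combine_significant_bins(dr3)$status, "no significant bins")
})
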