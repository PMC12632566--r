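# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

get_session <- function(key) {
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  s <- switch(key,
    s60 = make_session(session_config(duration_s = 60, seed = 4)),
    long4 = make_session(session_config(duration_s = 120, seed = 8,
                                        utterance_dur_s = 4)),
    grad = make_session(session_config(duration_s = 60, seed = 21,
                                       n_channels = 12,
                                       antiphase_fraction = 0)),
    err = make_session(session_config(duration_s = 120, seed = 31,
                                      n_channels = 6,
                                      error_trial_fraction = 0.35,
                                      antiphase_fraction = 0)),
    stop("unknown fixture key: ", key))
  .fixture_env[[key]] <- s
  s
}

# Theta-band analytic signal of the reference channel.
ref_theta <- function(s, band = c(6, 10)) {
  key <- paste0("theta_", s$config$seed, "_", paste(band, collapse = "_"))
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  out <- band_analytic(s$recording$data[, s$ground_truth$reference_channel],
                       s$recording$fs, band)
  .fixture_env[[key]] <- out
  out
}

# Unwrapped reference theta phase resampled onto the kinematic grid.
kin_theta_phase <- function(s, th = ref_theta(s)) {
  fs <- s$recording$fs
  nk <- nrow(s$kinematics$data)
  u <- thetaspeech:::unwrap_phase(th$phase)
  approx((seq_along(th$phase) - 1) / fs, u,
         xout = (seq_len(nk) - 1) / s$kinematics$fs, rule = 2)$y
}

with_seed_rnorm <- function(seed, n) thetaspeech:::with_seed(seed, rnorm(n))

expect_angle_near <- function(actual, expected, tol_deg) {
  d <- abs(circ_dist(actual, expected)) * 180 / pi
  expect_lt(d, tol_deg)
}
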