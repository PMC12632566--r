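# Synthetic session generator: narrowband theta oscillator over a 1/f
# background, inter-site phase offsets with an antiphase subset, high-gamma
# amplitude coupled to theta phase, and vocal-tract gesture pulses locked to
# a late theta phase with occasional skipped cycles.

TRACT_VARIABLES <- c(
  "lip_aperture", "lip_protrusion",
  "tongue_tip", "tongue_body", "tongue_root", "jaw"
)

#' Configuration for a synthetic speech-ECoG session
#'
#' Bundles every generator parameter with validation. Defaults encode the
#' study conditions the pipeline is designed around: a stable ~8.2 Hz
#' sensorimotor theta rhythm, high-gamma amplitude maximal near the theta
#' trough, articulatory-change (AC) pulses locked ~301 degrees into the
#' cycle (93 degrees after the high-gamma preferred phase), consonant
#' gestures flanking the vowel at ~0.125 s, and a cycle-skip probability
#' chosen so the AC pulse rate during fluent speech is ~7.3 pulses/s.
#'
#' @param n_channels Number of recording channels.
#' @param fs_lfp Field-potential sampling rate (Hz).
#' @param fs_kin Kinematic sampling rate (Hz).
#' @param duration_s Session duration (s); `duration_s * fs` must be integral.
#' @param theta_f0 Theta centre frequency (Hz).
#' @param theta_bandwidth Spectral full width at half maximum of the theta
#'   peak (Hz); smaller values give a more periodic rhythm.
#' @param aperiodic_exponent Exponent chi of the 1/f^chi background.
#' @param channel_phase_offsets Optional vector of per-channel phase offsets
#'   (radians in `[0, 2*pi)`); if `NULL`, a dorsoventral gradient plus an
#'   antiphase subset is drawn.
#' @param antiphase_fraction Proportion of channels oscillating in antiphase
#'   with the ventral reference site.
#' @param pac_depth High-gamma amplitude modulation depth in `[0, 1]`.
#' @param pac_phase Theta phase (radians) of maximal high-gamma amplitude.
#' @param ac_preferred_phase Theta phase (radians) at which AC pulses occur.
#' @param cycle_skip_prob Probability that a theta cycle carries no pulse.
#' @param syllable_rate Syllables per second during utterances.
#' @param triplet_spacing_s Spacing (s) of the consonant gestures flanking a
#'   vowel nucleus.
#' @param error_trial_fraction Proportion of utterances flagged as
#'   error/repair trials.
#' @param error_phase_jitter_sd Phase jitter SD (radians) applied to gesture
#'   timing on error trials.
#' @param hg_band High-gamma band edges (Hz).
#' @param utterance_dur_s,gap_s Utterance length and inter-utterance silence.
#' @param lock_preroll_s How long before utterance onset inter-site phase
#'   locking begins (s).
#' @param seed Integer seed; identical configs regenerate identical sessions.
#' @return A `session_config` list.
#' @export
session_config <- function(n_channels = 16,
                           fs_lfp = 1000,
                           fs_kin = 100,
                           duration_s = 60,
                           theta_f0 = 8.2,
                           theta_bandwidth = 1.5,
                           aperiodic_exponent = 1.5,
                           channel_phase_offsets = NULL,
                           antiphase_fraction = 0.2,
                           pac_depth = 0.4,
                           pac_phase = deg2rad(208),
                           ac_preferred_phase = deg2rad(301),
                           cycle_skip_prob = 0.11,
                           syllable_rate = 4,
                           triplet_spacing_s = 0.125,
                           error_trial_fraction = 0,
                           error_phase_jitter_sd = deg2rad(60),
                           hg_band = c(70, 150),
                           utterance_dur_s = 2,
                           gap_s = 1,
                           lock_preroll_s = 0.2,
                           seed = 1L) {
  for (nm in c("fs_lfp", "fs_kin", "duration_s", "theta_f0", "syllable_rate"))
    check_scalar(get(nm), nm, positive = TRUE)
  for (nm in c("antiphase_fraction", "pac_depth", "cycle_skip_prob",
               "error_trial_fraction"))
    check_proportion(get(nm), nm)
  if (theta_bandwidth < 0 || theta_bandwidth >= theta_f0)
    stopf("`theta_bandwidth` must lie in [0, theta_f0)")
  if (abs(duration_s * fs_lfp - round(duration_s * fs_lfp)) > 1e-9 ||
      abs(duration_s * fs_kin - round(duration_s * fs_kin)) > 1e-9)
    stopf("`duration_s` must give integral sample counts at both rates")
  if (hg_band[2] >= fs_lfp / 2)
    stopf("`hg_band` must lie below the Nyquist frequency")
  pac_phase <- wrap_2pi(pac_phase)
  ac_preferred_phase <- wrap_2pi(ac_preferred_phase)
  if (!is.null(channel_phase_offsets)) {
    if (length(channel_phase_offsets) != n_channels)
      stopf("`channel_phase_offsets` must have length `n_channels`")
    channel_phase_offsets <- wrap_2pi(channel_phase_offsets)
  }
  structure(
    list(
      n_channels = as.integer(n_channels), fs_lfp = fs_lfp, fs_kin = fs_kin,
      duration_s = duration_s, theta_f0 = theta_f0,
      theta_bandwidth = theta_bandwidth,
      aperiodic_exponent = aperiodic_exponent,
      channel_phase_offsets = channel_phase_offsets,
      antiphase_fraction = antiphase_fraction,
      pac_depth = pac_depth, pac_phase = pac_phase,
      ac_preferred_phase = ac_preferred_phase,
      cycle_skip_prob = cycle_skip_prob,
      syllable_rate = syllable_rate, triplet_spacing_s = triplet_spacing_s,
      error_trial_fraction = error_trial_fraction,
      error_phase_jitter_sd = error_phase_jitter_sd,
      hg_band = hg_band, utterance_dur_s = utterance_dur_s, gap_s = gap_s,
      lock_preroll_s = lock_preroll_s, seed = as.integer(seed)
    ),
    class = "session_config"
  )
}

# Complex narrowband analytic carrier; assumes the RNG is already seeded.
theta_carrier_analytic <- function(fs, n, f0, bandwidth) {
  t <- (seq_len(n) - 1L) / fs
  if (bandwidth == 0) {
    phi0 <- runif(1, 0, 2 * pi)
    return(exp(1i * (2 * pi * f0 * t + phi0)))
  }
  # FWHM of the power spectrum = bandwidth
  s_pow <- bandwidth / (2 * sqrt(2 * log(2)))
  s_amp <- s_pow * sqrt(2)
  f <- (seq_len(n) - 1L) * fs / n
  half <- floor(n / 2)
  keep <- 2:(half + 1L) # positive-frequency bins, DC excluded
  A <- exp(-(f[keep] - f0)^2 / (2 * s_amp^2))
  coefs <- complex(real = rnorm(length(keep)),
                   imaginary = rnorm(length(keep))) * A
  spec <- complex(length.out = n)
  spec[keep] <- coefs
  z <- fft(spec, inverse = TRUE) / sqrt(n)
  z / sd(Re(z))
}

#' Narrowband stochastic theta oscillator
#'
#' Generates a zero-mean waveform whose power spectrum is a Gaussian bump of
#' the given full width at half maximum centred on `f0` (frequency-domain
#' shaped Gaussian noise). `bandwidth = 0` gives a pure sinusoid with a
#' seeded random phase. Smaller bandwidth produces a more periodic signal
#' (larger secondary autocorrelation peak).
#'
#' @param fs Sampling rate (Hz).
#' @param duration_s Duration (s), at least 2.
#' @param f0 Centre frequency (Hz).
#' @param bandwidth Spectral FWHM (Hz), `0 <= bandwidth < f0`.
#' @param seed Integer seed.
#' @return Numeric waveform of length `fs * duration_s`, unit variance.
#' @export
theta_carrier <- function(fs, duration_s, f0, bandwidth = 1.5, seed = 1L) {
  check_scalar(fs, "fs", positive = TRUE)
  check_scalar(f0, "f0", positive = TRUE)
  if (duration_s < 2) stopf("`duration_s` must be at least 2 s")
  if (bandwidth < 0 || bandwidth >= f0)
    stopf("`bandwidth` must lie in [0, f0)")
  n <- round(fs * duration_s)
  with_seed(seed, Re(theta_carrier_analytic(fs, n, f0, bandwidth)))
}

#' Theta-phase-modulated high-gamma noise
#'
#' Band-limited Gaussian noise whose envelope is multiplied by
#' `1 + depth * cos(theta_phase - coupling_phase)`, emulating
#' phase-amplitude coupling of high-gamma amplitude to theta phase.
#'
#' @param theta_phase Instantaneous theta phase per sample (radians).
#' @param coupling_phase Phase of maximal amplitude (radians).
#' @param depth Modulation depth in `[0, 1]`; `0` gives a statistically
#'   unmodulated envelope.
#' @param hg_band Band edges (Hz) of the carrier noise.
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed.
#' @return Numeric waveform the length of `theta_phase`.
#' @export
pac_envelope_signal <- function(theta_phase, coupling_phase, depth,
                                hg_band = c(70, 150), fs = 1000, seed = 1L) {
  check_proportion(depth, "depth")
  if (hg_band[1] >= hg_band[2] || hg_band[2] >= fs / 2)
    stopf("`hg_band` must be increasing and below the Nyquist frequency")
  n <- length(theta_phase)
  with_seed(seed, {
    carrier <- fft_bandpass(rnorm(n), fs, hg_band, transition = 5)
    carrier <- carrier / sd(carrier)
    carrier * (1 + depth * cos(theta_phase - coupling_phase))
  })
}

#' Tract-variable kinematics container
#'
#' @param data Numeric matrix, samples by named tract variables.
#' @param fs Kinematic sampling rate (Hz).
#' @return A `tract_kinematics` object.
#' @export
tract_kinematics <- function(data, fs) {
  data <- as.matrix(data)
  if (is.null(colnames(data)))
    colnames(data) <- paste0("tv", seq_len(ncol(data)))
  structure(list(data = data, fs = fs, variables = colnames(data)),
            class = "tract_kinematics")
}

#' @export
print.tract_kinematics <- function(x, ...) {
  cat(sprintf("<tract_kinematics> %d variables x %d samples @ %g Hz\n",
              ncol(x$data), nrow(x$data), x$fs))
  invisible(x)
}

#' Theta-locked gesture-pulse kinematics
#'
#' Places Gaussian velocity bumps (sigma ~ 20 ms) in 2-4 randomly chosen
#' tract variables at the configured preferred theta phase of consecutive
#' cycles inside utterances. Each cycle's pulse is skipped with probability
#' `cycle_skip_prob`; pulses nearest a vowel nucleus are larger, with the
#' flanking cycles carrying the onset and coda consonant gestures. On error
#' trials the pulse timing receives Gaussian phase jitter.
#'
#' @param theta_phase Instantaneous theta phase per kinematic sample
#'   (radians, reference site).
#' @param fs Kinematic sampling rate (Hz).
#' @param cfg A [session_config()].
#' @param syllable_plan Event table containing `utterance` and `syllable`
#'   tier rows (see [make_session()]).
#' @param seed Integer seed.
#' @return A `tract_kinematics` object with a `pulse_truth` attribute: a
#'   tibble of realised pulse times, amplitudes, roles and the phase at the
#'   pulse, plus skipped-cycle times.
#' @export
gesture_pulse_kinematics <- function(theta_phase, fs, cfg, syllable_plan,
                                     seed = 1L) {
  n <- length(theta_phase)
  if (nrow(syllable_plan) == 0L || !any(syllable_plan$tier == "syllable")) {
    rlang::warn("empty syllable plan: returning zero kinematics")
    k <- tract_kinematics(
      matrix(0, n, length(TRACT_VARIABLES),
             dimnames = list(NULL, TRACT_VARIABLES)), fs)
    attr(k, "pulse_truth") <- list(
      pulses = tibble::tibble(time = numeric(0), amplitude = numeric(0),
                              role = character(0), phase = numeric(0),
                              utterance_id = integer(0)),
      skipped = numeric(0))
    return(k)
  }
  u <- unwrap_phase(theta_phase)
  tgrid <- (seq_len(n) - 1L) / fs
  utts <- syllable_plan[syllable_plan$tier == "utterance", ]
  sylls <- syllable_plan[syllable_plan$tier == "syllable", ]
  if (any(utts$offset_s > n / fs + 1e-9))
    stopf("syllable plan extends beyond the session duration")

  with_seed(seed, {
    # crossing times of the preferred phase, one per theta cycle
    m <- (u - cfg$ac_preferred_phase) / (2 * pi)
    cross_idx <- which(diff(floor(m)) > 0)
    cross_t <- tgrid[cross_idx] +
      (ceiling(m[cross_idx]) - m[cross_idx]) /
        pmax(diff(m)[cross_idx], 1e-12) / fs
    # keep crossings inside utterances
    utt_of <- vapply(cross_t, function(tt) {
      hit <- which(tt >= utts$onset_s & tt <= utts$offset_s)
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    keep <- !is.na(utt_of)
    cross_t <- cross_t[keep]
    utt_of <- utt_of[keep]
    # cycle skipping
    skip <- runif(length(cross_t)) < cfg$cycle_skip_prob
    skipped_t <- cross_t[skip]
    cross_t <- cross_t[!skip]
    utt_of <- utt_of[!skip]
    # roles and amplitudes: pulses nearest planned gesture targets
    role <- rep("filler", length(cross_t))
    amp <- rep(1.0, length(cross_t))
    assign_role <- function(target_t, lab, a) {
      for (tt in target_t) {
        if (!length(cross_t)) next
        j <- which.min(abs(cross_t - tt))
        if (abs(cross_t[j] - tt) < 1.2 / cfg$theta_f0 && role[j] == "filler") {
          role[j] <<- lab
          amp[j] <<- a
        }
      }
    }
    assign_role(sylls$nucleus_s, "vowel", 1.5)
    assign_role(sylls$nucleus_s - cfg$triplet_spacing_s, "onset_c", 1.1)
    assign_role(sylls$nucleus_s + cfg$triplet_spacing_s, "coda_c", 1.1)
    amp <- amp * exp(rnorm(length(amp), 0, 0.1))
    # error-trial phase jitter
    err_ids <- utts$utterance_id[!utts$fluent]
    is_err <- utt_of %in% match(err_ids, utts$utterance_id)
    if (any(is_err)) {
      jit <- rnorm(sum(is_err), 0, cfg$error_phase_jitter_sd)
      cross_t[is_err] <- cross_t[is_err] + jit / (2 * pi * cfg$theta_f0)
    }
    # velocity bumps in 2-4 tract variables per pulse
    vel <- matrix(0, n, length(TRACT_VARIABLES),
                  dimnames = list(NULL, TRACT_VARIABLES))
    sigma <- 0.02
    half <- ceiling(4 * sigma * fs)
    for (j in seq_along(cross_t)) {
      ctr <- round(cross_t[j] * fs) + 1L
      lo <- max(1L, ctr - half)
      hi <- min(n, ctr + half)
      if (lo > hi) next
      vars <- sample(length(TRACT_VARIABLES), sample(2:4, 1))
      # normalise by the synergy size so total squared speed is comparable
      bump <- amp[j] / sqrt(length(vars)) *
        exp(-(tgrid[lo:hi] - cross_t[j])^2 / (2 * sigma^2))
      for (v in vars)
        vel[lo:hi, v] <- vel[lo:hi, v] + sample(c(-1, 1), 1) * bump
    }
    # trapezoidal integration: rectangle-rule cumsum would shift the
    # trajectories by half a sample and bias the recovered pulse phase
    pos <- (apply(vel, 2, cumsum) - vel / 2) / fs
    phase_at <- approx(tgrid, u, xout = pmin(pmax(cross_t, 0), tgrid[n]))$y
    k <- tract_kinematics(pos, fs)
    attr(k, "pulse_truth") <- list(
      pulses = tibble::tibble(
        time = cross_t, amplitude = amp, role = role,
        phase = wrap_2pi(phase_at),
        utterance_id = utts$utterance_id[utt_of]),
      skipped = skipped_t)
    k
  })
}

# Utterance / syllable / phoneme plan; assumes the RNG is seeded.
make_event_plan <- function(cfg) {
  syll_inventory <- c("ri", "iz", "for", "li", "ju", "da", "ko", "ma",
                      "ne", "su", "ta", "vo")
  cons_inventory <- c("p", "t", "k", "b", "d", "g", "s", "m", "n", "l")
  step <- cfg$utterance_dur_s + cfg$gap_s
  onsets <- seq(1, cfg$duration_s - cfg$utterance_dur_s - 0.5, by = step)
  if (!length(onsets)) stopf("session too short for a single utterance")
  rows <- list()
  for (i in seq_along(onsets)) {
    on <- onsets[i]
    off <- on + cfg$utterance_dur_s
    rate <- cfg$syllable_rate * runif(1, 0.8, 1.2)
    # syllable durations vary around 1/rate as in natural speech
    gaps <- (1 / rate) * runif(ceiling((off - on) * rate), 0.75, 1.25)
    nuclei <- on + 0.35 + cumsum(c(0, gaps))
    nuclei <- nuclei[nuclei <= off - 0.2]
    fluent <- runif(1) >= cfg$error_trial_fraction
    rows[[length(rows) + 1L]] <- tibble::tibble(
      tier = "utterance", label = sprintf("utt%03d", i),
      onset_s = on, offset_s = off, nucleus_s = NA_real_,
      utterance_id = i, fluent = fluent,
      syllable_rate = length(nuclei) / (off - on))
    labs <- sample(syll_inventory, length(nuclei), replace = TRUE)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      tier = "syllable", label = labs,
      onset_s = nuclei - cfg$triplet_spacing_s,
      offset_s = nuclei + cfg$triplet_spacing_s,
      nucleus_s = nuclei, utterance_id = i, fluent = fluent,
      syllable_rate = length(nuclei) / (off - on))
    ph_on <- c(nuclei - cfg$triplet_spacing_s, nuclei,
               nuclei + cfg$triplet_spacing_s)
    ph_lab <- c(sample(cons_inventory, length(nuclei), replace = TRUE),
                substr(labs, nchar(labs), nchar(labs)),
                sample(cons_inventory, length(nuclei), replace = TRUE))
    ph_tier <- rep(c("C", "V", "C"), each = length(nuclei))
    ord <- order(ph_on)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      tier = "phoneme", label = paste0(ph_tier, ":", ph_lab)[ord],
      onset_s = ph_on[ord], offset_s = ph_on[ord] + 0.06,
      nucleus_s = NA_real_, utterance_id = i, fluent = fluent,
      syllable_rate = length(nuclei) / (off - on))
  }
  dplyr::bind_rows(rows)
}

# Shift syllable and phoneme annotation times onto the realised gesture
# pulses (vowel pulse for the nucleus, flanking consonant pulses for the
# onset and coda); events with no realised pulse keep their planned time.
realign_events <- function(events, pulses, tol_s) {
  snap <- function(tt, uid, role) {
    cand <- pulses[pulses$role == role & pulses$utterance_id == uid, ]
    if (!nrow(cand)) return(tt)
    j <- which.min(abs(cand$time - tt))
    if (abs(cand$time[j] - tt) <= tol_s) cand$time[j] else tt
  }
  syl <- which(events$tier == "syllable")
  for (i in syl) {
    uid <- events$utterance_id[i]
    nuc <- snap(events$nucleus_s[i], uid, "vowel")
    shift <- nuc - events$nucleus_s[i]
    events$nucleus_s[i] <- nuc
    events$onset_s[i] <- events$onset_s[i] + shift
    events$offset_s[i] <- events$offset_s[i] + shift
  }
  ph <- which(events$tier == "phoneme")
  for (i in ph) {
    uid <- events$utterance_id[i]
    role <- if (startsWith(events$label[i], "V")) "vowel" else NULL
    tt <- events$onset_s[i]
    if (is.null(role)) {
      # consonants: nearest onset or coda pulse
      t_on <- snap(tt, uid, "onset_c")
      t_cd <- snap(tt, uid, "coda_c")
      new <- if (abs(t_on - tt) <= abs(t_cd - tt)) t_on else t_cd
    } else new <- snap(tt, uid, role)
    events$offset_s[i] <- events$offset_s[i] + (new - events$onset_s[i])
    events$onset_s[i] <- new
  }
  events
}

# 1/f^chi background noise, unit variance; assumes seeded RNG.
pink_noise <- function(n, fs, exponent) {
  f <- (seq_len(n) - 1L) * fs / n
  half <- floor(n / 2)
  keep <- 2:(half + 1L)
  A <- pmax(f[keep], 0.5)^(-exponent / 2)
  spec <- complex(length.out = n)
  spec[keep] <- complex(real = rnorm(length(keep)),
                        imaginary = rnorm(length(keep))) * A
  x <- Re(fft(spec, inverse = TRUE)) / sqrt(n)
  x / sd(x)
}

#' Generate a complete synthetic session
#'
#' Composes the theta carrier, per-channel phase offsets (dorsoventral
#' gradient plus an antiphase subset), 1/f background, speech-gated
#' theta-coupled high-gamma, event annotations, and theta-locked gesture
#' kinematics into one consistent session with ground truth. Inter-site
#' phase locking is confined to utterances (beginning `lock_preroll_s`
#' before onset), so phase coherence rises with speech.
#'
#' @param cfg A [session_config()].
#' @return A `speech_session` list with elements `recording` (samples x
#'   channels matrix, sampling rate, channel table), `kinematics`
#'   (`tract_kinematics`), `events` (tibble), `ground_truth`, and `config`.
#' @export
make_session <- function(cfg) {
  stopifnot(inherits(cfg, "session_config"))
  n <- round(cfg$fs_lfp * cfg$duration_s)
  nk <- round(cfg$fs_kin * cfg$duration_s)
  with_seed(cfg$seed, {
    events <- make_event_plan(cfg)
    # channel geometry: z from ventral (0) to dorsal (40 mm)
    nch <- cfg$n_channels
    z <- seq(0, 40, length.out = nch)
    coords <- tibble::tibble(
      name = sprintf("ch%02d", seq_len(nch)),
      x = round(runif(nch, -5, 5), 2), y = round(runif(nch, -5, 5), 2),
      z = z, region = "vSMC", responsive = TRUE)
    if (is.null(cfg$channel_phase_offsets)) {
      n_anti <- round(cfg$antiphase_fraction * nch)
      offs <- deg2rad(40) * z / max(z) + rnorm(nch, 0, deg2rad(5))
      if (n_anti > 0) {
        anti_idx <- order(z, decreasing = TRUE)[seq_len(n_anti)]
        offs[anti_idx] <- pi + rnorm(n_anti, 0, deg2rad(10))
      } else anti_idx <- integer(0)
      offs[which.min(z)] <- 0
      offs <- wrap_2pi(offs)
    } else {
      offs <- cfg$channel_phase_offsets
      anti_idx <- which(abs(circ_dist(offs, pi)) < pi / 4)
    }
    # common carrier + per-channel independent carriers, blended by a
    # speech-locking mask
    z0 <- theta_carrier_analytic(cfg$fs_lfp, n, cfg$theta_f0,
                                 cfg$theta_bandwidth)
    tgrid <- (seq_len(n) - 1L) / cfg$fs_lfp
    utts <- events[events$tier == "utterance", ]
    lock <- numeric(n)
    for (i in seq_len(nrow(utts))) {
      # error/repair trials model a breakdown of coupling: sites keep
      # oscillating (theta power unchanged) but do not lock to the
      # common rhythm during those utterances
      if (!utts$fluent[i]) next
      a <- max(1L, round((utts$onset_s[i] - cfg$lock_preroll_s) *
                           cfg$fs_lfp) + 1L)
      b <- min(n, round(utts$offset_s[i] * cfg$fs_lfp))
      lock[a:b] <- 1
    }
    lock <- gauss_smooth(lock, cfg$fs_lfp, 0.05)
    speech_gain <- 1 + 1.5 * gauss_smooth(
      as.numeric(lock > 0.5), cfg$fs_lfp, 0.1)

    data <- matrix(0, n, nch, dimnames = list(NULL, coords$name))
    theta_phase_ch <- matrix(0, n, nch)
    for (k in seq_len(nch)) {
      zk <- theta_carrier_analytic(cfg$fs_lfp, n, cfg$theta_f0,
                                   max(cfg$theta_bandwidth, 0.5))
      zc <- exp(1i * offs[k]) * (lock * z0 + (1 - lock) * zk)
      thk <- Arg(zc)
      theta_phase_ch[, k] <- thk
      hg <- pac_envelope_signal(thk, cfg$pac_phase, cfg$pac_depth,
                                cfg$hg_band, cfg$fs_lfp,
                                seed = cfg$seed + 1000L + k)
      data[, k] <- Re(zc) + pink_noise(n, cfg$fs_lfp,
                                       cfg$aperiodic_exponent) +
        0.5 * hg * speech_gain
    }
    ref <- which.min(coords$z)
    uref <- unwrap_phase(theta_phase_ch[, ref])
    kin_t <- (seq_len(nk) - 1L) / cfg$fs_kin
    phase_kin <- approx(tgrid, uref, xout = kin_t, rule = 2)$y
    kin <- gesture_pulse_kinematics(phase_kin, cfg$fs_kin, cfg, events,
                                    seed = cfg$seed + 77L)
    # annotations mark *produced* speech: shift syllable/phoneme times to
    # the realised (theta-snapped) gesture pulses, and label the remaining
    # (filler) gestures as consonants so the phoneme tier covers all
    # produced constrictions
    pulses <- attr(kin, "pulse_truth")$pulses
    events <- realign_events(events, pulses, 1.2 / cfg$theta_f0)
    fillers <- pulses[pulses$role == "filler", ]
    if (nrow(fillers)) {
      events <- dplyr::bind_rows(events, tibble::tibble(
        tier = "phoneme", label = "C:x", onset_s = fillers$time,
        offset_s = fillers$time + 0.06, nucleus_s = NA_real_,
        utterance_id = fillers$utterance_id,
        fluent = events$fluent[match(fillers$utterance_id,
                                     events$utterance_id)],
        syllable_rate = events$syllable_rate[
          match(fillers$utterance_id, events$utterance_id)]))
      events <- events[order(events$utterance_id,
                             match(events$tier,
                                   c("utterance", "syllable", "phoneme")),
                             events$onset_s), ]
    }
    truth <- list(
      channels = dplyr::mutate(coords, phase_offset = offs,
                               antiphase = dplyr::row_number() %in% anti_idx,
                               pac_phase = cfg$pac_phase,
                               pac_depth = cfg$pac_depth),
      trials = dplyr::select(utts, "utterance_id", "fluent",
                             "syllable_rate"),
      pulses = attr(kin, "pulse_truth")$pulses,
      skipped_cycles = attr(kin, "pulse_truth")$skipped,
      reference_channel = coords$name[ref])
    structure(
      list(
        recording = structure(
          list(data = data, fs = cfg$fs_lfp, channels = coords),
          class = "speech_recording"),
        kinematics = kin,
        events = events,
        ground_truth = truth,
        config = cfg),
      class = "speech_session")
  })
}

#' @export
print.speech_session <- function(x, ...) {
  cat(sprintf(
    "<speech_session> %d channels x %g s @ %g Hz; %d utterances, %d syllables\n",
    ncol(x$recording$data), x$config$duration_s, x$recording$fs,
    sum(x$events$tier == "utterance"), sum(x$events$tier == "syllable")))
  invisible(x)
}

#' Logical mask of speech samples
#'
#' @param events Event table with an `utterance` tier.
#' @param fs Sampling rate (Hz).
#' @param n Number of samples.
#' @param pad_s Padding added around each utterance (s).
#' @return Logical vector of length `n`.
#' @export
speech_mask <- function(events, fs, n, pad_s = 0) {
  m <- logical(n)
  utts <- events[events$tier == "utterance", ]
  for (i in seq_len(nrow(utts))) {
    a <- max(1L, floor((utts$onset_s[i] - pad_s) * fs) + 1L)
    b <- min(n, ceiling((utts$offset_s[i] + pad_s) * fs))
    m[a:b] <- TRUE
  }
  m
}

#' Write a synthetic session to plain-text files
#'
#' Persists signals as TSV (`lfp.tsv`, `kinematics.tsv`), annotations as a
#' Praat TextGrid plus `events.tsv`, channel geometry as a BIDS-style
#' `electrodes.tsv`, and configuration plus ground truth as
#' `session.json`. [read_session()] round-trips the arrays to numeric
#' tolerance.
#'
#' @param session A `speech_session`.
#' @param directory Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_session <- function(session, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  if (file.access(directory, 2) != 0)
    stopf("directory `%s` is not writable", directory)
  paths <- file.path(directory, c(
    "lfp.tsv", "kinematics.tsv", "events.tsv", "electrodes.tsv",
    "annotations.TextGrid", "session.json"))
  utils::write.table(format(session$recording$data, digits = 10, trim = TRUE),
                     paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(session$kinematics$data, digits = 10,
                            trim = TRUE),
                     paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(session$events, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(session$ground_truth$channels[
    , c("name", "x", "y", "z", "region", "responsive")],
    paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(textgrid_lines(session$events, session$config$duration_s),
             paths[5])
  cfg <- session$config
  cfg$channel_phase_offsets <- as.numeric(cfg$channel_phase_offsets)
  jsonlite::write_json(
    list(config = unclass(cfg),
         ground_truth = list(
           channels = session$ground_truth$channels,
           trials = session$ground_truth$trials,
           pulses = session$ground_truth$pulses,
           skipped_cycles = session$ground_truth$skipped_cycles,
           reference_channel = session$ground_truth$reference_channel),
         fs_lfp = session$recording$fs, fs_kin = session$kinematics$fs),
    paths[6], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

textgrid_lines <- function(events, duration_s) {
  tiers <- c("utterance", "syllable", "phoneme")
  out <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
           "xmin = 0", sprintf("xmax = %g", duration_s),
           "tiers? <exists>", sprintf("size = %d", length(tiers)),
           "item []:")
  for (ti in seq_along(tiers)) {
    rows <- events[events$tier == tiers[ti], ]
    rows <- rows[order(rows$onset_s), ]
    # tile [0, duration] with labelled and empty intervals
    iv_on <- c(0, rows$onset_s)
    iv_off <- c(rows$onset_s[1], rows$offset_s)
    iv_lab <- c("", rows$label)
    fill_on <- rows$offset_s
    fill_off <- c(rows$onset_s[-1], duration_s)
    ok <- fill_off > fill_on + 1e-9
    iv_on <- c(iv_on, fill_on[ok])
    iv_off <- c(iv_off, fill_off[ok])
    iv_lab <- c(iv_lab, rep("", sum(ok)))
    ord <- order(iv_on)
    iv_on <- iv_on[ord]; iv_off <- iv_off[ord]; iv_lab <- iv_lab[ord]
    out <- c(out,
             sprintf("    item [%d]:", ti),
             '        class = "IntervalTier"',
             sprintf('        name = "%s"', tiers[ti]),
             "        xmin = 0",
             sprintf("        xmax = %g", duration_s),
             sprintf("        intervals: size = %d", length(iv_on)))
    for (j in seq_along(iv_on)) {
      out <- c(out,
               sprintf("        intervals [%d]:", j),
               sprintf("            xmin = %.6f", iv_on[j]),
               sprintf("            xmax = %.6f", iv_off[j]),
               sprintf('            text = "%s"', iv_lab[j]))
    }
  }
  out
}

#' Read a session written by [write_session()]
#'
#' @param directory Directory containing the session files.
#' @return A `speech_session` (ground truth restored from JSON).
#' @export
read_session <- function(directory) {
  js <- jsonlite::read_json(file.path(directory, "session.json"),
                            simplifyVector = TRUE)
  lfp <- as.matrix(utils::read.table(file.path(directory, "lfp.tsv"),
                                     header = TRUE, sep = "\t"))
  kin <- as.matrix(utils::read.table(file.path(directory, "kinematics.tsv"),
                                     header = TRUE, sep = "\t"))
  events <- tibble::as_tibble(utils::read.table(
    file.path(directory, "events.tsv"), header = TRUE, sep = "\t"))
  electrodes <- tibble::as_tibble(utils::read.table(
    file.path(directory, "electrodes.tsv"), header = TRUE, sep = "\t"))
  structure(
    list(
      recording = structure(
        list(data = lfp, fs = js$fs_lfp, channels = electrodes),
        class = "speech_recording"),
      kinematics = tract_kinematics(kin, js$fs_kin),
      events = events,
      ground_truth = lapply(js$ground_truth, function(el)
        if (is.data.frame(el)) tibble::as_tibble(el) else el),
      config = js$config),
    class = "speech_session")
}
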