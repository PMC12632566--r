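# Anchor epochs to theta troughs, warp signals onto a uniform unwrapped
# phase axis, phase-locked averaging with surrogate bands, and sliding
# phase-resolved decoding.

#' Locate the theta trough nearest an anchor time
#'
#' Troughs are where the unwrapped analytic phase crosses `pi` modulo
#' `2*pi` (phase convention: 0 = peak, pi = trough). Ties between two
#' equidistant troughs are broken toward the earlier one.
#'
#' @param theta A `band_signal` (from [band_analytic()]).
#' @param anchor_time Anchor time (s).
#' @param max_cycles Search radius in cycles (error beyond it).
#' @return Sample index of the trough.
#' @export
locate_anchor_trough <- function(theta, anchor_time, max_cycles = 2) {
  stopifnot(inherits(theta, "band_signal"))
  fs <- theta$fs
  n <- length(theta$phase)
  if (anchor_time < 0 || anchor_time > (n - 1) / fs)
    stopf("`anchor_time` lies outside the signal")
  u <- unwrap_phase(theta$phase)
  # crossings of pi + 2*pi*k
  m <- (u - pi) / (2 * pi)
  idx <- which(diff(floor(m)) > 0) + 1L
  if (!length(idx)) stopf("no theta trough found in the signal")
  tt <- (idx - 1L) / fs
  d <- abs(tt - anchor_time)
  cyc <- 1 / mean(theta$band)
  if (min(d) > max_cycles * cyc)
    stopf("no trough within %g cycles of the anchor", max_cycles)
  best <- which(d <= min(d) + 1e-9)
  idx[best[1]] # earlier trough on ties
}

#' Warp per-trial signals onto a uniform theta-phase axis
#'
#' For each trial, the unwrapped theta phase is re-referenced so the anchor
#' trough maps to phase 0, and every signal is linearly interpolated onto a
#' common uniform axis (default `[-9*pi, 7*pi]`). Phase points a trial does
#' not cover are left `NA` (edge-flagged, never extrapolated). Brief
#' non-monotonic phase slips are repaired by a running maximum; slips
#' longer than `max_slip_s` drop the trial.
#'
#' @param theta_phase List of per-trial wrapped or unwrapped theta phase
#'   vectors.
#' @param signals Named list; each element is a list (per trial) of equal-
#'   length numeric vectors (e.g. `list(ac = ..., hg = ...)`). A per-trial
#'   element may also be a samples x electrodes matrix.
#' @param anchor Integer vector: anchor trough sample index per trial.
#' @param fs Sampling rate (Hz) of the input series.
#' @param axis_range Phase axis endpoints (radians), default
#'   `c(-9*pi, 7*pi)`.
#' @param n_points Number of axis points (default 160, ten per half cycle).
#' @param labels Optional per-trial label tibble (syllable id, fluency ...).
#' @param max_slip_s Longest tolerated non-monotonic phase run (s).
#' @return A `phase_epochs` object: `phase_axis`, `signals` (named list of
#'   trials x points matrices or trials x electrodes x points arrays),
#'   `anchor_phase`, `labels`, `dropped` (indices of dropped trials).
#' @export
phase_warp_epochs <- function(theta_phase, signals, anchor, fs,
                              axis_range = c(-9 * pi, 7 * pi),
                              n_points = 160, labels = NULL,
                              max_slip_s = 0.05) {
  n_tr <- length(theta_phase)
  stopifnot(length(anchor) == n_tr)
  axis <- seq(axis_range[1], axis_range[2], length.out = n_points)
  keep <- logical(n_tr)
  warped <- lapply(signals, function(s) vector("list", n_tr))
  for (i in seq_len(n_tr)) {
    u <- unwrap_phase(theta_phase[[i]])
    du <- diff(u)
    if (any(du <= 0)) {
      runs <- rle(du <= 0)
      bad <- max(runs$lengths[runs$values])
      if (bad / fs > max_slip_s) next # phase slip: drop trial
      u <- cummax(u)
      u <- u + (seq_along(u) - 1L) * 1e-8 # break repaired flats
    }
    psi <- u - u[anchor[i]]
    keep[i] <- TRUE
    for (nm in names(signals)) {
      x <- signals[[nm]][[i]]
      if (is.matrix(x)) {
        warped[[nm]][[i]] <- apply(x, 2, function(col)
          approx(psi, col, xout = axis, rule = 1, ties = "ordered")$y)
      } else {
        warped[[nm]][[i]] <- approx(psi, x, xout = axis, rule = 1,
                                    ties = "ordered")$y
      }
    }
  }
  if (!any(keep)) stopf("every trial was dropped (phase slips)")
  out <- lapply(warped, function(lst) {
    lst <- lst[keep]
    if (is.matrix(lst[[1]])) {
      arr <- array(NA_real_,
                   c(length(lst), ncol(lst[[1]]), n_points))
      for (i in seq_along(lst)) arr[i, , ] <- t(lst[[i]])
      arr
    } else {
      do.call(rbind, lst)
    }
  })
  structure(list(phase_axis = axis, signals = out,
                 anchor_phase = pi,
                 labels = if (!is.null(labels)) labels[keep, , drop = FALSE]
                          else NULL,
                 dropped = which(!keep)),
            class = "phase_epochs")
}

#' @export
print.phase_epochs <- function(x, ...) {
  nt <- if (is.matrix(x$signals[[1]])) nrow(x$signals[[1]])
        else dim(x$signals[[1]])[1]
  cat(sprintf(
    "<phase_epochs> %d trials, axis [%.3g, %.3g] rad, %d points; signals: %s\n",
    nt, min(x$phase_axis), max(x$phase_axis), length(x$phase_axis),
    paste(names(x$signals), collapse = ", ")))
  invisible(x)
}

#' Phase-locked average with a circular-shift surrogate band
#'
#' Averages a warped signal across trials per phase point and builds a null
#' band by circularly shifting each trial's signal along the phase axis
#' (equivalent to circularly shifting its theta phases and re-warping).
#' Also returns the normalised histogram of per-trial signal-peak phases
#' (wrapped to one cycle).
#'
#' @param epochs A `phase_epochs`.
#' @param signal Name of the warped signal (e.g. `"ac"`, `"hg"`).
#' @param n_surrogates Number of surrogate re-warps, default 50.
#' @param min_trials Minimum trial count.
#' @param probs Null-band quantiles.
#' @param seed Integer seed.
#' @return A `phase_locked_average`: `phase_axis`, `mean`, `null_lo`,
#'   `null_hi`, `null_mean`, `peak_hist` (tibble: bin centre, probability),
#'   `n_trials`.
#' @export
phase_locked_average <- function(epochs, signal = "ac", n_surrogates = 50,
                                 min_trials = 20, probs = c(0.025, 0.975),
                                 seed = 1L) {
  stopifnot(inherits(epochs, "phase_epochs"))
  M <- epochs$signals[[signal]]
  if (is.null(M)) stopf("signal `%s` not present in the epochs", signal)
  if (length(dim(M)) == 3L) M <- apply(M, c(1, 3), mean) # pool electrodes
  if (nrow(M) < min_trials)
    stopf("insufficient data: %d trials (< %d)", nrow(M), min_trials)
  axis <- epochs$phase_axis
  npt <- length(axis)
  mu <- colMeans(M, na.rm = TRUE)
  sur <- with_seed(seed, {
    vapply(seq_len(n_surrogates), function(s) {
      shifts <- sample(npt - 1L, nrow(M), replace = TRUE)
      S <- M
      for (i in seq_len(nrow(M))) {
        k <- shifts[i]
        S[i, ] <- c(M[i, (k + 1L):npt], M[i, 1:k])
      }
      colMeans(S, na.rm = TRUE)
    }, numeric(npt))
  })
  # per-trial peak phases wrapped to one cycle
  pk <- unlist(lapply(seq_len(nrow(M)), function(i) {
    x <- M[i, ]
    ok <- !is.na(x)
    if (sum(ok) < 5L) return(numeric(0))
    idx <- find_peaks(ifelse(ok, x, -Inf),
                      min_height = stats::quantile(x[ok], 0.75),
                      min_sep = 3L)
    axis[idx]
  }))
  hb <- seq(0, 2 * pi, length.out = 25)
  hcount <- if (length(pk)) tabulate(bin_index(pk, 24), 24) else rep(0L, 24)
  hist_tbl <- tibble::tibble(
    phase = (hb[-1] + hb[-25]) / 2,
    probability = if (sum(hcount)) hcount / sum(hcount) else rep(0, 24))
  structure(list(phase_axis = axis, mean = mu,
                 null_lo = apply(sur, 1, quantile, probs[1], na.rm = TRUE),
                 null_hi = apply(sur, 1, quantile, probs[2], na.rm = TRUE),
                 null_mean = rowMeans(sur, na.rm = TRUE),
                 peak_hist = hist_tbl, n_trials = nrow(M),
                 signal = signal, n_surrogates = n_surrogates),
            class = "phase_locked_average")
}

# One-vs-rest linear SVM: returns per-trial class scores and predictions.
ovr_svm <- function(train_x, train_y, test_x, cost = 1) {
  classes <- levels(train_y)
  scores <- matrix(0, nrow(test_x), length(classes),
                   dimnames = list(NULL, classes))
  for (ci in seq_along(classes)) {
    yy <- factor(train_y == classes[ci], levels = c(FALSE, TRUE))
    fit <- e1071::svm(train_x, yy, kernel = "linear", cost = cost,
                      scale = FALSE)
    dv <- attr(predict(fit, test_x, decision.values = TRUE),
               "decision.values")
    # orient decision values so positive = member of the class
    sgn <- if (grepl("^TRUE", colnames(dv)[1])) 1 else -1
    scores[, ci] <- sgn * dv[, 1]
  }
  list(scores = scores,
       pred = factor(classes[max.col(scores)], levels = classes))
}

#' Sliding-window phase-resolved syllable decoder
#'
#' Trains a linear one-vs-rest SVM on high-gamma features averaged within a
#' sliding phase window, with stratified cross-validation, a label-shuffle
#' null per bin, and Benjamini-Hochberg selection of significant bins.
#' Classes with fewer than `min_repetitions` trials are dropped with a
#' warning.
#'
#' @param epochs A `phase_epochs` whose decoded signal is a trials x
#'   electrodes x phase array.
#' @param labels Factor (or character) of trial labels.
#' @param signal Name of the 3-D signal in `epochs` (default `"hg"`).
#' @param window_rad Phase window width (radians), default 0.3.
#' @param step_rad Window step; defaults to `window_rad`.
#' @param phase_range Restrict decoding to this part of the axis.
#' @param n_shuffles Label shuffles for the per-bin null.
#' @param cv_folds Stratified cross-validation folds.
#' @param cost SVM cost grid; length > 1 triggers nested 3-fold selection.
#' @param min_repetitions Minimum trials per class.
#' @param q FDR level for the significant-bin mask.
#' @param refit Retrain the classifier on each shuffle (slow) instead of
#'   permuting labels against the stored cross-validated predictions.
#' @param seed Integer seed.
#' @return A `decoding_result`: `bin_centers`, `accuracy`, `null_mean`,
#'   `null_lo`, `null_hi`, `p`, `significant`, `scores` (trials x classes x
#'   bins), `predictions`, `labels`, `n_classes`, `chance`.
#' @export
sliding_phase_decoder <- function(epochs, labels, signal = "hg",
                                  window_rad = 0.3, step_rad = NULL,
                                  phase_range = NULL, n_shuffles = 200,
                                  cv_folds = 5, cost = 1,
                                  min_repetitions = 10, q = 0.05,
                                  refit = FALSE, seed = 1L) {
  stopifnot(inherits(epochs, "phase_epochs"))
  A <- epochs$signals[[signal]]
  if (is.null(A) || length(dim(A)) != 3L)
    stopf("signal `%s` must be a trials x electrodes x phase array", signal)
  labels <- factor(labels)
  counts <- table(labels)
  drop_cls <- names(counts)[counts < min_repetitions]
  if (length(drop_cls)) {
    rlang::warn(sprintf("dropping %d class(es) below %d repetitions: %s",
                        length(drop_cls), min_repetitions,
                        paste(drop_cls, collapse = ", ")))
    sel <- !labels %in% drop_cls
    A <- A[sel, , , drop = FALSE]
    labels <- droplevels(labels[sel])
  }
  K <- nlevels(labels)
  if (K < 2L) stopf("at least two classes are required")
  axis <- epochs$phase_axis
  if (is.null(step_rad)) step_rad <- window_rad
  if (is.null(phase_range)) phase_range <- range(axis)
  centers <- seq(phase_range[1] + window_rad / 2,
                 phase_range[2] - window_rad / 2, by = step_rad)
  n_tr <- dim(A)[1]
  with_seed(seed, {
    # stratified folds
    fold <- integer(n_tr)
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
    }
    acc <- numeric(length(centers))
    scores <- array(NA_real_, c(n_tr, K, length(centers)),
                    dimnames = list(NULL, levels(labels), NULL))
    preds <- matrix(NA_character_, n_tr, length(centers))
    for (bi in seq_along(centers)) {
      sel <- axis >= centers[bi] - window_rad / 2 &
             axis <= centers[bi] + window_rad / 2
      feat <- apply(A[, , sel, drop = FALSE], c(1, 2), mean)
      ok_tr <- stats::complete.cases(feat)
      for (k in seq_len(cv_folds)) {
        tr <- fold != k & ok_tr
        te <- fold == k & ok_tr
        if (!any(te) || length(unique(labels[tr])) < K) next
        mu <- colMeans(feat[tr, , drop = FALSE])
        sg <- pmax(apply(feat[tr, , drop = FALSE], 2, sd), 1e-12)
        trx <- sweep(sweep(feat[tr, , drop = FALSE], 2, mu), 2, sg, "/")
        tex <- sweep(sweep(feat[te, , drop = FALSE], 2, mu), 2, sg, "/")
        cc <- if (length(cost) > 1L)
          select_cost(trx, labels[tr], cost) else cost
        res <- ovr_svm(trx, labels[tr], tex, cc)
        scores[te, , bi] <- res$scores
        preds[te, bi] <- as.character(res$pred)
      }
      ok <- !is.na(preds[, bi])
      acc[bi] <- if (any(ok)) mean(preds[ok, bi] == labels[ok]) else NA_real_
    }
    # shuffle null per bin
    null_acc <- matrix(NA_real_, n_shuffles, length(centers))
    for (s in seq_len(n_shuffles)) {
      perm <- sample(labels)
      for (bi in seq_along(centers)) {
        ok <- !is.na(preds[, bi])
        if (!any(ok)) next
        null_acc[s, bi] <- if (refit) {
          refit_accuracy(A, perm, axis, centers[bi], window_rad, fold,
                         cv_folds, cost)
        } else mean(preds[ok, bi] == perm[ok])
      }
    }
    p <- vapply(seq_along(centers), function(bi) {
      if (is.na(acc[bi])) return(NA_real_)
      (1 + sum(null_acc[, bi] >= acc[bi], na.rm = TRUE)) /
        (1 + sum(!is.na(null_acc[, bi])))
    }, numeric(1))
    ok_p <- !is.na(p)
    sig <- logical(length(p))
    if (any(ok_p)) sig[ok_p] <- bh_fdr(p[ok_p], q)$significant
    structure(list(bin_centers = centers, accuracy = acc,
                   null_mean = colMeans(null_acc, na.rm = TRUE),
                   null_lo = apply(null_acc, 2, quantile, 0.025,
                                   na.rm = TRUE),
                   null_hi = apply(null_acc, 2, quantile, 0.975,
                                   na.rm = TRUE),
                   p = p, significant = sig, scores = scores,
                   predictions = preds, labels = labels,
                   n_classes = K, chance = 1 / K,
                   window_rad = window_rad),
              class = "decoding_result")
  })
}

select_cost <- function(x, y, cost, inner_folds = 3) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- rep_len(seq_len(inner_folds), length(idx))
  }
  accs <- vapply(cost, function(cc) {
    mean(vapply(seq_len(inner_folds), function(k) {
      tr <- fold != k
      if (length(unique(y[tr])) < nlevels(y)) return(NA_real_)
      res <- ovr_svm(x[tr, , drop = FALSE], y[tr],
                     x[!tr, , drop = FALSE], cc)
      mean(res$pred == y[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  cost[which.max(accs)]
}

refit_accuracy <- function(A, labels, axis, center, window_rad, fold,
                           cv_folds, cost) {
  sel <- axis >= center - window_rad / 2 & axis <= center + window_rad / 2
  feat <- apply(A[, , sel, drop = FALSE], c(1, 2), mean)
  ok_tr <- stats::complete.cases(feat)
  pred <- rep(NA_character_, length(labels))
  for (k in seq_len(cv_folds)) {
    tr <- fold != k & ok_tr
    te <- fold == k & ok_tr
    if (!any(te) || length(unique(labels[tr])) < nlevels(labels)) next
    mu <- colMeans(feat[tr, , drop = FALSE])
    sg <- pmax(apply(feat[tr, , drop = FALSE], 2, sd), 1e-12)
    trx <- sweep(sweep(feat[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    tex <- sweep(sweep(feat[te, , drop = FALSE], 2, mu), 2, sg, "/")
    pred[te] <- as.character(ovr_svm(trx, labels[tr], tex,
                                     cost[1])$pred)
  }
  ok <- !is.na(pred)
  if (any(ok)) mean(pred[ok] == as.character(labels)[ok]) else NA_real_
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "<decoding_result> %d classes, %d bins; peak accuracy %.1f%% (chance %.1f%%), %d significant bin(s)\n",
    x$n_classes, length(x$bin_centers), 100 * max(x$accuracy, na.rm = TRUE),
    100 * x$chance, sum(x$significant, na.rm = TRUE)))
  invisible(x)
}

#' Combine classifier outputs across significant phase bins
#'
#' Sums per-trial class scores over the significant bins, weighted by each
#' bin's accuracy, takes the arg-max decision, and reports the combined
#' accuracy and confusion matrix.
#'
#' @param result A `decoding_result`.
#' @param weights `"accuracy"` (default) or `"equal"`.
#' @return List with `combined_accuracy`, `confusion` (true class x
#'   predicted class counts), `n_bins_combined`; when no bin is
#'   significant, `combined_accuracy` is `NULL` and `status` says so.
#' @export
combine_significant_bins <- function(result, weights = c("accuracy",
                                                         "equal")) {
  stopifnot(inherits(result, "decoding_result"))
  weights <- match.arg(weights)
  use <- which(result$significant & !is.na(result$accuracy))
  if (!length(use)) {
    return(list(combined_accuracy = NULL, confusion = NULL,
                n_bins_combined = 0L, status = "no significant bins"))
  }
  w <- if (weights == "accuracy") result$accuracy[use] else rep(1,
                                                                length(use))
  w <- w / sum(w)
  S <- 0
  for (j in seq_along(use)) S <- S + w[j] * result$scores[, , use[j]]
  ok <- stats::complete.cases(S)
  cls <- colnames(result$scores)
  pred <- factor(cls[max.col(S[ok, , drop = FALSE])], levels = cls)
  truth <- factor(as.character(result$labels)[ok], levels = cls)
  list(combined_accuracy = mean(pred == truth),
       confusion = table(truth = truth, predicted = pred),
       n_bins_combined = length(use))
}

#' Simulate phase-aligned epochs with class-specific patterns
#'
#' Generates a `phase_epochs` object directly on the uniform phase axis:
#' high-gamma is unit Gaussian noise per (trial, electrode, phase point),
#' plus a class-specific random electrode pattern active in a Gaussian
#' window centred `pattern_phase` radians into the cycle structure.
#' Emulates syllable-specific population activity appearing at a fixed
#' theta phase; used to validate the phase-resolved decoder.
#'
#' @param n_classes Number of syllable classes.
#' @param trials_per_class Trials per class.
#' @param n_electrodes Electrodes.
#' @param pattern_phase Centre (radians on the warped axis) of the
#'   discriminative window.
#' @param pattern_width Gaussian SD (radians) of the window.
#' @param effect_size Pattern amplitude in noise-SD units (0 = null).
#' @param axis_range,n_points Phase axis, as in [phase_warp_epochs()].
#' @param seed Integer seed.
#' @return A `phase_epochs` with signal `hg` and a `labels` tibble.
#' @export
simulate_phase_epochs <- function(n_classes = 12, trials_per_class = 10,
                                  n_electrodes = 16, pattern_phase = 0.5,
                                  pattern_width = 0.25, effect_size = 1.5,
                                  axis_range = c(-9 * pi, 7 * pi),
                                  n_points = 160, seed = 1L) {
  axis <- seq(axis_range[1], axis_range[2], length.out = n_points)
  n_tr <- n_classes * trials_per_class
  with_seed(seed, {
    patt <- matrix(rnorm(n_classes * n_electrodes), n_classes)
    envl <- exp(-(axis - pattern_phase)^2 / (2 * pattern_width^2))
    A <- array(rnorm(n_tr * n_electrodes * n_points),
               c(n_tr, n_electrodes, n_points))
    lab <- rep(seq_len(n_classes), each = trials_per_class)
    for (i in seq_len(n_tr))
      A[i, , ] <- A[i, , ] + effect_size * outer(patt[lab[i], ], envl)
    structure(list(phase_axis = axis, signals = list(hg = A),
                   anchor_phase = pi,
                   labels = tibble::tibble(
                     syllable = sprintf("syl%02d", lab)),
                   dropped = integer(0)),
              class = "phase_epochs")
  })
}

#' Build phase-warped epochs around syllable nuclei of a session
#'
#' Convenience pipeline step: theta-filters the chosen channel, keeps
#' syllables preceded by `quiet_s` of sub-threshold articulatory change,
#' anchors each epoch to the trough nearest the nucleus, and warps AC and
#' high-gamma onto the uniform phase axis.
#'
#' @param session A `speech_session`.
#' @param channel Channel name; defaults to the ground-truth reference.
#' @param theta_band Theta band (Hz pair).
#' @param hg_band High-gamma band (Hz pair).
#' @param quiet_s Required silent-articulation span before the nucleus (s);
#'   `0` disables the isolation filter.
#' @param epoch_s Epoch half-width (s) around each nucleus.
#' @param axis_range,n_points Phase axis, as in [phase_warp_epochs()].
#' @return A `phase_epochs` with signals `ac` and `hg` and syllable labels.
#' @export
session_phase_epochs <- function(session, channel = NULL,
                                 theta_band = c(6, 10),
                                 hg_band = c(70, 150), quiet_s = 0,
                                 epoch_s = 1.2,
                                 axis_range = c(-9 * pi, 7 * pi),
                                 n_points = 160) {
  stopifnot(inherits(session, "speech_session"))
  if (is.null(channel)) channel <- session$ground_truth$reference_channel
  fs <- session$recording$fs
  x <- session$recording$data[, channel]
  th <- band_analytic(x, fs, theta_band)
  hg <- band_analytic(x, fs, hg_band, transition = 5)$amplitude
  ack <- articulatory_change(session$kinematics)
  ac <- approx((seq_along(ack) - 1L) / session$kinematics$fs, ack,
               xout = (seq_along(x) - 1L) / fs, rule = 2)$y
  sylls <- session$events[session$events$tier == "syllable", ]
  if (quiet_s > 0) {
    thr <- median(ac[speech_mask(session$events, fs, length(ac))]) +
      stats::mad(ac[speech_mask(session$events, fs, length(ac))])
    keep <- vapply(sylls$nucleus_s, function(tt) {
      a <- round((tt - quiet_s - 0.06) * fs) + 1L
      b <- round((tt - 0.06) * fs)
      a >= 1L && b <= length(ac) && all(ac[a:b] < thr)
    }, logical(1))
    sylls <- sylls[keep, ]
  }
  n <- length(x)
  half <- round(epoch_s * fs)
  phase_l <- list(); ac_l <- list(); hg_l <- list(); lab <- list()
  anchors <- integer(0)
  for (i in seq_len(nrow(sylls))) {
    ctr <- round(sylls$nucleus_s[i] * fs) + 1L
    a <- ctr - half
    b <- ctr + half
    if (a < 1L || b > n) next
    tr_idx <- tryCatch(
      locate_anchor_trough(th, sylls$nucleus_s[i]),
      error = function(e) NA_integer_)
    if (is.na(tr_idx) || tr_idx < a || tr_idx > b) next
    phase_l[[length(phase_l) + 1L]] <- th$phase[a:b]
    ac_l[[length(ac_l) + 1L]] <- ac[a:b]
    hg_l[[length(hg_l) + 1L]] <- hg[a:b]
    anchors <- c(anchors, tr_idx - a + 1L)
    lab[[length(lab) + 1L]] <- sylls[i, c("label", "utterance_id", "fluent")]
  }
  if (!length(phase_l)) stopf("no usable syllable epochs")
  phase_warp_epochs(phase_l, list(ac = ac_l, hg = hg_l), anchors, fs,
                    axis_range, n_points, labels = dplyr::bind_rows(lab))
}
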