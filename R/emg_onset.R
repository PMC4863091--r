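#' EMG envelope for movement-onset detection
#'
#' High-pass filters the EMG at 10 Hz (6th-order Butterworth, zero-phase),
#' takes the magnitude of the analytic signal (Hilbert envelope), smooths it
#' with a moving average, and z-scores the result over the whole trial. The
#' EMG-based movement onset is then the first sustained zero upcrossing of
#' this envelope after the move cue.
#'
#' @param x numeric vector, one EMG channel (microvolt).
#' @param fs sampling rate, Hz.
#' @param smooth moving-average window, s.
#' @param hp_cutoff high-pass cutoff, Hz.
#' @param normalize z-score the smoothed envelope (the onset rule needs the
#'   z-scored form; `FALSE` returns the envelope in signal units).
#' @return Numeric vector (z-units, or signal units when `normalize = FALSE`),
#'   same length as `x`.
#' @export
emg_envelope <- function(x, fs, smooth = 0.2, hp_cutoff = 10,
                         normalize = TRUE) {
  n <- length(x)
  win <- max(1L, round(smooth * fs))
  if (n < fs) stop("signal shorter than the 1 s filter warm-up")
  if (n < win) stop("signal shorter than the smoothing window")
  bf <- signal::butter(6, hp_cutoff / (fs / 2), type = "high")
  xf <- signal::filtfilt(bf, x)
  env <- Mod(analytic_signal(xf))
  # moving average with edge replication so the output keeps full length
  pad <- c(rep(env[1], win), env, rep(env[n], win))
  sm <- stats::filter(pad, rep(1 / win, win), sides = 2)
  sm <- as.numeric(sm[(win + 1):(win + n)])
  if (!normalize) return(sm)
  s <- sd(sm)
  if (s == 0) return(numeric(n))   # constant envelope: no burst to normalize
  (sm - mean(sm)) / s
}

# Analytic signal via the frequency domain: positive frequencies doubled,
# negative zeroed.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Detect the EMG-based movement onset of one trial
#'
#' The moved arm's EMG channels are selected via the trial's arm label
#' (biceps and triceps; the earlier sustained crossing wins). The onset is
#' the first time at or after the move cue at which the z-scored envelope
#' exceeds zero and stays positive for at least `sustain` seconds. Trials
#' whose onset falls before `early_bound` or after `late_bound` seconds
#' post-cue-2 are flagged for rejection; an envelope that never crosses is
#' treated as a late (absent) movement.
#'
#' @param trial a cue-referenced [new_trial()].
#' @param early_bound,late_bound screening bounds, s post-cue-2.
#' @param sustain minimum time the envelope must stay positive, s.
#' @param smooth envelope smoothing window, s.
#' @return A list with `onset` (s post-cue-2, `NA` if no crossing),
#'   `accepted`, and `reason` (`"early"`, `"late"`, or `"none"`).
#' @export
detect_onset <- function(trial, early_bound = 3, late_bound = 11,
                         sustain = 0.1, smooth = 0.2) {
  if (trial$time_ref != "cue")
    stop("onset detection requires a cue-referenced trial")
  fs <- trial$fs
  chans <- if (trial$arm == "left") c("biceps_left", "triceps_left") else
    c("biceps_right", "triceps_right")
  chans <- intersect(chans, rownames(trial$emg))
  if (!length(chans)) stop("no EMG channel found for the moved arm")
  cue2 <- unname(trial$cues["cue2"])
  i2 <- max(1L, floor((cue2 - trial$t0) * fs) + 1L)
  m <- max(1L, round(sustain * fs))
  best <- Inf
  for (ch in chans) {
    env <- emg_envelope(trial$emg[ch, ], fs, smooth = smooth)
    pos <- env[i2:length(env)] > 0
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= m)
    if (length(hit)) {
      i_on <- i2 + starts[hit[1]] - 1L
      t_on <- trial$t0 + (i_on - 1) / fs
      best <- min(best, t_on - cue2)
    }
  }
  if (!is.finite(best))
    return(list(onset = NA_real_, accepted = FALSE, reason = "late"))
  reason <- if (best < early_bound) "early" else
    if (best > late_bound) "late" else "none"
  list(onset = best, accepted = reason == "none", reason = reason)
}

#' Detect onsets for every trial of a session
#'
#' @inheritParams detect_onset
#' @param session a cue-referenced [new_session()].
#' @return Data frame with one row per trial: `trial`, `arm`, `onset`
#'   (s post-cue-2), `accepted`, `reason`.
#' @export
detect_onsets <- function(session, early_bound = 3, late_bound = 11,
                          sustain = 0.1, smooth = 0.2) {
  res <- lapply(session$trials, detect_onset, early_bound = early_bound,
                late_bound = late_bound, sustain = sustain, smooth = smooth)
  data.frame(
    trial = seq_along(res),
    arm = vapply(session$trials, `[[`, "", "arm"),
    onset = vapply(res, `[[`, 0, "onset"),
    accepted = vapply(res, `[[`, TRUE, "accepted"),
    reason = vapply(res, `[[`, "", "reason"),
    row.names = NULL
  )
}

#' Summary of estimated movement onsets
#'
#' Mean, sd, min and max of the accepted onsets, s post-cue-2.
#'
#' @param onsets output of [detect_onsets()].
#' @return One-row data frame with `n`, `mean`, `sd`, `min`, `max`.
#' @export
onset_summary <- function(onsets) {
  ok <- onsets$onset[onsets$accepted]
  data.frame(n = length(ok), mean = mean(ok), sd = sd(ok),
             min = if (length(ok)) min(ok) else NA_real_,
             max = if (length(ok)) max(ok) else NA_real_)
}

#' Screen trials and re-reference time to the movement onset
#'
#' Runs [detect_onset()] on every trial, removes trials rejected by the
#' screening bounds, and for kept trials moves the time origin to the EMG
#' onset (`t = 0`) and trims the data to `[t_ini, 1]` s, where
#' `t_ini = -(onset + 3)` is the first-cue presentation in onset-referenced
#' time. Re-running on an already onset-referenced session is a no-op.
#'
#' @inheritParams detect_onset
#' @param session a cue-referenced [new_session()].
#' @return The onset-referenced, screened session; provenance records the
#'   early/late rejection counts.
#' @export
screen_and_realign <- function(session, early_bound = 3, late_bound = 11,
                               sustain = 0.1, smooth = 0.2) {
  if (length(session$trials) &&
      all(vapply(session$trials, `[[`, "", "time_ref") == "onset"))
    return(session)
  res <- detect_onsets(session, early_bound, late_bound, sustain, smooth)
  fs <- session$fs
  kept <- list()
  for (k in seq_along(session$trials)) {
    if (!res$accepted[k]) next
    tr <- session$trials[[k]]
    onset_cue <- unname(tr$cues["cue2"]) + res$onset[k]
    i0 <- round((onset_cue - tr$t0) * fs)   # 0-based sample index of onset
    idx <- seq_len(i0 + round(fs) + 1)      # [t_ini, 1] inclusive of endpoint
    tr$eeg <- tr$eeg[, idx, drop = FALSE]
    tr$emg <- tr$emg[, idx, drop = FALSE]
    tr$t0 <- tr$t0 - onset_cue
    tr$cues <- tr$cues - onset_cue
    tr$onset <- res$onset[k]
    tr$time_ref <- "onset"
    kept <- c(kept, list(tr))
  }
  n_early <- sum(res$reason == "early")
  n_late <- sum(res$reason == "late")
  out <- session
  out$trials <- kept
  out <- log_stage(out, "screen_and_realign",
                   params = list(early_bound = early_bound,
                                 late_bound = late_bound,
                                 sustain = sustain, smooth = smooth),
                   n_in = length(session$trials), n_out = length(kept),
                   extra = list(n_early = n_early, n_late = n_late))
  if (!length(kept)) warning("all trials were rejected by onset screening")
  out
}
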