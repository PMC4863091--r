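#' Configuration for the synthetic session generator
#'
#' The generator emulates the statistical structure the analysis pipeline
#' assumes: 18-s cue-locked trials (relax 3 s, move cue 12 s, rest 3 s) with a
#' self-paced movement onset drawn from a truncated normal distribution;
#' 1/f-type background EEG with a shared (spatially correlated) component;
#' narrowband alpha and beta rhythms over the nine motor-area electrodes whose
#' power ramps down from `erd_lead` seconds before the movement onset to a
#' plateau of `1 - depth` of baseline power during execution; and quiescent
#' EMG with a burst at the onset on the moved arm.
#'
#' @param n_trials number of trials (must be even: arms are balanced).
#' @param fs sampling rate, Hz.
#' @param n_eeg_channels 21 (full 10/10 montage) or 9 (motor-area subset).
#' @param onset_mean,onset_sd mean and sd of the movement onset, s post-cue-2.
#' @param onset_bounds truncation bounds for the onset, s post-cue-2.
#' @param erd_lead time before onset at which band power starts to decline, s.
#' @param erd_depth_alpha,erd_depth_beta fractional power drop in `[0, 1)` for
#'   the alpha and beta rhythms during execution.
#' @param alpha_band,beta_band frequency extent of the two rhythms, Hz.
#' @param alpha_sd,beta_sd rhythm amplitudes, microvolt (sd of the narrowband
#'   process at baseline).
#' @param background_sd sd of the 1/f background, microvolt.
#' @param background_spectrum_exponent exponent of the 1/f^e background power
#'   spectrum.
#' @param spatial_corr fraction of background variance shared across channels
#'   (gives the common average reference nontrivial work to do).
#' @param emg_burst_gain ratio of burst to rest EMG RMS.
#' @param emg_rest_sd resting EMG RMS, microvolt.
#' @param emg_band EMG noise band, Hz; default `[20, min(450, 0.4 fs)]`.
#' @param emg_burst_duration length of the EMG burst, s.
#' @param block_trials trials per block (arms balanced within blocks).
#' @param seed RNG seed; identical seeds give bit-identical sessions.
#' @return A validated list of class `mi_gen_config`.
#' @export
gen_config <- function(n_trials = 96L, fs = 2048, n_eeg_channels = 21L,
                       onset_mean = 7.04, onset_sd = 1.42,
                       onset_bounds = c(3, 11),
                       erd_lead = 1.0,
                       erd_depth_alpha = 0.40, erd_depth_beta = 0.20,
                       alpha_band = c(8, 13), beta_band = c(15, 25),
                       alpha_sd = 10, beta_sd = 8,
                       background_sd = 7,
                       background_spectrum_exponent = 1.0,
                       spatial_corr = 0.3,
                       emg_burst_gain = 10, emg_rest_sd = 5,
                       emg_band = NULL, emg_burst_duration = 2,
                       block_trials = 24L, seed = NULL) {
  cfg_error <- function(field, why)
    stop(sprintf("invalid generator configuration: field '%s' %s", field, why),
         call. = FALSE)
  if (length(n_trials) != 1 || n_trials < 0 || n_trials != round(n_trials))
    cfg_error("n_trials", "must be a nonnegative integer")
  if (n_trials %% 2 != 0)
    cfg_error("n_trials", "must be even (left/right arms are balanced)")
  if (!(n_eeg_channels %in% c(9L, 21L)))
    cfg_error("n_eeg_channels", "must be 21 (10/10 montage) or 9 (motor subset)")
  if (length(onset_bounds) != 2 || onset_bounds[1] >= onset_bounds[2] ||
      onset_bounds[1] <= 0 || onset_bounds[2] >= 12)
    cfg_error("onset_bounds", "must lie within (0, 12) with lower < upper")
  if (onset_sd <= 0) cfg_error("onset_sd", "must be positive")
  if (erd_lead <= 0) cfg_error("erd_lead", "must be positive")
  for (f in c("erd_depth_alpha", "erd_depth_beta")) {
    d <- get(f)
    if (d < 0 || d >= 1) cfg_error(f, "must be in [0, 1)")
  }
  if (is.null(emg_band)) emg_band <- c(20, min(450, 0.4 * fs))
  if (fs <= 2 * max(beta_band, alpha_band))
    cfg_error("fs", "must exceed twice the highest generated EEG frequency")
  if (fs <= 2 * emg_band[2])
    cfg_error("emg_band", "upper edge must be below the Nyquist frequency")
  if (emg_burst_gain < 1) cfg_error("emg_burst_gain", "must be >= 1")
  if (spatial_corr < 0 || spatial_corr >= 1)
    cfg_error("spatial_corr", "must be in [0, 1)")
  structure(
    list(n_trials = as.integer(n_trials), fs = fs,
         n_eeg_channels = as.integer(n_eeg_channels),
         onset_mean = onset_mean, onset_sd = onset_sd,
         onset_bounds = onset_bounds, erd_lead = erd_lead,
         erd_depth_alpha = erd_depth_alpha, erd_depth_beta = erd_depth_beta,
         alpha_band = alpha_band, beta_band = beta_band,
         alpha_sd = alpha_sd, beta_sd = beta_sd,
         background_sd = background_sd,
         background_spectrum_exponent = background_spectrum_exponent,
         spatial_corr = spatial_corr,
         emg_burst_gain = emg_burst_gain, emg_rest_sd = emg_rest_sd,
         emg_band = emg_band, emg_burst_duration = emg_burst_duration,
         block_trials = as.integer(block_trials), seed = seed),
    class = "mi_gen_config"
  )
}

#' Amplitude gain of the simulated event-related desynchronization
#'
#' Linear amplitude ramp: gain is 1 up to `erd_lead` seconds before the
#' movement onset, then declines linearly so that band power reaches
#' `1 - depth` of baseline at the onset and stays there. A power drop of
#' `d` corresponds to an amplitude multiplier of `sqrt(1 - d)`.
#'
#' @param t time relative to the movement onset, s (vectorized).
#' @param cfg a [gen_config()].
#' @param band `"alpha"` or `"beta"`.
#' @return Dimensionless amplitude multipliers, same length as `t`.
#' @export
erd_gain <- function(t, cfg, band = c("alpha", "beta")) {
  band <- match.arg(band)
  d <- if (band == "alpha") cfg$erd_depth_alpha else cfg$erd_depth_beta
  g_exec <- sqrt(1 - d)
  frac <- pmin(1, pmax(0, (t + cfg$erd_lead) / cfg$erd_lead))
  1 - frac * (1 - g_exec)
}

# Gaussian noise with a prescribed amplitude-spectrum shape, unit variance.
# shape is a function of frequency (Hz, > 0) returning nonnegative weights.
spectral_noise <- function(n, fs, shape) {
  x <- fft(rnorm(n))
  f <- seq(0, fs - fs / n, by = fs / n)
  f <- pmin(f, fs - f)                     # fold to [0, fs/2]
  w <- ifelse(f > 0, shape(f), 0)
  y <- Re(fft(x * w, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) return(y)
  y / s
}

shape_one_over_f <- function(exponent, f_floor = 0.5) {
  function(f) pmax(f, f_floor)^(-exponent / 2)
}

# Flat band with 1 Hz raised-cosine roll-off outside [f1, f2].
shape_band <- function(f1, f2, roll = 1) {
  function(f) {
    w <- numeric(length(f))
    w[f >= f1 & f <= f2] <- 1
    lo <- f >= f1 - roll & f < f1
    w[lo] <- 0.5 * (1 + cos(pi * (f1 - f[lo]) / roll))
    hi <- f > f2 & f <= f2 + roll
    w[hi] <- 0.5 * (1 + cos(pi * (f[hi] - f2) / roll))
    w
  }
}

#' Generate synthetic EMG for one trial
#'
#' Band-limited noise on all four bipolar channels (biceps/triceps, both
#' arms); on the moved arm the RMS rises by `emg_burst_gain` within 50 ms of
#' the movement onset and decays back after `emg_burst_duration`. The burst
#' morphology is a stand-in: its only contract is detectability by a
#' high-pass + Hilbert-envelope onset detector.
#'
#' @param onset movement onset, s post-cue-2.
#' @param trial_len trial length, s.
#' @param fs sampling rate, Hz.
#' @param cfg a [gen_config()].
#' @param arm the moved arm, `"left"` or `"right"`.
#' @return 4 x samples numeric matrix with rownames
#'   `biceps_left, triceps_left, biceps_right, triceps_right`.
#' @export
generate_emg <- function(onset, trial_len, fs, cfg, arm = c("left", "right")) {
  arm <- match.arg(arm)
  t_onset <- 3 + onset                     # cue-referenced burst time
  if (t_onset < 0 || t_onset > trial_len)
    stop("onset lies outside the trial")
  n <- round(trial_len * fs)
  tt <- (seq_len(n) - 1) / fs
  shape <- shape_band(cfg$emg_band[1], cfg$emg_band[2], roll = 5)
  rise <- 0.05
  gain_env <- 1 + (cfg$emg_burst_gain - 1) *
    pmin(1, pmax(0, (tt - t_onset) / rise)) *
    pmin(1, pmax(0, 1 - (tt - t_onset - cfg$emg_burst_duration) / 0.2))
  emg <- matrix(0, 4, n, dimnames = list(EMG_LABELS_4, NULL))
  moved <- if (arm == "left") c(1L, 2L) else c(3L, 4L)
  for (ch in 1:4) {
    x <- spectral_noise(n, fs, shape) * cfg$emg_rest_sd
    if (ch %in% moved) x <- x * gain_env
    emg[ch, ] <- x
  }
  emg
}

# Truncated-normal onset sampler (rejection).
sample_onsets <- function(n, mean, sd, bounds) {
  out <- numeric(n)
  k <- 0L
  while (k < n) {
    draw <- rnorm(n - k, mean, sd)
    keep <- draw[draw >= bounds[1] & draw <= bounds[2]]
    if (length(keep)) {
      out[(k + 1):(k + length(keep))] <- keep
      k <- k + length(keep)
    }
  }
  out
}

# Balanced arm labels, shuffled within blocks (equal left/right per block
# when the block size is even, else balanced overall).
sample_arms <- function(n_trials, block_trials) {
  if (n_trials == 0) return(character(0))
  arms <- character(n_trials)
  starts <- seq(1, n_trials, by = block_trials)
  for (s in starts) {
    e <- min(s + block_trials - 1, n_trials)
    m <- e - s + 1
    if (m %% 2 == 0) {
      arms[s:e] <- sample(rep(c("left", "right"), m / 2))
    } else {
      arms[s:e] <- sample(rep(c("left", "right"), length.out = m))
    }
  }
  # guarantee overall balance (block remainders could skew odd blocks)
  n_left <- sum(arms == "left")
  if (n_left != n_trials / 2) arms <- sample(rep(c("left", "right"), n_trials / 2))
  arms
}

#' Generate a synthetic EEG/EMG session with ground truth
#'
#' Produces `n_trials` cue-referenced 18-s trials at `fs` Hz. EEG is 1/f
#' background (independent plus shared component) with narrowband alpha and
#' beta rhythms on the nine motor-area channels, amplitude-modulated by
#' [erd_gain()] around each trial's true onset. EMG follows
#' [generate_emg()]. Onsets are drawn from the truncated normal
#' `N(onset_mean, onset_sd^2)` restricted to `onset_bounds`.
#'
#' @param cfg a [gen_config()].
#' @return A list with elements `session` (an [new_session()] object) and
#'   `truth` (data frame: trial, arm, onset s post-cue-2, erd_start s relative
#'   to onset, block).
#' @export
generate_session <- function(cfg = gen_config()) {
  stopifnot(inherits(cfg, "mi_gen_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  st <- trial_structure(block_trials = cfg$block_trials)
  trial_len <- st$trial_duration_s
  n <- round(trial_len * cfg$fs)
  labels <- if (cfg$n_eeg_channels == 21L) EEG_LABELS_21 else MOTOR_LABELS_9
  motor_idx <- match(MOTOR_LABELS_9, labels)

  onsets <- sample_onsets(cfg$n_trials, cfg$onset_mean, cfg$onset_sd,
                          cfg$onset_bounds)
  arms <- sample_arms(cfg$n_trials, cfg$block_trials)

  bg_shape <- shape_one_over_f(cfg$background_spectrum_exponent)
  a_shape <- shape_band(cfg$alpha_band[1], cfg$alpha_band[2])
  b_shape <- shape_band(cfg$beta_band[1], cfg$beta_band[2])
  sd_ind <- cfg$background_sd * sqrt(1 - cfg$spatial_corr)
  sd_shared <- cfg$background_sd * sqrt(cfg$spatial_corr)
  tt <- (seq_len(n) - 1) / cfg$fs

  trials <- vector("list", cfg$n_trials)
  for (k in seq_len(cfg$n_trials)) {
    t_rel <- tt - (3 + onsets[k])          # time relative to movement onset
    g_a <- erd_gain(t_rel, cfg, "alpha")
    g_b <- erd_gain(t_rel, cfg, "beta")
    shared <- spectral_noise(n, cfg$fs, bg_shape) * sd_shared
    eeg <- matrix(0, length(labels), n, dimnames = list(labels, NULL))
    for (ch in seq_along(labels)) {
      x <- spectral_noise(n, cfg$fs, bg_shape) * sd_ind + shared
      if (ch %in% motor_idx) {
        x <- x + spectral_noise(n, cfg$fs, a_shape) * cfg$alpha_sd * g_a +
          spectral_noise(n, cfg$fs, b_shape) * cfg$beta_sd * g_b
      }
      eeg[ch, ] <- x
    }
    emg <- generate_emg(onsets[k], trial_len, cfg$fs, cfg, arm = arms[k])
    trials[[k]] <- new_trial(eeg, emg, cfg$fs, t0 = 0, cues = st$cue_times,
                             arm = arms[k],
                             block = (k - 1) %/% cfg$block_trials + 1L)
  }

  session <- new_session(trials, cfg$fs, subject = "synthetic",
                         eeg_labels = labels, emg_labels = EMG_LABELS_4)
  session <- log_stage(session, "generate_session",
                       params = unclass(cfg), n_in = 0L,
                       n_out = cfg$n_trials)
  truth <- data.frame(
    trial = seq_len(cfg$n_trials),
    arm = arms %||% character(0),
    onset = onsets,
    erd_start = rep(-cfg$erd_lead, cfg$n_trials),
    block = if (cfg$n_trials) (seq_len(cfg$n_trials) - 1) %/% cfg$block_trials + 1L
            else integer(0)
  )
  list(session = session, truth = truth)
}
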