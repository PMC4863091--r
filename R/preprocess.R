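#' Keep only the configured EEG channels
#'
#' Electrodes far from the motor cortex (frontopolar, temporal, occipital and
#' earlobe sites) are prone to ocular and muscular artifacts; analysis keeps
#' the nine electrodes on or around the motor cortex.
#'
#' @param trial an [new_trial()].
#' @param channels labels to keep, in the desired output order.
#' @return The trial with EEG reduced to `channels`.
#' @export
select_channels <- function(trial, channels = MOTOR_LABELS_9) {
  missing <- setdiff(channels, rownames(trial$eeg))
  if (length(missing))
    stop(sprintf("channel(s) not present in trial: %s",
                 paste(missing, collapse = ", ")))
  trial$eeg <- trial$eeg[channels, , drop = FALSE]
  trial
}

# FIR low-pass decimator (upfirdn style): zero-stuff by p, filter with a
# linear-phase fir1 low-pass at 0.9 of the tighter Nyquist, compensate the
# group delay, take every q-th sample.
resample_vector <- function(x, p, q, taps = 256L) {
  if (p == 1 && q == 1) return(x)
  nx <- length(x)
  if (p > 1) {
    up <- numeric(nx * p)
    up[seq(1, nx * p, by = p)] <- x * p
    x <- up
  }
  h <- signal::fir1(taps, 0.9 / max(p, q))
  y <- signal::fftfilt(h, c(x, numeric(taps)))
  y <- y[(taps / 2 + 1):(taps / 2 + length(x))]
  y[seq(1, length(y), by = q)]
}

#' Resample a trial to a lower sampling rate
#'
#' Anti-aliased FIR resampling (polyphase-style low-pass + decimation). All
#' times (cues, onset, `t0`) are carried in seconds and are unchanged. The
#' output has `round(duration * target_fs)` samples.
#'
#' @param trial an [new_trial()].
#' @param target_fs new sampling rate, Hz.
#' @return The resampled trial (EEG and EMG).
#' @export
resample_trial <- function(trial, target_fs = 256) {
  if (target_fs > trial$fs)
    stop("target sampling rate exceeds the original; upsampling not supported")
  if (target_fs == trial$fs) {
    warning("target sampling rate equals the original; returning unchanged")
    return(trial)
  }
  g <- gcd(round(target_fs), round(trial$fs))
  p <- round(target_fs) / g
  q <- round(trial$fs) / g
  n_out <- round(ncol(trial$eeg) / trial$fs * target_fs)
  fix_len <- function(y) {
    if (length(y) >= n_out) y[seq_len(n_out)] else c(y, rep(y[length(y)], n_out - length(y)))
  }
  trial$eeg <- t(apply(trial$eeg, 1, function(x) fix_len(resample_vector(x, p, q))))
  trial$emg <- t(apply(trial$emg, 1, function(x) fix_len(resample_vector(x, p, q))))
  trial$fs <- target_fs
  trial
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering of the EEG channels.
#'
#' @param trial an [new_trial()].
#' @param band two-element numeric, pass band in Hz.
#' @param order filter order (applied twice by the forward-backward pass).
#' @return The filtered trial.
#' @export
bandpass_trial <- function(trial, band = c(0.1, 100), order = 4) {
  nyq <- trial$fs / 2
  if (band[1] <= 0 || band[2] >= nyq)
    stop("band edges must lie strictly inside (0, fs/2)")
  bf <- signal::butter(order, band / nyq, type = "pass")
  trial$eeg <- t(apply(trial$eeg, 1, function(x) signal::filtfilt(bf, x)))
  trial
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean across the retained EEG channels from
#' each channel.
#'
#' @param trial an [new_trial()].
#' @return The re-referenced trial.
#' @export
apply_car <- function(trial) {
  if (nrow(trial$eeg) < 2)
    stop("common average reference needs at least two channels")
  trial$eeg <- sweep(trial$eeg, 2, colMeans(trial$eeg))
  trial
}

#' Preprocess a session: select, resample, band-pass, re-reference
#'
#' Fixed stage order: channel selection to the motor-area montage, FIR
#' resampling to `target_fs`, zero-phase Butterworth band-pass, common
#' average reference over the retained channels. Only the EEG is filtered
#' and re-referenced; the EMG (already consumed by onset detection) is
#' resampled so the matrices stay aligned.
#'
#' @param session an [new_session()].
#' @param channels EEG labels to keep.
#' @param target_fs resampling rate, Hz.
#' @param band band-pass edges, Hz.
#' @param order Butterworth order.
#' @return The preprocessed session.
#' @export
preprocess_session <- function(session, channels = MOTOR_LABELS_9,
                               target_fs = 256, band = c(0.1, 100),
                               order = 4) {
  session$trials <- lapply(session$trials, function(tr) {
    tr <- select_channels(tr, channels)
    if (target_fs < tr$fs) tr <- resample_trial(tr, target_fs)
    tr <- bandpass_trial(tr, band, order)
    apply_car(tr)
  })
  session$fs <- target_fs
  session$eeg_labels <- channels
  log_stage(session, "preprocess",
            params = list(channels = channels, target_fs = target_fs,
                          band = band, order = order,
                          stage_order = "select>resample>bandpass>car"))
}
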