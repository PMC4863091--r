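#' Construct a trial
#'
#' A trial is one cue-locked (or, after realignment, onset-locked) segment of
#' the recording: an EEG matrix, an EMG matrix, the cue times, the moved arm
#' and, once estimated, the EMG-based movement onset. Time is carried as the
#' time of the first sample (`t0`, seconds) plus the sampling rate; sample
#' `i` (1-based) sits at `t0 + (i - 1) / fs`.
#'
#' @param eeg numeric matrix, channels x samples (microvolt), rownames are
#'   channel labels.
#' @param emg numeric matrix, EMG channels x samples (microvolt).
#' @param fs sampling rate, Hz.
#' @param t0 time of the first sample, s.
#' @param cues named numeric vector of cue presentation times in the trial's
#'   current time reference.
#' @param arm `"left"` or `"right"`.
#' @param onset EMG-based movement onset, s post-cue-2, or `NA` until
#'   estimated.
#' @param time_ref `"cue"` (t = 0 at cue 1) or `"onset"` (t = 0 at movement
#'   onset).
#' @param block block index the trial belongs to.
#' @return An object of class `mi_trial`.
#' @export
new_trial <- function(eeg, emg, fs, t0 = 0, cues = c(cue1 = 0, cue2 = 3, cue3 = 15),
                      arm = c("left", "right"), onset = NA_real_,
                      time_ref = c("cue", "onset"), block = 1L) {
  arm <- match.arg(arm)
  time_ref <- match.arg(time_ref)
  stopifnot(is.matrix(eeg), is.matrix(emg), fs > 0)
  if (ncol(eeg) != ncol(emg))
    stop("eeg and emg must have the same number of samples")
  structure(
    list(eeg = eeg, emg = emg, fs = fs, t0 = t0, cues = cues, arm = arm,
         onset = onset, time_ref = time_ref, block = as.integer(block)),
    class = "mi_trial"
  )
}

#' Time axis of a trial
#'
#' @param trial an `mi_trial`.
#' @return Numeric vector of sample times, s.
#' @export
trial_time <- function(trial) {
  trial$t0 + (seq_len(ncol(trial$eeg)) - 1) / trial$fs
}

#' Construct a session
#'
#' A session is an ordered collection of trials from one subject, sharing the
#' sampling rate and channel sets, plus a provenance log to which every
#' pipeline stage appends a structured record.
#'
#' @param trials list of [new_trial()] objects.
#' @param fs sampling rate, Hz.
#' @param subject subject identifier.
#' @param eeg_labels,emg_labels channel label vectors shared by all trials.
#' @param provenance list of provenance records.
#' @return An object of class `mi_session`.
#' @export
new_session <- function(trials, fs, subject = "S01",
                        eeg_labels = NULL, emg_labels = NULL,
                        provenance = list()) {
  if (length(trials)) {
    if (is.null(eeg_labels)) eeg_labels <- rownames(trials[[1]]$eeg)
    if (is.null(emg_labels)) emg_labels <- rownames(trials[[1]]$emg)
    for (tr in trials) {
      if (!isTRUE(all.equal(tr$fs, fs)))
        stop("all trials must share the session sampling rate")
      if (!identical(rownames(tr$eeg), eeg_labels))
        stop("all trials must share the session EEG channel set")
    }
  }
  structure(
    list(subject = subject, trials = trials, fs = fs,
         eeg_labels = eeg_labels, emg_labels = emg_labels,
         provenance = provenance),
    class = "mi_session"
  )
}

#' @export
print.mi_session <- function(x, ...) {
  cat(sprintf("<mi_session> subject %s: %d trial(s) at %g Hz\n",
              x$subject, length(x$trials), x$fs))
  if (length(x$trials)) {
    tr <- x$trials[[1]]
    cat(sprintf("  EEG %d ch, EMG %d ch, time ref '%s'\n",
                nrow(tr$eeg), nrow(tr$emg), tr$time_ref))
  }
  for (p in x$provenance)
    cat(sprintf("  stage %s (%d -> %d trials)\n", p$stage,
                p$n_in %||% NA_integer_, p$n_out %||% NA_integer_))
  invisible(x)
}

#' @export
print.mi_trial <- function(x, ...) {
  tt <- trial_time(x)
  cat(sprintf("<mi_trial> %s arm, %d EEG ch x %d samples, t in [%.3f, %.3f] s (%s-referenced)\n",
              x$arm, nrow(x$eeg), ncol(x$eeg), tt[1], tt[length(tt)], x$time_ref))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Append a provenance record; every stage that transforms a session calls this.
log_stage <- function(session, stage, params = list(), n_in = NULL, n_out = NULL,
                      extra = list()) {
  rec <- c(list(stage = stage, params = params,
                n_in = n_in %||% length(session$trials),
                n_out = n_out %||% length(session$trials)),
           extra)
  session$provenance <- c(session$provenance, list(rec))
  session
}
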