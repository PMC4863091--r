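#' Trim all trials to a common onset-referenced span
#'
#' ERD/ERS maps need equal-length trials; every trial is cut to
#' `[span[1], span[2]]` s around the movement onset and trials that do not
#' cover the span are dropped (logged in provenance).
#'
#' @param session an onset-referenced [new_session()].
#' @param span two-element numeric, s.
#' @return The trimmed session.
#' @export
trim_common <- function(session, span = c(-6, 1)) {
  fs <- session$fs
  n_keep <- round((span[2] - span[1]) * fs) + 1L
  kept <- list()
  n_dropped <- 0L
  for (tr in session$trials) {
    n <- ncol(tr$eeg)
    t_last <- tr$t0 + (n - 1) / fs
    # realigned trials end at span[2] up to one-sample quantization; anchor
    # the cut at the trial end and snap the axis onto the requested span
    if (tr$t0 > span[1] + 0.5 / fs || n < n_keep ||
        abs(t_last - span[2]) > 1.5 / fs) {
      n_dropped <- n_dropped + 1L
      next
    }
    idx <- (n - n_keep + 1L):n
    tr$eeg <- tr$eeg[, idx, drop = FALSE]
    tr$emg <- tr$emg[, idx, drop = FALSE]
    tr$t0 <- span[1]
    kept <- c(kept, list(tr))
  }
  out <- session
  out$trials <- kept
  log_stage(out, "trim_common", params = list(span = span),
            n_in = length(session$trials), n_out = length(kept),
            extra = list(n_dropped = n_dropped))
}

#' Morlet wavelet time-frequency representation of one channel
#'
#' Complex Morlet wavelets with a fixed number of cycles (default 7); power
#' is the squared magnitude of the wavelet transform. Cells whose wavelet
#' support extends past the trial edges are flagged (`edge`) and excluded
#' from downstream baseline statistics and significance.
#'
#' @param trial an [new_trial()].
#' @param channel channel label or row index.
#' @param freqs analysis frequencies, Hz.
#' @param n_cycles wavelet width in cycles.
#' @param decim keep every `decim`-th time sample of the output.
#' @return A list of class `mi_tfr`: `power` (frequency x time, microvolt^2),
#'   `freqs`, `times` (s), `edge` (logical, same shape as `power`).
#' @export
morlet_tfr <- function(trial, channel, freqs = 2:40, n_cycles = 7, decim = 1L) {
  fs <- trial$fs
  if (any(freqs >= fs / 2)) stop("analysis frequency at or above Nyquist")
  x <- if (is.character(channel)) trial$eeg[channel, ] else trial$eeg[channel, ]
  n <- length(x)
  half_max <- ceiling(3.5 * n_cycles / (2 * pi * min(freqs)) * fs)
  nfft <- stats::nextn(n + 2 * half_max + 1, 2)
  X <- fft(c(x, numeric(nfft - n)))
  keep <- seq(1, n, by = decim)
  times <- trial$t0 + (keep - 1) / fs
  power <- matrix(0, length(freqs), length(keep))
  edge <- matrix(FALSE, length(freqs), length(keep))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sig_t <- n_cycles / (2 * pi * f)
    half <- ceiling(3.5 * sig_t * fs)
    tau <- (-half:half) / fs
    w <- exp(2i * pi * f * tau) * exp(-tau^2 / (2 * sig_t^2))
    w <- w / sqrt(sum(Mod(w)^2))
    W <- fft(c(w, complex(real = numeric(nfft - length(w)))))
    conv <- fft(X * W, inverse = TRUE) / nfft
    # align: sample j of x corresponds to conv index j + half
    vals <- conv[keep + half]
    power[i, ] <- Mod(vals)^2
    edge[i, ] <- keep <= half | keep > n - half
  }
  structure(list(power = power, freqs = freqs, times = times,
                 fs = fs, decim = decim),
            class = "mi_tfr", edge = edge)
}

#' @rdname morlet_tfr
#' @param session an onset-referenced, trimmed [new_session()].
#' @return `compute_tfrs()`: a list of `mi_tfr`, one per trial.
#' @export
compute_tfrs <- function(session, channel, freqs = 2:40, n_cycles = 7,
                         decim = 1L) {
  lapply(session$trials, morlet_tfr, channel = channel, freqs = freqs,
         n_cycles = n_cycles, decim = decim)
}

tfr_edge <- function(tfr) attr(tfr, "edge")

#' Event-related desynchronization/synchronization map
#'
#' Trial-averaged percent power change relative to a per-frequency baseline:
#' `ERDS(t, f) = 100 (TFR(t, f) - TFR_baseline(f)) / TFR_baseline(f)`, where
#' `TFR_baseline(f)` is the average of the trial-mean power over the baseline
#' interval. Negative values are desynchronization (power decrease).
#'
#' @param tfrs list of [morlet_tfr()] maps (one channel, all trials).
#' @param baseline baseline interval, s, half-open `[a, b)`.
#' @return A list of class `mi_erds`: `erds` (frequency x time, percent),
#'   `freqs`, `times`, `baseline`, `baseline_power`, `edge`, and `mask`
#'   (`NULL` until [bootstrap_mask()] fills it).
#' @export
erds_map <- function(tfrs, baseline = c(-6, -3)) {
  stopifnot(length(tfrs) >= 1)
  avg <- Reduce(`+`, lapply(tfrs, `[[`, "power")) / length(tfrs)
  t1 <- tfrs[[1]]
  edge <- tfr_edge(t1)
  bcols <- which(t1$times >= baseline[1] & t1$times < baseline[2])
  if (!length(bcols)) stop("baseline interval contains no samples")
  base_pow <- vapply(seq_along(t1$freqs), function(i) {
    ok <- bcols[!edge[i, bcols]]
    if (!length(ok)) return(NA_real_)
    mean(avg[i, ok])
  }, 0)
  if (any(is.na(base_pow)) || any(base_pow <= 0))
    stop("degenerate baseline power (zero or fully edge-contaminated)")
  erds <- 100 * (avg - base_pow) / base_pow
  structure(list(erds = erds, freqs = t1$freqs, times = t1$times,
                 baseline = baseline, baseline_power = base_pow,
                 edge = edge, mask = NULL),
            class = "mi_erds")
}

#' Bootstrap significance mask for an ERD/ERS map
#'
#' Trials are resampled with replacement `B` times; for each resample the
#' trial-averaged ERDS map (including its own baseline) is recomputed. A
#' `(t, f)` cell is significant when the empirical
#' `(alpha/2, 1 - alpha/2)` percentile interval of its bootstrap
#' distribution excludes zero. Edge-flagged cells are never significant.
#'
#' @param tfrs list of [morlet_tfr()] maps (one channel, all trials).
#' @param baseline baseline interval, s.
#' @param alpha significance level.
#' @param B number of bootstrap resamples (>= 100).
#' @param seed RNG seed for the resampling; same seed, same mask.
#' @return Logical matrix, frequency x time.
#' @export
bootstrap_mask <- function(tfrs, baseline = c(-6, -3), alpha = 0.05,
                           B = 1000L, seed = NULL) {
  if (B < 100) stop("B must be at least 100 for stable percentiles")
  if (length(tfrs) < 20) stop("bootstrap needs at least 20 trials")
  if (!is.null(seed)) set.seed(seed)
  ntr <- length(tfrs)
  t1 <- tfrs[[1]]
  edge <- tfr_edge(t1)
  nt <- length(t1$times)
  nf <- length(t1$freqs)
  # one set of resamples shared across frequencies
  W <- matrix(0, B, ntr)
  for (b in seq_len(B))
    W[b, ] <- tabulate(sample.int(ntr, ntr, replace = TRUE), ntr) / ntr
  bcols0 <- which(t1$times >= baseline[1] & t1$times < baseline[2])
  mask <- matrix(FALSE, nf, nt)
  probs <- c(alpha / 2, 1 - alpha / 2)
  for (i in seq_len(nf)) {
    M <- t(vapply(tfrs, function(o) o$power[i, ], numeric(nt)))  # trials x t
    Mb <- W %*% M
    bc <- bcols0[!edge[i, bcols0]]
    if (!length(bc)) next
    base_b <- rowMeans(Mb[, bc, drop = FALSE])
    Eb <- 100 * (Mb - base_b) / base_b
    q <- apply(Eb, 2, quantile, probs = probs, names = FALSE)
    mask[i, ] <- (q[1, ] > 0 | q[2, ] < 0) & !edge[i, ]
  }
  mask
}

#' ERD/ERS maps with significance for a set of channels
#'
#' Convenience wrapper: Morlet TFRs per trial, trial-averaged ERDS map and
#' bootstrap mask for each requested channel of a trimmed, onset-referenced
#' session.
#'
#' @inheritParams bootstrap_mask
#' @inheritParams morlet_tfr
#' @param session trimmed, onset-referenced [new_session()].
#' @param channels channel labels.
#' @return Named list of `mi_erds` maps with masks filled in.
#' @export
compute_erds <- function(session, channels = session$eeg_labels,
                         freqs = 2:40, n_cycles = 7, baseline = c(-6, -3),
                         alpha = 0.05, B = 1000L, seed = NULL, decim = 1L) {
  out <- list()
  for (ch in channels) {
    tfrs <- compute_tfrs(session, ch, freqs, n_cycles, decim)
    em <- erds_map(tfrs, baseline)
    em$mask <- bootstrap_mask(tfrs, baseline, alpha, B, seed)
    out[[ch]] <- em
  }
  out
}

#' Band-by-window summary of significant ERD/ERS
#'
#' For each channel, frequency band and 1-s time window, the mean ERDS over
#' the significant cells in that region; windows with no significant cell
#' report exactly 0. A final `Avg` row averages the per-channel entries.
#'
#' @param maps named list of masked `mi_erds` maps (see [compute_erds()]).
#' @param bands named list of `[lo, hi]` frequency bands, Hz.
#' @param windows window start times, s; each window is `[w, w + width)`.
#' @param width window width, s.
#' @return Data frame: `channel`, `band`, `win_start`, `win_end`, `erds`.
#' @export
band_window_table <- function(maps,
                              bands = list(alpha = c(8, 13), beta = c(14, 30)),
                              windows = -6:0, width = 1) {
  rows <- list()
  for (ch in names(maps)) {
    m <- maps[[ch]]
    if (is.null(m$mask)) stop("maps must carry a significance mask")
    for (bn in names(bands)) {
      fr <- m$freqs >= bands[[bn]][1] & m$freqs <= bands[[bn]][2]
      for (w in windows) {
        tc <- m$times >= w & m$times < w + width
        sel <- m$mask[fr, tc, drop = FALSE]
        vals <- m$erds[fr, tc, drop = FALSE][sel]
        rows[[length(rows) + 1]] <- data.frame(
          channel = ch, band = bn, win_start = w, win_end = w + width,
          erds = if (length(vals)) mean(vals) else 0)
      }
    }
  }
  tab <- do.call(rbind, rows)
  avg <- stats::aggregate(erds ~ band + win_start + win_end, tab, mean)
  avg$channel <- "Avg"
  rbind(tab, avg[, names(tab)])
}
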