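#' Burg autoregressive power spectrum
#'
#' Fits an AR model of the given order by Burg's method (forward+backward
#' prediction error minimization, via [stats::ar.burg()]) to the demeaned
#' segment and evaluates the one-sided parametric power spectral density
#' `P(f) = 2 sigma^2 / (fs |1 - sum_k a_k e^(-2 pi i f k / fs)|^2)` at the
#' requested frequencies.
#'
#' @param x numeric vector, one signal segment.
#' @param freqs frequencies at which to evaluate the spectrum, Hz.
#' @param fs sampling rate, Hz.
#' @param order AR model order.
#' @return Strictly positive numeric vector of spectral power values.
#' @export
burg_spectrum <- function(x, freqs, fs, order = 16L) {
  if (length(x) <= order)
    stop("segment must be longer than the AR order")
  if (sd(x) == 0)
    stop("constant segment: zero variance, AR spectrum undefined")
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  ar_psd(fit$ar, fit$var.pred, freqs, fs)
}

# One-sided AR(p) PSD from coefficients and innovation variance.
ar_psd <- function(a, sigma2, freqs, fs) {
  k <- seq_along(a)
  denom <- vapply(freqs, function(f) {
    Mod(1 - sum(a * exp(-2i * pi * f * k / fs)))^2
  }, 0)
  2 * sigma2 / (fs * denom)
}

#' Causal spectral-power feature vector
#'
#' Per retained electrode, the Burg AR(16) spectrum of the EEG in the causal
#' window `[t - T, t)` is evaluated at 1 Hz resolution over the motor-related
#' alpha `[8, 14]` and beta `[14, 25]` Hz bands (the shared 14 Hz point is
#' counted once: 18 values per electrode). Electrode blocks are concatenated
#' in montage order, giving `x` in `R^162` for the 9-electrode montage.
#'
#' @param trial a preprocessed [new_trial()].
#' @param t window endpoint, s (in the trial's time reference).
#' @param T_win window length, s.
#' @param freqs feature frequencies, Hz.
#' @param order AR order.
#' @return A list of class `mi_features`: `x` (numeric, length
#'   `length(freqs) * nrow(eeg)`), `t`, `T_win`, `label` (`NA` until
#'   assigned).
#' @export
feature_vector <- function(trial, t, T_win = 1, freqs = 8:25, order = 16L) {
  fs <- trial$fs
  i_end <- floor((t - trial$t0) * fs)        # window is [t - T, t) in samples
  i_start <- i_end - round(T_win * fs) + 1L
  if (i_start < 1 || i_end > ncol(trial$eeg))
    stop("feature window extends outside the trial")
  seg <- trial$eeg[, i_start:i_end, drop = FALSE]
  # apply() returns one column per electrode; column-major flattening
  # concatenates the electrode blocks in montage order
  x <- as.numeric(apply(seg, 1, burg_spectrum, freqs = freqs, fs = fs,
                        order = order))
  structure(list(x = x, t = t, T_win = T_win, label = NA_character_),
            class = "mi_features")
}

#' Non-overlapping training windows of a trial
#'
#' Feature windows for classifier training are drawn from the relax phase
#' `[t_ini, t_ini + 3]` and the movement-intention phase `[-3, 0]` only.
#' Relax endpoints are `t_ini + 3 - k T`, intention endpoints `-k T`
#' (`k = 0, 1, ...`), each kept while the whole window stays inside its
#' phase. Both phases last 3 s, so the classes are balanced for any `T`.
#'
#' @param trial an onset-referenced [new_trial()] (`t0` is `t_ini`).
#' @param T_win window length, s.
#' @return Data frame with `t` (window endpoint, s) and `label`
#'   (`"relax"` or `"intention"`).
#' @export
training_windows <- function(trial, T_win = 1) {
  t_ini <- trial$t0
  eps <- 1e-9
  k <- 0:floor(3 / T_win + eps)
  relax <- (t_ini + 3 - k * T_win)
  relax <- relax[relax - T_win >= t_ini - eps]
  intent <- -k * T_win
  intent <- intent[intent - T_win >= -3 - eps]
  data.frame(
    t = c(relax, intent),
    label = rep(c("relax", "intention"), c(length(relax), length(intent))),
    stringsAsFactors = FALSE
  )
}

#' Feature scaling fitted on training data
#'
#' Per-feature z-scaling `x_i' = (x_i - mu_i) / sigma_i` with statistics
#' computed exclusively from the training set.
#'
#' @param X numeric matrix, training feature rows.
#' @return A list of class `mi_scaling` with `mu` and `sigma`.
#' @export
fit_scaling <- function(X) {
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  bad <- which(sigma == 0)
  if (length(bad))
    stop(sprintf("zero-variance feature(s) at index: %s",
                 paste(bad, collapse = ", ")))
  structure(list(mu = mu, sigma = sigma), class = "mi_scaling")
}

#' @rdname fit_scaling
#' @param scaling an `mi_scaling`.
#' @return `apply_scaling()`: the scaled matrix.
#' @export
apply_scaling <- function(X, scaling) {
  sweep(sweep(X, 2, scaling$mu), 2, scaling$sigma, "/")
}
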