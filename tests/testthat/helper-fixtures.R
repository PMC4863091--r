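# Shared fixtures, generated once per test run. Sessions are small and use a
# reduced sampling rate so the whole suite stays fast; the acceptance tests
# use larger sessions closer to the recording conditions.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixture_env[[name]])) assign(name, make(), envir = .fixture_env)
  .fixture_env[[name]]
}

# 8 trials, 512 Hz, full ERD depths, with ground truth
small_gen <- function() fixture("small_gen", function()
  generate_session(gen_config(n_trials = 8, fs = 512, seed = 101)))

# the same session realigned and preprocessed to 256 Hz
small_prep <- function() fixture("small_prep", function()
  preprocess_session(screen_and_realign(small_gen()$session)))

# feature cache of the preprocessed small session (T = 1 s)
small_cache <- function() fixture("small_cache", function()
  precompute_features(small_prep(), detector_config()))

# white-noise trial factory (channels x samples, onset-referenced)
noise_trial <- function(n_ch = 9, dur = 7, fs = 256, t0 = -6,
                        labels = paste0("ch", seq_len(n_ch))) {
  eeg <- matrix(rnorm(n_ch * (dur * fs + 1)), n_ch,
                dimnames = list(labels, NULL))
  new_trial(eeg, matrix(0, 4, ncol(eeg),
                        dimnames = list(moveintent:::EMG_LABELS_4, NULL)),
            fs = fs, t0 = t0, time_ref = "onset")
}

# hand-built TFR object for unit-testing the ERDS formula and mask
make_tfr <- function(power, freqs, times, edge = NULL) {
  if (is.null(edge)) edge <- matrix(FALSE, nrow(power), ncol(power))
  structure(list(power = power, freqs = freqs, times = times,
                 fs = 1 / diff(times[1:2]), decim = 1L),
            class = "mi_tfr", edge = edge)
}
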