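test_that("ERD amplitude gain is a continuous monotone ramp with the right plateau", {
  cfg <- gen_config(n_trials = 2, fs = 512)
  expect_equal(erd_gain(-5, cfg, "alpha"), 1)
  expect_equal(erd_gain(0.5, cfg, "alpha"), sqrt(0.60))
  expect_equal(erd_gain(10, cfg, "beta"), sqrt(0.80))
  # midpoint of the ramp sits halfway between the endpoints
  expect_equal(erd_gain(-0.5, cfg, "alpha"), (1 + sqrt(0.6)) / 2)
  tt <- seq(-3, 2, by = 0.01)
  g <- erd_gain(tt, cfg, "alpha")
  expect_true(all(diff(g) <= 0))
  expect_lt(max(abs(diff(g))), 0.01)   # no jumps: continuous ramp
  cfg0 <- gen_config(n_trials = 2, fs = 512, erd_depth_alpha = 0)
  expect_true(all(erd_gain(tt, cfg0, "alpha") == 1))
})

test_that("invalid generator configurations fail naming the offending field", {
  expect_error(gen_config(n_trials = 7), "n_trials")
  expect_error(gen_config(erd_depth_alpha = 1.2), "erd_depth_alpha")
  expect_error(gen_config(onset_bounds = c(3, 13)), "onset_bounds")
  expect_error(gen_config(fs = 40), "fs")
  expect_error(gen_config(n_eeg_channels = 12), "n_eeg_channels")
})

test_that("truncated-normal onset sampler matches its analytic mean", {
  set.seed(5)
  b <- c(3, 11); mu <- 7.04; s <- 1.42
  x <- moveintent:::sample_onsets(500, mu, s, b)
  expect_true(all(x >= b[1] & x <= b[2]))
  a1 <- (b[1] - mu) / s; a2 <- (b[2] - mu) / s
  m_true <- mu + s * (dnorm(a1) - dnorm(a2)) / (pnorm(a2) - pnorm(a1))
  expect_lt(abs(mean(x) - m_true), 0.15)
  expect_lt(abs(m_true - 7.04), 0.01)  # near-symmetric truncation
})

test_that("EMG bursts have the configured RMS gain on the moved arm only", {
  set.seed(7)
  cfg <- gen_config(n_trials = 2, fs = 512)
  emg <- generate_emg(7, 18, 512, cfg, arm = "left")
  tt <- (seq_len(ncol(emg)) - 1) / 512
  pre <- tt > 4 & tt < 9.8            # burst starts at cue2 + 7 = 10 s
  post <- tt > 10.1 & tt < 11.5
  rms <- function(v) sqrt(mean(v^2))
  ratio_moved <- rms(emg["biceps_left", post]) / rms(emg["biceps_left", pre])
  expect_gt(ratio_moved, 8); expect_lt(ratio_moved, 12)
  ratio_other <- rms(emg["biceps_right", post]) / rms(emg["biceps_right", pre])
  expect_gt(ratio_other, 0.8); expect_lt(ratio_other, 1.25)
  # unit gain: no burst anywhere
  cfg1 <- gen_config(n_trials = 2, fs = 512, emg_burst_gain = 1)
  emg1 <- generate_emg(7, 18, 512, cfg1, arm = "left")
  r1 <- rms(emg1["biceps_left", post]) / rms(emg1["biceps_left", pre])
  expect_gt(r1, 0.8); expect_lt(r1, 1.25)
  expect_error(generate_emg(16, 18, 512, cfg, arm = "left"), "outside")
})

test_that("sessions are reproducible, balanced, and sized by the protocol", {
  g1 <- generate_session(gen_config(n_trials = 4, fs = 512, seed = 9))
  g2 <- generate_session(gen_config(n_trials = 4, fs = 512, seed = 9))
  expect_identical(g1$session$trials[[3]]$eeg, g2$session$trials[[3]]$eeg)
  expect_identical(g1$truth, g2$truth)
  s <- small_gen()
  expect_length(s$session$trials, 8)
  arms <- vapply(s$session$trials, `[[`, "", "arm")
  expect_equal(sum(arms == "left"), 4)
  expect_equal(ncol(s$session$trials[[1]]$eeg), 18 * 512)
  expect_true(all(s$truth$onset >= 3 & s$truth$onset <= 11))
  g0 <- generate_session(gen_config(n_trials = 0, fs = 512, seed = 1))
  expect_length(g0$session$trials, 0)
  expect_equal(nrow(g0$truth), 0)
})

test_that("a no-ERD motor channel has spectral peaks at the rhythm bands", {
  g <- generate_session(gen_config(n_trials = 2, fs = 512, seed = 33,
                                   erd_depth_alpha = 0, erd_depth_beta = 0))
  x <- g$session$trials[[1]]$eeg["Cz", ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = 512), spans = c(25, 25),
                          plot = FALSE, taper = 0.1)
  f <- sp$freq
  low <- f >= 4 & f <= 18
  peak_a <- f[low][which.max(sp$spec[low])]
  expect_gte(peak_a, 8); expect_lte(peak_a, 13)
  mid <- f >= 16 & f <= 32
  peak_b <- f[mid][which.max(sp$spec[mid])]
  expect_gte(peak_b, 14.5); expect_lte(peak_b, 25.5)
})
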