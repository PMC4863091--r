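test_that("trimming to a common span keeps exactly [-6, 1] and drops short trials", {
  s <- small_prep()
  st <- trim_common(s)
  expect_length(st$trials, length(s$trials))
  for (tr in st$trials) {
    tt <- trial_time(tr)
    expect_equal(tt[1], -6)
    expect_equal(length(tt), 7 * st$fs + 1)
  }
  # a trial that starts after -6 s cannot cover the span
  short <- s
  short$trials[[1]]$eeg <- short$trials[[1]]$eeg[, -(1:(6 * s$fs)), drop = FALSE]
  short$trials[[1]]$emg <- short$trials[[1]]$emg[, -(1:(6 * s$fs)), drop = FALSE]
  short$trials[[1]]$t0 <- short$trials[[1]]$t0 + 6
  st2 <- trim_common(short)
  expect_length(st2$trials, length(s$trials) - 1)
})

test_that("Morlet TFR localizes tones and tracks amplitude steps quadratically", {
  fs <- 256
  tt <- seq(-6, 1, by = 1 / fs)
  amp <- ifelse(tt < 0, 2, 1)          # amplitude halves at t = 0
  tr <- new_trial(rbind(Cz = amp * sin(2 * pi * 10 * tt)),
                  matrix(0, 4, length(tt),
                         dimnames = list(moveintent:::EMG_LABELS_4, NULL)),
                  fs, t0 = -6, time_ref = "onset")
  tfr <- morlet_tfr(tr, "Cz", freqs = 2:40)
  edge <- attr(tfr, "edge")
  avg <- vapply(seq_along(tfr$freqs), function(i)
    mean(tfr$power[i, !edge[i, ]]), 0)
  expect_equal(tfr$freqs[which.max(avg)], 10)
  i10 <- which(tfr$freqs == 10)
  pre <- tfr$times > -4 & tfr$times < -1 & !edge[i10, ]
  post <- tfr$times > 0.3 & tfr$times < 0.8 & !edge[i10, ]
  ratio <- mean(tfr$power[i10, post]) / mean(tfr$power[i10, pre])
  expect_gt(ratio, 0.2); expect_lt(ratio, 0.3)   # power follows amplitude^2
  expect_error(morlet_tfr(tr, "Cz", freqs = c(10, 130)), "Nyquist")
})

test_that("averaged white-noise TFR power is flat over time", {
  set.seed(12)
  trials <- replicate(300, noise_trial(n_ch = 1, labels = "Cz"),
                      simplify = FALSE)
  tfrs <- lapply(trials, morlet_tfr, channel = "Cz", freqs = c(5, 10, 20),
                 decim = 4L)
  avg <- Reduce(`+`, lapply(tfrs, `[[`, "power")) / length(tfrs)
  edge <- attr(tfrs[[1]], "edge")
  for (i in 1:3) {
    prof <- avg[i, !edge[i, ]]
    expect_lt(sd(prof) / mean(prof), 0.10)
  }
})

test_that("the ERDS formula and its significance mask behave on constructed maps", {
  freqs <- 8:12
  times <- seq(-6, 1, by = 0.05)
  pow <- matrix(1, length(freqs), length(times))
  pow[, times >= 0] <- 0.5             # power halves at t = 0
  tfrs <- replicate(25, make_tfr(pow, freqs, times), simplify = FALSE)
  em <- erds_map(tfrs, baseline = c(-6, -3))
  expect_true(all(abs(em$erds[, em$times < -3]) < 1e-9))
  expect_true(all(abs(em$erds[, em$times >= 0] + 50) < 1e-9))
  expect_true(all(em$erds >= -100))
  # identical trials: zero bootstrap variance, significant iff erds != 0
  mask <- bootstrap_mask(tfrs, baseline = c(-6, -3), B = 200, seed = 4)
  expect_true(all(mask[, em$times >= 0]))
  expect_false(any(mask[, em$times < -3]))
  expect_error(bootstrap_mask(tfrs, B = 50), "at least 100")
  expect_error(bootstrap_mask(tfrs[1:5], B = 200), "20 trials")
  # degenerate baseline
  pow0 <- pow; pow0[, times < -3] <- 0
  expect_error(erds_map(replicate(25, make_tfr(pow0, freqs, times),
                                  simplify = FALSE)), "baseline")
})

test_that("bootstrap mask keeps near-nominal false-positive rate under the null", {
  set.seed(31)
  freqs <- 8:12
  times <- seq(-6, 1, by = 0.1)
  tfrs <- replicate(40, make_tfr(
    matrix(rchisq(length(freqs) * length(times), df = 4) / 4,
           length(freqs), length(times)), freqs, times), simplify = FALSE)
  mask <- bootstrap_mask(tfrs, baseline = c(-6, -3), alpha = 0.05,
                         B = 400, seed = 8)
  expect_lt(mean(mask), 0.12)
  # deterministic given the seed
  mask2 <- bootstrap_mask(tfrs, baseline = c(-6, -3), alpha = 0.05,
                          B = 400, seed = 8)
  expect_identical(mask, mask2)
})

test_that("band/window table averages significant cells and zeroes quiet windows", {
  freqs <- 2:40
  times <- seq(-6, 1, by = 0.05)
  erds <- matrix(-30, length(freqs), length(times))
  mask <- matrix(TRUE, length(freqs), length(times))
  mask[, times < -3] <- FALSE
  m <- structure(list(erds = erds, freqs = freqs, times = times,
                      baseline = c(-6, -3), mask = mask,
                      edge = matrix(FALSE, length(freqs), length(times))),
                 class = "mi_erds")
  tab <- band_window_table(list(Cz = m))
  quiet <- tab$channel == "Cz" & tab$win_start < -3
  expect_true(all(tab$erds[quiet] == 0))
  act <- tab$channel == "Cz" & tab$win_start >= -3
  expect_true(all(abs(tab$erds[act] + 30) < 1e-9))
  expect_true("Avg" %in% tab$channel)
})
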