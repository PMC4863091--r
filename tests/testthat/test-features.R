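test_that("Burg spectrum matches the closed-form AR spectrum of a known process", {
  set.seed(3)
  fs <- 256
  r <- 0.95; th <- 2 * pi * 10 / fs
  a_true <- c(2 * r * cos(th), -r^2)           # spectral peak at 10 Hz
  n <- 1e5
  x <- as.numeric(stats::filter(rnorm(n), a_true, method = "recursive"))
  grid <- 1:40
  est <- burg_spectrum(x, grid, fs)
  oracle <- moveintent:::ar_psd(a_true, 1, grid, fs)
  expect_equal(grid[which.max(est)], grid[which.max(oracle)])
  expect_equal(grid[which.max(oracle)], 10)
  # band powers within 10 percent of the closed form
  for (band in list(8:14, 15:25)) {
    rel <- sum(est[band]) / sum(oracle[band])
    expect_gt(rel, 0.9); expect_lt(rel, 1.1)
  }
})

test_that("Burg spectrum of white noise is flat and degenerate inputs error", {
  set.seed(4)
  psd <- burg_spectrum(rnorm(1e5), 8:25, 256)
  expect_true(all(psd > 0))
  expect_lt(max(psd) / mean(psd), 1.1)
  expect_gt(min(psd) / mean(psd), 0.9)
  expect_error(burg_spectrum(rnorm(16), 8:25, 256, order = 16), "longer")
  expect_error(burg_spectrum(rep(1, 100), 8:25, 256), "constant")
})

test_that("feature vectors have 18 frequencies x 9 electrodes and are causal", {
  set.seed(6)
  tr <- noise_trial(n_ch = 9, dur = 7, fs = 256, t0 = -6,
                    labels = moveintent:::MOTOR_LABELS_9)
  fv <- feature_vector(tr, t = 0, T_win = 1)
  expect_length(fv$x, 162)
  expect_equal(length(8:25), 18)
  # causality: samples at times >= t do not matter
  tr2 <- tr
  after <- trial_time(tr) >= 0
  tr2$eeg[, after] <- 0
  expect_identical(feature_vector(tr2, 0, 1)$x, fv$x)
  # identical electrodes give identical 18-value blocks
  tr3 <- tr
  tr3$eeg["Fz", ] <- tr3$eeg["F3", ]
  fv3 <- feature_vector(tr3, 0, 1)
  expect_identical(fv3$x[1:18], fv3$x[19:36])
  expect_error(feature_vector(tr, t = -6.5, T_win = 1), "outside")
})

test_that("training windows tile both 3-s phases without overlap, balanced for any T", {
  tr <- noise_trial(n_ch = 2, dur = 11, fs = 256, t0 = -10)
  w1 <- training_windows(tr, 1)
  expect_setequal(w1$t[w1$label == "relax"], c(-7, -8, -9))
  expect_setequal(w1$t[w1$label == "intention"], c(0, -1, -2))
  w75 <- training_windows(tr, 0.75)
  expect_equal(sum(w75$label == "relax"), 4)
  expect_equal(sum(w75$label == "intention"), 4)
  expect_equal(nrow(training_windows(tr, 4)), 0)
  for (T_win in c(0.5, 0.75, 1)) {
    w <- training_windows(tr, T_win)
    expect_equal(sum(w$label == "relax"), sum(w$label == "intention"))
    # windows stay inside their phases
    expect_true(all(w$t[w$label == "relax"] - T_win >= tr$t0 - 1e-9))
    expect_true(all(w$t[w$label == "intention"] >= -3 + T_win - 1e-9 |
                      w$t[w$label == "intention"] - T_win >= -3 - 1e-9))
  }
})

test_that("feature scaling is fitted on training data only", {
  set.seed(8)
  X <- matrix(rnorm(40 * 6, mean = 3, sd = 2), 40)
  sc <- fit_scaling(X)
  Xs <- apply_scaling(X, sc)
  expect_lt(max(abs(colMeans(Xs))), 1e-9)
  expect_lt(max(abs(apply(Xs, 2, sd) - 1)), 1e-9)
  held <- matrix(rnorm(40 * 6, mean = 5), 40)
  expect_gt(max(abs(colMeans(apply_scaling(held, sc)))), 0.1)
  Xbad <- X; Xbad[, 4] <- 2
  expect_error(fit_scaling(Xbad), "4")
})

test_that("alpha features separate intention from relax on ERD sessions", {
  cache <- small_cache()
  a_cols <- as.vector(outer(1:6, (0:8) * 18, "+"))   # 8-13 Hz blocks
  rel <- c(); int <- c()
  for (tr in cache$trials) {
    # window order is fixed: relax (t_ini+3, +2, +1), intention (0, -1, -2);
    # the window ending at the onset (row 4) carries the ERD ramp
    expect_identical(tr$train_labels, rep(c("relax", "intention"), each = 3))
    int <- c(int, mean(tr$train_X[4, a_cols]))
    rel <- c(rel, mean(tr$train_X[1:3, a_cols]))
  }
  expect_lt(mean(int), mean(rel))
})
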