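# fabricate eval/chance objects with a known DA structure for rule tests
fake_summary <- function(grid, da_mean, das_mean = 0.5, n_rep = 30,
                         jitter = 0.02, seed = 1) {
  set.seed(seed)
  ng <- length(grid)
  DA <- matrix(rep(da_mean, each = n_rep), n_rep, ng) +
    matrix(rnorm(n_rep * ng, 0, jitter), n_rep, ng)
  DS <- matrix(das_mean, n_rep, ng) + matrix(rnorm(n_rep * ng, 0, jitter),
                                             n_rep, ng)
  list(
    eval = structure(list(repeats = data.frame(CA = rep(0.7, n_rep)),
                          grid = grid, DA = DA, timelines = list()),
                     class = "mi_eval"),
    chance = structure(list(DA_sig = DS, grid = grid, CA_sig = 0.5,
                            repeats = NULL), class = "mi_chance"))
}

test_that("the SVM separates well-separated clouds and needs both classes", {
  set.seed(10)
  X <- rbind(matrix(rnorm(60 * 5), 60), matrix(rnorm(60 * 5, mean = 3), 60))
  y <- rep(c("relax", "intention"), each = 60)
  cfg <- detector_config()
  m <- train_detector(X, y, cfg)
  expect_gte(mean(predict(m, X) == y), 0.95)
  expect_error(train_detector(X, rep("relax", 120), cfg), "both classes")
  # duplicating every training point leaves the decision function unchanged
  m2 <- train_detector(rbind(X, X), c(y, y), cfg)
  probe <- matrix(rnorm(40 * 5, 1.5), 40)
  expect_identical(as.character(predict(m, probe)),
                   as.character(predict(m2, probe)))
})

test_that("the sliding grid is anchored at 1 s with 0.1 s steps", {
  set.seed(11)
  tr <- noise_trial(n_ch = 9, dur = 11, fs = 256, t0 = -10,
                    labels = moveintent:::MOTOR_LABELS_9)
  tw <- training_windows(tr, 1)
  X <- t(vapply(tw$t, function(t) feature_vector(tr, t, 1)$x, numeric(162)))
  sc <- fit_scaling(X)
  m <- train_detector(apply_scaling(X, sc), tw$label, detector_config())
  tl <- predict_timeline(m, sc, tr, detector_config())
  expect_equal(nrow(tl), 101)
  expect_equal(tl$t[1], -9)
  expect_equal(tl$t[nrow(tl)], 1)
  expect_true(all(abs(diff(tl$t) - 0.1) < 1e-9))
})

test_that("evaluation pools balanced phases so CA = (TPE + TNE) / 2, deterministically", {
  cache <- small_cache()
  cfg <- detector_config(n_repeats = 2, seed = 5)
  ev1 <- evaluate_once(cache, cfg, split_seed = 42)
  ev2 <- evaluate_once(cache, cfg, split_seed = 42)
  expect_identical(ev1$CA, ev2$CA)
  expect_identical(ev1$da, ev2$da)
  expect_equal(ev1$CA, (ev1$TPE + ev1$TNE) / 2)
  expect_true(all(ev1$da$da >= 0 & ev1$da$da <= 1))
  one <- cache
  one$trials <- cache$trials[1]
  one$n_trials <- 1L
  expect_error(evaluate_once(one, detector_config()), "empty")
})

test_that("Wilcoxon decisions respect exact small-sample limits", {
  grid <- round(seq(-3, 1, by = 0.1), 9)
  # 5 repeats, all CA above chance: minimal two-sided signed-rank p is 1/16
  fs5 <- fake_summary(grid, da_mean = rep(0.5, length(grid)), n_rep = 5)
  fs5$eval$repeats <- data.frame(CA = 0.6 + (1:5) / 100)
  tst <- significance_tests(fs5$eval, fs5$chance, alpha_test = 0.01)
  expect_false(tst$ca_above)
  expect_equal(tst$ca_p, 1 / 16)
  # 30 repeats all above by a margin: rejection
  fs30 <- fake_summary(grid, rep(0.5, length(grid)), n_rep = 30)
  fs30$eval$repeats <- data.frame(CA = 0.6 + (1:30) / 1000)
  tst30 <- significance_tests(fs30$eval, fs30$chance, alpha_test = 0.01)
  expect_true(tst30$ca_above)
  expect_lt(tst30$ca_p, 0.01)
})

test_that("tMI follows the sustained-significance rule and handles null sessions", {
  grid <- round(seq(-3, 1, by = 0.1), 9)
  da <- ifelse(grid >= -1, 1, 0.5)
  fs <- fake_summary(grid, da, das_mean = 0.5, jitter = 0.01)
  # one always-intention timeline so NT_D is defined and 1
  fs$eval$timelines <- list(list(data.frame(t = grid, label = "intention")))
  m <- detection_metrics(fs$eval, fs$chance, alpha_test = 0.01, run_len = 3)
  expect_equal(m$tMI, -1.0)
  expect_equal(m$NT_D, 1)
  # flat DA at chance: undefined metrics, not errors
  fs0 <- fake_summary(grid, rep(0.5, length(grid)))
  fs0$eval$timelines <- list(list(data.frame(t = grid, label = "relax")))
  m0 <- detection_metrics(fs0$eval, fs0$chance)
  expect_true(is.na(m0$tMI))
  expect_true(is.na(m0$NT_D))
  # a run of intention labels entirely after the onset does not count
  fs1 <- fake_summary(grid, da, das_mean = 0.5, jitter = 0.01)
  lab <- ifelse(grid >= 0.2, "intention", "relax")
  fs1$eval$timelines <- list(list(data.frame(t = grid, label = lab)))
  m1 <- detection_metrics(fs1$eval, fs1$chance)
  expect_equal(m1$NT_D, 0)
})

test_that("permutation chance stays near coin-flip and is seed-stable", {
  cache <- small_cache()
  cfg <- detector_config(n_repeats = 6, seed = 13)
  ch1 <- permutation_chance(cache, cfg)
  ch2 <- permutation_chance(cache, cfg)
  expect_identical(ch1$DA_sig, ch2$DA_sig)
  expect_gt(ch1$CA_sig, 0.3); expect_lt(ch1$CA_sig, 0.75)
  expect_true(all(ch1$DA_sig >= 0 & ch1$DA_sig <= 1))
})
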