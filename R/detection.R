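#' Configuration for the relax/intention detector
#'
#' Soft-margin SVM with a radial basis function kernel. The kernel width is
#' per dimension: `k(u, v) = exp(-||u - v||^2 / (2 sigma^2 D))` where `D` is
#' the feature dimension, i.e. LIBSVM `gamma = 1 / (2 sigma^2 D)`. For
#' z-scored features the expected squared distance between two independent
#' points is about `2 D`, so a width tied to `D` keeps the kernel informative
#' regardless of how many electrodes and frequencies are concatenated; an
#' unnormalized width of 0.5 over 162 summed dimensions would make every
#' off-diagonal kernel value vanish (`exp(-600)`) and the classifier would
#' degenerate to a constant.
#'
#' @param C regularization parameter.
#' @param sigma RBF kernel width.
#' @param T_win feature window length, s.
#' @param step sliding-window step, s.
#' @param train_frac fraction of trials used for training in each split.
#' @param n_repeats number of random splits (and of permutation runs).
#' @param alpha_test confidence level of the Wilcoxon tests.
#' @param run_len consecutive intention outputs required for an unequivocal
#'   detection (`run_len * step` seconds sustained).
#' @param freqs feature frequencies, Hz.
#' @param ar_order Burg AR order.
#' @param seed RNG seed for splits and permutations.
#' @return A list of class `mi_detector_config`.
#' @export
detector_config <- function(C = 1, sigma = 0.5, T_win = 1, step = 0.1,
                            train_frac = 0.8, n_repeats = 30L,
                            alpha_test = 0.01, run_len = 3L,
                            freqs = 8:25, ar_order = 16L, seed = NULL) {
  stopifnot(C > 0, sigma > 0, step > 0, T_win > 0,
            train_frac > 0, train_frac < 1, n_repeats >= 1)
  structure(list(C = C, sigma = sigma, T_win = T_win, step = step,
                 train_frac = train_frac, n_repeats = as.integer(n_repeats),
                 alpha_test = alpha_test, run_len = as.integer(run_len),
                 freqs = freqs, ar_order = as.integer(ar_order), seed = seed),
            class = "mi_detector_config")
}

#' Precompute feature matrices for a session
#'
#' Feature extraction dominates the cost of repeated evaluation, so the
#' phase-window training features and the sliding-grid features of every
#' trial are computed once and reused across splits and permutation runs.
#' The sliding grid runs from `t_ini + T` to 1 s in `step` increments,
#' anchored at 1 s so grids of different trials share time points.
#'
#' @param session a preprocessed, onset-referenced [new_session()].
#' @param cfg a [detector_config()].
#' @return A list of class `mi_feature_cache`.
#' @export
precompute_features <- function(session, cfg = detector_config()) {
  eps <- 1e-9
  trials <- lapply(session$trials, function(tr) {
    tw <- training_windows(tr, cfg$T_win)
    train_X <- t(vapply(tw$t, function(t)
      feature_vector(tr, t, cfg$T_win, cfg$freqs, cfg$ar_order)$x,
      numeric(length(cfg$freqs) * nrow(tr$eeg))))
    n_steps <- floor((1 - (tr$t0 + cfg$T_win)) / cfg$step + eps)
    grid_t <- round(1 - cfg$step * (n_steps:0), 9)
    grid_X <- t(vapply(grid_t, function(t)
      feature_vector(tr, t, cfg$T_win, cfg$freqs, cfg$ar_order)$x,
      numeric(length(cfg$freqs) * nrow(tr$eeg))))
    list(train_X = train_X, train_labels = tw$label,
         grid_t = grid_t, grid_X = grid_X)
  })
  structure(list(trials = trials, T_win = cfg$T_win, step = cfg$step,
                 freqs = cfg$freqs, n_trials = length(trials)),
            class = "mi_feature_cache")
}

#' Train the relax/intention SVM
#'
#' @param X scaled feature matrix (rows = windows).
#' @param labels character vector, `"relax"` / `"intention"`.
#' @param cfg a [detector_config()].
#' @return A fitted [e1071::svm()] model.
#' @export
train_detector <- function(X, labels, cfg = detector_config()) {
  if (length(unique(labels)) < 2)
    stop("training data must contain both classes")
  y <- factor(labels, levels = c("relax", "intention"))
  e1071::svm(X, y, kernel = "radial",
             gamma = 1 / (2 * cfg$sigma^2 * ncol(X)),
             cost = cfg$C, scale = FALSE)
}

#' Continuous prediction timeline of one trial
#'
#' Classifies each causal sliding window of the trial (endpoints every
#' `step` s from `t_ini + T` to 1 s).
#'
#' @param detector fitted model from [train_detector()].
#' @param scaling an `mi_scaling` fitted on the training set.
#' @param trial a preprocessed, onset-referenced [new_trial()].
#' @param cfg a [detector_config()].
#' @return Data frame with `t` (window endpoint, s) and `label`.
#' @export
predict_timeline <- function(detector, scaling, trial, cfg = detector_config()) {
  eps <- 1e-9
  n_steps <- floor((1 - (trial$t0 + cfg$T_win)) / cfg$step + eps)
  grid_t <- round(1 - cfg$step * (n_steps:0), 9)
  X <- t(vapply(grid_t, function(t)
    feature_vector(trial, t, cfg$T_win, cfg$freqs, cfg$ar_order)$x,
    numeric(length(cfg$freqs) * nrow(trial$eeg))))
  lab <- as.character(predict(detector, apply_scaling(X, scaling)))
  data.frame(t = grid_t, label = lab, stringsAsFactors = FALSE)
}

# Common sliding grid shared by every trial of a cache (times from the end,
# anchored at 1 s).
common_grid <- function(cache) {
  k_max <- min(vapply(cache$trials, function(tr) length(tr$grid_t), 0L)) - 1L
  round(1 - cache$step * (k_max:0), 9)
}

# One train/test split evaluated end to end on precomputed features.
# permute = TRUE shuffles the training labels (chance-level run).
eval_split <- function(cache, cfg, permute = FALSE) {
  ntr <- cache$n_trials
  n_train <- max(1L, floor(cfg$train_frac * ntr))
  if (n_train >= ntr) stop("test set is empty; lower train_frac")
  idx_train <- sort(sample.int(ntr, n_train))
  idx_test <- setdiff(seq_len(ntr), idx_train)

  X <- do.call(rbind, lapply(cache$trials[idx_train], `[[`, "train_X"))
  y <- unlist(lapply(cache$trials[idx_train], `[[`, "train_labels"))
  if (permute) y <- sample(y)
  scaling <- fit_scaling(X)
  model <- train_detector(apply_scaling(X, scaling), y, cfg)

  grid <- common_grid(cache)
  k_common <- length(grid)
  n_int <- 0L; n_int_hit <- 0L; n_rel <- 0L; n_rel_hit <- 0L
  intent_at <- matrix(FALSE, length(idx_test), k_common)
  timelines <- vector("list", length(idx_test))
  for (j in seq_along(idx_test)) {
    tr <- cache$trials[[idx_test[j]]]
    ph <- as.character(predict(model, apply_scaling(tr$train_X, scaling)))
    is_int <- tr$train_labels == "intention"
    n_int <- n_int + sum(is_int)
    n_int_hit <- n_int_hit + sum(ph[is_int] == "intention")
    n_rel <- n_rel + sum(!is_int)
    n_rel_hit <- n_rel_hit + sum(ph[!is_int] == "relax")
    tl <- as.character(predict(model, apply_scaling(tr$grid_X, scaling)))
    m <- length(tl)
    intent_at[j, ] <- tl[(m - k_common + 1):m] == "intention"
    timelines[[j]] <- data.frame(t = tr$grid_t, label = tl,
                                 stringsAsFactors = FALSE)
  }
  list(CA = (n_int_hit + n_rel_hit) / (n_int + n_rel),
       TPE = n_int_hit / n_int, TNE = n_rel_hit / n_rel,
       da = data.frame(t = grid, da = colMeans(intent_at)),
       timelines = timelines, idx_test = idx_test)
}

#' Evaluate one random train/test split
#'
#' Trials (not windows) are split 80/20; scaling and classifier are fitted
#' on the training trials' phase windows only. CA pools the relax and
#' intention phase windows of the test trials; TPE/TNE are the per-phase
#' rates; `DA(t)` is the fraction of test trials labelled intention at each
#' grid time.
#'
#' @param cache an `mi_feature_cache` (or a session, converted on the fly).
#' @param cfg a [detector_config()].
#' @param split_seed RNG seed for this split.
#' @return A list with `CA`, `TPE`, `TNE`, `da`, per-trial `timelines`, and
#'   the test-trial indices.
#' @export
evaluate_once <- function(cache, cfg = detector_config(), split_seed = NULL) {
  if (inherits(cache, "mi_session")) cache <- precompute_features(cache, cfg)
  if (!is.null(split_seed)) set.seed(split_seed)
  eval_split(cache, cfg, permute = FALSE)
}

#' Repeated random-split evaluation
#'
#' The split-train-test procedure is repeated `n_repeats` times;
#' distributions and mean +/- sd of CA/TPE/TNE and the mean `DA(t)` curve
#' are collected.
#'
#' @inheritParams evaluate_once
#' @return A list of class `mi_eval`: `repeats` (data frame CA/TPE/TNE per
#'   run), `grid`, `DA` (repeats x grid matrix), `timelines` (list over
#'   runs), `cfg`.
#' @export
repeated_evaluation <- function(cache, cfg = detector_config()) {
  if (inherits(cache, "mi_session")) cache <- precompute_features(cache, cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (cfg$n_repeats == 1)
    warning("a single repeat gives degenerate (sd = 0) distributions; no test will be performed")
  grid <- common_grid(cache)
  DA <- matrix(0, cfg$n_repeats, length(grid))
  reps <- data.frame(CA = numeric(cfg$n_repeats), TPE = 0, TNE = 0)
  timelines <- vector("list", cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    ev <- eval_split(cache, cfg, permute = FALSE)
    reps[r, ] <- c(ev$CA, ev$TPE, ev$TNE)
    DA[r, ] <- ev$da$da
    timelines[[r]] <- ev$timelines
  }
  structure(list(repeats = reps, grid = grid, DA = DA,
                 timelines = timelines, cfg = cfg),
            class = "mi_eval")
}

#' Permutation-based empirical chance levels
#'
#' `n_repeats` runs with the class labels permuted during training only
#' (fresh 80/20 splits); test windows keep their true labels for scoring.
#' `DA_sig(t)` is the per-run chance detection curve; `CA_sig` is the
#' maximum over the relax and intention phases of the mean chance-level
#' accuracy.
#'
#' @inheritParams evaluate_once
#' @return A list of class `mi_chance`: `DA_sig` (repeats x grid), `grid`,
#'   `CA_sig`, `repeats` (per-run chance CA/TPE/TNE).
#' @export
permutation_chance <- function(cache, cfg = detector_config()) {
  if (inherits(cache, "mi_session")) cache <- precompute_features(cache, cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  grid <- common_grid(cache)
  DA_sig <- matrix(0, cfg$n_repeats, length(grid))
  reps <- data.frame(CA = numeric(cfg$n_repeats), TPE = 0, TNE = 0)
  for (r in seq_len(cfg$n_repeats)) {
    ev <- eval_split(cache, cfg, permute = TRUE)
    reps[r, ] <- c(ev$CA, ev$TPE, ev$TNE)
    DA_sig[r, ] <- ev$da$da
  }
  structure(list(DA_sig = DA_sig, grid = grid,
                 CA_sig = max(mean(reps$TPE), mean(reps$TNE)),
                 repeats = reps),
            class = "mi_chance")
}

#' Wilcoxon tests of detection against chance
#'
#' Signed-rank test of the CA repeats against `CA_sig` (two-sided), and
#' rank-sum tests of `DA(t)` against `DA_sig(t)` at every grid point, at the
#' configured confidence level.
#'
#' @param eval an `mi_eval` from [repeated_evaluation()].
#' @param chance an `mi_chance` from [permutation_chance()].
#' @param alpha_test test level.
#' @return A list: `ca_p`, `ca_above` (significantly above chance),
#'   `da_p` (per grid point), `da_above` (rejection with mean DA > mean
#'   DA_sig).
#' @export
significance_tests <- function(eval, chance, alpha_test = 0.01) {
  stopifnot(identical(eval$grid, chance$grid))
  d <- eval$repeats$CA - chance$CA_sig
  ca_p <- if (nrow(eval$repeats) < 2 || all(d == 0)) 1 else
    suppressWarnings(wilcox.test(d)$p.value)
  ng <- length(eval$grid)
  da_p <- numeric(ng)
  da_above <- logical(ng)
  for (k in seq_len(ng)) {
    a <- eval$DA[, k]; b <- chance$DA_sig[, k]
    da_p[k] <- if (all(a == b[1]) && all(b == b[1])) 1 else
      suppressWarnings(wilcox.test(a, b)$p.value)
    da_above[k] <- da_p[k] < alpha_test && mean(a) > mean(b)
  }
  list(ca_p = ca_p,
       ca_above = ca_p < alpha_test && mean(eval$repeats$CA) > chance$CA_sig,
       da_p = da_p, da_above = da_above)
}

#' Time-resolved detection metrics
#'
#' `tMI` is the earliest pre-movement grid time from which `DA(t)` is
#' significantly above `DA_sig(t)` at every grid point up to the movement
#' onset (sustained, "unequivocal" significance); `NA` when even the last
#' pre-onset point is not significant. `NT_D` is the fraction of test-trial
#' timelines containing at least `run_len` consecutive intention outputs
#' ending before `t = 0`; undefined (`NA`) when `tMI` is undefined.
#'
#' @inheritParams significance_tests
#' @param run_len consecutive intention outputs required for a detection.
#' @return A list with `tMI` (s) and `NT_D` (rate), possibly `NA`.
#' @export
detection_metrics <- function(eval, chance, alpha_test = 0.01, run_len = 3L) {
  tests <- significance_tests(eval, chance, alpha_test)
  neg <- which(eval$grid < 0)
  if (!length(neg)) return(list(tMI = NA_real_, NT_D = NA_real_))
  ok <- tests$da_above[neg]
  if (!ok[length(ok)]) return(list(tMI = NA_real_, NT_D = NA_real_))
  first <- length(ok)
  while (first > 1 && ok[first - 1]) first <- first - 1
  tMI <- eval$grid[neg[first]]
  hits <- 0L; total <- 0L
  for (run in eval$timelines) for (tl in run) {
    if (!any(tl$t < 0)) next
    total <- total + 1L
    is_int <- tl$label == "intention" & !is.na(tl$t)
    r <- rle(is_int)
    # a detection: run of >= run_len intention labels whose last window
    # endpoint is still before the movement onset
    ends <- cumsum(r$lengths)
    det <- FALSE
    for (i in which(r$values & r$lengths >= run_len)) {
      e <- ends[i]; s <- e - r$lengths[i] + 1L
      last_neg <- max(which(tl$t < 0))
      if (s <= last_neg && min(e, last_neg) - s + 1L >= run_len) det <- TRUE
    }
    if (det) hits <- hits + 1L
  }
  list(tMI = tMI, NT_D = hits / total)
}

#' Full movement-intention detection analysis of a session
#'
#' Runs the repeated evaluation, the permutation chance levels, the Wilcoxon
#' tests and the time-resolved metrics on a preprocessed, onset-referenced
#' session.
#'
#' @inheritParams evaluate_once
#' @return A list of class `mi_detection_summary` with elements `eval`,
#'   `chance`, `tests`, `metrics`, `cfg`, and the headline numbers
#'   `CA` (mean +/- sd), `CA_sig`, `tMI`, `NT_D`.
#' @export
detect_movement_intention <- function(cache, cfg = detector_config()) {
  if (inherits(cache, "mi_session")) cache <- precompute_features(cache, cfg)
  ev <- repeated_evaluation(cache, cfg)
  ch <- permutation_chance(cache, cfg)
  tests <- significance_tests(ev, ch, cfg$alpha_test)
  metrics <- detection_metrics(ev, ch, cfg$alpha_test, cfg$run_len)
  structure(list(eval = ev, chance = ch, tests = tests, metrics = metrics,
                 cfg = cfg,
                 CA = c(mean = mean(ev$repeats$CA), sd = sd(ev$repeats$CA)),
                 TPE = mean(ev$repeats$TPE), TNE = mean(ev$repeats$TNE),
                 CA_sig = ch$CA_sig,
                 tMI = metrics$tMI, NT_D = metrics$NT_D),
            class = "mi_detection_summary")
}

#' @export
print.mi_detection_summary <- function(x, ...) {
  cat(sprintf("<movement-intention detection> T = %g s, %d repeats\n",
              x$cfg$T_win, x$cfg$n_repeats))
  cat(sprintf("  CA  %.3f +/- %.3f  (TPE %.3f, TNE %.3f; chance CA_sig %.3f)\n",
              x$CA["mean"], x$CA["sd"], x$TPE, x$TNE, x$CA_sig))
  cat(sprintf("  CA above chance: %s (signed-rank p = %.2g)\n",
              x$tests$ca_above, x$tests$ca_p))
  cat(sprintf("  tMI = %s s, NT_D = %s\n",
              if (is.na(x$tMI)) "undefined" else sprintf("%.1f", x$tMI),
              if (is.na(x$NT_D)) "undefined" else sprintf("%.2f", x$NT_D)))
  invisible(x)
}
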