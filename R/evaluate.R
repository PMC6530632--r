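## Block-wise six-fold cross-validation, correlation metrics, shuffle-based
## chance levels, and decoder-comparison statistics.

#' Pearson correlation between predicted and true kinematics
#'
#' Per-parameter Pearson correlation over aligned samples, plus the
#' per-quantity axis means (position = mean of the X/Y position
#' correlations, speed likewise). Parameters whose ground truth has zero
#' variance are reported as `NA` and excluded from the axis means, with a
#' note.
#'
#' @param predicted,truth 4 x N matrices in row order `{sx, sy, dx, dy}`.
#' @return List with `per_param` (named, `X-Speed`, `Y-Speed`, `X-Position`,
#'   `Y-Position`), `axis_mean` (named, `speed`, `position`), `note`.
#' @export
correlation_metric <- function(predicted, truth) {
  predicted <- as.matrix(predicted); truth <- as.matrix(truth)
  if (!all(dim(predicted) == dim(truth))) pk_stop("predicted and truth shapes differ")
  if (nrow(truth) != 4L) pk_stop("expected 4 kinematic parameters in rows")
  cc <- numeric(4L); note <- character(0)
  for (p in 1:4) {
    if (stats::var(truth[p, ]) == 0 || stats::var(predicted[p, ]) == 0) {
      cc[p] <- NA_real_
      note <- c(note, sprintf("%s undefined (zero variance)", kin_param_names()[p]))
    } else {
      cc[p] <- stats::cor(predicted[p, ], truth[p, ])
    }
  }
  names(cc) <- kin_param_names()
  axis_mean <- c(speed = mean(cc[1:2], na.rm = TRUE),
                 position = mean(cc[3:4], na.rm = TRUE))
  list(per_param = cc, axis_mean = axis_mean,
       note = if (length(note)) paste(note, collapse = "; ") else NULL)
}

## Assemble everything block-wise CV needs from a session: lag-embedded
## predictors, targets, and per-column/per-trial bookkeeping. Features are
## trial-local (CAR, filtering, normalization all within-trial), so they can
## be computed once and reused across folds without leakage.
decoding_data <- function(session, feature_kind = "phase", band = c(0.1, 1),
                          order = 2, theta = 11L, car = TRUE, unwrap = NULL,
                          targets = c("movement", "epoch")) {
  targets <- match.arg(targets)
  validate_session(session)
  sess <- if (car) preprocess_session(session, band = NULL, target_rate = NULL) else session
  # phase is decoded wrapped to [0, 2*pi) — the interval where the
  # movement trajectory has no discontinuity — and unit-normalized like
  # the other representations; unwrapping is off by default because 2*pi
  # step detection is unreliable on noisy single trials
  fts <- session_features(sess, feature_kind, band = band, order = order,
                          normalize = "unit", unwrap = unwrap %||% FALSE)
  X <- lag_embed(fts, theta = theta, targets = targets)
  Y <- kinematic_targets(fts, theta = theta, targets = targets)
  trial_blocks <- vapply(sess$trials, function(tr) tr$block, integer(1))
  first <- if (targets == "movement") {
    vapply(sess$trials, function(tr) tr$onset_index + 1L, integer(1))
  } else {
    rep(as.integer(theta), length(sess$trials))
  }
  onset_states <- vapply(seq_along(sess$trials), function(i) {
    kin_matrix(sess$trials[[i]]$kin)[, first[i]]
  }, numeric(4))
  list(X = X$values, boundaries = X$trial_boundaries, col_trial = X$col_trial,
       Y = Y, trial_blocks = trial_blocks, onset_states = onset_states,
       theta = theta, feature_kind = feature_kind, band = band,
       targets = targets)
}

trial_cols <- function(dd, trial) (dd$boundaries[trial] + 1L):dd$boundaries[trial + 1L]

## 0-based boundaries of a subset of trials within the column subset they span.
subset_boundaries <- function(dd, trials) {
  lens <- dd$boundaries[trials + 1L] - dd$boundaries[trials]
  c(0L, cumsum(lens))
}

#' Block-wise cross-validated decoding of a session
#'
#' Folds are the session's blocks: for each fold the decoder is fitted on
#' the other blocks' movement-interval samples and predicts the held-out
#' block trial by trial (the Kalman state resets at each trial start).
#' Performance is the Pearson correlation per kinematic parameter over the
#' held-out samples; with `aggregate = "fold_mean"` (default) per-fold
#' correlations are averaged over folds, with `"concatenated"` a single
#' correlation is computed over all held-out samples pooled.
#'
#' @param session An [eeg_session()] with at least 2 distinct blocks.
#' @param feature_kind `"phase"`, `"amplitude"` or `"power"`.
#' @param band,order Feature band (Hz) and filter design order.
#' @param theta Embedding dimension (default 11).
#' @param decoder `"mlr"` or `"kf"`.
#' @param car Apply common-average referencing.
#' @param unwrap Use unwrapped phase.
#' @param targets `"movement"` (default) restricts fitting and scoring to
#'   movement-interval samples — pre-onset kinematics are identically zero
#'   and would otherwise dominate the correlation trivially; `"epoch"`
#'   reconstructs continuously across each whole trial (rest and reach),
#'   the way whole-trial reconstruction traces are rendered, in which mode
#'   the chance level becomes a non-trivial positive baseline.
#' @param aggregate Fold aggregation mode.
#' @param keep_predictions Also return each fold's predictions and truth.
#' @return An `eval_report`: `per_fold_cc` (folds x 4), `mean_cc` (per
#'   parameter), `axis_mean_cc` (position/speed), `config_tag`, `decoder`,
#'   `folds` (block labels), and optionally `predictions`.
#' @export
blockwise_cv <- function(session, feature_kind = c("phase", "amplitude", "power"),
                         band = c(0.1, 1), order = 2, theta = 11L,
                         decoder = c("mlr", "kf"), car = TRUE, unwrap = NULL,
                         targets = c("movement", "epoch"),
                         aggregate = c("fold_mean", "concatenated"),
                         keep_predictions = FALSE) {
  feature_kind <- match.arg(feature_kind)
  decoder <- match.arg(decoder)
  aggregate <- match.arg(aggregate)
  targets <- match.arg(targets)
  dd <- decoding_data(session, feature_kind, band, order, theta, car, unwrap,
                      targets = targets)
  cv_decode(dd, decoder, aggregate = aggregate,
            config_tag = sprintf("%s %g-%g Hz %s", feature_kind, band[1], band[2],
                                 toupper(decoder)),
            keep_predictions = keep_predictions)
}

## Core CV loop over a decoding_data object; `targets` overrides dd$Y (used
## by the shuffle null, where predictors are fixed and targets permuted).
cv_decode <- function(dd, decoder, targets = NULL, aggregate = "fold_mean",
                      config_tag = "", keep_predictions = FALSE) {
  Y <- targets %||% dd$Y
  blocks <- sort(unique(dd$trial_blocks))
  if (length(blocks) < 2L) pk_stop("cross-validation needs at least 2 distinct blocks")
  per_fold <- matrix(NA_real_, nrow = length(blocks), ncol = 4L,
                     dimnames = list(paste0("block", blocks), kin_param_names()))
  pooled_pred <- list(); pooled_truth <- list()
  for (bi in seq_along(blocks)) {
    b <- blocks[bi]
    train_trials <- which(dd$trial_blocks != b)
    test_trials <- which(dd$trial_blocks == b)
    train_cols <- unlist(lapply(train_trials, trial_cols, dd = dd))
    test_cols <- unlist(lapply(test_trials, trial_cols, dd = dd))
    if (length(test_cols) == 0L) pk_stop("fold for block %d has zero movement samples", b)
    Xtr <- dd$X[, train_cols, drop = FALSE]
    Ytr <- Y[, train_cols, drop = FALSE]
    if (decoder == "mlr") {
      model <- fit_mlr(Xtr, Ytr)
      pred <- predict_mlr(model, dd$X[, test_cols, drop = FALSE])
    } else {
      model <- fit_kf(Xtr, Ytr, boundaries = subset_boundaries(dd, train_trials),
                      onset_states = dd$onset_states[, train_trials, drop = FALSE])
      pred <- kf_predict_trials(model, dd, test_trials)
    }
    truth <- Y[, test_cols, drop = FALSE]
    per_fold[bi, ] <- correlation_metric(pred, truth)$per_param
    pooled_pred[[bi]] <- pred; pooled_truth[[bi]] <- truth
  }
  if (aggregate == "fold_mean") {
    mean_cc <- colMeans(per_fold, na.rm = TRUE)
  } else {
    mean_cc <- correlation_metric(do.call(cbind, pooled_pred),
                                  do.call(cbind, pooled_truth))$per_param
  }
  out <- structure(list(per_fold_cc = per_fold, mean_cc = mean_cc,
                        axis_mean_cc = c(speed = mean(mean_cc[1:2], na.rm = TRUE),
                                         position = mean(mean_cc[3:4], na.rm = TRUE)),
                        config_tag = config_tag, decoder = decoder,
                        aggregate = aggregate, folds = blocks),
                   class = "eval_report")
  if (keep_predictions) {
    out$predictions <- Map(function(p, t) list(predicted = p, truth = t),
                           pooled_pred, pooled_truth)
    names(out$predictions) <- paste0("block", blocks)
  }
  out
}

## Filter every test trial with fold-level gain caching: the covariance/gain
## recursion is data-independent, so one gain sequence (computed to the
## longest test trial) serves all trials in the fold.
kf_predict_trials <- function(model, dd, test_trials) {
  lens <- vapply(test_trials, function(i) length(trial_cols(dd, i)), integer(1))
  gains <- kf_gain_sequence(model, max(lens))
  preds <- lapply(test_trials, function(i) {
    kf_filter(model, dd$X[, trial_cols(dd, i), drop = FALSE], gains = gains)
  })
  do.call(cbind, preds)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report %s: %d folds>\n", x$config_tag, nrow(x$per_fold_cc)))
  cat("  mean CC: ", paste(sprintf("%s %.3f", names(x$mean_cc), x$mean_cc),
                           collapse = ", "), "\n")
  cat(sprintf("  axis means: position %.3f, speed %.3f\n",
              x$axis_mean_cc["position"], x$axis_mean_cc["speed"]))
  invisible(x)
}

## Permute the assignment of kinematics to trials: trial i receives the
## kinematics of trial perm[i], with the donor's movement-interval track
## linearly resampled onto the host's movement length (trials are self-paced
## and differ in duration). Returns a 4 x N target matrix aligned with dd$X.
shuffle_targets <- function(dd, perm) {
  n_trials <- length(dd$trial_blocks)
  if (length(perm) != n_trials) pk_stop("permutation length mismatch")
  out <- matrix(NA_real_, nrow = 4L, ncol = ncol(dd$Y))
  for (i in seq_len(n_trials)) {
    host_cols <- trial_cols(dd, i)
    donor <- dd$Y[, trial_cols(dd, perm[i]), drop = FALSE]
    m_h <- length(host_cols); m_d <- ncol(donor)
    if (m_d == m_h) {
      out[, host_cols] <- donor
    } else {
      tau_h <- seq(0, 1, length.out = m_h)
      tau_d <- seq(0, 1, length.out = m_d)
      for (p in 1:4) {
        out[p, host_cols] <- stats::approx(tau_d, donor[p, ], xout = tau_h)$y
      }
    }
  }
  out
}

#' Chance-level decoding via trial shuffling
#'
#' Destroys the correspondence between EEG and kinematics by randomly
#' permuting which kinematics track belongs to which trial (resampling each
#' donor track to the host trial's movement length), then reruns the full
#' block-wise cross-validation on every shuffled dataset. The distribution
#' of shuffled performances is the empirical null against which authentic
#' decoding is judged.
#'
#' Predictors are fixed under the shuffle, so fold-level factorizations are
#' cached and reused across shuffles.
#'
#' @inheritParams blockwise_cv
#' @param n_shuffles Number of shuffles (default 20).
#' @param seed Seed for the permutations; results are fully reproducible.
#' @param permutations Optional list of explicit permutations (overrides
#'   `n_shuffles`/`seed`); e.g. the identity permutation reproduces the
#'   authentic result exactly.
#' @return A `chance_report`: `shuffle_mean_cc` (shuffles x 4 matrix of
#'   fold-averaged CCs), `mean_cc`, `q95_cc` (per-parameter 95th
#'   percentiles), `reports` omitted for compactness.
#' @export
chance_level <- function(session, feature_kind = c("phase", "amplitude", "power"),
                         band = c(0.1, 1), order = 2, theta = 11L,
                         decoder = c("mlr", "kf"), car = TRUE,
                         targets = c("movement", "epoch"),
                         n_shuffles = 20L, seed = 1L, permutations = NULL) {
  feature_kind <- match.arg(feature_kind)
  decoder <- match.arg(decoder)
  targets <- match.arg(targets)
  dd <- decoding_data(session, feature_kind, band, order, theta, car,
                      targets = targets)
  n_trials <- length(dd$trial_blocks)
  perms <- permutations %||% with_seed(seed, {
    lapply(seq_len(n_shuffles), function(s) sample.int(n_trials))
  })
  n_shuffles <- length(perms)
  targets <- lapply(perms, function(p) shuffle_targets(dd, p))

  blocks <- sort(unique(dd$trial_blocks))
  acc <- array(NA_real_, dim = c(n_shuffles, length(blocks), 4L))
  for (bi in seq_along(blocks)) {
    b <- blocks[bi]
    train_trials <- which(dd$trial_blocks != b)
    test_trials <- which(dd$trial_blocks == b)
    train_cols <- unlist(lapply(train_trials, trial_cols, dd = dd))
    Xtr <- dd$X[, train_cols, drop = FALSE]
    tb <- subset_boundaries(dd, train_trials)
    if (decoder == "mlr") {
      sv_tr <- svd(t(rbind(Xtr, 1)))                 # shared across shuffles
      keep <- sv_tr$d > 1e-3 * sv_tr$d[1L]
      Vk <- sv_tr$v[, keep, drop = FALSE]
      Utk <- t(sv_tr$u[, keep, drop = FALSE])
      dk <- sv_tr$d[keep]
    } else {
      Sxx <- tcrossprod(Xtr) / ncol(Xtr)
    }
    for (s in seq_len(n_shuffles)) {
      Ys <- targets[[s]]
      Ytr <- Ys[, train_cols, drop = FALSE]
      if (decoder == "mlr") {
        coef <- Vk %*% ((Utk %*% t(Ytr)) / dk)
        model <- structure(list(weights = t(coef), L = nrow(Xtr)), class = "mlr_model")
        test_cols <- unlist(lapply(test_trials, trial_cols, dd = dd))
        pred <- predict_mlr(model, dd$X[, test_cols, drop = FALSE])
      } else {
        model <- fit_kf(Xtr, Ytr, boundaries = tb,
                        onset_states = dd$onset_states[, train_trials, drop = FALSE],
                        Sxx = Sxx)
        pred <- kf_predict_trials(model, dd, test_trials)
        test_cols <- unlist(lapply(test_trials, trial_cols, dd = dd))
      }
      acc[s, bi, ] <- correlation_metric(pred, Ys[, test_cols, drop = FALSE])$per_param
    }
  }
  shuffle_mean_cc <- apply(acc, c(1L, 3L), mean, na.rm = TRUE)
  colnames(shuffle_mean_cc) <- kin_param_names()
  structure(list(shuffle_mean_cc = shuffle_mean_cc,
                 mean_cc = colMeans(shuffle_mean_cc),
                 q95_cc = apply(shuffle_mean_cc, 2L, stats::quantile, probs = 0.95,
                                names = FALSE),
                 n_shuffles = n_shuffles, decoder = decoder,
                 feature_kind = feature_kind, seed = seed),
            class = "chance_report")
}

#' @export
print.chance_report <- function(x, ...) {
  cat(sprintf("<chance_report: %d shuffles, %s/%s>\n", x$n_shuffles,
              x$feature_kind, toupper(x$decoder)))
  cat("  mean CC: ", paste(sprintf("%s %.3f", names(x$mean_cc), x$mean_cc),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Compare two sets of decoding performances
#'
#' Two-sided Wilcoxon test on per-dataset performances: the paired signed
#' rank test for matched subject-session sets, or the rank sum test for
#' unmatched sets (e.g. authentic vs chance). Zero differences are dropped
#' per the standard signed-rank convention (noted in the output); if all
#' pairs are tied the p-value is 1 by convention.
#'
#' @param perf_a,perf_b Numeric vectors of per-dataset performance (e.g.
#'   mean CCs). For `signed_rank` they must be aligned pair-wise.
#' @param test `"signed_rank"` (paired) or `"rank_sum"`.
#' @param tags_a,tags_b Optional dataset tags; `signed_rank` requires them
#'   to match.
#' @return List with `statistic`, `p_value`, `method`, `differences` (for
#'   paired tests) and `note`.
#' @export
compare_decoders <- function(perf_a, perf_b, test = c("signed_rank", "rank_sum"),
                             tags_a = NULL, tags_b = NULL) {
  test <- match.arg(test)
  note <- NULL
  if (test == "signed_rank") {
    if (length(perf_a) != length(perf_b)) pk_stop("paired test needs equal-length sets")
    if (length(perf_a) < 5L) pk_stop("need at least 5 pairs")
    if (!is.null(tags_a) && !is.null(tags_b) && !identical(tags_a, tags_b)) {
      pk_stop("signed-rank pairs must come from matching datasets")
    }
    diffs <- perf_a - perf_b
    if (all(diffs == 0)) {
      return(list(statistic = 0, p_value = 1,
                  method = "Wilcoxon signed rank test", differences = diffs,
                  note = "all differences zero; p = 1 by convention"))
    }
    if (any(diffs == 0)) note <- sprintf("%d zero difference(s) dropped", sum(diffs == 0))
    wt <- suppressWarnings(stats::wilcox.test(perf_a, perf_b, paired = TRUE,
                                              alternative = "two.sided"))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = wt$method, differences = diffs, note = note)
  } else {
    if (length(perf_a) < 2L || length(perf_b) < 2L) pk_stop("need at least 2 values per set")
    wt <- suppressWarnings(stats::wilcox.test(perf_a, perf_b, paired = FALSE,
                                              alternative = "two.sided"))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = wt$method, differences = NULL, note = note)
  }
}

#' Feature-comparison decoder grid
#'
#' Runs the standard comparator grid end-to-end on one session: the
#' low-delta phase decoder against power and amplitude features from the
#' high-delta (1-4 Hz), theta (4-8 Hz), mu (8-12 Hz) and beta (12-30 Hz)
#' bands, each with both decoders, reporting the position and speed axis
#' means.
#'
#' @param session An [eeg_session()].
#' @param decoders Which decoders to run.
#' @param theta Embedding dimension.
#' @return Data frame with columns `config`, `feature`, `band`, `decoder`,
#'   `position_cc`, `speed_cc`.
#' @export
decoder_grid <- function(session, decoders = c("mlr", "kf"), theta = 11L) {
  bands <- nuisance_bands()
  configs <- list(list(name = "low_delta_phase", kind = "phase",
                       band = c(0.1, 1), order = 2))
  for (b in names(bands)) {
    for (kind in c("power", "amplitude")) {
      configs[[length(configs) + 1L]] <-
        list(name = sprintf("%s_%s", b, substr(kind, 1, 3)), kind = kind,
             band = bands[[b]], order = 8)
    }
  }
  rows <- list()
  for (cfg in configs) {
    for (dec in decoders) {
      rep <- blockwise_cv(session, cfg$kind, band = cfg$band, order = cfg$order,
                          theta = theta, decoder = dec)
      rows[[length(rows) + 1L]] <- data.frame(
        config = sprintf("%s-%s", cfg$name, toupper(dec)),
        feature = cfg$kind, band = sprintf("%g-%g", cfg$band[1], cfg$band[2]),
        decoder = dec,
        position_cc = unname(rep$axis_mean_cc["position"]),
        speed_cc = unname(rep$axis_mean_cc["speed"]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
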