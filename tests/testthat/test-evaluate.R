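test_that("correlation metric reports per-parameter r and axis means", {
  set.seed(41)
  Y <- matrix(rnorm(4 * 100), 4)
  m <- correlation_metric(Y, Y)
  expect_equal(unname(m$per_param), rep(1, 4))
  m2 <- correlation_metric(-Y, Y)
  expect_equal(unname(m2$per_param), rep(-1, 4))
  P <- matrix(rnorm(4 * 100), 4)
  m3 <- correlation_metric(P, Y)
  oracle <- vapply(1:4, function(i) {
    cv <- mean((P[i, ] - mean(P[i, ])) * (Y[i, ] - mean(Y[i, ])))
    cv / (sqrt(mean((P[i, ] - mean(P[i, ]))^2)) * sqrt(mean((Y[i, ] - mean(Y[i, ]))^2)))
  }, numeric(1))
  expect_equal(unname(m3$per_param), oracle, tolerance = 1e-12)
  expect_equal(unname(m3$axis_mean["position"]), mean(oracle[3:4]), tolerance = 1e-12)
  # zero-variance truth: NA with a note, excluded from axis means
  Y0 <- Y; Y0[4, ] <- 0
  m4 <- correlation_metric(P, Y0)
  expect_true(is.na(m4$per_param["Y-Position"]))
  expect_match(m4$note, "Y-Position")
  expect_equal(unname(m4$axis_mean["position"]), oracle[3], tolerance = 1e-12)
})

test_that("block-wise CV tests every block exactly once", {
  s <- small_session(seed = 43, n_blocks = 3, trials_per_block = 8)
  r <- blockwise_cv(s, "amplitude", theta = 5L, decoder = "mlr")
  expect_equal(nrow(r$per_fold_cc), 3L)
  expect_equal(r$folds, 1:3)
  expect_true(all(is.finite(r$per_fold_cc)))
  expect_true(all(abs(r$per_fold_cc) <= 1))
  expect_equal(unname(r$axis_mean_cc["position"]),
               mean(r$mean_cc[3:4]), tolerance = 1e-12)
  expect_error(blockwise_cv(small_session(seed = 1, n_blocks = 1, trials_per_block = 8),
                            "amplitude", theta = 5L), "2 distinct blocks")
})

test_that("an exactly recoverable construction decodes almost perfectly", {
  # features that encode the kinematics linearly and noiselessly
  set.seed(44)
  n_trials <- 12
  L <- 9
  M <- matrix(rnorm(L * 4), L)
  Xs <- list(); Ys <- list()
  for (i in seq_len(n_trials)) {
    n <- 30
    Y <- matrix(rnorm(4 * n), 4)
    Xs[[i]] <- M %*% Y
    Ys[[i]] <- Y
  }
  dd <- list(X = do.call(cbind, Xs) + 1e-8 * matrix(rnorm(L * n_trials * 30), L),
             Y = do.call(cbind, Ys),
             boundaries = c(0L, cumsum(rep(30L, n_trials))),
             col_trial = rep(seq_len(n_trials), each = 30),
             trial_blocks = rep(1:3, each = 4),
             onset_states = matrix(0, 4, n_trials),
             theta = 1L, feature_kind = "amplitude", band = c(0.1, 1))
  r <- phasekin:::cv_decode(dd, "mlr")
  expect_true(all(r$per_fold_cc > 0.99))
})

test_that("per-fold CCs match an independent recomputation from dumped predictions", {
  s <- small_session(seed = 45, n_blocks = 2, trials_per_block = 6)
  r <- blockwise_cv(s, "amplitude", theta = 4L, decoder = "kf",
                    keep_predictions = TRUE)
  for (bi in seq_along(r$folds)) {
    pr <- r$predictions[[bi]]
    for (p in 1:4) {
      expect_equal(unname(r$per_fold_cc[bi, p]),
                   stats::cor(pr$predicted[p, ], pr$truth[p, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("no fold leaks the held-out block's kinematics into its predictions", {
  s <- small_session(seed = 46, n_blocks = 2, trials_per_block = 6)
  r1 <- blockwise_cv(s, "amplitude", theta = 4L, decoder = "mlr",
                     keep_predictions = TRUE)
  # corrupt the kinematics of block 1's trials
  s2 <- s
  for (i in seq_along(s2$trials)) {
    if (s2$trials[[i]]$block == 1L) {
      k <- s2$trials[[i]]$kin
      s2$trials[[i]]$kin <- kinematics_track(rev(k$sx), k$sy * 3, rev(k$dx), k$dy * 3)
    }
  }
  r2 <- blockwise_cv(s2, "amplitude", theta = 4L, decoder = "mlr",
                     keep_predictions = TRUE)
  # fold 1 (testing block 1) was fitted without block 1: identical predictions
  expect_equal(r2$predictions[["block1"]]$predicted,
               r1$predictions[["block1"]]$predicted, tolerance = 1e-10)
  # fold 2's model trained on block 1, so its predictions legitimately change
  expect_false(isTRUE(all.equal(r2$predictions[["block2"]]$predicted,
                                r1$predictions[["block2"]]$predicted)))
})

test_that("the identity permutation reproduces the authentic result exactly", {
  s <- small_session(seed = 47, n_blocks = 2, trials_per_block = 6)
  auth <- blockwise_cv(s, "amplitude", theta = 4L, decoder = "mlr")
  ch <- chance_level(s, "amplitude", theta = 4L, decoder = "mlr",
                     permutations = list(seq_along(s$trials)))
  expect_equal(unname(ch$shuffle_mean_cc[1, ]), unname(auth$mean_cc),
               tolerance = 1e-8)
  chk <- chance_level(s, "amplitude", theta = 4L, decoder = "kf",
                      permutations = list(seq_along(s$trials)))
  authk <- blockwise_cv(s, "amplitude", theta = 4L, decoder = "kf")
  expect_equal(unname(chk$shuffle_mean_cc[1, ]), unname(authk$mean_cc),
               tolerance = 1e-8)
})

test_that("chance level is reproducible from its seed", {
  s <- small_session(seed = 48, n_blocks = 2, trials_per_block = 6)
  c1 <- chance_level(s, "amplitude", theta = 4L, decoder = "mlr",
                     n_shuffles = 3, seed = 5)
  c2 <- chance_level(s, "amplitude", theta = 4L, decoder = "mlr",
                     n_shuffles = 3, seed = 5)
  expect_identical(c1$shuffle_mean_cc, c2$shuffle_mean_cc)
  c3 <- chance_level(s, "amplitude", theta = 4L, decoder = "mlr",
                     n_shuffles = 3, seed = 6)
  expect_false(identical(c1$shuffle_mean_cc, c3$shuffle_mean_cc))
})

test_that("shuffled targets resample donor kinematics onto host movement lengths", {
  s <- small_session(seed = 49, n_blocks = 2, trials_per_block = 4)
  dd <- phasekin:::decoding_data(s, "amplitude", theta = 4L)
  n_trials <- length(s$trials)
  perm <- c(n_trials, seq_len(n_trials - 1L))
  Ys <- phasekin:::shuffle_targets(dd, perm)
  expect_equal(dim(Ys), dim(dd$Y))
  cols1 <- phasekin:::trial_cols(dd, 1L)
  donor <- dd$Y[, phasekin:::trial_cols(dd, n_trials), drop = FALSE]
  # endpoints preserved under linear time resampling
  expect_equal(Ys[, cols1[1]], unname(donor[, 1]))
  expect_equal(Ys[, cols1[length(cols1)]], unname(donor[, ncol(donor)]))
})

test_that("decoder comparison handles ties and matches exact enumeration", {
  r <- compare_decoders(rep(0.5, 6), rep(0.5, 6), test = "signed_rank")
  expect_equal(r$p_value, 1)
  # all positive differences: the smallest attainable two-sided p is 2^(1-n)
  set.seed(50)
  a <- runif(8, 0.6, 0.9); b <- a - runif(8, 0.05, 0.2)
  r2 <- compare_decoders(a, b, test = "signed_rank")
  expect_equal(r2$p_value, 2^(1 - 8), tolerance = 1e-12)
  # exact enumeration oracle for small n
  enum_p <- function(d) {
    n <- length(d)
    rk <- rank(abs(d))
    w_obs <- sum(rk[d > 0])
    signs <- expand.grid(rep(list(c(0, 1)), n))
    ws <- as.matrix(signs) %*% rk
    p_ge <- mean(ws >= w_obs); p_le <- mean(ws <= w_obs)
    min(1, 2 * min(p_ge, p_le))
  }
  for (i in 1:3) {
    d <- round(runif(7, -1, 1), 3)
    d <- d[d != 0]
    if (length(d) < 5) next
    x <- runif(length(d)); y <- x - d
    r3 <- compare_decoders(x, y, test = "signed_rank")
    expect_equal(r3$p_value, enum_p(d), tolerance = 1e-9)
  }
  # rank-sum path returns a finite two-sided p
  r4 <- compare_decoders(runif(6, 0.5, 0.7), runif(6, 0.1, 0.3), test = "rank_sum")
  expect_lt(r4$p_value, 0.05)
  expect_error(compare_decoders(1:6 / 10, 1:5 / 10, test = "signed_rank"),
               "equal-length")
})

test_that("the comparator grid runs end-to-end and is shaped like the standard table", {
  s <- small_session(seed = 51, n_blocks = 2, trials_per_block = 6)
  g <- decoder_grid(s, decoders = "mlr", theta = 3L)
  expect_equal(nrow(g), 9L)     # low-delta phase + 4 bands x {power, amplitude}
  expect_setequal(unique(g$feature), c("phase", "power", "amplitude"))
  expect_true(all(is.finite(g$position_cc)))
  expect_true(all(abs(g$position_cc) <= 1 & abs(g$speed_cc) <= 1))
  expect_equal(g$config[1], "low_delta_phase-MLR")
})
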