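test_that("MLR recovers an exact linear model and matches the normal equations", {
  set.seed(11)
  X <- matrix(rnorm(10 * 200), 10)
  a0 <- matrix(rnorm(4 * 11), 4)
  Y <- a0 %*% rbind(X, 1)
  m <- fit_mlr(X, Y)
  expect_lt(max(abs(m$weights - a0)), 1e-8)
  expect_lt(max(abs(predict_mlr(m, X) - Y)), 1e-8)

  m0 <- fit_mlr(X, matrix(0, 4, 200))
  expect_lt(max(abs(m0$weights)), 1e-10)

  # normal-equations oracle on a noisy problem
  Yn <- Y + matrix(rnorm(4 * 200, sd = 0.3), 4)
  mn <- fit_mlr(X, Yn)
  A <- rbind(X, 1)
  w_ne <- t(solve(A %*% t(A), A %*% t(Yn)))
  expect_lt(max(abs(mn$weights - w_ne)), 1e-6)

  expect_error(fit_mlr(X, Yn[, 1:100]), "columns")
  expect_error(fit_mlr(X[, 1:8], Yn[, 1:8]), "more samples")
})

test_that("MLR predictions equal an element-wise product loop", {
  set.seed(12)
  X <- matrix(rnorm(5 * 20), 5)
  m <- fit_mlr(X, matrix(rnorm(2 * 20), 2))
  pred <- predict_mlr(m, X)
  Xa <- rbind(X, 1)
  oracle <- matrix(0, 2, 20)
  for (i in 1:2) for (k in 1:20) oracle[i, k] <- sum(m$weights[i, ] * Xa[, k])
  expect_equal(pred, oracle, tolerance = 1e-12)
  expect_error(predict_mlr(m, X[1:3, ]), "rows")
})

test_that("rank-deficient predictors fall back to the minimum-norm solution", {
  set.seed(13)
  X <- matrix(rnorm(4 * 100), 4)
  X <- rbind(X, X[1, ] + X[2, ])          # dependent row
  Y <- matrix(rnorm(2 * 100), 2)
  expect_warning(m <- fit_mlr(X, Y, sv_tol = 0), "rank-deficient")
  expect_true(all(is.finite(m$weights)))
  expect_equal(m$rank, 5L)
  # fitted values still minimize the residual: compare to svd least squares
  A <- t(rbind(X, 1))
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-10
  w <- t(sv$v[, pos] %*% (t(sv$u[, pos]) %*% t(Y) / sv$d[pos]))
  expect_lt(max(abs(predict_mlr(m, X) - w %*% rbind(X, 1))), 1e-8)
  # the default truncation drops near-null directions silently
  m2 <- fit_mlr(X, Y)
  expect_lt(m2$rank, 6L)
  expect_true(all(is.finite(m2$weights)))
})

test_that("noiseless system identification recovers A and H exactly", {
  set.seed(21)
  d <- 4; L <- 12; n <- 400
  A0 <- diag(d) * 0.9 + matrix(rnorm(d * d, sd = 0.02), d)
  H0 <- matrix(rnorm(L * d), L)
  Y <- matrix(0, d, n)
  Y[, 1] <- rnorm(d)
  for (k in 2:n) Y[, k] <- A0 %*% Y[, k - 1]
  X <- H0 %*% Y
  m <- fit_kf(X, Y)
  expect_lt(max(abs(m$A - A0)), 1e-6)
  expect_lt(max(abs(m$H - H0)), 1e-6)
  expect_lt(max(abs(m$h0)), 1e-6)
  ridge <- 1e-6 * mean(diag(m$Q))
  expect_lt(max(abs(m$Q - diag(diag(m$Q)[1], L))), ridge * 10 + 1e-9)
  expect_lt(max(abs(m$W)), 1e-10)
})

test_that("noise covariances are recovered within 10% from a long random walk", {
  set.seed(22)
  d <- 3; L <- 5; n <- 10000
  A0 <- diag(d)
  W0 <- diag(c(0.5, 1, 2))
  H0 <- matrix(rnorm(L * d), L)
  Q0 <- diag(seq(0.5, 1.5, length.out = L))
  Y <- matrix(0, d, n)
  for (k in 2:n) Y[, k] <- A0 %*% Y[, k - 1] + rnorm(d, sd = sqrt(diag(W0)))
  X <- H0 %*% Y + matrix(rnorm(L * n, sd = sqrt(diag(Q0))), L)
  m <- fit_kf(X, Y)
  expect_lt(max(abs(diag(m$W) / diag(W0) - 1)), 0.10)
  expect_lt(max(abs(diag(m$Q) / diag(Q0) - 1)), 0.10)
})

test_that("shuffling sample order degrades the dynamics fit", {
  set.seed(23)
  d <- 2; n <- 2000
  A0 <- matrix(c(0.95, 0.1, -0.1, 0.9), 2)
  Y <- matrix(0, d, n)
  for (k in 2:n) Y[, k] <- A0 %*% Y[, k - 1] + rnorm(d, sd = 0.1)
  X <- matrix(rnorm(3 * n), 3) + rbind(Y, 0)
  resid <- function(Ym) {
    m <- fit_kf(X, Ym)
    Y1 <- Ym[, -n]; Y2 <- Ym[, -1]
    mean((Y2 - m$A %*% Y1)^2)
  }
  r_ord <- resid(Y)
  r_shuf <- resid(Y[, sample(n)])
  expect_gt(r_shuf, r_ord * 2)
})

test_that("Kalman filter limit cases behave as expected", {
  d <- 2; L <- 2
  # observations ignored: no process noise, perfect prior, huge Q
  m1 <- structure(list(H = diag(2), h0 = c(0, 0), Q = diag(2) * 1e12,
                       A = diag(2), W = diag(2) * 0,
                       init_state = c(3, -1), init_cov = diag(2) * 0,
                       d = 2L, L = 2L), class = "kf_model")
  X <- matrix(rnorm(2 * 50), 2)
  out1 <- kf_filter(m1, X)
  expect_lt(max(abs(out1 - c(3, -1))), 1e-8)
  # observations trusted fully: invertible H, vanishing Q
  H <- matrix(c(2, 0.5, -1, 1.5), 2)
  m2 <- structure(list(H = H, h0 = c(1, -2), Q = diag(2) * 1e-12,
                       A = diag(2), W = diag(2),
                       init_state = c(0, 0), init_cov = diag(2),
                       d = 2L, L = 2L), class = "kf_model")
  out2 <- kf_filter(m2, X)
  expect_lt(max(abs(out2 - solve(H, X - c(1, -2)))), 1e-6)
})

test_that("the multivariate recursion matches a hand-written scalar Kalman filter", {
  set.seed(24)
  a <- 0.8; h <- 1.7; q <- 0.6; w <- 0.25
  x <- rnorm(50, sd = 2)
  m <- structure(list(H = matrix(h), h0 = 0, Q = matrix(q), A = matrix(a),
                      W = matrix(w), init_state = 0.4, init_cov = 1.2,
                      d = 1L, L = 1L), class = "kf_model")
  out <- kf_filter(m, matrix(x, 1))
  # independent scalar recursion (Joseph-form covariance update)
  y <- 0.4; P <- 1.2
  oracle <- numeric(50)
  for (k in 1:50) {
    if (k > 1) { y <- a * y; P <- a * P * a + w }
    S <- h * P * h + q
    K <- P * h / S
    y <- y + K * (x[k] - h * y)
    P <- (1 - K * h) * P * (1 - K * h) + K * q * K
    oracle[k] <- y
  }
  expect_lt(max(abs(as.numeric(out) - oracle)), 1e-10)
})

test_that("the state covariance recursion stays symmetric positive semidefinite", {
  set.seed(25)
  for (rep in 1:5) {
    d <- 3; L <- 6
    H <- matrix(rnorm(L * d), L)
    Q <- crossprod(matrix(rnorm(L * L), L)) / L + diag(L) * 0.1
    A <- diag(d) * 0.9
    W <- crossprod(matrix(rnorm(d * d), d)) / d
    m <- structure(list(H = H, h0 = rep(0, L), Q = Q, A = A, W = W,
                        init_state = rep(0, d), init_cov = diag(d),
                        d = d, L = L), class = "kf_model")
    g <- phasekin:::kf_gain_sequence(m, 30, tol = 0)
    Pf <- g$P_final
    expect_equal(Pf, t(Pf), tolerance = 1e-10)
    expect_gt(min(eigen(Pf, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("trial boundaries keep transitions within trials", {
  set.seed(26)
  d <- 2
  Y <- matrix(rnorm(d * 20), d)
  X <- rbind(Y, 1) + matrix(rnorm(3 * 20), 3) * 0.01
  # two trials of 10; the cross-boundary pair (10 -> 11) must be excluded
  m <- fit_kf(X, Y, boundaries = c(0L, 10L, 20L))
  pr <- phasekin:::transition_pairs(c(0L, 10L, 20L))
  expect_false(any(pr$from == 10L))
  expect_length(pr$from, 18L)
  expect_warning(phasekin:::transition_pairs(c(0L, 1L, 20L)), "fewer than 2")
})

test_that("decoders are equivariant under invertible linear rescaling of Y", {
  set.seed(27)
  L <- 6; n <- 300
  X <- matrix(rnorm(L * n), L)
  Y <- matrix(rnorm(4 * n), 4) + 0.5 * X[1:4, ]
  M <- diag(c(2, -1, 0.5, 3)) + matrix(rnorm(16, sd = 0.05), 4)
  bounds <- c(0L, 150L, 300L)
  mm <- fit_mlr(X[, 1:150], Y[, 1:150])
  mm2 <- fit_mlr(X[, 1:150], M %*% Y[, 1:150])
  expect_equal(predict_mlr(mm2, X[, 151:300]),
               M %*% predict_mlr(mm, X[, 151:300]), tolerance = 1e-8)
  mk <- fit_kf(X[, 1:150], Y[, 1:150], boundaries = c(0L, 150L))
  mk2 <- fit_kf(X[, 1:150], M %*% Y[, 1:150], boundaries = c(0L, 150L))
  p1 <- kf_filter(mk, X[, 151:300])
  p2 <- kf_filter(mk2, X[, 151:300])
  expect_equal(p2, M %*% p1, tolerance = 1e-6)
})
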