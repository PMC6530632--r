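## Kalman-filter decoder with least-squares system identification.
##
## Generative model: the high-dimensional predictor observation x_k is a
## linear function of the low-dimensional kinematic state y_k,
##     x_k = H y_k + h0 + q_k,   q_k ~ N(0, Q)
## and the state evolves as
##     y_{k+1} = A y_k + w_k,    w_k ~ N(0, W)
## with H, Q, A, W constant and estimated from training data by least
## squares. The observation intercept h0 absorbs the (large) predictor mean
## that a zero-mean kinematic state cannot represent. Decoding is the
## standard two-step predict/update recursion with Joseph-form covariance
## updates; the state is reset to the training-set onset statistics at each
## trial start.

## Within-trial (k, k+1) column index pairs given 0-based trial boundaries.
transition_pairs <- function(boundaries) {
  from <- integer(0); to <- integer(0)
  for (i in seq_len(length(boundaries) - 1L)) {
    a <- boundaries[i] + 1L; b <- boundaries[i + 1L]
    if (b - a + 1L < 2L) {
      pk_warn("trial %d has fewer than 2 samples; excluded from transition estimation", i)
      next
    }
    from <- c(from, a:(b - 1L))
    to <- c(to, (a + 1L):b)
  }
  list(from = from, to = to)
}

#' Fit the Kalman-filter decoder by least squares
#'
#' Estimates the state-transition matrix `A` (and its residual covariance
#' `W`) from within-trial consecutive state pairs only — transitions never
#' span trial boundaries — and the observation matrix `H` with intercept
#' `h0` (and residual covariance `Q`, ridge-stabilized) from all training
#' samples. The initial state and covariance are the mean and covariance of
#' the movement-onset kinematics over training trials.
#'
#' @param X Predictors: [lag_embed()] result or L x N matrix.
#' @param Y States, d x N, column-aligned with `X`.
#' @param boundaries 0-based column offsets of trial starts (length
#'   `n_trials + 1`, last element `N`). Taken from a `predictor_matrix`
#'   automatically; a plain matrix with no boundaries is treated as a single
#'   trial.
#' @param onset_states Optional d x n_trials matrix of state vectors at the
#'   movement onsets of the training trials, used for `init_state` /
#'   `init_cov`; defaults to the first column of each trial.
#' @param Sxx Optional precomputed `X %*% t(X) / N` (a fold-level cache used
#'   by the shuffle-null evaluation, where `X` is fixed and `Y` varies).
#' @param ridge_scale Ridge added to `Q` as `ridge_scale * mean(diag(Q))`
#'   for invertibility and to keep the innovation solve from amplifying the
#'   near-null directions of heavily collinear lag-embedded features (the
#'   Kalman analog of the singular-value truncation in [fit_mlr()]).
#' @return An object of class `kf_model` with `H`, `h0`, `Q`, `A`, `W`,
#'   `init_state`, `init_cov`.
#' @export
fit_kf <- function(X, Y, boundaries = NULL, onset_states = NULL, Sxx = NULL,
                   ridge_scale = 1e-3) {
  if (inherits(X, "predictor_matrix")) {
    boundaries <- boundaries %||% X$trial_boundaries
  }
  Xv <- pm_values(X)
  Y <- as.matrix(Y)
  N <- ncol(Xv); d <- nrow(Y); L <- nrow(Xv)
  if (ncol(Y) != N) pk_stop("X has %d columns but Y has %d", N, ncol(Y))
  boundaries <- boundaries %||% c(0L, N)

  ## state transition: A = argmin sum ||Y_{k+1} - A Y_k||^2 over within-trial pairs
  pr <- transition_pairs(boundaries)
  if (length(pr$from) < d + 1L) pk_stop("too few within-trial transitions to estimate A")
  Y1 <- Y[, pr$from, drop = FALSE]; Y2 <- Y[, pr$to, drop = FALSE]
  A <- t(qr.solve(t(Y1), t(Y2)))
  RW <- Y2 - A %*% Y1
  W <- make_psd(tcrossprod(RW) / ncol(RW))

  ## observation model with intercept: X ~ H Y + h0
  Ya <- rbind(Y, 1)
  Syy <- tcrossprod(Ya) / N                  # (d+1) x (d+1)
  Syx <- (Ya %*% t(Xv)) / N                  # (d+1) x L
  G <- t(solve(Syy, Syx))                    # L x (d+1)
  H <- G[, seq_len(d), drop = FALSE]
  h0 <- G[, d + 1L]
  if (is.null(Sxx)) Sxx <- tcrossprod(Xv) / N
  Q <- Sxx - t(Syx) %*% solve(Syy, Syx)      # residual covariance, exact identity
  Q <- (Q + t(Q)) / 2
  eps <- ridge_scale * mean(diag(Q))
  if (!is.finite(eps) || eps <= 0) eps <- ridge_scale
  Q <- Q + diag(eps, L)

  ## initial state statistics from training movement onsets
  if (is.null(onset_states)) {
    onset_states <- Y[, boundaries[-length(boundaries)] + 1L, drop = FALSE]
  }
  init_state <- rowMeans(onset_states)
  init_cov <- if (ncol(onset_states) > 1L) {
    make_psd(stats::cov(t(onset_states)))
  } else {
    matrix(0, d, d)
  }

  structure(list(H = H, h0 = h0, Q = Q, A = A, W = W,
                 init_state = init_state, init_cov = init_cov,
                 d = d, L = L),
            class = "kf_model")
}

#' @export
print.kf_model <- function(x, ...) {
  cat(sprintf("<kf_model: state dim %d, observation dim %d>\n", x$d, x$L))
  invisible(x)
}

## Precompute the gain sequence K_k and Joseph covariance recursion for a
## trial of n steps. P_k does not depend on the data, so gains are shared by
## every trial (up to length) within a fold; the recursion is truncated once
## P converges to steady state and the last gain is reused.
kf_gain_sequence <- function(model, n_steps, tol = 1e-10, max_distinct = Inf) {
  d <- model$d
  H <- model$H; Q <- model$Q; A <- model$A; W <- model$W
  P <- model$init_cov
  Ks <- vector("list", 0L)
  ImKHs <- vector("list", 0L)
  converged <- FALSE
  for (k in seq_len(n_steps)) {
    P_pred <- if (k == 1L) P else A %*% P %*% t(A) + W
    S <- H %*% P_pred %*% t(H) + Q           # L x L innovation covariance
    ## K = P_pred H' S^{-1}  via the symmetric solve S K' = H P_pred
    K <- t(solve(S, H %*% P_pred))
    ImKH <- diag(d) - K %*% H
    P_new <- ImKH %*% P_pred %*% t(ImKH) + K %*% Q %*% t(K)
    P_new <- (P_new + t(P_new)) / 2
    Ks[[k]] <- K; ImKHs[[k]] <- ImKH
    if (k > 1L && max(abs(P_new - P)) < tol) {
      converged <- TRUE
      P <- P_new
      break
    }
    P <- P_new
    if (length(Ks) >= max_distinct) { converged <- TRUE; break }
  }
  list(K = Ks, ImKH = ImKHs, converged = converged, P_final = P)
}

#' Run the Kalman filter over one trial's predictors
#'
#' Standard predict/update recursion: predict `y- = A y`,
#' `P- = A P A' + W`; update with gain `K = P- H' (H P- H' + Q)^{-1}`,
#' `y = y- + K (x - H y- - h0)`, `P` updated in Joseph form (which preserves
#' symmetry and positive semi-definiteness). The state starts from the
#' model's `init_state` / `init_cov`.
#'
#' Because the covariance recursion is data-independent, the gain sequence
#' can be computed once per model and trial length and reused across trials;
#' pass `gains` (from the internal cache) to do so.
#'
#' @param model A `kf_model`.
#' @param X Predictor sequence for one trial (L x n).
#' @param gains Optional precomputed gain sequence.
#' @return d x n matrix of filtered state estimates.
#' @export
kf_filter <- function(model, X, gains = NULL) {
  Xv <- pm_values(X)
  if (nrow(Xv) != model$L) {
    pk_stop("predictor has %d rows but the model expects %d", nrow(Xv), model$L)
  }
  n <- ncol(Xv)
  if (is.null(gains)) gains <- kf_gain_sequence(model, n)
  n_distinct <- length(gains$K)
  y <- model$init_state
  out <- matrix(NA_real_, nrow = model$d, ncol = n)
  for (k in seq_len(n)) {
    y_pred <- if (k == 1L) y else as.numeric(model$A %*% y)
    idx <- min(k, n_distinct)
    K <- gains$K[[idx]]
    innov <- Xv[, k] - as.numeric(model$H %*% y_pred) - model$h0
    y <- y_pred + as.numeric(K %*% innov)
    if (!all(is.finite(y))) pk_stop("non-finite Kalman state at sample %d", k)
    out[, k] <- y
  }
  out
}
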