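## Multiple linear regression decoder: kinematics as a linear readout of the
## bias-augmented lag-embedded predictors, fitted by least squares.

pm_values <- function(X) if (inherits(X, "predictor_matrix")) X$values else as.matrix(X)

#' Fit the multiple linear regression decoder
#'
#' Solves `Y ~ weights %*% rbind(X, 1)` in the least-squares sense by a
#' rank-revealing singular value decomposition: singular directions below
#' `sv_tol` times the leading singular value are treated as rank-deficient
#' and dropped, giving the minimum-norm solution on the effective column
#' space. Lag-embedded narrowband features are heavily collinear (adjacent
#' lags of a slow oscillation are nearly identical), so the unregularized
#' solution would carry enormous opposing weights that amplify feature
#' noise on held-out data; the truncation discards directions whose scale
#' is far below the feature noise floor. `sv_tol = 0` gives the exact
#' least-squares solution.
#'
#' @param X Predictors: a [lag_embed()] result or a plain L x N matrix.
#' @param Y Targets, d x N (rows `{sx, sy, dx, dy}` in the standard
#'   pipeline).
#' @param sv_tol Relative singular-value cutoff (default `1e-3`).
#' @return An object of class `mlr_model` with `weights` (d x (L+1); the
#'   last column is the bias).
#' @export
fit_mlr <- function(X, Y, sv_tol = 1e-3) {
  Xv <- pm_values(X)
  Y <- as.matrix(Y)
  N <- ncol(Xv)
  if (ncol(Y) != N) {
    pk_stop("X has %d columns (samples) but Y has %d", N, ncol(Y))
  }
  L <- nrow(Xv)
  if (N <= L + 1L) {
    pk_stop("need more samples (%d) than predictors + 1 (%d) for least squares",
            N, L + 1L)
  }
  A <- t(rbind(Xv, 1))                       # N x (L+1)
  sv <- svd(A)
  keep <- sv$d > max(sv_tol * sv$d[1L],
                     max(dim(A)) * .Machine$double.eps * sv$d[1L])
  if (sum(keep) < L + 1L && sv_tol == 0) {
    pk_warn("predictor matrix is rank-deficient (rank %d < %d); using the minimum-norm solution",
            sum(keep), L + 1L)
  }
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% t(Y)) / sv$d[keep])
  structure(list(weights = t(coef), L = L, rank = sum(keep)), class = "mlr_model")
}

#' Predict kinematics with a fitted MLR model
#'
#' @param model An `mlr_model`.
#' @param X Predictors with the same row count as at fit time.
#' @return d x N matrix of predicted kinematics.
#' @export
predict_mlr <- function(model, X) {
  Xv <- pm_values(X)
  if (nrow(Xv) != model$L) {
    pk_stop("predictor has %d rows but the model was fitted with %d", nrow(Xv), model$L)
  }
  model$weights %*% rbind(Xv, 1)
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("<mlr_model: %d outputs x %d predictors (+bias)>\n",
              nrow(x$weights), x$L))
  invisible(x)
}
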