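## Feature extraction: analytic signal, instantaneous phase, amplitude and
## sliding-window bandpower representations, and the lag-embedded predictor
## matrix fed to the decoders.

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns `x + i * HT(x)` where `HT` is the discrete Hilbert transform,
#' built in the frequency domain by doubling positive frequencies and
#' zeroing negative ones. The real part equals `x` exactly.
#'
#' @param x Finite real numeric vector, length >= 4.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 4L) pk_stop("analytic_signal needs at least 4 samples (got %d)", n)
  if (!all(is.finite(x))) pk_stop("analytic_signal needs finite input")
  if (all(x == 0)) pk_stop("analytic_signal is undefined for an all-zero series")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  complex(real = x, imaginary = Im(z))
}

#' Instantaneous phase of a narrowband series
#'
#' The four-quadrant angle of the analytic signal, wrapped to `(-pi, pi]`.
#' Intended for band-limited input (after 0.1-1 Hz filtering). With
#' `unwrap = TRUE` the series is unwrapped to a continuous trajectory
#' differing from the wrapped one by multiples of `2*pi`.
#'
#' @param x Real numeric vector (band-limited).
#' @param unwrap Return the unwrapped (continuous) phase.
#' @return Phase in radians, same length as `x`.
#' @export
instantaneous_phase <- function(x, unwrap = FALSE) {
  ph <- Arg(analytic_signal(x))
  if (unwrap) ph <- unwrap_phase(ph)
  ph
}

## Standard phase unwrapping: remove 2*pi jumps between successive samples.
unwrap_phase <- function(ph) {
  d <- diff(ph)
  steps <- cumsum(c(0, round(d / (2 * pi))))
  ph - 2 * pi * steps
}

#' Time-resolved bandpower
#'
#' Mean of squared samples in a sliding window (default 500 ms) ending at
#' each step sample (causal alignment, so the feature never uses future
#' data), stepped at `step_s` (default 10 ms). At the head of the series,
#' before one full window has elapsed, the mean is taken over the samples
#' available so far (expanding window), keeping the output on the same clock
#' grid from the first step.
#'
#' @param x Band-filtered numeric vector, or channels x samples matrix.
#' @param window_s Window length in seconds (default 0.5).
#' @param step_s Step in seconds (default 0.01).
#' @param sample_rate Hz.
#' @return Non-negative power series on the feature clock (rate
#'   `1 / step_s`); with `step_s == 1 / sample_rate` the output has the
#'   length of `x`.
#' @export
bandpower_feature <- function(x, window_s = 0.5, step_s = 0.01, sample_rate = 100) {
  w <- as.integer(round(window_s * sample_rate))
  k <- as.integer(round(step_s * sample_rate))
  if (w < 1L || k < 1L) pk_stop("window and step must cover at least one sample")
  one <- function(v) {
    n <- length(v)
    if (w > n) pk_stop("window (%d samples) longer than the series (%d)", w, n)
    cs <- cumsum(v^2)
    full_start <- (w + 1L):n
    means <- c(cs[seq_len(w)] / seq_len(w),            # expanding head
               (cs[full_start] - cs[full_start - w]) / w)
    means[seq(1L, n, by = k)]
  }
  if (is.null(dim(x))) one(x) else t(apply(x, 1L, one))
}

#' Per-trial feature representations of a session
#'
#' Computes one of the three feature representations for every trial:
#' \describe{
#'   \item{phase}{instantaneous phase of the band-filtered signal (wrapped by
#'     default; the movement-interval trajectory occupies roughly
#'     `[pi, 3*pi/2]` and is treated as a continuous linear variable).}
#'   \item{amplitude}{the band-filtered signal's time course itself.}
#'   \item{power}{sliding-window mean square of the band-filtered signal.}
#' }
#' Each trial is band-filtered at the session rate, transformed, and (by
#' default) each channel is normalized to unit Euclidean length over the
#' trial. Because an epoch (about 1.3 s) is much shorter than the slowest
#' time constant of a 0.1 Hz band edge, epochs are demeaned and zero-padded
#' to three filter time constants before the zero-phase filter, and the
#' analytic signal for the phase representation is computed on the padded
#' filtered series before cropping — this keeps filter and Hilbert edge
#' transients away from the movement interval at the epoch tail.
#'
#' @param session An [eeg_session()] (already re-referenced if desired; see
#'   [preprocess_session()]).
#' @param kind `"phase"`, `"amplitude"` or `"power"`.
#' @param band `c(low, high)` Hz.
#' @param order Butterworth design order (2 for low-delta, 8 otherwise).
#' @param normalize Per-trial, per-channel normalization: `"unit"` divides
#'   each channel by its Euclidean norm over the trial (the decoding-path
#'   treatment of amplitude and power features); `"zscore"` centers and
#'   scales each channel (the treatment applied to the continuous phase
#'   variable, which also removes per-trial common-mode phase offsets and
#'   the arbitrary `2*pi` branch of an unwrapped trajectory); `"none"`
#'   leaves raw values. `TRUE`/`FALSE` are accepted as `"unit"`/`"none"`.
#' @param unwrap Use unwrapped (continuous) phase. Defaults to `TRUE` when
#'   `normalize = "zscore"` is selected for phase, else `FALSE`.
#' @param phase_range Wrapping convention for the phase feature:
#'   `"two_pi"` (default) maps angles to `[0, 2*pi)`, where the
#'   movement-interval trajectory `[pi, 3*pi/2]` is continuous and can be
#'   treated as an ordinary linear variable; `"pi"` keeps the raw
#'   `(-pi, pi]` four-quadrant angle, which places the wrap point in the
#'   middle of the movement trajectory.
#' @param window_s,step_s Bandpower window and step.
#' @return A list of `feature_trial` objects (fields: `values` channels x
#'   samples, `kind`, `band`, `sample_rate`, `onset_index`, `direction`,
#'   `block`, `kin`).
#' @export
session_features <- function(session, kind = c("phase", "amplitude", "power"),
                             band = c(0.1, 1), order = 2, normalize = "unit",
                             unwrap = NULL, window_s = 0.5, step_s = NULL,
                             phase_range = c("two_pi", "pi")) {
  kind <- match.arg(kind)
  phase_range <- match.arg(phase_range)
  if (isTRUE(normalize)) normalize <- "unit"
  if (isFALSE(normalize)) normalize <- "none"
  normalize <- match.arg(normalize, c("unit", "zscore", "none"))
  unwrap <- unwrap %||% (kind == "phase" && normalize == "zscore")
  validate_session(session)
  fs <- session$sample_rate
  step_s <- step_s %||% (1 / fs)
  if (kind == "power" && abs(step_s * fs - round(step_s * fs)) > 1e-9) {
    pk_stop("bandpower step must be a whole number of samples at %g Hz", fs)
  }
  chan <- session$montage$channel
  sos <- butter_bandpass_sos(order, band[1], band[2], fs)
  pad <- sos_settle_samples(sos)
  lapply(session$trials, function(tr) {
    n <- ncol(tr$eeg)
    vals <- t(apply(tr$eeg, 1L, function(row) {
      f <- sos_filtfilt(sos, row, pad, edge = "zero", crop = FALSE)
      if (kind == "phase") {
        # extend to an FFT-friendly length (the tail is already near zero)
        y <- f$y
        tgt <- stats::nextn(length(y), c(2, 3, 5))
        if (tgt > length(y)) y <- c(y, rep(0, tgt - length(y)))
        ph <- instantaneous_phase(y, unwrap = unwrap)
        ph <- ph[(f$pad + 1L):(f$pad + n)]
        if (!unwrap && phase_range == "two_pi") ph <- ph %% (2 * pi)
        ph
      } else {
        f$y[(f$pad + 1L):(f$pad + n)]
      }
    }))
    if (kind == "power") {
      vals <- bandpower_feature(vals, window_s = window_s, step_s = step_s,
                                sample_rate = fs)
    }
    if (kind == "power" && step_s * fs != 1) {
      pk_stop("decoder features require the bandpower step to equal the sample interval")
    }
    if (normalize == "unit") {
      vals <- normalize_unit_length(vals, chan)
    } else if (normalize == "zscore") {
      mu <- rowMeans(vals)
      sdv <- apply(vals, 1L, stats::sd)
      if (any(sdv == 0)) pk_stop("cannot z-score constant channel(s)")
      vals <- (vals - mu) / sdv
    }
    structure(list(values = vals, kind = kind, band = band, sample_rate = fs,
                   onset_index = tr$onset_index, direction = tr$direction,
                   block = tr$block, kin = tr$kin),
              class = "feature_trial")
  })
}

#' Lag-embedded predictor matrix
#'
#' Stacks, for every movement-interval sample `k` of every trial, the feature
#' of channel `c` at samples `k, k-1, ..., k-(theta-1)` into one predictor
#' column. With `C` channels the matrix has `L = C * theta` rows (plus a bias
#' row of ones when requested); row `(c-1)*theta + tau` holds channel `c` at
#' lag `tau - 1`. Targets are restricted to the movement interval
#' `[onset, end)`; the lag history may reach into the pre-onset epoch but
#' never across trials.
#'
#' @param feature_trials List of `feature_trial` objects (or any list with
#'   `values` and `onset_index`), all with the same channel count.
#' @param theta Embedding dimension: number of time delays plus one
#'   (default 11).
#' @param bias Append a row of ones.
#' @param targets Which samples become predictor columns: `"movement"`
#'   (default; movement-interval samples only, though the lag history may
#'   reach into the pre-onset epoch) or `"epoch"` (every sample with a
#'   complete lag history, i.e. from sample `theta - 1` on, so
#'   reconstruction runs continuously across rest and movement).
#' @return An object of class `predictor_matrix`: `values` (L x N),
#'   `theta`, `channel_of_row`, `lag_of_row`, `trial_boundaries` (0-based
#'   column offsets of each trial's first column, plus the total), and
#'   `col_trial` (trial index per column).
#' @export
lag_embed <- function(feature_trials, theta = 11L, bias = FALSE,
                      targets = c("movement", "epoch")) {
  stopifnot(is_count(theta))
  targets <- match.arg(targets)
  C <- nrow(feature_trials[[1L]]$values)
  if (!all(vapply(feature_trials, function(ft) nrow(ft$values), integer(1)) == C)) {
    pk_stop("all trials must share one channel count")
  }
  L <- C * theta
  first_k <- function(ft) {
    if (targets == "movement") ft$onset_index + 1L else as.integer(theta)
  }
  n_cols <- vapply(feature_trials, function(ft) {
    ncol(ft$values) - first_k(ft) + 1L
  }, integer(1))
  total <- sum(n_cols)
  values <- matrix(NA_real_, nrow = L, ncol = total)
  col_trial <- integer(total)
  off <- 0L
  for (i in seq_along(feature_trials)) {
    ft <- feature_trials[[i]]
    n <- ncol(ft$values)
    ks <- first_k(ft):n                    # R indices of target samples
    if (min(ks) - theta < 0L) {
      pk_stop("trial %d is too short for theta = %d (needs %d pre-onset samples)",
              i, theta, theta - 1L)
    }
    for (tau in seq_len(theta)) {
      rows <- (seq_len(C) - 1L) * theta + tau
      values[rows, (off + 1L):(off + length(ks))] <- ft$values[, ks - tau + 1L, drop = FALSE]
    }
    col_trial[(off + 1L):(off + length(ks))] <- i
    off <- off + length(ks)
  }
  channel_of_row <- rep(seq_len(C), each = theta)
  lag_of_row <- rep(seq_len(theta) - 1L, times = C)
  if (bias) {
    values <- rbind(values, 1)
    channel_of_row <- c(channel_of_row, NA_integer_)
    lag_of_row <- c(lag_of_row, NA_integer_)
  }
  structure(list(values = values, theta = as.integer(theta),
                 channel_of_row = channel_of_row, lag_of_row = lag_of_row,
                 trial_boundaries = c(0L, cumsum(n_cols)),
                 col_trial = col_trial, bias = bias, targets = targets),
            class = "predictor_matrix")
}

#' Kinematic target matrix
#'
#' The 4 x N target matrix matching the columns of [lag_embed()]: rows
#' `{sx, sy, dx, dy}` over the target samples of every trial, concatenated
#' in trial order.
#'
#' @param feature_trials The same list passed to [lag_embed()] (each element
#'   carrying `kin` and `onset_index`), or a list of [eeg_trial()] objects.
#' @param theta,targets Must match the [lag_embed()] call.
#' @return 4 x N numeric matrix.
#' @export
kinematic_targets <- function(feature_trials, theta = 11L,
                              targets = c("movement", "epoch")) {
  targets <- match.arg(targets)
  cols <- lapply(feature_trials, function(ft) {
    n <- length(ft$kin)
    a <- if (targets == "movement") ft$onset_index + 1L else as.integer(theta)
    kin_matrix(kin_slice(ft$kin, a:n))
  })
  do.call(cbind, cols)
}
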