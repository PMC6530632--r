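## Channel-level movement statistics: time-resolved effect size,
## feature-speed correlation, the rest-vs-movement contrast coefficient F,
## and activation-index channel selection.

## Sample indices (R, 1-based) of a window given in seconds relative to the
## movement onset; half-open [from, to).
window_idx <- function(onset_index, window_s, sample_rate) {
  a <- as.integer(round(window_s[1] * sample_rate))
  b <- as.integer(round(window_s[2] * sample_rate))
  if (b <= a) pk_stop("empty window [%g, %g)", window_s[1], window_s[2])
  (onset_index + a + 1L):(onset_index + b)
}

check_window_inside <- function(ft, idx, what) {
  if (min(idx) < 1L || max(idx) > ncol(ft$values)) {
    pk_stop("%s window falls outside an epoch (%d samples, needs %d..%d)",
            what, ncol(ft$values), min(idx), max(idx))
  }
}

#' Time-resolved effect size of a feature
#'
#' Computes the grand average of the feature over trials per channel, then
#' expresses the movement sub-interval as a deviation from the baseline in
#' baseline-standard-deviation units: `(GA(t) - mean(GA_baseline)) /
#' sd(GA_baseline)`. This is a per-channel signal-to-noise measure of the
#' movement-locked response.
#'
#' @param feature_trials List of `feature_trial` objects (see
#'   [session_features()]).
#' @param baseline,movement Windows in seconds relative to onset, half-open
#'   (defaults \[-0.2, -0.1) and \[0, 0.2)).
#' @return Channels x movement-window-samples matrix of effect sizes.
#' @export
effect_size <- function(feature_trials, baseline = c(-0.2, -0.1),
                        movement = c(0, 0.2)) {
  if (length(feature_trials) < 2L) pk_stop("effect size needs at least 2 trials")
  fs <- feature_trials[[1L]]$sample_rate
  ga_win <- function(window_s, what) {
    mats <- lapply(feature_trials, function(ft) {
      idx <- window_idx(ft$onset_index, window_s, fs)
      check_window_inside(ft, idx, what)
      ft$values[, idx, drop = FALSE]
    })
    Reduce(`+`, mats) / length(mats)
  }
  ga_bl <- ga_win(baseline, "baseline")
  ga_mv <- ga_win(movement, "movement")
  bl_mean <- rowMeans(ga_bl)
  bl_sd <- apply(ga_bl, 1L, stats::sd)
  if (any(bl_sd == 0)) {
    pk_stop("degenerate baseline: zero variance on channel(s) %s",
            paste(which(bl_sd == 0), collapse = ", "))
  }
  (ga_mv - bl_mean) / bl_sd
}

#' Absolute correlation between a feature and movement speed
#'
#' Pools the movement-interval samples of every trial by concatenation and
#' returns the absolute Pearson correlation between each channel's feature
#' and the absolute hand speed — the strength of their linear relationship,
#' 0 (none) to 1 (perfect).
#'
#' @param feature_trials List of `feature_trial` objects.
#' @param movement_window Window in seconds relative to onset, or `NULL`
#'   (default) for each trial's full movement interval.
#' @return Named numeric vector of `|r|` per channel.
#' @export
feature_speed_correlation <- function(feature_trials, movement_window = NULL) {
  fs <- feature_trials[[1L]]$sample_rate
  feats <- list(); speeds <- list()
  for (ft in feature_trials) {
    idx <- if (is.null(movement_window)) {
      (ft$onset_index + 1L):ncol(ft$values)
    } else {
      i <- window_idx(ft$onset_index, movement_window, fs)
      check_window_inside(ft, i, "movement")
      i
    }
    feats[[length(feats) + 1L]] <- ft$values[, idx, drop = FALSE]
    speeds[[length(speeds) + 1L]] <- abs_speed(ft$kin)[idx]
  }
  fmat <- do.call(cbind, feats)
  sp <- unlist(speeds)
  if (stats::var(sp) == 0) pk_stop("speed has zero variance in the window")
  v <- apply(fmat, 1L, stats::var)
  if (any(v == 0)) {
    pk_stop("feature has zero variance on channel(s) %s",
            paste(which(v == 0), collapse = ", "))
  }
  r <- abs(as.numeric(stats::cor(t(fmat), sp)))
  names(r) <- rownames(fmat)
  r
}

#' Rest-vs-movement contrast coefficient F
#'
#' Quantifies how strongly a feature changes between the rest (baseline) and
#' movement states: the magnitude of the signed point-biserial correlation
#' squared,
#' `F = | sign(m - r) (m - r)^2 N_m N_r / (sigma^2 N^2) |`,
#' where `m` and `r` are the state means, `sigma^2` the pooled (population)
#' variance over both states and `N = N_m + N_r`. Algebraically this equals
#' the squared Pearson correlation between the feature and the 0/1 state
#' indicator, so `F` lies in `[0, 1]` and is invariant to affine rescaling
#' of the feature.
#'
#' @param values Numeric vector of feature samples.
#' @param labels Character/factor vector per sample, `"rest"` or
#'   `"movement"`.
#' @return Scalar F in `[0, 1]`.
#' @export
state_contrast_F <- function(values, labels) {
  labels <- as.character(labels)
  if (!all(labels %in% c("rest", "movement"))) {
    pk_stop("labels must be 'rest' or 'movement'")
  }
  xm <- values[labels == "movement"]; xr <- values[labels == "rest"]
  if (length(xm) == 0L || length(xr) == 0L) pk_stop("both states must be represented")
  n <- length(values)
  sigma2 <- mean((values - mean(values))^2)   # pooled population variance
  if (sigma2 == 0) pk_stop("pooled variance is zero")
  m <- mean(xm); r <- mean(xr)
  abs(sign(m - r) * (m - r)^2 * length(xm) * length(xr) / (sigma2 * n^2))
}

#' Electrode activation index
#'
#' Per-channel maximum of the amplitude- and phase-derived contrast
#' coefficients: whichever representation shows the greater rest-to-movement
#' change defines the channel's activation.
#'
#' @param F_amplitude,F_phase Numeric vectors over the same channel set.
#' @return Element-wise maximum, keeping names.
#' @export
activation_index <- function(F_amplitude, F_phase) {
  if (length(F_amplitude) != length(F_phase)) {
    pk_stop("F_amplitude and F_phase must cover the same channels")
  }
  pmax(F_amplitude, F_phase)
}

#' Per-channel contrast statistics for a session
#'
#' Computes, per direction and channel, the rest-vs-movement contrast
#' coefficient of the amplitude and phase representations (rest samples
#' drawn from the baseline window of every epoch, movement samples from the
#' movement window) and the activation index.
#'
#' @param session An [eeg_session()].
#' @param band,order Band and filter design order for the representations.
#' @param baseline,movement Windows in seconds relative to onset.
#' @param car Apply common-average referencing first.
#' @return Data frame with columns `direction`, `channel`, `region`,
#'   `F_amplitude`, `F_phase`, `AI`.
#' @export
channel_contrast <- function(session, band = c(0.1, 1), order = 2,
                             baseline = c(-0.2, -0.1), movement = c(0, 0.2),
                             car = TRUE) {
  validate_session(session)
  sess <- if (car) preprocess_session(session, band = NULL, target_rate = NULL) else session
  amp <- session_features(sess, "amplitude", band = band, order = order, normalize = FALSE)
  pha <- session_features(sess, "phase", band = band, order = order, normalize = FALSE)
  fs <- session$sample_rate
  dirs <- unique(vapply(sess$trials, function(tr) tr$direction, character(1)))
  out <- list()
  for (dir in dirs) {
    sel <- which(vapply(amp, function(ft) ft$direction == dir, logical(1)))
    pool <- function(fts) {
      vals <- list(); labs <- list()
      for (i in sel) {
        ft <- fts[[i]]
        bi <- window_idx(ft$onset_index, baseline, fs)
        mi <- window_idx(ft$onset_index, movement, fs)
        check_window_inside(ft, bi, "baseline"); check_window_inside(ft, mi, "movement")
        vals[[length(vals) + 1L]] <- cbind(ft$values[, bi, drop = FALSE],
                                           ft$values[, mi, drop = FALSE])
        labs[[length(labs) + 1L]] <- c(rep("rest", length(bi)), rep("movement", length(mi)))
      }
      list(values = do.call(cbind, vals), labels = unlist(labs))
    }
    pa <- pool(amp); pp <- pool(pha)
    Fa <- apply(pa$values, 1L, state_contrast_F, labels = pa$labels)
    Fp <- apply(pp$values, 1L, state_contrast_F, labels = pp$labels)
    out[[length(out) + 1L]] <- data.frame(
      direction = dir, channel = session$montage$channel,
      region = session$montage$region,
      F_amplitude = Fa, F_phase = Fp, AI = activation_index(Fa, Fp),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Representative frontal and parietal channels
#'
#' Selects the channel with the highest activation index within the frontal
#' region and within the parietal region — the cortices reported to carry
#' reach planning/execution information. Ties break by montage order, with
#' a message.
#'
#' @param AI Named numeric vector of activation indices (names are channel
#'   labels) for one direction.
#' @param montage The session [montage()].
#' @return List with elements `frontal` and `parietal` (channel labels).
#' @export
select_representative_channels <- function(AI, montage) {
  validate_montage(montage, need_regions = TRUE)
  if (is.null(names(AI))) names(AI) <- montage$channel
  pick <- function(region) {
    ch <- montage$channel[montage$region == region]
    if (length(ch) == 0L) pk_stop("montage has no %s channels", region)
    vals <- AI[ch]
    if (anyNA(vals)) pk_stop("AI missing for %s channel(s)", region)
    top <- which(vals == max(vals))
    if (length(top) > 1L) {
      message(sprintf("AI tie in the %s region (%s); keeping montage order",
                      region, paste(ch[top], collapse = ", ")))
    }
    ch[top[1L]]
  }
  list(frontal = pick("frontal"), parietal = pick("parietal"))
}
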