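## Signal-conditioning chain: common-average reference, zero-phase
## Butterworth band filtering, decimation, per-channel normalization.
##
## Filters are designed as Butterworth second-order sections (biquads) from
## the analog prototype poles via the bilinear transform, rather than as a
## single transfer function: high-order narrowband designs (e.g. 8th-order
## 1-4 Hz at 100 Hz) are numerically unstable in expanded polynomial form but
## well-conditioned as cascaded biquads.

#' Common-average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, the
#' standard re-referencing step to suppress globally shared activity.
#'
#' @param eeg Channels x samples matrix.
#' @return Matrix of the same shape; column means are zero.
#' @export
common_average_reference <- function(eeg) {
  eeg <- as_channel_matrix(eeg)
  if (nrow(eeg) < 2L) pk_stop("CAR needs at least 2 channels")
  sweep(eeg, 2L, colMeans(eeg), "-")
}

## Analog Butterworth lowpass prototype poles (unit cutoff), order n.
butter_prototype_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

## Pair complex-conjugate (and real) digital poles into biquad denominators.
pair_poles <- function(zp) {
  zp <- zp[order(-Mod(zp), Re(zp), abs(Im(zp)))]
  used <- rep(FALSE, length(zp))
  out <- list()
  for (i in seq_along(zp)) {
    if (used[i]) next
    p1 <- zp[i]; used[i] <- TRUE
    if (abs(Im(p1)) > 1e-10) {
      j <- which(!used & Mod(zp - Conj(p1)) < 1e-7)[1]
      if (is.na(j)) pk_stop("internal: unpaired complex pole in filter design")
      used[j] <- TRUE
      out[[length(out) + 1L]] <- c(1, -2 * Re(p1), Mod(p1)^2)
    } else {
      j <- which(!used & abs(Im(zp)) <= 1e-10)[1]
      if (is.na(j)) {
        out[[length(out) + 1L]] <- c(1, -Re(p1), 0)
      } else {
        used[j] <- TRUE
        out[[length(out) + 1L]] <- c(1, -Re(p1 + zp[j]), Re(p1 * zp[j]))
      }
    }
  }
  out
}

sos_gain_at <- function(sos, w) {
  z <- exp(1i * w)
  g <- 1 + 0i
  for (s in sos) {
    g <- g * (s$b[1] * z^2 + s$b[2] * z + s$b[3]) /
      (s$a[1] * z^2 + s$a[2] * z + s$a[3])
  }
  g
}

## Bandpass Butterworth as second-order sections; `order` is the design
## order of the underlying lowpass prototype (the conventional reading of
## "2nd order" / "8th order" band-pass descriptions), giving a polynomial
## of degree 2*order.
butter_bandpass_sos <- function(order, low_hz, high_hz, sample_rate) {
  fs <- sample_rate
  wl <- 2 * fs * tan(pi * low_hz / fs)
  wh <- 2 * fs * tan(pi * high_hz / fs)
  w0 <- sqrt(wl * wh); bw <- wh - wl
  poles <- unlist(lapply(butter_prototype_poles(order), function(p) {
    disc <- sqrt((p * bw)^2 / 4 - w0^2)
    c(p * bw / 2 + disc, p * bw / 2 - disc)
  }))
  zp <- (2 * fs + poles) / (2 * fs - poles)
  dens <- pair_poles(zp)
  wc <- 2 * atan(w0 / (2 * fs))   # digital center frequency
  lapply(dens, function(a) {
    s <- list(b = c(1, 0, -1), a = a)   # one zero at z = 1, one at z = -1
    g <- Mod(sos_gain_at(list(s), wc))
    s$b <- s$b / g
    s
  })
}

## Lowpass Butterworth as second-order sections, unit DC gain.
butter_lowpass_sos <- function(order, cutoff_hz, sample_rate) {
  fs <- sample_rate
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)
  poles <- butter_prototype_poles(order) * wc
  zp <- (2 * fs + poles) / (2 * fs - poles)
  dens <- pair_poles(zp)
  lapply(dens, function(a) {
    s <- list(b = c(1, 2, 1), a = a)    # zeros at z = -1
    g <- Mod(sos_gain_at(list(s), 0))
    s$b <- s$b / g
    s
  })
}

## One forward pass of an SOS cascade.
sos_apply <- function(sos, x) {
  for (s in sos) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

## Samples needed for `factor` time constants of the cascade's slowest
## pole: the settling length of the filter's impulse response, which is
## what edge padding has to cover. Three time constants (residual e^-3,
## ~5%) suffice where the padded content is already small (demeaned
## epochs); start-up transients from un-demeaned signals need more.
sos_settle_samples <- function(sos, factor = 3) {
  pmax_ <- max(vapply(sos, function(s) {
    max(Mod(polyroot(rev(s$a))))
  }, numeric(1)))
  pmax_ <- min(pmax_, 1 - 1e-8)
  as.integer(ceiling(-factor / log(pmax_)))
}

## Forward-backward (zero-phase) SOS filtering with edge padding.
sos_filtfilt <- function(sos, x, pad, edge = "reflect", crop = TRUE) {
  p <- switch(edge, reflect = reflect_pad(x, pad), zero = zero_pad(x, pad),
              pk_stop("unknown edge mode '%s'", edge))
  y <- sos_apply(sos, p$x)
  y <- rev(sos_apply(sos, rev(y)))
  if (!crop) return(list(y = y, pad = p$pad))
  if (p$pad > 0L) y[(p$pad + 1L):(p$pad + length(x))] else y
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the filter forward and backward (zero net phase shift; the
#' effective magnitude response is the squared one-pass response). Edge
#' transients are mitigated by padding of three filter time constants — the
#' settling length of the cascade's slowest pole — capped at the signal
#' length in the reflective mode.
#'
#' @param x Numeric vector, or channels x samples matrix (filtered per row).
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low < high < sample_rate / 2`.
#' @param order One-pass design order (2 for the low-delta band, 8 for the
#'   other-band comparators).
#' @param sample_rate Hz.
#' @param edge Edge treatment: `"reflect"` (odd reflection, capped at the
#'   signal length; appropriate for long continuous signals) or `"zero"`
#'   (demean then zero-pad; appropriate for epochs shorter than the
#'   filter's slowest time constant, where a reflection cannot supply the
#'   needed context).
#' @return Filtered signal, same shape and length as `x`.
#' @export
bandpass_filter <- function(x, low_hz, high_hz, order = 2, sample_rate = 100,
                            edge = c("reflect", "zero")) {
  edge <- match.arg(edge)
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < sample_rate / 2)) {
    pk_stop("band edges must satisfy 0 < %g < %g < Nyquist (%g Hz)",
            low_hz, high_hz, sample_rate / 2)
  }
  sos <- butter_bandpass_sos(order, low_hz, high_hz, sample_rate)
  pad <- sos_settle_samples(sos, factor = 8)
  if (is.null(dim(x))) {
    sos_filtfilt(sos, x, pad, edge = edge)
  } else {
    t(apply(x, 1L, function(row) sos_filtfilt(sos, row, pad, edge = edge)))
  }
}

#' Downsample by an integer factor
#'
#' Applies a zero-phase 8th-order Butterworth anti-aliasing low-pass at 45%
#' of the target rate before decimation, unless the caller asserts the signal
#' is already band-limited below `to_hz / 2` (as it is after 0.1-1 Hz
#' filtering). Output length is `ceiling(n * to_hz / from_hz)`.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param from_hz,to_hz Source and target rates; `from_hz` must be an integer
#'   multiple of `to_hz`.
#' @param band_limited Set `TRUE` to skip the anti-aliasing filter.
#' @return Decimated signal.
#' @export
downsample <- function(x, from_hz, to_hz, band_limited = FALSE) {
  if (to_hz <= 0 || from_hz < to_hz) pk_stop("need 0 < to_hz <= from_hz")
  ratio <- from_hz / to_hz
  if (abs(ratio - round(ratio)) > 1e-9) {
    pk_stop("from_hz (%g) must be an integer multiple of to_hz (%g)", from_hz, to_hz)
  }
  k <- as.integer(round(ratio))
  if (k == 1L) return(x)
  dec1 <- function(v) {
    if (!band_limited) {
      sos <- butter_lowpass_sos(8L, 0.45 * to_hz, from_hz)
      v <- sos_filtfilt(sos, v, pad = sos_settle_samples(sos))
    }
    v[seq(1L, length(v), by = k)]
  }
  if (is.null(dim(x))) dec1(x) else t(apply(x, 1L, dec1))
}

#' Normalize each channel to unit Euclidean length
#'
#' Divides every channel's row by its Euclidean norm over the trial's
#' samples, the per-trial normalization applied to decoder features. The
#' trial-wise scope keeps trials independent across cross-validation folds.
#'
#' @param x Channels x samples matrix (one trial's feature values).
#' @param channel_names Optional labels used in the zero-norm error message.
#' @return Same-shape matrix with every row at unit norm.
#' @export
normalize_unit_length <- function(x, channel_names = NULL) {
  x <- as_channel_matrix(x)
  norms <- sqrt(rowSums(x^2))
  bad <- which(norms == 0)
  if (length(bad) > 0L) {
    lab <- if (!is.null(channel_names)) paste(channel_names[bad], collapse = ", ")
           else paste(bad, collapse = ", ")
    pk_stop("cannot normalize zero-norm channel(s): %s", lab)
  }
  x / norms
}

#' Artifact-removal hook
#'
#' Placeholder for ICA-based ocular/muscular artifact removal on real
#' recordings. The synthetic generator produces artifact-free data, so the
#' default method is the identity; users of real data can plug in an external
#' decomposition by passing a function that maps a channels x samples matrix
#' to a cleaned matrix of the same shape.
#'
#' @param session An [eeg_session()].
#' @param clean_fun `NULL` (identity) or `function(eeg_matrix) -> eeg_matrix`.
#' @return The session with each trial's EEG passed through `clean_fun`.
#' @export
remove_artifacts <- function(session, clean_fun = NULL) {
  validate_session(session)
  if (is.null(clean_fun)) return(session)
  session$trials <- lapply(session$trials, function(tr) {
    tr$eeg <- as_channel_matrix(clean_fun(tr$eeg))
    tr
  })
  validate_session(session)
  session
}

#' Apply the full conditioning chain to a session
#'
#' Per trial: common-average reference, optional zero-phase band-pass, then
#' decimation to `target_rate` (EEG with anti-aliasing unless the band-pass
#' already limits the band; kinematics decimated as band-limited smooth
#' signals). Filtering happens at the native rate; the filter order given is
#' the design order at that rate.
#'
#' @param session An [eeg_session()].
#' @param band `c(low, high)` in Hz, or `NULL` to skip filtering.
#' @param order Filter design order.
#' @param target_rate Output rate in Hz, `NULL` to keep the native rate.
#' @param car Apply common-average referencing first (default `TRUE`).
#' @return A new [eeg_session()].
#' @export
preprocess_session <- function(session, band = c(0.1, 1), order = 2,
                               target_rate = 100, car = TRUE) {
  validate_session(session)
  fs <- session$sample_rate
  to <- target_rate %||% fs
  if (to > fs) pk_stop("target_rate %g exceeds the native rate %g", to, fs)
  k <- fs / to
  if (abs(k - round(k)) > 1e-9) pk_stop("native rate must be an integer multiple of target_rate")
  k <- as.integer(round(k))
  band_limited <- !is.null(band) && band[2] < to / 2
  session$trials <- lapply(session$trials, function(tr) {
    eeg <- tr$eeg
    if (car) eeg <- common_average_reference(eeg)
    if (!is.null(band)) eeg <- bandpass_filter(eeg, band[1], band[2], order, fs)
    if (k > 1L) {
      if (tr$onset_index %% k != 0L) {
        pk_stop("onset index %d is not aligned to the decimation factor %d",
                tr$onset_index, k)
      }
      eeg <- downsample(eeg, fs, to, band_limited = band_limited)
      kinm <- downsample(kin_matrix(tr$kin), fs, to, band_limited = TRUE)
      tr <- eeg_trial(eeg, kin_from_matrix(kinm), tr$direction, tr$block,
                      tr$onset_index %/% k, to)
    } else {
      tr$eeg <- eeg
    }
    tr
  })
  session$sample_rate <- to
  validate_session(session)
  session
}
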