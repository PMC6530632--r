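#' Per-sample 2D kinematics track
#'
#' Holds the four recorded movement parameters per sample: signed per-axis
#' velocities `sx`, `sy` (m/s) and positions `dx`, `dy` (m). Absolute speed
#' and position are their Euclidean magnitudes, computed on demand by
#' [abs_speed()] and [abs_position()].
#'
#' @param sx,sy Numeric vectors, velocity components in m/s.
#' @param dx,dy Numeric vectors, position components in m.
#' @return An object of class `kinematics_track`.
#' @export
kinematics_track <- function(sx, sy, dx, dy) {
  n <- length(sx)
  if (length(sy) != n || length(dx) != n || length(dy) != n) {
    pk_stop("kinematics series must have equal length (got %d/%d/%d/%d)",
            length(sx), length(sy), length(dx), length(dy))
  }
  structure(list(sx = as.numeric(sx), sy = as.numeric(sy),
                 dx = as.numeric(dx), dy = as.numeric(dy)),
            class = "kinematics_track")
}

#' @rdname kinematics_track
#' @param kin A `kinematics_track`.
#' @export
abs_speed <- function(kin) sqrt(kin$sx^2 + kin$sy^2)

#' @rdname kinematics_track
#' @export
abs_position <- function(kin) sqrt(kin$dx^2 + kin$dy^2)

#' @export
length.kinematics_track <- function(x) length(x$sx)

## 4 x n matrix in the canonical row order {sx, sy, dx, dy}
kin_matrix <- function(kin) {
  rbind(sx = kin$sx, sy = kin$sy, dx = kin$dx, dy = kin$dy)
}

kin_from_matrix <- function(m) {
  kinematics_track(m[1L, ], m[2L, ], m[3L, ], m[4L, ])
}

kin_slice <- function(kin, idx) {
  kinematics_track(kin$sx[idx], kin$sy[idx], kin$dx[idx], kin$dy[idx])
}

## Display names for the four kinematic parameters, in row order.
kin_param_names <- function() c("X-Speed", "Y-Speed", "X-Position", "Y-Position")

movement_directions <- function() c("left", "right", "up", "down")

## Unit direction vectors in the 2D workspace.
direction_vector <- function(direction) {
  switch(direction,
         left = c(-1, 0), right = c(1, 0), up = c(0, 1), down = c(0, -1),
         pk_stop("unknown direction '%s' (expected left/right/up/down)", direction))
}

#' Single epoched trial
#'
#' One movement epoch: EEG time-locked to movement onset together with the
#' simultaneously recorded kinematics. Epochs run from `onset_index` samples
#' before the onset (nominally 1 s) until the end of the reach. The sample
#' index convention is 0-based with half-open intervals: `onset_index` is the
#' 0-based index of the first movement sample, i.e. the number of pre-onset
#' samples.
#'
#' @param eeg Channels x samples numeric matrix, microvolts.
#' @param kin [kinematics_track()] with the same sample count.
#' @param direction One of `"left"`, `"right"`, `"up"`, `"down"`.
#' @param block Integer block label (1-6 in the standard protocol).
#' @param onset_index 0-based index of the first movement sample.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `eeg_trial`.
#' @export
eeg_trial <- function(eeg, kin, direction, block, onset_index, sample_rate) {
  eeg <- as_channel_matrix(eeg)
  n <- ncol(eeg)
  if (length(kin) != n) {
    pk_stop("eeg has %d samples but kinematics has %d", n, length(kin))
  }
  if (!is_number(onset_index) || onset_index < 0 || onset_index != round(onset_index)) {
    pk_stop("onset_index must be a non-negative integer (got %s)", format(onset_index))
  }
  if (n <= onset_index) {
    pk_stop("movement interval is empty: %d samples with onset_index %d", n, onset_index)
  }
  if (!is_number(sample_rate) || sample_rate <= 0) pk_stop("sample_rate must be > 0")
  direction <- match.arg(direction, movement_directions())
  structure(list(eeg = eeg, kin = kin, direction = direction,
                 block = as.integer(block), onset_index = as.integer(onset_index),
                 sample_rate = sample_rate),
            class = "eeg_trial")
}

## R 1-based indices of the movement-interval samples of a trial.
movement_idx <- function(trial) (trial$onset_index + 1L):ncol(trial$eeg)

n_movement <- function(trial) ncol(trial$eeg) - trial$onset_index

#' Epoched session
#'
#' A set of epoched trials sharing one montage and sampling rate; the unit of
#' analysis for feature extraction, decoding and cross-validation. In the
#' standard protocol a session holds 6 blocks x 40 trials with the four
#' directions balanced within each block.
#'
#' @param trials List of [eeg_trial()] objects.
#' @param montage A [montage()] matching every trial's channel count.
#' @param subject_id,session_id Free-form identifiers.
#' @param sample_rate Sampling rate in Hz, shared by all trials.
#' @return An object of class `eeg_session`.
#' @export
eeg_session <- function(trials, montage, subject_id = "S1", session_id = "1",
                        sample_rate = NULL) {
  if (length(trials) == 0L) pk_stop("a session needs at least one trial")
  sample_rate <- sample_rate %||% trials[[1L]]$sample_rate
  s <- structure(list(trials = trials, montage = montage,
                      subject_id = subject_id, session_id = session_id,
                      sample_rate = sample_rate),
                 class = "eeg_session")
  validate_session(s)
  s
}

#' Validate the structural invariants of a session
#'
#' Checks channel counts against the montage, per-trial EEG/kinematics
#' alignment, shared sampling rate and non-empty movement intervals.
#'
#' @param session An [eeg_session()].
#' @return The session, invisibly; errors on the first violated invariant.
#' @export
validate_session <- function(session) {
  if (!inherits(session, "eeg_session")) pk_stop("not an eeg_session")
  validate_montage(session$montage)
  nch <- nrow(session$montage)
  for (i in seq_along(session$trials)) {
    tr <- session$trials[[i]]
    if (!inherits(tr, "eeg_trial")) pk_stop("trial %d is not an eeg_trial", i)
    if (nrow(tr$eeg) != nch) {
      pk_stop("trial %d has %d channels, montage has %d", i, nrow(tr$eeg), nch)
    }
    if (ncol(tr$eeg) != length(tr$kin)) {
      pk_stop("trial %d: eeg and kinematics sample counts differ", i)
    }
    if (tr$sample_rate != session$sample_rate) {
      pk_stop("trial %d sample rate %g differs from session rate %g",
              i, tr$sample_rate, session$sample_rate)
    }
    if (ncol(tr$eeg) <= tr$onset_index) pk_stop("trial %d has an empty movement interval", i)
  }
  invisible(session)
}

#' @export
print.eeg_session <- function(x, ...) {
  durs <- vapply(x$trials, function(tr) n_movement(tr) / tr$sample_rate, numeric(1))
  cat(sprintf("<eeg_session %s/%s: %d trials, %d channels @ %g Hz>\n",
              x$subject_id, x$session_id, length(x$trials), nrow(x$montage),
              x$sample_rate))
  cat(sprintf("  blocks: %s; movement duration %.3f +/- %.3f s\n",
              paste(sort(unique(session_blocks(x))), collapse = ","),
              mean(durs), stats::sd(durs)))
  invisible(x)
}

#' @rdname eeg_session
#' @param session An `eeg_session`.
#' @export
session_blocks <- function(session) {
  vapply(session$trials, function(tr) tr$block, integer(1))
}

#' Continuous (unepoched) recording
#'
#' A continuous multichannel EEG signal plus an event table marking movement
#' onsets/ends. Sample indices are 0-based; event intervals are half-open
#' `[onset, end)`.
#'
#' @param signal Channels x samples matrix, microvolts.
#' @param sample_rate Hz.
#' @param events Data frame with columns `onset` and `end` (0-based sample
#'   indices), `direction` and `block`.
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(signal, sample_rate, events) {
  signal <- as_channel_matrix(signal)
  if (!is_number(sample_rate) || sample_rate <= 0) pk_stop("sample_rate must be > 0")
  need <- c("onset", "end", "direction", "block")
  if (!all(need %in% names(events))) {
    pk_stop("events must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(events) == 0L) pk_stop("the event table is empty")
  events <- events[order(events$onset), , drop = FALSE]
  n <- ncol(signal)
  with(events, {
    if (any(onset < 0) || any(end > n) || any(onset >= end)) {
      pk_stop("every event must satisfy 0 <= onset < end <= %d samples", n)
    }
    if (any(utils::head(end, -1) > utils::tail(onset, -1))) {
      pk_stop("events overlap in time")
    }
  })
  structure(list(signal = signal, sample_rate = sample_rate, events = events),
            class = "continuous_recording")
}

#' Epoch a continuous recording into trials
#'
#' Cuts one trial per event, running from `pre_onset_s` seconds before the
#' movement onset to the event end, and slices the kinematics stream
#' identically. Events with insufficient pre-onset signal are rejected with a
#' warning rather than aborting the session.
#'
#' @param recording A [continuous_recording()].
#' @param kinematics_stream A [kinematics_track()] on the same sample clock.
#' @param pre_onset_s Seconds of pre-movement baseline to keep (default 1).
#' @param montage A [montage()]; defaults to [default_montage()] when the
#'   channel count matches.
#' @param subject_id,session_id Identifiers stored on the session.
#' @return An [eeg_session()] with one trial per accepted event.
#' @export
epoch_trials <- function(recording, kinematics_stream, pre_onset_s = 1,
                         montage = NULL, subject_id = "S1", session_id = "1") {
  if (!inherits(recording, "continuous_recording")) pk_stop("not a continuous_recording")
  fs <- recording$sample_rate
  if (length(kinematics_stream) != ncol(recording$signal)) {
    pk_stop("kinematics stream (%d samples) does not match the recording (%d samples)",
            length(kinematics_stream), ncol(recording$signal))
  }
  pre <- as.integer(round(pre_onset_s * fs))
  trials <- list()
  for (i in seq_len(nrow(recording$events))) {
    ev <- recording$events[i, ]
    if (ev$onset - pre < 0) {
      pk_warn("event %d at sample %d rejected: needs %d pre-onset samples", i, ev$onset, pre)
      next
    }
    idx <- (ev$onset - pre + 1L):ev$end   # 0-based [onset-pre, end) -> 1-based
    trials[[length(trials) + 1L]] <- eeg_trial(
      eeg = recording$signal[, idx, drop = FALSE],
      kin = kin_slice(kinematics_stream, idx),
      direction = as.character(ev$direction), block = ev$block,
      onset_index = pre, sample_rate = fs)
  }
  if (length(trials) == 0L) pk_stop("no event had %g s of pre-onset signal", pre_onset_s)
  mont <- montage %||% default_montage()
  eeg_session(trials, mont, subject_id, session_id, fs)
}
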