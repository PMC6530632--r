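#' Configuration for the synthetic center-out session generator
#'
#' The generator emulates the statistical structure of a center-out reaching
#' session: 6 blocks x 40 trials, four orthogonal 10 cm reaches, self-paced
#' movement durations of 0.320 +/- 0.126 s clipped to the observed range
#' \[0.2, 0.5\] s, and a slow (0.1-1 Hz) cortical oscillation whose phase
#' trajectory is locked to the movement — rising through pi/2 to pi over the
#' last 0.5 s before onset and from pi to 3pi/2 over the movement — while its
#' amplitude envelope varies across trials. Each channel carries the
#' oscillation with an idealized cosine direction tuning (a small
#' direction-dependent phase shift), plus 1/f background noise and narrowband
#' nuisance oscillations in the high-delta, theta, mu and beta bands.
#'
#' @param n_blocks Number of blocks (default 6).
#' @param trials_per_block Trials per block (default 40).
#' @param directions Reach targets; the four orthogonal directions.
#' @param duration_mean_s,duration_sd_s Movement duration distribution in
#'   seconds before clipping (defaults 0.320, 0.126).
#' @param duration_range_s Clipping range for duration draws (default
#'   \[0.2, 0.5\] s, the observed extremes).
#' @param target_distance_m Center-to-target distance in meters (0.10).
#' @param sample_rate Hz. Simulation is native at the 100 Hz analysis rate; a
#'   1000 Hz mode exists to exercise the downsampling path.
#' @param pre_onset_s Pre-movement epoch length in seconds (1).
#' @param phase_coupling_gain Per-channel amplitude (microvolts) of the
#'   movement-locked slow oscillation. A scalar is recycled over channels;
#'   `NULL` means the topographic [default_coupling_gains()] map. Zero gain
#'   decouples EEG from kinematics.
#' @param direction_phase_shift Radians of phase modulation per unit of
#'   projection of the (normalized) hand position onto a channel's preferred
#'   direction (default 0.5). This kinematics-coupled modulation is what
#'   makes the four directions separable by a decoder.
#' @param amplitude_jitter_sd Log-scale standard deviation of the global
#'   (cross-channel coherent) excitability fluctuation multiplying the
#'   slow oscillation (dimensionless, default 1.25; a weaker fixed
#'   channel-specific component is added on top). Because it is a positive
#'   multiplicative gain, it corrupts the amplitude representation while
#'   leaving the instantaneous phase exactly invariant — and because it is
#'   shared across channels, a decoder cannot average it away.
#' @param phase_jitter_sd Per-trial entrainment jitter (radians, default
#'   0.2): a random phase offset of the whole locked trajectory, drawn once
#'   per trial and shared by all channels — phase resetting is imperfect,
#'   so the trajectory is locked up to a trial-specific lag/lead.
#' @param block_phase_drift_sd Slow session-state drift (radians, default
#'   0.5): a common-mode offset of the entrainment reference drawn once per
#'   block (electrode and arousal state change across the breaks between
#'   blocks). Common-mode additive phase is one linear dimension of the
#'   phase feature space, so a linear phase decoder tolerates it across
#'   cross-validation folds; in the amplitude waveform the same drift is a
#'   nonlinear (cosine) warp that a linear fit cannot extrapolate to a
#'   held-out block.
#' @param ongoing_rhythm_ratio Amplitude of the ongoing (non-entrained)
#'   fraction of the slow rhythm, relative to the movement-locked fraction
#'   (default 0.8). The ongoing fraction shares the entrained oscillation's
#'   spatial topography and band — it is the same cortical rhythm, of which
#'   movement entrains only part — with random frequency and phase per
#'   trial. Because it is spatially coherent along the informative
#'   topography, no decoder can average or project it away: it corrupts the
#'   amplitude time course in full, while the phase error it induces is
#'   bounded by roughly `atan` of this ratio.
#' @param noise List: `exponent` (1/f spectral slope), `sd_uV` (broadband 1/f
#'   noise SD in microvolts), `band_amps_uV` (named amplitudes for the
#'   high_delta, theta, mu and beta nuisance oscillations).
#' @param seed Master seed; every random draw in the generator flows from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_blocks = 6L, trials_per_block = 40L,
                         directions = movement_directions(),
                         duration_mean_s = 0.320, duration_sd_s = 0.126,
                         duration_range_s = c(0.2, 0.5),
                         target_distance_m = 0.10,
                         sample_rate = 100, pre_onset_s = 1,
                         phase_coupling_gain = NULL,
                         direction_phase_shift = 1.5,
                         amplitude_jitter_sd = 1.5,
                         phase_jitter_sd = 0.2,
                         block_phase_drift_sd = 0,
                         ongoing_rhythm_ratio = 0.3,
                         noise = list(exponent = 1, sd_uV = 1,
                                      band_amps_uV = c(high_delta = 1.5, theta = 1.2,
                                                       mu = 1.5, beta = 0.8)),
                         seed = 1L) {
  stopifnot(is_count(n_blocks), is_count(trials_per_block), is_count(seed))
  if (!all(directions %in% movement_directions())) pk_stop("unknown direction in config")
  if (duration_range_s[1] <= 0 || duration_range_s[2] <= duration_range_s[1]) {
    pk_stop("invalid duration range")
  }
  if (!is.null(phase_coupling_gain) && any(phase_coupling_gain < 0)) {
    pk_stop("phase coupling gains must be >= 0")
  }
  if (amplitude_jitter_sd < 0) pk_stop("amplitude_jitter_sd must be >= 0")
  if (phase_jitter_sd < 0) pk_stop("phase_jitter_sd must be >= 0")
  if (block_phase_drift_sd < 0) pk_stop("block_phase_drift_sd must be >= 0")
  if (ongoing_rhythm_ratio < 0) pk_stop("ongoing_rhythm_ratio must be >= 0")
  band_edges <- nuisance_bands()
  top <- max(vapply(band_edges, function(b) b[2], numeric(1)))
  if (sample_rate <= 2 * top) {
    pk_stop("sample_rate %g must exceed twice the highest simulated band edge (%g Hz)",
            sample_rate, top)
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 directions = directions,
                 duration_mean_s = duration_mean_s, duration_sd_s = duration_sd_s,
                 duration_range_s = duration_range_s,
                 target_distance_m = target_distance_m,
                 sample_rate = sample_rate, pre_onset_s = pre_onset_s,
                 phase_coupling_gain = phase_coupling_gain,
                 direction_phase_shift = direction_phase_shift,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 phase_jitter_sd = phase_jitter_sd,
                 block_phase_drift_sd = block_phase_drift_sd,
                 ongoing_rhythm_ratio = ongoing_rhythm_ratio,
                 noise = noise, seed = as.integer(seed)),
            class = "synth_config")
}

nuisance_bands <- function() {
  list(high_delta = c(1, 4), theta = c(4, 8), mu = c(8, 12), beta = c(12, 30))
}

## Minimum-jerk displacement profile and its derivative on tau in [0, 1].
min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
min_jerk_deriv <- function(tau) 30 * tau^2 * (1 - tau)^2

#' Generate the kinematics of one center-out reach
#'
#' Produces a minimum-jerk reach of length `target_distance_m` rotated to the
#' requested direction, preceded by `pre_onset_s` seconds of all-zero
#' kinematics (the hand rests at the home position until onset). Position
#' starts at the origin and ends exactly at the target; velocity is zero at
#' both ends. The minimum-jerk profile is the canonical smooth-reach model in
#' motor control and has closed-form derivatives (peak speed
#' `1.875 * distance / duration`).
#'
#' @param direction `"left"`, `"right"`, `"up"` or `"down"`.
#' @param duration_s Movement duration in seconds.
#' @param sample_rate Hz.
#' @param target_distance_m Reach distance in meters.
#' @param pre_onset_s Seconds of pre-onset rest to prepend.
#' @return A [kinematics_track()] of `round(pre_onset_s * sample_rate) +
#'   round(duration_s * sample_rate)` samples.
#' @export
generate_kinematics <- function(direction, duration_s, sample_rate,
                                target_distance_m = 0.10, pre_onset_s = 1) {
  if (duration_s <= 0) pk_stop("duration_s must be > 0")
  u <- direction_vector(direction)
  n_pre <- as.integer(round(pre_onset_s * sample_rate))
  n_move <- as.integer(round(duration_s * sample_rate))
  if (n_move < 2L) pk_stop("movement too short for the sample rate")
  # tau hits 0 at the onset sample and exactly 1 at the final sample
  d_eff <- (n_move - 1L) / sample_rate
  tau <- (seq_len(n_move) - 1L) / (n_move - 1L)
  pos <- target_distance_m * min_jerk(tau)
  vel <- target_distance_m * min_jerk_deriv(tau) / d_eff
  zeros <- rep(0, n_pre)
  kinematics_track(sx = c(zeros, u[1] * vel), sy = c(zeros, u[2] * vel),
                   dx = c(zeros, u[1] * pos), dy = c(zeros, u[2] * pos))
}

## Programmed instantaneous-phase trajectory of the slow oscillation, radians
## (unwrapped). Time runs relative to onset; before the onset the phase
## climbs at pi rad/s (a 0.5 Hz carrier) reaching pi/2 at -0.5 s and pi at
## the onset; over the movement it climbs linearly to 3*pi/2 at the final
## sample, time-warped to the trial's duration.
phase_trajectory <- function(n_pre, n_move, sample_rate) {
  t_rel <- (seq_len(n_pre + n_move) - 1L - n_pre) / sample_rate
  d_eff <- (n_move - 1L) / sample_rate
  phi <- ifelse(t_rel <= 0, pi + pi * t_rel, pi + (pi / 2) * t_rel / d_eff)
  phi
}

## Preferred direction of each channel: unit vectors spread uniformly around
## the circle by channel index (idealized cosine tuning).
channel_preferred_directions <- function(n_channels) {
  ang <- 2 * pi * (seq_len(n_channels) - 1L) / n_channels
  cbind(cos(ang), sin(ang))
}

#' Topographic default coupling gains
#'
#' Default per-channel amplitudes (microvolts) of the movement-locked slow
#' oscillation, shaped like a movement-related cortical potential: strongest
#' over the fronto-central midline (FCz/Cz) and falling off toward lateral
#' and far frontal/parietal sites. A spatially structured topography is
#' essential for realism — a spatially uniform source would be cancelled by
#' common-average referencing.
#'
#' @param montage A [montage()]; labels are parsed for row (F/FC/C/CP/P) and
#'   laterality (z, 1/2, 3/4, 5/6...).
#' @return Named numeric vector of gains in microvolts.
#' @export
default_coupling_gains <- function(montage = default_montage()) {
  row_base <- c(F = 4, FC = 7, C = 8, CP = 7, P = 4)
  vapply(montage$channel, function(lab) {
    row <- if (grepl("^FC", lab)) "FC" else if (grepl("^CP", lab)) "CP"
           else substr(lab, 1L, 1L)
    base <- if (row %in% names(row_base)) row_base[[row]] else 3
    side <- substring(lab, nchar(row) + 1L)
    fall <- if (side %in% c("z", "Z", "")) 1.0
            else switch(side, "1" = , "2" = 0.85, "3" = , "4" = 0.6, 0.4)
    base * fall
  }, numeric(1))
}

## 1/f^exponent Gaussian noise via frequency-domain shaping, unit SD.
one_over_f_noise <- function(n, exponent) {
  if (n < 4L) return(stats::rnorm(n))
  half <- floor(n / 2)
  freqs <- seq_len(half) / n
  mag <- freqs^(-exponent / 2)
  phases <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = phases)
  full <- complex(real = numeric(n))
  full[2:(half + 1L)] <- spec
  if (n %% 2 == 0) full[half + 1L] <- complex(real = Re(spec[half]))
  full[n:(n - half + 2L)] <- Conj(full[2:half])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate the EEG of one trial
#'
#' Each channel is `gain * A(t) * cos(phi(t) + dphi_c(t))` plus noise, where
#' `phi(t)` is the movement-locked phase trajectory (see [synth_config()]),
#' `A(t)` a slowly varying log-normal amplitude envelope redrawn every
#' trial, and `dphi_c(t)` a kinematics-coupled phase modulation: the
#' projection of the hand position onto the channel's preferred direction,
#' scaled by `direction_phase_shift`. The modulation is zero before onset
#' (phase locks identically across directions pre-movement) and grows with
#' the reach, so direction-specific phase topographies emerge after onset.
#' Noise is 1/f background plus random-phase narrowband oscillations in the
#' four nuisance bands. Identical seeds give identical arrays.
#'
#' @param kin [kinematics_track()] of the trial (defines the epoch length).
#' @param config A [synth_config()].
#' @param channel_gains Numeric vector of per-channel oscillation amplitudes
#'   (microvolts).
#' @param channel_polarity Per-channel sign of the oscillation (+1/-1),
#'   emulating the polarity inversion of a tangential cortical source across
#'   the scalp. A spatially uniform polarity would leave the oscillation
#'   mostly in the common average and thus largely cancelled by CAR;
#'   [generate_session()] inverts the parietal region by default. Defaults
#'   to +1 everywhere.
#' @param direction Reach direction of the trial.
#' @param onset_index 0-based index of the first movement sample; defaults to
#'   `config$pre_onset_s * config$sample_rate`.
#' @param seed Integer seed for this trial's random draws.
#' @return Channels x samples matrix, microvolts.
#' @export
generate_trial_eeg <- function(kin, config, channel_gains, direction = "right",
                               onset_index = NULL, seed = 1L,
                               channel_polarity = NULL, phase_offset = 0) {
  fs <- config$sample_rate
  n <- length(kin)
  n_pre <- as.integer(onset_index %||% round(config$pre_onset_s * fs))
  n_move <- n - n_pre
  if (n_move < 2L) pk_stop("trial has no movement interval")
  C <- length(channel_gains)
  channel_polarity <- channel_polarity %||% rep(1, C)
  if (length(channel_polarity) != C || !all(abs(channel_polarity) == 1)) {
    pk_stop("channel_polarity must be +1/-1, one per channel")
  }
  pref <- channel_preferred_directions(C)
  # per-channel, per-sample phase modulation from the hand position
  proj <- (outer(pref[, 1], kin$dx) + outer(pref[, 2], kin$dy)) /
    config$target_distance_m
  offs <- config$direction_phase_shift * proj   # C x n
  phi <- phase_trajectory(n_pre, n_move, fs)
  pj <- config$phase_jitter_sd %||% 0
  t <- (seq_len(n) - 1L) / fs
  bands <- nuisance_bands()
  amps <- config$noise$band_amps_uV

  with_seed(seed, {
    # amplitude envelopes (log-normal, 0.1-0.4 Hz): slower than the 0.5 Hz
    # carrier, so the modulation sidebands stay inside the analysis band
    # and the band-pass filter preserves the product structure — a positive
    # multiplicative gain then leaves the instantaneous phase exactly
    # invariant while corrupting the waveform the amplitude decoder sees.
    # The dominant component is global (cross-channel correlated, so a
    # decoder cannot average it away); a weaker one is channel-specific.
    draw_z <- function() {
      z <- rep(0, n)
      for (j in 1:4) {
        f <- stats::runif(1, 0.1, 0.4)
        z <- z + sqrt(2 / 4) * cos(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
      }
      z
    }
    z_global <- draw_z()
    # imperfect phase reset (per-trial) on top of the caller-supplied
    # session-state drift: the whole locked trajectory leads or lags by a
    # common-mode offset
    phi_t <- phi + phase_offset + stats::rnorm(1, 0, pj)
    # ongoing (non-entrained) fraction of the slow rhythm: one coherent
    # oscillation shared by all channels through the same topography,
    # with trial-random frequency and phase
    f_on <- stats::runif(2, 0.15, 0.9)
    ps_on <- stats::runif(2, 0, 2 * pi)
    ongoing <- config$ongoing_rhythm_ratio / sqrt(2) *
      (cos(2 * pi * f_on[1] * t + ps_on[1]) + cos(2 * pi * f_on[2] * t + ps_on[2]))
    eeg <- matrix(0, nrow = C, ncol = n)
    sj <- config$amplitude_jitter_sd
    for (c in seq_len(C)) {
      # log-normal excitability: a dominant global (cross-channel coherent)
      # component plus a small channel-specific one, median-normalized
      # (typical carrier strength independent of the jitter depth) and
      # bounded below so the carrier never vanishes entirely. The
      # channel-specific share is kept small: after common-average
      # referencing each channel mixes oscillations of different phase
      # offsets, and strongly channel-specific envelopes would perturb the
      # mixture ratios and hence the phase, which the entrainment model
      # holds invariant to intensity fluctuations.
      zc <- sj * z_global + 0.1 * draw_z()
      env <- (0.4 + exp(zc)) / 1.4
      # the excitability envelope multiplies the whole rhythm — entrained
      # and ongoing fractions alike — so the entrained-to-ongoing ratio
      # (hence the phase error) is independent of the envelope state
      osc <- channel_polarity[c] * channel_gains[c] * env *
        (cos(phi_t + offs[c, ]) + ongoing)
      nz <- config$noise$sd_uV * one_over_f_noise(n, config$noise$exponent)
      for (b in names(bands)) {
        amp <- if (b %in% names(amps)) amps[[b]] else 0
        if (amp > 0) {
          fb <- stats::runif(1, bands[[b]][1], bands[[b]][2])
          nz <- nz + amp * cos(2 * pi * fb * t + stats::runif(1, 0, 2 * pi))
        }
      }
      eeg[c, ] <- osc + nz
    }
    eeg
  })
}

#' Generate a full synthetic session
#'
#' Assembles `n_blocks * trials_per_block` trials with directions balanced
#' within each block (random order), per-trial durations drawn from the
#' clipped normal, and EEG generated by [generate_trial_eeg()]. All
#' randomness flows from `config$seed`; two calls with equal configs are
#' bit-identical.
#'
#' @param config A [synth_config()].
#' @param montage Montage to attach; defaults to [default_montage()].
#' @param subject_id,session_id Identifiers stored on the session.
#' @return A validated [eeg_session()].
#' @export
generate_session <- function(config, montage = NULL, subject_id = "synth",
                             session_id = "1") {
  mont <- montage %||% default_montage()
  C <- nrow(mont)
  gains <- config$phase_coupling_gain
  if (is.null(gains)) gains <- default_coupling_gains(mont)
  if (length(gains) == 1L) gains <- rep(gains, C)
  if (!is.null(names(gains))) {
    if (!all(mont$channel %in% names(gains))) {
      pk_stop("named phase_coupling_gain must cover every montage channel")
    }
    gains <- gains[mont$channel]
  }
  if (length(gains) != C) pk_stop("need one phase coupling gain per channel")

  n_trials <- config$n_blocks * config$trials_per_block
  plan <- with_seed(config$seed, {
    dirs <- unlist(lapply(seq_len(config$n_blocks), function(b) {
      sample(rep_len(config$directions, config$trials_per_block))
    }))
    durs <- stats::rnorm(n_trials, config$duration_mean_s, config$duration_sd_s)
    durs <- pmin(pmax(durs, config$duration_range_s[1]), config$duration_range_s[2])
    list(dirs = dirs, durs = durs,
         block_drift = stats::rnorm(config$n_blocks, 0,
                                    config$block_phase_drift_sd %||% 0),
         trial_seeds = sample.int(.Machine$integer.max - 1L, n_trials))
  })

  trials <- vector("list", n_trials)
  polarity <- ifelse(mont$region == "parietal", -1, 1)
  for (i in seq_len(n_trials)) {
    blk <- (i - 1L) %/% config$trials_per_block + 1L
    kin <- generate_kinematics(plan$dirs[i], plan$durs[i], config$sample_rate,
                               config$target_distance_m, config$pre_onset_s)
    eeg <- generate_trial_eeg(kin, config, gains, direction = plan$dirs[i],
                              seed = plan$trial_seeds[i],
                              channel_polarity = polarity,
                              phase_offset = plan$block_drift[blk])
    trials[[i]] <- eeg_trial(eeg, kin, plan$dirs[i],
                             block = (i - 1L) %/% config$trials_per_block + 1L,
                             onset_index = round(config$pre_onset_s * config$sample_rate),
                             sample_rate = config$sample_rate)
  }
  eeg_session(trials, mont, subject_id, session_id, config$sample_rate)
}
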