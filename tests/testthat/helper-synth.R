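# Shared fixtures: all synthetic, built in code at test time.

small_montage <- function() {
  montage(c("F1", "Fz", "F2", "C1", "Cz", "CP1", "Pz", "P2"),
          c("frontal", "frontal", "frontal", "other", "other",
            "parietal", "parietal", "parietal"))
}

# A compact but fully structured session: 8 channels, a few blocks.
small_session <- function(seed = 1, n_blocks = 2, trials_per_block = 8, ...) {
  cfg <- synth_config(n_blocks = n_blocks, trials_per_block = trials_per_block,
                      seed = seed, ...)
  generate_session(cfg, montage = small_montage())
}

# Hand-built trivial trial: linear ramps, known onset.
toy_trial <- function(n_pre = 10, n_move = 6, channels = 2, sample_rate = 100,
                      block = 1, direction = "right", seed = 1) {
  n <- n_pre + n_move
  set.seed(seed)
  eeg <- matrix(rnorm(channels * n), nrow = channels)
  mv <- c(rep(0, n_pre), seq(0, 1, length.out = n_move))
  kin <- kinematics_track(sx = mv, sy = -mv, dx = mv * 0.1, dy = mv * 0.05)
  eeg_trial(eeg, kin, direction, block, n_pre, sample_rate)
}

# Wrap an angle difference into (-pi, pi].
wrap_angle <- function(x) atan2(sin(x), cos(x))
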