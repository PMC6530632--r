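test_that("minimum-jerk kinematics meet their boundary conditions", {
  k <- generate_kinematics("right", 0.4, 100, target_distance_m = 0.10)
  n <- length(k)
  expect_equal(n, 100L + 40L)
  expect_equal(k$dx[n], 0.10, tolerance = 1e-9)
  expect_equal(k$dy, rep(0, n))
  expect_equal(k$sx[101], 0)               # onset sample
  expect_equal(k$sx[n], 0, tolerance = 1e-12)
  expect_true(all(k$sx[1:100] == 0) && all(k$dx[1:100] == 0))
  # left is the exact mirror image of right in x
  kl <- generate_kinematics("left", 0.4, 100)
  expect_equal(kl$dx, -k$dx)
  expect_equal(kl$sx, -k$sx)
  expect_error(generate_kinematics("diagonal", 0.4, 100), "unknown direction")
})

test_that("peak speed equals the minimum-jerk closed form 1.875 d / D", {
  # differentiate the quintic analytically: max of 30 tau^2 (1-tau)^2 is
  # 30/16 at tau = 1/2, so peak speed = 1.875 * distance / duration
  k <- generate_kinematics("up", 0.5, 1000, target_distance_m = 0.10)
  d_eff <- (round(0.5 * 1000) - 1) / 1000
  expect_equal(max(abs_speed(k)), 1.875 * 0.10 / d_eff, tolerance = 1e-4)
})

test_that("the default protocol yields 240 direction-balanced trials", {
  cfg <- synth_config(seed = 1)
  expect_equal(cfg$n_blocks * cfg$trials_per_block, 240L)
  s <- generate_session(synth_config(seed = 61, n_blocks = 2, trials_per_block = 8),
                        montage = small_montage())
  dirs <- vapply(s$trials, function(tr) tr$direction, character(1))
  expect_equal(as.integer(table(dirs)), rep(4L, 4))     # balanced overall
  # one trial per direction per block when trials_per_block = 4
  s4 <- generate_session(synth_config(seed = 62, n_blocks = 3, trials_per_block = 4),
                         montage = small_montage())
  for (b in 1:3) {
    db <- vapply(s4$trials[session_blocks(s4) == b],
                 function(tr) tr$direction, character(1))
    expect_setequal(db, c("left", "right", "up", "down"))
  }
  validate_session(s4)
})

test_that("movement durations follow the clipped normal", {
  # the generator clamps N(0.320, 0.126) draws to [0.2, 0.5]; its mean is the
  # clipped-normal mean, computed numerically
  mu <- 0.320; sg <- 0.126
  m_clip <- 0.2 * pnorm(0.2, mu, sg) + 0.5 * (1 - pnorm(0.5, mu, sg)) +
    integrate(function(x) x * dnorm(x, mu, sg), 0.2, 0.5)$value
  set.seed(63)
  draws <- pmin(pmax(rnorm(10000, mu, sg), 0.2), 0.5)
  expect_lt(abs(mean(draws) - m_clip), 0.01)
  # sessions respect the clipping range and hover near the clipped mean
  s <- generate_session(synth_config(seed = 64), montage = small_montage())
  durs <- vapply(s$trials, function(tr) {
    (length(tr$kin) - tr$onset_index) / tr$sample_rate
  }, numeric(1))
  expect_true(all(durs >= 0.2 - 1e-9 & durs <= 0.5 + 1e-9))
  expect_lt(abs(mean(durs) - m_clip), 0.03)
})

test_that("all generator randomness flows from the config seed", {
  cfg <- synth_config(seed = 65, n_blocks = 1, trials_per_block = 4)
  s1 <- generate_session(cfg, montage = small_montage())
  s2 <- generate_session(cfg, montage = small_montage())
  expect_identical(s1$trials[[1]]$eeg, s2$trials[[1]]$eeg)
  expect_identical(s1$trials[[4]]$eeg, s2$trials[[4]]$eeg)
  s3 <- generate_session(synth_config(seed = 66, n_blocks = 1, trials_per_block = 4),
                         montage = small_montage())
  expect_false(identical(s1$trials[[1]]$eeg, s3$trials[[1]]$eeg))
  # trial-level determinism
  kin <- generate_kinematics("down", 0.3, 100)
  e1 <- generate_trial_eeg(kin, cfg, rep(5, 3), direction = "down", seed = 9)
  e2 <- generate_trial_eeg(kin, cfg, rep(5, 3), direction = "down", seed = 9)
  expect_identical(e1, e2)
})

test_that("zero phase coupling decouples the EEG from the kinematics", {
  cfg <- synth_config(seed = 67, phase_coupling_gain = 0)
  k_r <- generate_kinematics("right", 0.3, 100)
  k_u <- generate_kinematics("up", 0.3, 100)
  e_r <- generate_trial_eeg(k_r, cfg, rep(0, 4), direction = "right", seed = 3)
  e_u <- generate_trial_eeg(k_u, cfg, rep(0, 4), direction = "up", seed = 3)
  expect_identical(e_r, e_u)     # nothing kinematic reaches the signal
})

test_that("the programmed phase trajectory is recovered from a noise-free channel", {
  # generous pre/post context so the Hilbert transform sees whole cycles;
  # the epoch-edge exclusion reflects the transform's finite-window limits
  cfg <- synth_config(noise = list(exponent = 1, sd_uV = 0, band_amps_uV = c()),
                      amplitude_jitter_sd = 0, phase_jitter_sd = 0,
                      ongoing_rhythm_ratio = 0, pre_onset_s = 9, seed = 68)
  kin <- generate_kinematics("up", 0.4, 100, pre_onset_s = 9)
  # channel 1 has preferred direction (1, 0), orthogonal to "up": no
  # kinematic phase modulation on this channel
  eeg <- generate_trial_eeg(kin, cfg, channel_gains = rep(5, 4),
                            direction = "up", onset_index = 900L, seed = 69)
  n <- ncol(eeg)
  prog <- phasekin:::phase_trajectory(900L, n - 900L, 100)
  sos <- phasekin:::butter_bandpass_sos(2, 0.1, 1, 100)
  f <- phasekin:::sos_filtfilt(sos, eeg[1, ], pad = 3000L, edge = "zero",
                               crop = FALSE)
  ph <- instantaneous_phase(f$y)[(f$pad + 1):(f$pad + n)]
  # 0.4 s exclusion at each edge: the finite-window Hilbert transform is
  # systematically biased within roughly half a carrier swing of the edges
  interior <- 150:(n - 40)
  err <- wrap_angle(ph - prog)[interior]
  expect_lt(max(abs(err)), 0.1)
})

test_that("default coupling gains form a fronto-central-peaked topography", {
  g <- default_coupling_gains()
  expect_equal(length(g), 33L)
  expect_true(all(g > 0))
  expect_equal(unname(which.max(g)), which(default_montage()$channel == "Cz"))
  expect_gt(g[["FCz"]], g[["F3"]])
  expect_gt(g[["Cz"]], g[["C5"]])
})

test_that("config invariants are enforced", {
  expect_error(synth_config(phase_coupling_gain = -1), ">= 0")
  expect_error(synth_config(sample_rate = 50), "twice the highest")
  expect_error(synth_config(duration_range_s = c(0.5, 0.2)), "duration range")
  expect_error(synth_config(amplitude_jitter_sd = -0.1), ">= 0")
})

test_that("stronger phase coupling yields better phase decoding on average", {
  seeds <- phasekin:::derive_seeds(9090, 10L)
  mont <- small_montage()
  base <- default_coupling_gains(mont)
  cc_at <- function(mult, sd) {
    cfg <- synth_config(seed = sd, n_blocks = 2L, trials_per_block = 8L,
                        phase_coupling_gain = unname(base) * mult)
    s <- generate_session(cfg, montage = mont)
    mean(blockwise_cv(s, "phase", theta = 5L, decoder = "mlr")$mean_cc)
  }
  lo <- vapply(seeds, function(sd) cc_at(0.25, sd), numeric(1))
  hi <- vapply(seeds, function(sd) cc_at(1.0, sd), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("with heavy amplitude jitter, phase outdecodes amplitude on modest sessions", {
  # the regime where the entrained-phase advantage expresses itself with
  # linear decoders: sessions small enough that the waveform's
  # higher-complexity code cannot be fitted
  seeds <- phasekin:::derive_seeds(3030, 3L)
  margins <- sapply(seeds, function(sd) {
    s <- generate_session(synth_config(seed = sd, n_blocks = 2L,
                                       trials_per_block = 24L))
    sapply(c("mlr", "kf"), function(dec) {
      mean(blockwise_cv(s, "phase", decoder = dec)$mean_cc) -
        mean(blockwise_cv(s, "amplitude", decoder = dec)$mean_cc)
    })
  })
  expect_gt(mean(margins["mlr", ]), 0)
  expect_gt(mean(margins["kf", ]), 0)
})
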