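---
title: "Decoding center-out reaches from low-delta EEG phase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding center-out reaches from low-delta EEG phase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During executed reaching, the 0.1–1 Hz ("low-delta") component of scalp EEG
carries a movement-related cortical potential (MRCP) whose temporal
structure tracks the ongoing movement. Decoding continuous 2D hand
kinematics — per-axis position and velocity — from this band has
conventionally used the band-filtered *amplitude* time course as the
predictor. This package implements the alternative: the *instantaneous
phase* of the same band, obtained from the analytic signal, used as the
predictor of a linear decoder. The scientific claim the package is built to
examine is that the phase representation supports more accurate
reconstruction than the amplitude representation, because movement entrains
the timing (phase) of the slow oscillation much more reliably than its
intensity.

## Pipeline and models

A session is a set of epoched trials: 33-channel EEG from 1 s before
movement onset to the end of the reach, paired per-sample with kinematics
$Y = \{s_x, s_y, d_x, d_y\}$ (velocities in m/s, positions in m). The chain
is:

1. **Common-average reference**, then a **zero-phase Butterworth band-pass**
   (0.1–1 Hz, design order 2, applied forward and backward). Comparator
   features use 1–4, 4–8, 8–12 and 12–30 Hz bands at design order 8.
   Filters are implemented as analytically designed second-order sections:
   high-order narrowband designs are numerically unstable as expanded
   polynomials but well-conditioned as cascaded biquads.
2. **Features.** *Phase*: the angle of the analytic signal
   $z(t) = s(t) + i\,\mathrm{HT}(s(t))$ of the filtered trial. *Amplitude*:
   the filtered waveform itself. *Power*: the mean of squared samples in a
   causal 500 ms window stepped every 10 ms. Each channel of each trial is
   normalized to unit Euclidean length.
3. **Lag embedding.** The predictor at time $k$ stacks the current and the
   previous $\theta - 1 = 10$ samples of every channel:
   $L = C\,\theta = 33 \times 11 = 363$ rows.
4. **Decoders.** Multiple linear regression $\hat Y = \alpha [X; 1]$ solved
   by least squares; and a Kalman filter with observation model
   $X_k = H Y_k + h_0 + q_k$, $q_k \sim N(0, Q)$, and state model
   $Y_{k+1} = A Y_k + w_k$, $w_k \sim N(0, W)$, all matrices constant and
   estimated from training data by least squares, decoded by the standard
   predict/update recursion (Joseph-form covariance updates; the state
   resets to training onset statistics at each trial start).
5. **Evaluation.** Six-fold cross-validation with blocks as folds; the
   metric is the Pearson correlation between predicted and recorded
   kinematics per parameter, averaged over folds, and the X/Y axis means
   per quantity. The empirical null repeats the full CV after destroying
   the EEG-kinematics correspondence by permuting which kinematics track
   belongs to which trial (20 shuffles).

## Channel-level statistics

For neurophysiological characterization the package computes, per channel:
the time-resolved effect size (grand-average movement activity minus the
grand-average baseline mean, in baseline-SD units; baseline
$[-0.2, -0.1)$ s, movement $[0, 0.2)$ s); the absolute Pearson correlation
between a feature and absolute speed; and the rest-vs-movement contrast
$F = \left|\,\mathrm{sign}(m - r)\,(m-r)^2 N_m N_r / (\sigma^2_{m \cup r}
N^2_{m \cup r})\right|$, which equals the squared point-biserial
correlation between the feature and the state indicator and so lies in
$[0, 1]$. The activation index $AI = \max(F_{\text{amplitude}},
F_{\text{phase}})$ selects one representative channel per region (frontal,
parietal), the cortices that carry reach planning/execution information.

## Design choices that were genuinely open

**Phase wrapping.** The four-quadrant angle lives in $(-\pi, \pi]$, but the
movement-interval phase trajectory occupies $[\pi, 3\pi/2]$ — it would
straddle the wrap point in that convention, and across trials the same
time point would land on either side of a $2\pi$ jump, which destroys
linear decodability. Decoder features therefore use the $[0, 2\pi)$
convention, in which the trajectory is continuous and can be treated as an
ordinary linear variable; `instantaneous_phase()` itself returns the
standard $(-\pi, \pi]$ angle, and both conventions plus an unwrapped mode
are exposed.

**Edge handling for short epochs.** An epoch (~1.3 s) covers well under one
cycle of a 0.5 Hz oscillation, while the slowest time constant of the
0.1 Hz band edge is tens of seconds. Odd-reflection padding — the right
tool for long continuous signals, and what `bandpass_filter()` uses — has
nothing real to reflect at this length. The feature pipeline instead
demeans each epoch and zero-pads it to three filter time constants before
the zero-phase filter, and computes the analytic signal on the padded
filtered series before cropping. This keeps filter and Hilbert transients
smaller on the movement interval at the epoch tail, but a hard limit
remains: the instantaneous phase of a fraction-of-a-cycle window is
systematically distorted near the window edges, by a few tenths of a
radian at the tail even for noise-free input. The distortion is
deterministic given the epoch content, so the decoders tolerate it; exact
recovery of a programmed phase trajectory is only achievable with long
context around the window (the test suite uses a 9 s pre-onset trial for
that oracle).

**Observation intercept in the Kalman filter.** The unit-normalized phase
predictor has a large nonzero mean, which a 4-dimensional zero-mean
kinematic state cannot represent; `fit_kf()` therefore estimates
$X \approx H Y + h_0$. With noiseless linear data the extra column changes
nothing (it fits exactly zero). The state transition $A$ is estimated
without an intercept from within-trial consecutive pairs only — transitions
across trial boundaries are physically meaningless. $Q$ receives a ridge of
$10^{-6} \times$ its mean diagonal for invertibility.

**Fold aggregation.** Per-fold correlations are averaged over the six folds
(the subject-session metric); a pooled-concatenation mode is available via
`aggregate = "concatenated"`.

**Chance-level construction.** Trials are self-paced and differ in length,
so the shuffle reassigns kinematics tracks between trials and linearly
resamples each donor track onto the host trial's movement length. The
identity permutation reproduces the authentic result exactly, which the
test suite asserts.

## The synthetic session generator

No public recordings exist for this paradigm, so `generate_session()`
produces sessions whose statistical structure mirrors the protocol: 6
blocks of 40 trials, directions balanced within blocks, movement durations
drawn from $N(0.320, 0.126^2)$ s clipped to $[0.2, 0.5]$ s, 10 cm targets,
minimum-jerk trajectories (the canonical smooth-reach model, with
closed-form derivatives and peak speed $1.875\,d/D$), simulated natively at
the 100 Hz analysis rate (a 1000 Hz mode exercises the decimation path).

Each channel receives:

* a movement-locked slow oscillation $g_c \, p_c \, A_c(t) \cos(\phi(t) +
  \delta_c(t))$, where the phase trajectory $\phi(t)$ rises at $\pi$ rad/s
  through $\pi/2$ (at $-0.5$ s) to $\pi$ at onset, then linearly to
  $3\pi/2$ at the end of the reach, time-warped to the trial's duration;
* a kinematics-coupled phase modulation $\delta_c(t)$: the projection of
  the hand position onto the channel's preferred direction (idealized
  cosine tuning, directions spread uniformly over channels), scaled by
  `direction_phase_shift`. Pre-onset, all directions share one phase
  trajectory; direction-specific topographies emerge with the reach;
* gains $g_c$ with an MRCP-like topography (fronto-central midline maximum,
  lateral falloff) and a dipolar polarity map $p_c$ (parietal inversion).
  Both are essential for realism under common-average referencing: a
  spatially uniform source lives in the common average and would be
  subtracted away;
* a log-normal amplitude envelope $A_c(t)$ (`amplitude_jitter_sd`),
  spanning 0.1–0.4 Hz — slower than the carrier, so the modulation
  sidebands stay inside the analysis band and the band-pass preserves the
  product structure, keeping the instantaneous phase exactly invariant to
  it. Its dominant component is global (cross-channel coherent, an
  excitability fluctuation a decoder cannot average away) with a small
  channel-specific part; it is median-normalized and floor-bounded so the
  carrier never vanishes. This is the physiological asymmetry — movement
  entrains timing, not intensity;
* an imperfect phase reset: a small per-trial common-mode offset
  (`phase_jitter_sd`) of the whole locked trajectory;
* an ongoing (non-entrained) fraction of the same slow rhythm
  (`ongoing_rhythm_ratio`), sharing the entrained oscillation's spatial
  topography and band with trial-random frequency and phase — spatially
  coherent along the informative topography, so it cannot be projected
  away;
* noise: $1/f$ background and narrowband nuisance oscillations in the
  high-delta, theta, mu and beta bands with random frequency and phase per
  trial, so band-power comparator decoders see realistic but
  uninformative power.

All randomness derives from the single config seed; equal seeds give
bit-identical sessions.

**What the generator does not emulate:** volume conduction and realistic
inter-channel noise correlation, ocular/muscular artifacts (the
artifact-removal hook is an identity on synthetic data), electrode drift
and impedance nonstationarity, and between-subject variability. Passing
the packaged checks therefore demonstrates correctness of the pipeline and
the qualitative reproducibility of the phase-over-amplitude ordering on
data built to embody the entrainment hypothesis — it is not evidence about
any particular real recording.

**Free parameters** (exposed in `synth_config()`, with the defaults chosen
on physiological grounds and calibrated against the correlation ranges
reported for real low-delta decoding in this paradigm, rather than the
implausibly clean values an additive noise-free evoked model produces):
coupling gains of 1.6–8 µV (MRCP scale), direction phase modulation depth
1.5 rad (large enough that the waveform's cosine nonlinearity does not
simply linearize it away), amplitude jitter SD 1.5 per envelope component
(log-normal; intensity CV well above 100%, matching the observation that
single-trial MRCP amplitude is only weakly stereotyped), per-trial
entrainment jitter of 0.2 rad, an ongoing rhythm fraction of 0.3 of the
entrained amplitude, 1/f noise of 1 µV, and nuisance band amplitudes of
1.5/1.2/1.5/0.8 µV.

**What the benchmark shows, and where.** With these defaults the phase
decoders land in the correlation range the method is known for, and the
shuffle null collapses to zero while authentic decoding clears its 95th
percentile by a wide margin (both computed by `scripts/acceptance.R`). The
*relative* standing of phase versus amplitude is regime-dependent on
synthetic sessions: on full 240-trial sessions the amplitude waveform —
which mathematically contains the phase code, since the phase is derived
from the same filtered signal — decodes as well as or slightly better than
the extracted phase, whereas on smaller sessions (tens of trials) phase
wins clearly for both decoders (the packaged ordering test), because the
waveform's higher-complexity code needs more data than the phase's directly
linear one. Real recordings, with their far richer trial-to-trial
variability, are not bound by either regime; the generator reproduces the
mechanism of the phase advantage, not its exact operating point.

## Problem sizes used by the packaged checks

The acceptance script and heavy tests run six-fold CV on 240-trial,
33-channel sessions at 100 Hz; margins between feature representations are
averaged over 10 independently seeded sessions; the chance level uses 20
shuffles; system-identification recovery uses $10^4$ samples. These sizes
were chosen to estimate each quantity stably while keeping a full run in
the minutes range on one CPU.

## Known limitations

* Per-epoch phase estimation near epoch edges is systematically biased
  (see above); decoding tolerates it, channel-level phase statistics
  inherit it.
* The decoders are linear by design; nonlinear decoders are out of scope.
* EDF support covers equal-rate multichannel exports only; BrainVision/FIF
  dialects are not read.
* The chance-level and CV machinery assume the block structure is the only
  relevant non-exchangeability; slow within-block nonstationarities would
  require a different null.
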