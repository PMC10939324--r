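---
title: "Methods: simulating and analysing robot-supported reaching sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing robot-supported reaching sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

`reachmetrics` analyses three-dimensional upper-limb reaching sessions
recorded with a robotic haptic interface in a virtual-reality workspace. A
session consists of repeated *movement segments*: a target ball appears at
one of eight predetermined locations, the participant reaches until the hand
contacts the target, and the target disappears. Sessions are organised in
blocks — a baseline block of 16 segments, then alternating training blocks
(24 segments, with terminal visual, haptic, or multimodal feedback) and
feedback-free retention blocks (16 segments) — and the whole protocol is run
once with a large target ball and once with a small one, which changes the
required reach distance.

Three data streams describe a session:

* the end-effector **trajectory** (uniformly sampled 3-D positions, metres),
* a five-channel **surface EMG** recording at a nominal 1 kHz (biceps
  brachii, triceps brachii, upper trapezius, anterior and posterior
  deltoid),
* the **trial event log**, which is the segmentation authority: per segment
  the target's appearance and disappearance times, its position, the ball
  mode and the condition labels.

From these the package computes five per-segment kinematic variables
(movement time, mean velocity, peak velocity, time to peak, and the velocity
peak number — a movement-smoothness count), the per-muscle sEMG peak
latency on each block's first segment, and a two-way repeated-measures
ANOVA (ball size × condition cell) with Mauchly's sphericity check,
Greenhouse–Geisser correction and Bonferroni-corrected post-hoc paired
t-tests.

Because no public recording of this task exists, the package ships a
first-class synthetic-session generator with programmable condition effects.
All statistical guarantees of the package are validated against this
generator's ground truth.

## The synthetic-session generator

### Movement model

Each reach is a sequence of non-overlapping **minimum-jerk submovements**.
The quintic profile $x(s) = 10s^3 - 15s^4 + 6s^5$ ($s = t/T$) moves from
rest to rest while minimising integrated squared jerk; its speed is
bell-shaped with peak $1.875\,D/T$ at the temporal midpoint. A segment is:

1. a **primary (ballistic) reach** of programmed duration from the current
   hand position to the target, then
2. $k \ge 1$ **corrective submovements** of 0.25 s each, whose endpoints
   alternate around the target centre along a random direction, with
   geometrically decaying amplitudes (factor 0.6, floor 5 mm); the last
   lands on the target centre.

Design rationale, in order of the constraints that force it:

* *Every bump countable.* The 5 mm amplitude floor keeps every corrective
  speed bump above the 20 mm/s counting cutoff (a 5 mm, 0.25 s submovement
  peaks at 37.5 mm/s), so a noise-free segment with $k$ correctives yields
  exactly $k + 1$ counted velocity peaks. The 0.25 s duration keeps
  consecutive peaks 250 ms apart, resolvable under the 150 ms separation
  rule.
* *A unique, sharp envelope peak.* The EMG peak-latency statistic is the
  argmax of a noisy envelope, so the programmed envelope must have one
  dominant, narrow peak. The first corrective amplitude scales with the
  reach (40 % of the primary distance): its speed bump then exceeds the
  broad primary peak by a factor of roughly the primary duration in
  seconds (≈ 2×), for *every* target distance. Constant absolute
  amplitudes cannot achieve this — they tie with the primary peak at some
  distances — and equal-amplitude correctives would create exact ties among
  themselves, making the argmax a coin flip.
* *At least one corrective.* Reaching a target with a terminal precision
  demand essentially always ends in at least one corrective adjustment, so
  the per-segment count is drawn as $k = 1 + \mathrm{NB}(\mu - 1, \theta)$
  (negative binomial, dispersion $\theta = 20$), preserving the configured
  mean $\mu$.
* *Contact by construction.* The printed target radii (84 mm small, twice
  that big) exceed the printed mean inter-target distances (56 mm and
  39 mm), so a "first sample within the radius" contact rule would be
  degenerate — the hand can start a segment already inside the new target.
  The generator therefore defines the disappearance time as the programmed
  arrival at the target centre; the radius is carried as metadata.

### Geometry

Eight target centres sit on the corners of a cube inside the workspace,
with a per-ball-mode scale chosen so that the mean distance between
successive randomly ordered targets equals the configured mean movement
distance (0.056 m small-ball, 0.039 m big-ball; for a cube the mean
neighbour distance is $a(3 + 3\sqrt{2} + \sqrt{3})/7$ for edge $a$). Each
block starts at the fixed first target — latency comparisons across
conditions rely on a common first reach — and the remaining targets are
drawn in randomised order without immediate repeats. Between blocks the
hand returns smoothly to the start position during the rest interval, so
the recorded trajectory contains no jumps that could bleed through the
position low-pass into adjacent segments.

### Condition structure and variability

Per (ball mode, cell) the generator takes a primary duration and a mean
corrective count; the default table gives expected movement times of about
3.2–3.5 s at baseline and 2.4–2.8 s in retention cells, with retention
shorter under haptic and multimodal feedback — the effect directions the
analysis is designed to detect. Participants receive an additive duration
offset (SD 0.30 s) constant across their session; individual segments jitter
with SD 0.15 s. `sim_config(feedback_effect_s = x)` replaces the table by a
pure movement-time effect of `x` seconds (baseline vs all retention cells,
corrective counts equalised), and `x = 0` gives the null configuration used
for type-I calibration. Recorded positions carry additive Gaussian noise
(default 0.1 mm, the scale of robot end-effector telemetry).

### EMG synthesis

Per channel the recording is baseline Gaussian noise (0.02 mV SD) plus a
50 Hz mains sinusoid (0.05 mV) plus a burst component: band-limited
(20–400 Hz) Gaussian noise whose amplitude envelope is the session speed
profile shifted by the muscle's latency offset and scaled by a gain of
10 mV/(m·s⁻¹). The burst carrier is produced by single-pass Butterworth
filtering of white noise — the phase of a noise carrier is irrelevant —
while the *analysis* chain is strictly zero-phase. The default latency
offsets are all anticipatory (upper trapezius −260 ms through triceps
−20 ms, 60 ms apart): muscle activity leads the kinematics by the
electromechanical delay, proximal stabilisers earliest. Anticipatory
offsets also keep the dominant envelope peak inside the movement segment,
whose last corrective ends exactly at contact. The per-segment,
per-muscle ground-truth latency is the argmax of the shifted analytic
envelope restricted to the segment window.

### What the generator does not emulate

Motor-unit physiology (the EMG burst is envelope-modulated noise, not a
spike train), biomechanical arm dynamics, robot impedance control, visual
rendering, fatigue and learning drifts within a block, movement curvature
(reaches are straight), and endpoint variability beyond the corrective
model. Tests passing on this generator therefore demonstrate that the
*measurement pipeline* recovers what it claims to measure under realistic
noise — not that human data would show any particular effect.

## The analysis pipeline

### Segmentation

Segments are cut on the closed interval `[appear, disappear]` (the contact
sample belongs to the reach); inter-trial samples are discarded. The event
log is authoritative — no velocity-threshold onset detection. Segments with
fewer than four samples (too short to differentiate) are rejected with an
error naming the trial.

### Speed and the five variables

Positions are differentiated by central differences with one-sided boundary
stencils and reduced to 3-D Euclidean speed. Because peak counting is
sensitive to differentiated quantisation noise, positions are low-pass
filtered before differentiation — 2nd-order Butterworth, zero-phase, 10 Hz
default; configurable, and `NULL` disables it. The whole-session route
(`analyze_kinematics()`) filters the continuous recording once before
segmentation, which avoids per-segment filter transients and is the
pipeline default; the per-segment route (`speed_profile()`) exists for
isolated segments. The two differ only in boundary stencils.

Movement time is `disappear − appear`; mean velocity is the arithmetic mean
of the speed samples; peak velocity is the maximum sample (earliest sample
on plateaus); time to peak is the peak time minus the appearance time.

### Velocity peak counting

The smoothness count scans the speed profile for alternating local minima
and maxima, with three decisions the original rule statement leaves open:

* the segment start is treated as the initial minimum, so a reach that
  rises monotonically to a single peak counts 1 (not 0);
* a maximum is a candidate iff it rises *strictly more than* 20 mm/s above
  the preceding (alternation-merged) minimum;
* the 150 ms separation rule is applied greedily in time order: a candidate
  is accepted iff it is at least 150 ms after the last *accepted* peak.
  Greedy-earliest is deterministic and independent of amplitude ordering.
* plateaus are compressed to their first sample (earliest-wins tie-break).

The implementation is validated against an independent brute-force
enumeration oracle on 1,000 random synthetic profiles, including
sub-cutoff and sub-150 ms adversarial cases.

### EMG preprocessing and peak latency

Each channel passes a 4th-order Butterworth band-pass (20–400 Hz) and a
2nd-order band-stop notch (50 Hz, Q = 30, width f₀/Q), both applied
forward–backward. Zero-phase filtering is non-negotiable here: the
statistic *is* a latency, and causal filtering would bias it. "Peak of the
sEMG signal" is read as the argmax of the rectified, smoothed envelope —
moving RMS over a centred 50 ms window (truncated at edges) — because the
argmax of the raw band-passed signal is a single noisy sample; a
rectified-raw mode is available. The latency is measured on each block's
first segment, restricted to `[appear, disappear]`, with no pre-appearance
anticipation window; `peak_latency()` filters a window padded by 1 s around
the segment rather than the whole recording (the IIR chain is local; this
keeps cohort-scale analyses fast). Mains frequency defaults to 50 Hz and is
configurable for 60 Hz recordings.

### Statistics

The condition means (per participant, ball mode and analysis cell — cells
are baseline and the three retention blocks; training blocks are emitted by
the simulator but excluded from inference, mirroring the baseline-versus-
retention comparisons the design supports) enter a two-way within-subject
ANOVA implemented as an explicit sums-of-squares decomposition: effects A,
B, A×B each tested against their subject-interaction error term. Mauchly's
test is computed per effect on the covariance of orthonormal contrasts
(averaging over the other factor for main effects, Kronecker contrasts for
the interaction); under the default `"auto"` policy the Greenhouse–Geisser
correction — the standard, conservative companion when sphericity is
rejected — deflates that effect's degrees of freedom when Mauchly's p
< .05. A two-level factor is trivially spherical. The implementation is
cross-checked in the tests against `aov()` error strata and
`mauchly.test()` to 1e-8 on the statistics.

Post-hoc comparisons are paired t-tests with Bonferroni adjustment
(`p_adj = min(1, m·p)`). The default family is baseline versus each
retention cell (m = 3), separately per ball mode; an all-pairs family
(m = 6) is available. Because the original table layout pools both ball
modes for the feedback effect while the narrative reports per-mode
comparisons, `posthoc_bonferroni()` exposes `by = "ball_mode"` (default)
and `by = NULL` — both layouts, neither guessed as canonical. No outliers
are excluded anywhere.

`power_check()` wires the whole chain — simulate, segment, features,
condition means, ANOVA — into a Monte-Carlo loop and reports the rejection
rate per effect, which doubles as a type-I calibration under the null
configuration and a power estimate under a programmed effect.

## File formats

Sessions are stored as plain, diffable text: `trajectory.csv` and `emg.csv`
carry a one-line versioned header with the sampling rate (the robot's
logging rate is not standardised, so the file declares it), then CSV
columns in seconds/metres/millivolts; `events.jsonl` holds one JSON record
per trial after a format-header line — JSON lines because trial records mix
numeric, array and categorical fields. Readers validate and reject rather
than repair, with file and line positions in every error; a write/read
round trip reproduces values to better than 1e-9.

## Reproducibility

A single run seed fans out to per-participant substreams derived from
(seed, participant index), so enlarging a cohort does not reshuffle
existing participants. `run_pipeline()` executes simulate/analyze/full
modes, writes all tables as CSV plus a JSON manifest (config echo, seed,
package version, per-stage record counts); identical configuration and seed
give byte-identical outputs.

## Numerical choices and degenerate inputs

* All zero-phase filtering pads the signal by odd reflection about its
  endpoints before forward–backward filtering; without this, segments that
  end away from zero (every reach ends at the target position) acquire
  large edge transients that masquerade as velocity peaks.
* Closed-interval sample selection uses a 1e-6-sample tolerance so grid
  round-off cannot drop boundary samples.
* Uniform-grid validation tolerates 1 % step deviation.
* The amplitude cutoff is stored in m/s (0.020); the greedy separation rule
  uses a 1e-9 s tolerance.
* Degenerate ANOVA effects (zero error term with zero effect SS) report
  F = 0, p = 1 rather than NaN.
* Corrective counts keep durations positive via a 0.4 s floor on primary
  durations.
* Segments whose primary reach is a nearest-corner move can have a primary
  speed peak below 20 mm/s; the counting rule correctly does not count it,
  which is the dominant source of truth-versus-measured count differences
  at the defaults.

## Validation scale

The shipped suite validates at these problem sizes: 1,000 random profiles
for the counting oracle; 100 simulated participants for latency recovery
(mean absolute error ≤ 50 ms, muscle-order recovery ≥ 95 %); 10 random
balanced 2×4 designs for the ANOVA cross-check (1e-8); 200 null and 100
effect replicates of the full pipeline for calibration (rejection within
1–12 % at α = .05) and power (≥ 80 % for a 0.8 s movement-time effect,
n = 10). The acceptance script recomputes the same quantities at reduced
Monte-Carlo sizes (300 profiles, 25 participants, 100/50 replicates) chosen
to keep a from-scratch rerun short while leaving the estimates stable.

## Known limitations

The generator's realism limits what green tests mean for human data (see
above). The ANOVA requires a complete balanced design — no imputation for
dropped segments; condition means simply use the segments present, and
whole missing cells are an error. The Mauchly chi-square approximation is
the standard first-order one (agreement with `mauchly.test()` to ~1e-3 in
p). Only Greenhouse–Geisser correction is offered (no Huynh–Feldt), and no
effect sizes beyond the reported statistics are computed.
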