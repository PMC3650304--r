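---
title: "Quantifying larval zebrafish prey capture: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying larval zebrafish prey capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preycapture)
```

## The behavior and the measurement problem

Hunting zebrafish larvae chain discrete swim bouts into a prey-capture
sequence: each bout lasts on the order of 150 ms, turns the fish toward
the prey by a graded angle, and is separated from the next bout by an
inter-bout interval (IBI) that shortens as the sequence progresses. The
bout itself is one elementary motor pattern — a symmetric tail
oscillation near 30 Hz, about three cycles long — onto which a slow,
one-sided bend is superimposed; the amplitude of that asymmetric
component sets the turn angle on a continuous scale.

This package implements the full computational chain needed to quantify
that behavior from high-speed dark-field video, plus a discrete-event
simulation of a closed-loop virtual-reality assay in which a restrained
larva's detected swims trigger updates of a projected prey-like target.
Because no raw recordings ship with the package, a synthetic-data
generator produces bout kinematics, rendered video, and tail-sensor
traces with exact ground truth, so every downstream stage is testable by
recovery.

## Coordinate and sign conventions

All image-space computation uses pixel coordinates with x to the right
and y downward. Under a dorsal camera view this makes a positive angular
step a rotation toward the fish's *right*, and the package reports all
angles in that right-positive convention:

* heading `theta`: direction of the head segment; a positive change in
  orientation `dtheta` is a rightward turn;
* tail segment angles `gamma1..gamma5`: deviation of each tail segment
  from the body axis, positive when the tail tip is displaced toward the
  fish's right;
* fish-target angle `phi`: signed angle from the heading direction to
  the fish-prey vector; prey on the left gives `phi < 0`;
* eye angles: nasal rotation positive, for each eye.

The sign of the mean tail-angle integral equals the sign of `dtheta` by
construction in the generator, which is what makes the Direction Index
(below) signed consistently.

## The synthetic bout generator

`gen_bout_kinematics()` builds each tail-segment trace as

```
gamma_i(t) = turn_gains[i] * A_turn * P(t)
           + segment_gains[i] * osc_amp * sin(2 pi f_osc t + phi_i) * E(t)
           + noise
```

with `P` a raised-cosine pulse (the asymmetric turn component), `E` a
raised-cosine on/off envelope over the oscillation, and `phi_i` a small
rostro-caudal phase lag (default 20 degrees per segment) emulating the
traveling bend wave. The heading trajectory is *prescribed* as the
normalized integral of `P`, so the net heading change equals
`delta_theta` exactly — there is no hydrodynamic model, by design: the
generator exists to provide exact ground truth for recovery tests, and
swimming physics is outside its scope.

Parameters that matter, with defaults and rationale:

* `f_osc` (30 Hz) and `n_cycles` (3): the tail-beat frequency and cycle
  count of the elementary pattern; recovery tests draw `f_osc` from
  20-35 Hz, the observed range.
* `bout_ms` (`max(150, n_cycles/f_osc * 1000)`): bout duration. The
  oscillation is active for `n_cycles / f_osc` seconds from onset; the
  slow turn deflection spans the whole bout. This decoupling mirrors the
  measured kinematics (about three cycles of ~30 Hz oscillation inside a
  ~150 ms bout) and keeps the turn component's spectral weight in the
  few-Hz range, where the low-frequency peak of real bout spectra sits.
  A turn pulse confined to a single 33 ms tail-beat cycle would place
  most of its energy above 15 Hz and merge with the tail-beat band —
  with a bout-long pulse, low-pass filtering below 8 Hz isolates the
  turn and high-pass filtering above 15 Hz isolates the oscillation, as
  the band-pass decomposition of real traces shows.
* envelope shape: a full raised-cosine (Hann) envelope. The smooth rise
  and fall keep amplitude-modulation sidebands of the oscillation out of
  the 3-5 Hz band; a flat-topped envelope with short ramps leaks several
  degrees of spurious low-frequency amplitude, enough to corrupt the
  Direction Index of a perfectly symmetric bout. The cost is a soft
  onset: threshold detectors see the bout 1-2 frames late, which the
  detection tests account for by using small thresholds on noise-free
  traces.
* `turn_scale` (1): tail-tip turn amplitude per degree of heading
  change. The linear link makes the low-frequency spectral amplitude
  proportional to the turn angle, the relation the spectral analysis is
  designed to read out.
* `segment_gains`/`turn_gains`: non-decreasing rostro-caudal amplitude
  profiles (0.25-1 and 0.2-1). The paper-level data do not constrain
  these profiles; they are free parameters of the generator, not claims
  about the fish.

`gen_capture_sequence()` chains bouts with a scheduled IBI series; each
bout's true turn is `undershoot * phi_pre` (default 0.9) computed from
the simulated geometry, so `phi_post = 0.1 * phi_pre` for a distant
stationary prey — the stepwise angular homing seen in real sequences.
The default eye-angle schedule follows the measured two-step convergence
(contralateral eye from ~13 to ~31 degrees after the first bout, the
ipsilateral eye reaching ~32 degrees only after the second).

`gen_psd_trace()` projects the lateral tail-tip displacement to a 1 kHz
voltage trace with Gaussian noise, emulating the position-sensitive
photodetector used for real-time swim detection.

## Rendering

`render_frames()` rasterizes the pose as a bright, tapered silhouette on
a dark, weakly textured background (dark-field contrast), with the prey
as a small bright ellipsoid and, in restrained mode, two dark eye
ellipses at scheduled angles inside the bright head. The default scene
is 240 x 240 pixels at 0.04 mm/pixel with a 4 mm fish (100 pixels, above
the 60-pixel floor for midline resolvability). What the renderer does
*not* emulate: optical blur, motion blur, pigmentation, water-surface
artifacts, or multiple animals. Tests passing on these images therefore
establish algorithmic correctness of the pipeline on clean dark-field
scenes, not robustness to arbitrary real-world video.

## The image pipeline

Free mode subtracts a background frame; restrained mode (no background
available) applies a linear histogram remap around the background level.
Binarization uses an automatic Otsu threshold on the background-
subtracted difference image by default. This deviates deliberately from
thresholding after histogram equalization: equalization rescales by the
shifted cumulative histogram, which maps the dimmest silhouette pixels
onto the background plateau and erodes the silhouette in a spatially
correlated way (we measured heading biases up to 6 degrees from this
effect on rendered frames). The original workflow tuned its thresholds
empirically per recording; Otsu on the difference image is the
deterministic counterpart. Components below `min_area` or touching the
image border are rejected and holes filled, leaving the larva as the
only object; the prey path inverts the size rule (large-object
rejection).

Midline extraction follows the distance-map ridge: the mask is rotated
so the previous frame's heading lies along +x (first frame: silhouette
principal axis), an exact Euclidean distance transform is computed, and
the per-column distance maximum is followed from the global maximum
(near the head center) toward snout and tail, with sub-pixel parabolic
refinement, a +/-8-row search window, and nearest-to-previous-row tie
breaking. Ridge points within ~1.5 px of the boundary at the snout tip
are trimmed — on a rounded tip the column maximum is dominated by
boundary quantization and tilts the head fit.

The midline is then fit with six connected segments: the head segment
spans a fixed arclength fraction (`head_fraction = 0.30`) from the
snout, standing in for the snout-to-swim-bladder landmark, which is not
resolvable in synthetic silhouettes; the remaining midline is divided
into five chords of exactly equal length (a bisection on the chord
length places the fifth vertex on the tail tip). `theta` is the head
segment's direction in the global frame; `gamma_i` are measured from
the body axis. Known limitation: the column-wise ridge walk assumes the
body is roughly monotone along the rotation axis; tail curls beyond
~90 degrees from the heading truncate the extracted midline.

Eye fitting thresholds dark objects inside a user ROI (adaptive Otsu on
the inverted ROI), drops components touching the ROI border (the dark
background), and fits moment-based ellipses to the two largest remaining
components; the angle between each major axis and the body axis is
reported nasal-positive, with left/right assigned by side of the axis.

Fish-prey geometry measures distance from the head-segment center (the
same reference as the distance measurements in the source workflow); the
alternative eye-midpoint reference differs by less than half the head
segment and can be added by shifting the reference point. Angular size
is `2 atan(prey_len / 2d)` and angular velocity the centered difference
of `phi`.

## Bout spectra and the Direction Index

A window of `N = round(window_ms * fs / 1000)` samples (150 ms free,
300 ms restrained; at 250 frames/s and 150 ms, N rounds from 37.5 to 38)
is centered on the bout midpoint and clipped to the series. Each
tail-segment trace is band-pass filtered with an order-4 Bessel filter,
0.5-100 Hz. The analog prototype is built from the reversed Bessel
polynomial and rescaled numerically to -3 dB at unit frequency, then
converted to the digital band-pass by pre-warped bilinear transform. The
filter is applied forward-backward: the zero-phase pass preserves the
sign of the tail-angle integral and the timing of cycles. A single
causal pass would shift peaks slightly; nothing in the analysis depends
on absolute phase, so the zero-phase choice is the conservative one.

The spectrum follows the textbook single-sided RMS construction:
`X_k = sum_n x_n exp(-i 2 pi n k / N)`, `A_k = X_k / N`, `B_0 = A_0`,
`B_k = 2 A_k` for `k = 1 .. N/2 - 1`, and `Bmag = |B_k|`. The five
per-segment spectra are summed, the sum is interpolated with a natural
cubic spline on a 0.1 Hz grid, and two peaks are read off: the
low-frequency (LF) peak in 2-8 Hz (the turn component; its amplitude
grades with the turn angle) and the high-frequency (HF) peak in
15-45 Hz (the tail-beat frequency). The search bands are supersets of
the observed 3-5 Hz and 20-35 Hz ranges and are configurable.

The Direction Index is

```
DI = sign( integral of mean(gamma_1..gamma_5) dt )
     * mean( interpolated sum spectrum at 3, 4, 5 Hz )
```

The 3-5 Hz set is interpreted as frequencies in Hz on the interpolated
grid (with the 1/3 normalization making it an average), matching the
description of an average peak amplitude between 3 and 5 Hz; reading
the summation index as raw bin numbers instead would tie the frequencies
to the window length, which contradicts the fixed 3-5 Hz band. `sign(0)`
yields `DI = 0`.

Per-bout metrics: `dtheta` is the heading difference between the first
frame after the bout and the last frame before it; `phi_pre`/`phi_post`
and the distance advance `dd` come from the same frames; the first-cycle
duration is the time from onset to the second zero crossing of the
high-band (>15 Hz) mean tail angle, and the cycle count is half the
zero-crossing count.

## Sequence statistics

`compute_ibis()` is the end-to-onset difference. `linefit()` implements
the two plotting conventions for folding left/right symmetry: `point`
point-reflects pairs with negative x about the origin (both coordinates
negated) and `mirror_x` negates only x; slope, intercept and Pearson r
are computed on the reflected data, matching how the fits are drawn.
Both reflections are involutions, so reflecting the data set leaves the
fit invariant — a property test. The folded histograms use 10-degree
bins with the first bin spanning -5 to 5 degrees, and the normalized
turn histogram divides turn counts by target-angle counts per bin (0/0
flagged undefined).

The sequence-start classifier implements the two-step eye-convergence
criterion: the sequence starts at the first bout after which the
contralateral eye exceeds `contra_high` and the ipsilateral eye exceeds
`ipsi_high` by the following bout boundary. No numeric criterion for
"near-maximal convergence" is given at source; the defaults (21.9 and
24.0 degrees) are midway between the measured pre- and post-convergence
levels of each eye, and both thresholds are configuration parameters.

## The closed-loop simulation

`run_trial()` is an event-driven state machine at 1 ms resolution (the
sensor rate). A target of width `size_deg` (height = width/2, the fixed
2:1 aspect ratio) sweeps a peripheral zone (30-50 or 35-55 degrees) at
`velocity_dps`. A detected swim — the responder agent's onset plus a
40 ms detection latency, inside the ~30-50 ms intrinsic delay of the
real apparatus — triggers a translation of target and background to the
update location at ~400 deg/s. Update locations are signed: negative
means the translation stops short of the midline on the original side
(simulated undershoot), positive crosses the midline (overshoot). In
the sequence paradigms the target is then held until the swim ends and
resumes motion into the contralateral hemifield, with an optional
per-bout escalation schedule of (size, velocity); in the
delayed-reappearance paradigm the target hides and reappears at the
center exactly `update_delay_ms` after swim onset. A trial with no
response ends at 56 s; the open-loop response-probability protocol
exposes its 60 s observation window as a separate configuration field,
since the two limits describe different protocol stages.

Timing measures follow the two-swim definitions: `IBI` from the end of
the first swim to the onset of the second, `RT` from stimulus
reappearance to the second onset, `dt` from first-swim end to
reappearance (negative when the stimulus returns before the swim ends).
The identity `dt = IBI - RT` is asserted on every simulated log.
Display-refresh quantization (60 Hz in the physical rig) is not modeled;
event times are continuous, which separates the control logic from
hardware artifacts. Left/right trial sides are interspersed by seed
parity.

The responder agent is plumbing, not a model of the fish: its reaction
time is a configurable base plus penalties for update-location
eccentricity and reappearance-timing mismatch, minus gains for larger
and faster stimuli, plus Gaussian noise. The simulated IBI/RT tables in
`analysis/05_virtual_reality.R` therefore characterize the state
machine and the timing bookkeeping, not the animal; the package makes no
claim of reproducing empirical reaction-time magnitudes.

## Numerical choices and degenerate inputs

* Problem sizes: the test and acceptance runs use 50 rendered noise-free
  bouts for heading recovery, 50 generated bouts for frequency recovery,
  100 noisy bouts for DI sign accuracy, 200 points for the regression
  recovery, and 400-1000 simulated trials for the timing identities —
  sizes chosen so the statistical checks are stable at desk scale.
* Rendering uses hard-edged disk stamping at ~0.7 px spacing; no
  anti-aliasing. Midline accuracy on these images is ~0.3 deg (heading)
  and ~1.6 deg RMS (tail angles), comfortably inside the 1 and 3 degree
  test tolerances.
* Ridge ties are broken toward the previous column's row; the first
  frame's rotation reference is the principal axis, later frames use the
  previous heading, and `theta` is unwrapped across frames.
* Degenerate inputs raise errors rather than guessing: empty masks, a
  prey centroid at the head center (undefined angle), bouts at the edge
  of a pose series, windows longer than the series, zero x-variance in
  fits, overlapping bouts in an IBI computation.
* All randomness is seeded; equal seeds give bit-identical traces,
  frames and logs.

## What passing tests do and do not show

The recovery suite demonstrates that the implemented chain — rendering,
segmentation, distance-map midline, six-segment fit, spectral
decomposition, DI, sequence statistics, closed-loop timing — is
internally consistent and recovers known ground truth under the stated
synthetic conditions. It does not demonstrate segmentation robustness on
real video (lighting, pigment, blur), nor does it validate the responder
agent as a behavioral model. The numbers a real experiment would
produce (IBI magnitudes, reaction times, peak locations of live fish)
are properties of the animal; the package reproduces the *machinery*
that measures them and verifies that machinery on data where the truth
is known.
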