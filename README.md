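# preycapture

Quantitative analysis of larval zebrafish prey-capture behavior from
high-speed dark-field video, with a discrete-event simulation of a
closed-loop virtual-reality assay.

Hunting zebrafish larvae chain discrete swim bouts into a goal-directed
sequence: each ~150 ms bout turns the fish toward the prey by a graded
angle and advances it, with inter-bout intervals (IBIs) that shorten as
the sequence progresses. The bout itself is one elementary motor
pattern — a symmetric tail oscillation near 30 Hz (~3 cycles) with a
slow, one-sided bend superimposed — and the amplitude of the asymmetric
component sets the turn angle continuously. This package is for
behavioral neuroscientists and tool builders who need the complete
measurement chain for that behavior, verified end to end on synthetic
data with exact ground truth.

## What it computes

* **Synthetic generator** (`gen_bout_kinematics`, `gen_capture_sequence`,
  `gen_psd_trace`, `render_frames`): tail-segment kinematics
  `gamma_i(t) = turn_gains_i A_turn P(t) + segment_gains_i A_osc
  sin(2 pi f_osc t + phi_i) E(t) + noise`, a prescribed heading ramp with
  exact net change, rendered dark-field video (bright larva + prey on a
  textured dark background; dark eye ellipses in restrained mode), and a
  1 kHz tail-sensor voltage trace.
* **Image pipeline** (`preprocess_free`, `preprocess_restrained`,
  `extract_midline`, `track_prey`, `prey_geometry`, `fit_eyes`):
  background subtraction or histogram remap, thresholding and
  morphological clean-up, exact Euclidean distance-map ridge following,
  and a six-segment midline fit (head segment + five equal-length tail
  segments) yielding heading `theta` and tail angles `gamma_1..gamma_5`;
  prey centroid tracking and the fish-target angle `phi`, distance `d`,
  angular size and angular velocity; moment-based eye-ellipse angles.
* **Bout spectra** (`detect_bouts`, `bandpass`, `rms_spectrum`,
  `summed_spectrum`, `direction_index`, `bout_metrics`): order-4
  zero-phase Bessel band-pass (0.5-100 Hz), the single-sided RMS
  amplitude spectrum `B_0 = A_0`, `B_k = 2 X_k / N` for
  `k = 1..N/2-1`, summed over segments and spline-interpolated; LF
  (turn) and HF (tail-beat) peaks; the signed Direction Index
  `DI = sign(integral of mean tail angle) x mean(sum spectrum at 3-5 Hz)`.
* **Sequence statistics** (`compute_ibis`, `linefit`,
  `angle_histograms`, `classify_sequence_start`): IBIs, straight-line
  fits under the point- and mirror-reflection plotting conventions,
  folded 10-degree histograms, and the two-step eye-convergence
  criterion for the start of a capture sequence.
* **Closed-loop simulation** (`stimulus_config`, `run_trial`,
  `run_grid`, `detect_swim_online`, `measure_timing`,
  `responder_agent`): the virtual-reality state machine — peripheral
  sweep, swim-triggered translation to an update location at
  ~400 deg/s, hold-until-swim-end with per-bout size/velocity
  escalation, delayed reappearance, 56 s no-response abort — with
  event logs and the IBI / RT / delta-t timing measures
  (`delta_t = IBI - RT` by construction).

## Worked example

Generate a bout that turns 30 degrees to the right, render it, track it
back, and decompose it:

```r
library(preycapture)

p      <- generator_params(delta_theta = 30, f_osc = 28, seed = 5)
truth  <- gen_bout_kinematics(p, pad_ms = c(30, 20))
scene  <- scene_params()
frames <- render_frames(truth, scene)
prep   <- preprocess_free(frames, background_texture(scene))
poses  <- track_midline(prep)

n <- nrow(poses)
poses$theta_deg[n] - poses$theta_deg[1]
#> [1] 30.09999

cfg <- spectrum_config("free", fs = 500)
win <- bout_window(truth$gamma, 500, truth$onset_ms, truth$offset_ms, cfg)
sp  <- summed_spectrum(win$gammas, cfg)
round(c(sp$lf, sp$hf), 2)
#> freq_hz     amp freq_hz     amp
#>    5.50   46.65   26.70   27.94
direction_index(win$gammas, sp, cfg)
#> [1] 43.57698
```

The tracked heading change (30.1 deg) recovers the generated 30 deg
within a tenth of a degree. The summed spectrum shows the two
signatures of the elementary motor pattern: a high-frequency peak at
the tail-beat frequency (26.7 Hz, within the ~1.5 Hz resolution of the
150 ms window around the generated 28 Hz) and a low-frequency peak
whose amplitude grades with the turn; the positive Direction Index
(+43.6, in summed-spectrum degrees) marks the bout as a rightward,
target-directed turn.

The numbered scripts under `analysis/` run the full study flow —
`01_simulate.R` (synthetic data), `02_track.R` (video pipeline +
recovery), `03_spectra.R` (spectral decomposition), `04_sequences.R`
(IBI and regression statistics), `05_virtual_reality.R` (closed-loop
protocols) — writing their tables under `results/`.

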