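# cifes — closed-loop, EMG-gated functional electrical stimulation, in silico

Foot drop after stroke is the inability to dorsiflex the foot during the
swing phase of gait. Functional electrical stimulation (FES) of the
tibialis anterior (TA) restores dorsiflexion, but conventional stimulators
are gated by tilt or pressure sensors and deliver a preset intensity.
`cifes` implements, as a fully synthetic and testable simulation, a
closed-loop architecture in which

* the **switch** is the patient's own rectus femoris (RF) surface EMG
  envelope crossing a threshold (T2 = 0.15 V) — stimulation fires on the
  intent to step;
* the **intensity waveform** is the contralateral healthy-side TA envelope,
  captured each cycle while it exceeds T1 = 0.15 V, stored as a normalized
  template, and replayed as the intensity profile of a biphasic pulse train
  (33 Hz, 200 µs anodic / 400 µs cathodic, charge-balanced, capped at
  240 V);
* the **gain** multiplying the template adapts from inertial (IMU)
  ankle-angle feedback: with the maximum ankle angle (MaxAA) of recent
  cycles above the healthy reference of 100.72°, the gain grows as
  `g' = clamp(g (1 + η e), g_min, g_max)`, `e` being the windowed MaxAA
  error, with a ±2° deadband.

The package is aimed at researchers in neurorehabilitation engineering and
closed-loop biosignal processing who want an executable, reproducible
version of this control loop. Since no patient recordings are public, a
**virtual patient** generates bilateral gait (per-cycle MaxAA, MinAA and
cycle-duration draws threaded by smooth raised-cosine curves, with exact
`IMU_up + IMU_down + 90°` decomposition), gait-locked sEMG bursts, and a
plant whose response to a delivered peak voltage V is a saturating
Hill-type assistance `a(V) = s·G·V²/(V² + V₅₀²)` with per-site muscle
fatigue `s = exp(−k·max load)`. The foot-drop defaults are calibrated to
the reported clinical operating points: unassisted MaxAA 105.53° /
28.84 deg², normalizing to 102.81° / 17.71 deg² under closed-loop
stimulation.

Beyond the loop itself the package provides the gait analytics (peak-based
cycle segmentation, 5°-bin distribution summaries), an SVM rehabilitation
tracker (median-heuristic Gaussian kernel, stratified 10-fold CV,
confusion matrix and ROC), and an fNIRS chain (spline motion-artifact
correction, 0.01–0.2 Hz zero-phase band-pass, modified Beer–Lambert
conversion to HbO/HbR/HbT, block averaging, task-window variance).

## Worked example

```r
library(cifes)

p <- make_profile("foot_drop")
p
#> <subject_profile> foot_drop
#>   MaxAA ~ N(105.53, 28.84), MinAA ~ N(86.00, 18.00), GCD ~ N(1.40, 0.040)
#>   TA burst 0.60 V (affected 0.25 V), RF burst 0.70 V, floor 0.02 V

sim <- run_closed_loop(p, controller_config(), n_steps = 300, seed = 1)
sim
#> <cifes_sim> closed mode, 300 steps, seed 1
#>   final 100 steps: MaxAA mean 103.16 deg, variance 17.34 deg^2
#>   trigger rate 100.0%, mean delivered peak 240.0 V, gain 2.000, fatigue scale 0.934

summary(run_closed_loop(p, controller_config(), n_steps = 300, seed = 1,
                        mode = "none"))
#>   final 100 steps: MaxAA mean 106.01 deg, variance 28.40 deg^2
#>   trigger rate 0.0%, mean delivered peak 0.0 V, gain 0.500, fatigue scale 1.000
```

Unassisted, the virtual patient walks at its foot-drop baseline
(MaxAA ≈ 105.5°, variance ≈ 28.8 deg²). Under the closed loop, every step
is triggered by the RF envelope, the drive saturates at the 240 V cap with
mild session fatigue (response scale 0.93), and the final-window statistics
sit at the assisted operating point — the mean pulled ~2.5° toward the
healthy reference and the variance concentrated by a third. `plot(sim)`
shows the MaxAA, delivered-peak and gain trajectories.

A command-line front end installs as `exec/cifes` with subcommands
(`simulate`, `envelope`, `switch`, `stim`, `gait-features`, `closed-loop`,
`classify`, `fnirs`); every run writes a `manifest.json` with the echoed
configuration, seed and file digests.

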