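---
title: "Models and methods of the cifes closed-loop FES simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the cifes closed-loop FES simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cifes)
options(cifes.quiet = TRUE)
```

# The system being simulated

Foot drop after stroke leaves a patient unable to dorsiflex the affected
foot during the swing phase of gait. Functional electrical stimulation
(FES) of the tibialis anterior (TA) can restore dorsiflexion, but
conventional devices are gated by tilt or foot-pressure sensors and deliver
a preset intensity. The architecture implemented here closes both loops
with the patient's own signals:

* the **switch** is the surface EMG (sEMG) of the ipsilateral rectus
  femoris (RF) — the patient's intent to step, available even when the TA
  is weak;
* the **intensity waveform** is the contralateral (healthy-side) TA sEMG
  envelope, captured each gait cycle, so the stimulated muscle is driven
  with the activation profile the healthy leg is actually using;
* the **intensity gain** is adapted cycle-by-cycle from inertial (IMU)
  ankle-angle feedback, pulling the affected side's gait statistics toward
  the healthy side.

No public recording accompanies the clinical study, so the package pairs
the controller with a *virtual patient*: a generative model of bilateral
gait kinematics, gait-locked sEMG, and a stimulation dose-response with
muscle fatigue. Everything below is testable end to end with synthetic
data; what that does and does not demonstrate is discussed at the end.

# The virtual patient

## Gait kinematics

Gait is modelled at the level the analysis operates on: per-cycle summary
features. For each side, cycle $k$ draws

$$\mathrm{MaxAA}_k \sim \mathcal N(\mu_{\max}, \sigma^2_{\max}),\quad
  \mathrm{MinAA}_k \sim \mathcal N(\mu_{\min}, \sigma^2_{\min}),\quad
  \mathrm{GCD}_k \sim \mathcal N(\mu_g, \sigma^2_g),$$

independently (MaxAA/MinAA: maximum and minimum ankle angle in degrees;
GCD: gait cycle duration in seconds). A smooth curve is threaded through
the draws as raised-cosine segments — peak to trough over the first 55% of
the cycle, trough to next peak over the remaining 45% — giving unambiguous
extrema with zero slope at every peak and trough. The waveform shape
itself is a free choice: only the per-cycle features are constrained by
the clinical report. Durations are quantized to the sample grid so that
feature extraction recovers the drawn values *exactly* on noise-free
recordings, which the tests exploit as a round-trip identity. Troughs are
clamped at least 4° below both adjacent peaks (affecting roughly 2% of
foot-drop draws); without that, a high trough next to a low peak yields a
"cycle" with no peak-trough-peak shape that no peak detector should be
expected to find.

Foot-drop defaults are the printed clinical operating points: affected-side
MaxAA mean 105.53° and variance 28.84 deg², healthy reference mean 100.72°.
The healthy-side variance is not printed (healthy gait is only described as
more concentrated), so 10 deg² is declared, well below the patient value.
MinAA and GCD laws (healthy 84°/8 deg², 1.2 s/0.01 s²; foot drop
86°/18 deg², 1.4 s/0.04 s²) are likewise declared defaults in
physiological ranges, not claimed clinical values.

Each ankle trace is emitted with its two IMU attitude components
(`imu_up`, `imu_down`, a fixed 60/40 split of the joint excursion) such
that the stance-referenced reconstruction

$$\text{ankle} = \mathrm{IMU}_{up} + \mathrm{IMU}_{down} + 90^\circ$$

holds sample-for-sample; in quiet stance both components are zero and the
joint reads 90°. Intermittent walking (`rest_prob > 0`) inserts standing
rests of 1–3 s between bouts, used to exercise the switch the way the
switching-accuracy comparison does.

## Surface EMG

Raw sEMG is band-limited (20–450 Hz) Gaussian noise gated by Hann windows
locked to the gait phase: one RF complex per cycle spanning late stance
into the swing onset, and one TA burst per cycle over the dorsiflexion
phase. The noise carrier is scaled by $\sqrt{\pi/2}$ so that the
*envelope* of a burst (whose rectified mean is $\sigma\sqrt{2/\pi}$)
reproduces the profile's burst amplitude. Defaults: healthy TA and RF
0.6 V, foot-drop RF 0.7 V (patients lift the leg harder than normal — the
basis for using RF as the switch), affected TA 0.25 V (the foot-drop
signature), noise floor 0.02 V. The floor maps to an envelope of roughly
0.016 V, an order of magnitude under the 0.15 V thresholds, so the switch
cannot false-trigger between steps. Motor-unit structure, electrode-skin
impedance and powerline interference are not modelled.

## Dose-response, calibration, and fatigue

The plant's response to a delivered peak voltage $V$ is a saturating
Hill-type curve in $V^2$,

$$a(V) = s \cdot G \cdot \frac{V^2}{V^2 + V_{50}^2},$$

with $G$ = `response_gain` (the maximum normalization, 4.81° — the gap
between the unassisted foot-drop MaxAA mean and the healthy reference),
$V_{50}$ the half-effect voltage and $s \in (0,1]$ the fatigue response
scale. The assisted per-cycle law is

$$\mathrm{MaxAA} \sim \mathcal N\!\big(\mu_{\max} - f\,(\mu_{\max} -
  \mu_{healthy}),\; \sigma^2_{\max}(1 - \kappa f)\big), \qquad
  f = m\,\frac{a(V)}{G} \in [0, 1],$$

so assistance both lowers the mean toward (never past) the healthy
reference and concentrates the variance. The shrink factor $\kappa$ is not
a free dial: it is solved from the calibration identity that at the
calibrated operating voltage the law must hit the reported assisted state
(mean 102.81°, variance 17.71 deg²), giving $\kappa = 0.682$.

$m \in [0,1]$ is the *waveform-modulation depth* of the drive: 1 for a
template-shaped closed-loop burst, 0 for a flat constant-intensity burst.
The clinical comparison lumps unassisted and constant-intensity FES
together as the same 105.53°/28.84 baseline — the improvement is specific
to closed-loop, waveform-modulated stimulation — so a flat drive moves the
gait statistics nowhere. This is the one place the package deliberately
departs from a pure dose-in/angle-out plant; without it a constant 240 V
drive would outperform the closed loop, contradicting the study the
simulator reproduces.

$V_{50}$ is fixed at 193 V by the operating condition under which the
assisted state was measured: sustained walking sessions with the deployed
dual-channel stimulator, i.e. cap-level (240 V) drive at a session-scale
fatigue response of about 0.93. The resulting fresh-muscle calibrated
voltage, `calibrated_voltage()` ≈ 220 V, lies inside the deliverable
138–240 V band.

Fatigue is a per-site leaky integrator: over an interval the load obeys
$\dot L = u - L/\tau$ with $u$ the stimulation duty and $\tau = 300$ s,
and the response scale is $s = \exp(-k \max_i L_i)$. $k = 1.009\times
10^{-3}$ is calibrated so that 900 s of continuous single-site stimulation
costs about 25% of the response, matching the reported fatigue test.
Because $s$ depends on the *maximum* per-site load, splitting a fixed
exposure across alternating channels always fatigues less — the rationale
for the dual-channel default.

# The sEMG conditioning chain

The envelope chain applies, in order: gain, full-wave rectification, a
2nd-order causal Butterworth low-pass at 10 Hz, a 50 ms trailing windowed
mean (the integration stage), a 100 ms moving average, and a 3.3 V
saturation clamp standing in for the ADC input range. The hardware
description names the stages but not orders or cutoffs; these defaults
produce one smooth peak per physiological burst. The chain is linear
(degree-1 homogeneous) below the clamp and settles at $2A/\pi$ for a
zero-mean sine of amplitude $A$ — the oracle the tests check to 2%.

# Switches and the accuracy metric

A switch turns on at the first sample *strictly* beyond threshold after at
least one sample on the other side (a crossing, deterministic on sampled
data), holds for `max(countdown, time beyond threshold)`, and refuses a
new onset within the refractory time of the previous one. Countdown
0.8 s and refractory 0.3 s are sized to a swing phase within the default
cycle durations; the clinical text states a countdown exists without a
value. The same operation serves the sEMG switch (0.15 V in the
controller, 0.2 V in the switching-accuracy harness — both thresholds
appear in the source description), the tilt switch (−25°, direction
below) and the foot-pressure switch (0.25 V).

Accuracy is greedy one-to-one matching of activation onsets to true swing
onsets within 0.3 s, scored as `matched / max(n_true, n_activations)`, so
misses and false triggers are penalized symmetrically.

# Stimulus synthesis

Intensity is an integer count: the calibration map takes 20→138 V and
140→255 V linearly (the two printed anchors; the intermediate curve is
unavailable, so linearity is declared), clamps outside the anchors, and
delivery is capped at 240 V. Pulses at 33 Hz are biphasic with a 200 µs
anodic phase and a 1:2 width ratio. The cathodic amplitude is $-V/2$ so
the phases carry equal and opposite charge — standard safe-stimulation
practice; the hardware text fixes the width ratio but not the amplitudes,
and `equal_amplitude = TRUE` renders the non-balanced alternative. The
16.67 kHz / 83.3% duty intensity carrier is off by default: it is a boost
stage implementation detail and rendering it honestly requires ≥167 kHz
sampling. Intensity is sampled-and-held at each pulse onset; a count of
zero suppresses the pulse, so every delivered amplitude is 0 or within
138–240 V.

# The closed-loop controller

Per gait cycle: the healthy-side TA envelope segment above T1 = 0.15 V is
captured, resampled to 100 points, and peak-normalized (the storage is
released every cycle, as in the device). When the affected RF envelope
crosses T2 = T1 the stimulator delivers a burst over the 0.8 s stimulation
window with counts

$$c(t) = \mathrm{clamp}\big(c_{\min} + g\,\cdot\,\mathrm{template}(t)\,
  (c_{\max} - c_{\min}),\ 0,\ c_{\max}\big),$$

i.e. the intensity tracks the template *within* the burst (the
waveform-modulation reading of the device's sampling-array description).
The gain update law is not given in the source — the multiplier is
"burned" from a host computer — so a clamped multiplicative proportional
rule was chosen for scale-invariance and boundedness:

$$g' = \mathrm{clamp}\big(g\,(1 + \eta\,e),\ g_{\min},\ g_{\max}\big),
 \qquad e = \overline{\mathrm{MaxAA}}_{w} - \mathrm{target},$$

with $\eta = 0.02$, a 10-cycle feedback window, bounds $[0.05, 2]$, target
100.72° (the healthy reference) and a ±2° deadband in which the gain is
held. MaxAA above target means insufficient dorsiflexion and raises the
gain. Because the healthy target is below what the plant can reach, the
loop settles where the feedback window hovers at the deadband edge
(~102.7°), which is what places the equilibrium at the reported assisted
state. Sensor-to-stimulator transport is treated as in-process (zero
delay).

# Gait analytics

Cycle segmentation uses Findpeaks-style peaks and troughs with a 3°
prominence criterion and a 0.5 s minimum peak separation (the clinical
peak-finder settings are unreported); each adjacent peak pair is one
cycle, GCD is the inter-peak sample count times the sample period, and the
maximum angular velocity is taken over the dorsiflexion interval
(trough→next peak) of the central-difference derivative. Distribution
summaries bin at 5° (reporting only — the mean and the *unbiased* sample
variance are computed from the raw values; the divisor is not stated in
the source, so $n-1$ is declared).

# Rehabilitation tracking

The 8-D feature matrix pairs left/right cycles by index: MaxAA, MinAA,
maximum angular velocity and GCD per side, in a fixed documented column
order. Classification is a radial-kernel SVM with the median heuristic,
$\gamma = 1/(2\,\mathrm{med}^2)$ where med is the median pairwise
Euclidean distance of the *training* rows of each fold, standardized with
training-fold statistics only — "median Gaussian kernel" names a library
preset, so the standard heuristic is declared, and per-fold
standardization is added because distance kernels on mixed units (deg,
deg/s, s) are otherwise dominated by the angle columns. Folds are
stratified and seeded; accuracy is the mean of the per-fold validation
accuracies. The day-over-day tracker runs the binary patient-vs-healthy
problem per session against a fixed healthy reference; as a synthetic
recovery schedule interpolates the foot-drop laws toward healthy the
accuracy decays toward chance, mirroring the reported 100→92.5% trend
qualitatively. The clinical 93.3%/600-sample figure mixes five patients
and one normal subject and is not claimed reproducible without the
patient data; both the multi-class and binary harnesses are provided.

# fNIRS processing

Optical-density traces are cleaned in three steps. (1) Motion artifacts:
samples whose 1 s moving SD exceeds 3× the trace's median moving SD are
flagged, dilated by half a window, merged across gaps under 2 s (so a
baseline-shift artifact is one segment), fit with a smoothing spline
(`spar = 0.3`) whose prediction is subtracted, re-leveled onto the line
joining the segment's neighbours, and the residual's spread is normalized
to the reference noise level — a spline cannot follow a sharp
discontinuity, and without that normalization the edge spikes re-trigger
detection; the routine iterates until a pass detects nothing, making it
idempotent. (2) A 3rd-order zero-phase Butterworth band-pass at
0.01–0.2 Hz (order declared; the band is as reported) after demeaning, so
DC is rejected exactly and the long high-pass transient is not excited.
(3) The modified Beer–Lambert law as a per-sample 2×2 solve,

$$\Delta OD(\lambda) = \big(\varepsilon_{HbO}(\lambda)\,\Delta HbO +
  \varepsilon_{HbR}(\lambda)\,\Delta HbR\big)\, d \cdot DPF(\lambda),$$

with bundled literature extinction coefficients for 760/850 nm
(0.586/1.548 and 1.058/0.691 mM⁻¹cm⁻¹ for HbO/HbR), DPF 6 per wavelength
and a 3 cm source-detector distance — the device's wavelengths and
coefficients are not published, and all constants are overridable.
Concentrations are reported in µmol/L; the source's own HbO units are
internally inconsistent (mmol L⁻¹ mm⁻¹ in one place, µmol L⁻¹ in another),
which is documented rather than resolved. Block averaging aligns windows
at task onsets with the onset sample as baseline; the task-window variance
is the unbiased variance over the first 45 s. `simulate_hemodynamics()`
provides the ground-truth synthesis (gamma-shaped response, cardiac and
respiratory sinusoids, optional artifacts) used to validate the chain by
round trip.

# Determinism, sizes, and degenerate inputs

Every stochastic entry point takes a seed or draws from the caller's
seeded stream; equal seeds give bit-identical outputs, which the CLI
manifest records alongside input/output digests. Validation failures
(Nyquist violations, negative voltages, unknown configuration keys,
schema-permuted feature files, out-of-range task onsets) raise errors
naming the offence; genuinely empty results (no peaks, no supra-threshold
segment) return empty objects and log instead.

The simulation sizes used throughout the tests and the acceptance script
are the package's choices for a desk-scale study: 1,000 cycles at 200 Hz
for generator-consistency checks, 300-step closed-loop runs (final 100
steps summarized) repeated over 20 seeds for convergence, walks of 10–250
steps for switch accuracy, 600 feature rows for the chance-level SVM
check, and 25-block hemodynamic runs at 10 Hz.

One statistical note: a variance estimated from 100 cycles has sampling
standard deviation $\sigma^2\sqrt{2/99} \approx 2.5$ deg² at the assisted
operating point, so individual-seed variance estimates scatter over
roughly ±5 deg² even when the simulator is exactly on target; per-seed
checks of the final-window variance should be read with that dispersion in
mind.

# What passing tests do and do not show

The virtual patient reproduces the *statistical* structure the analysis
consumes — per-cycle feature laws, burst timing and amplitudes, a
saturating dose-response, history-dependent fatigue — not the physics
underneath it. Passing tests demonstrate that the controller, signal
chain and analytics are internally correct and reproduce the reported
operating points *under the declared generative model*. They do not
demonstrate clinical efficacy, robustness to real electrode artifacts,
inter-subject variability beyond the two profile kinds, or transfer of
the SVM accuracies to real patient recordings. Known limitations:
stimulation affects only the per-cycle feature draws (no within-cycle
kinematic perturbation); frequency dependence of the dose-response is
fixed at the 33 Hz operating point; the fNIRS layout is reduced to
per-channel processing with no cortical registration.
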