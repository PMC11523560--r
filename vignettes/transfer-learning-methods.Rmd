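---
title: "Modelling fatiguing elbow flexion: simulation, synthesis and transfer learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fatiguing elbow flexion: simulation, synthesis and transfer learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(flexfatigue)
```

# The problem

Muscle fatigue — the exercise-induced loss of force capacity — changes the
relationship between muscle activation and joint torque over the course of a
sustained contraction. `flexfatigue` models sustained isometric elbow
flexion at a fixed posture (45° shoulder flexion, 90° elbow flexion, forearm
supinated) and asks a practical question: does pre-training a sequence model
on cheap musculoskeletal *simulations* improve torque prediction on
*recorded-style* data, compared with training on recorded-style data alone?
The package contains everything needed to pose and answer this question at
desk scale: a surrogate musculoskeletal model, a motor-unit fatigue model,
an EMG processing chain, a generator of synthetic "recorded" sessions, the
two learning regimes, and the evaluation harness.

# The surrogate musculoskeletal model

The elbow is driven by 7 muscle–tendon actuators: three triceps heads
(extensors, signed moment arm \(r_i < 0\)), two biceps heads, brachialis and
brachioradialis (flexors, \(r_i > 0\)). Because the task is isometric at a
fixed posture, muscle–tendon dynamics collapse and excitation ≡ activation;
the forward map is algebraic:

\[ T(t) = \sum_i F_{\max,i}\, a_i(t)\, r_i . \]

The inverse problem (which activations produce a target torque?) is
redundant; we resolve it per time step by **static optimization**, the
standard muscle-redundancy resolution:

\[ \min_a \sum_i a_i^2 \quad \text{s.t.} \quad \sum_i F_{\max,i} r_i a_i = T,
   \quad 0 \le a_i \le 1 , \]

with extensors pinned at a configurable co-activation floor (default 0 —
which is why triceps activations in the simulated dataset sit at zero, with
nonzero values only if the floor is raised). The KKT solution is
\(a_i = \lambda c_i\) with \(c_i = F_{\max,i} r_i\), clamped at 1 and
redistributed (largest \(c_i\) first, ties broken by actuator name). A
target above the strength ceiling \(\sum_{\text{flexors}} c_i\) is flagged
non-converged; this infeasibility is the package's surrogate for the
partial convergence of torque-tracking simulations, and it reproduces the
right structure: small subjects fail the high-torque targets, so the
converged subset thins toward higher peaks.

Scaling is deliberately simple: moment arms scale with height, maximum
isometric forces with mass, relative to a reference subject. Only the
product \(F_{\max} r\) matters downstream, so finer-grained scaling would be
invisible to the rest of the pipeline. The generic actuator parameters are
package defaults chosen so that the reference subject's strength ceiling
(~74 Nm) lies inside the 30–90 Nm target grid — the grid then spans
feasible-to-infeasible, as intended.

# The fatigue model

Each muscle's motor-unit pool is partitioned into rested (\(M_R\)), active
(\(M_A\)) and fatigued (\(M_F\)) fractions:

\[
\frac{dM_R}{dt} = -C + R\,M_F,\qquad
\frac{dM_A}{dt} = C - F\,M_A,\qquad
\frac{dM_F}{dt} = F\,M_A - R\,M_F,
\]

with the recruitment drive
\(C = L_D(TL - M_A)\) when under-activated (bounded by the available rested
fraction) and \(C = L_R(TL - M_A) \le 0\) when over-activated. We use the
elbow parameterization \(F = 0.00912\), \(R = 0.00094\), interpreted as
per-second rates: under that reading a sustained 80% load exhausts
(\(M_A < 0.8\)) near 27 s, which matches the 30 s horizon used for the
simulated trials; the dimensionless reading has no such correspondence.
\(L_D = L_R = 10\,\mathrm{s}^{-1}\) are deliberately fast so that results
are insensitive to them. The fatigued excitation passed to the forward map
is \(M_A(t)\), the achievable active fraction. Integration is forward Euler
at `dt = 0.01` s (stability requires `dt * max(LD, LR) < 1`); the onset
transient of a step input converges at \(O(dt\,L_D)\), everything after it
to well under \(10^{-3}\).

Two useful closed forms anchor the tests: sustained full load drives
\(M_A \to R/(F+R) \approx 0.0934\), and the 80% endurance time falls in
24–31 s.

A consequence worth knowing: while the target load stays below the residual
capacity, the drive replaces fatigued units from the rested pool and torque
holds *constant* — low-intensity trials do not visibly decline within 30 s.
Decline appears when a muscle's target saturates its capacity, i.e. near
the strength ceiling. That is the model, not an artifact.

# The simulated dataset

`simulate_dataset()` crosses a sampled cohort with peak torques 30–90 Nm in
10 Nm steps (300 models × 7 peaks = 2,100 configurations at full scale).
Per configuration: a 1.5 s ramp from 10 Nm to the peak, 1.5 s plateau, held
to 30 s; static-optimization inverse solve; non-converged configurations
dropped; fatigue applied (the pool starts tracking the 10 Nm baseline, so
trials begin at 10 Nm rather than with an activation transient); forward
torque; resampling to 300 time instances (10 Hz); and aggregation of the 7
actuators into 4 muscle groups (brachialis, triceps, biceps,
brachioradialis) by fmax-weighted mean — the weighting reflects each
member's torque contribution; a simple mean is available by option.

Cohorts are sampled from normal distributions truncated to the 5th–95th
percentile band. We use the recorded cohort's moments (height 1.7 ± 0.07 m,
mass 75.1 ± 12.2 kg) as the reference distribution for both cohorts — one
parameterization, no external tables — with the remaining statics derived
from height and mass by fixed allometric ratios plus 2% log-normal jitter,
and MVC torque scaling with mass.

# The recorded-style world and its reality gap

`synthesize_recorded_cohort()` stands in for the human experiment. Statics
are drawn at the recorded cohort's means/SDs truncated at ±3 SD (MVC
torque 46.9 ± 14.0 Nm, 9:16 female:male). Each session contains:

* three 5 s MVC plateaus with 2% multiplicative noise; the peak defines the
  task target (80% MVC) and the termination threshold (70% MVC);
* a sustained task whose per-muscle target loads come from the inverse
  solve **on a strength-matched model**: the subject's muscle forces are
  calibrated so the model's strength ceiling equals the measured MVC — the
  standard way a measured maximum enters a subject-specific model, and the
  reason per-muscle loads land high enough (≈0.6–0.95) that task failure
  occurs at realistic times;
* per-subject log-normal jitter (SD 0.3) on the fatigue rate, the stated
  mechanism for population spread in time-to-task-failure (defaults give a
  mean near 30 s with a 15–70 s spread, inside the plausible endurance
  band for an 80% MVC hold);
* achieved torque = forward map of the fatigued activations plus Gaussian
  noise whose SD ramps from 0.8 Nm toward 2.4 Nm as torque decays toward
  the 70% line — end-of-task variability growth;
* termination when torque spends 3 of the trailing 5 s below 70% MVC
  (cumulative-time rule, evaluated at 100 Hz);
* raw EMG at 3000 Hz per muscle: a band-limited (20–450 Hz) unit-RMS
  Gaussian carrier, amplitude-modulated by the fatigued activation
  envelope, with slow multiplicative jitter, additive baseline noise, a DC
  offset — and a 10% upward amplitude drift across the task. The drift is
  the deliberate **simulation-to-reality gap**: fatigue-related EMG
  amplitude growth that the clean simulated dataset does not contain, and
  that learning on recorded-style data must absorb.

What the generator does *not* emulate: motor-unit-level EMG structure,
crosstalk, electrode placement effects, sex-specific endurance, or the
noise spectra of any particular hardware. Passing tests therefore show that
the pipeline and the learning machinery behave correctly in a world whose
difficulty is plausible but synthetic; they do not certify performance on
human recordings.

# EMG processing

`process_emg()` follows the standard envelope chain, in order: mean
subtraction; zero-phase 4th-order Butterworth bandpass 10–500 Hz; full-wave
rectification; zero-phase 4th-order Butterworth lowpass 5 Hz; running
median over the largest odd window within 0.5 s (1499 samples at 3000 Hz,
reflect padding); division by the subject's cross-trial peak; clipping to
[0, 1]; linear interpolation to 300 time instances. Both Butterworth
filters are applied forward–backward because phase lag between the envelope
and torque would corrupt a sequence regression; the stated filter orders
refer to the underlying design. Normalizing by the observed peak of a
stochastic envelope biases amplitude upward by a few percent — shape is
preserved (the noise-free self-consistency test agrees with the generating
activations to under 5% RMS on a unit-mean scale).

For the physics baseline, activations are additionally smoothed by a
25-sample centered moving average; `select_smoothing_window()` reproduces
the window-selection diagnostic (sum of absolute successive differences
over windows 5–50 in steps of 5) and returns 25 unless the SAD curve's
elbow (first relative improvement below 5%) fires at a smaller window — the
default mirrors a choice originally made by inspecting that curve.

# The two learning regimes

Both models share one architecture: a stack of unidirectional LSTM layers
(3 × width 24) consuming the four activation channels per step, whose
per-step output is concatenated with the encoded static features (sex as
0/1, six measurements z-scored on training subjects only) and fed to a
feedforward head (2 ReLU hidden layers) ending in one torque output per
step — 300 outputs per trial, trained with Adam, MSE loss in raw
newton-meters, and L2 weight decay on weights and biases.

* **Direct learning**: everything trained from scratch on recorded-style
  trials. Selected hyperparameters: learning rate 6.4e-3, weight decay
  4.5e-2, feedforward width 23.
* **Transfer learning**: the backbone is pre-trained on simulated trials
  through a temporary per-step linear readout (discarded at hand-off;
  simulated trials carry no statics), then frozen except its last
  `unfrozen_backend_layers` ∈ {0, 1, 2} layers, and a fresh head is trained
  on recorded-style trials. Selected: learning rate 9.0e-3, weight decay
  9.4e-2, feedforward width 18, 2 unfrozen backend layers.

Implementation notes, since the networks are authored here (no deep
learning framework is used): gate order is (input, forget, cell, output);
initialization is uniform \(\pm 1/\sqrt{H}\); the output bias starts at the
training-target mean so optimization spends its steps on shape rather than
on travelling to the ~40 Nm scale; backprop-through-time is verified
against central finite differences in the test suite. Freezing is enforced
by exclusion from the optimizer, so frozen parameters are bitwise invariant.

Pre-training has an irreducible error floor worth understanding: simulated
trials carry no statics, and the same activation pattern maps to different
torques across differently scaled subjects, so a statics-free regressor
cannot resolve the subject scale (about half of the torque SD remains).
That is fine — the backbone's job is to encode activation–torque–time
structure, and the statics enter with the head at fine-tuning.

`random_search()` draws learning rate and weight decay log-uniformly
(defaults \(10^{-4}\)–\(10^{-1}\) and \(10^{-4}\)–1), widths from
{8, 16, 24, 32, 48} and the unfrozen count from {0, 1, 2}, evaluating each
draw by 5-fold cross-validation whose folds partition *subjects*, never
trials; ties break by parameter count, then draw order.

# Evaluation and the headline benchmark

`evaluate_three_way()` compares transfer, direct, and the physics baseline
(forward torque of smoothed envelopes through each subject's
anthropometrically scaled — not strength-matched — model) on leave-out
subjects: pooled RMSE/MAE over all leave-out time steps (per-subject values
are also emitted), prediction SD versus actual SD, and parity pairs.
Pooling is used for the headline numbers because single summary errors are
wanted; quartile conventions in `distribution_summary()` are type-7
(linear interpolation), with Tukey fences at 1.5 IQR.

`run_transfer_benchmark()` is the package's study-in-miniature, sized for a
single CPU: 40 simulated models × 7 peaks (≈200 converged pre-training
trials), 25 synthetic subjects, 5 leave-out, three seeds, ~150 fine-tuning
epochs — about 2–3 minutes per seed. Each seed replicates the whole
pipeline: simulate → pre-train → synthesize → fine-tune/train → evaluate.
The claim it tests is directional and stochastic: the *median* leave-out
RMSE of the transfer model does not exceed the direct model's, and both
beat the physics baseline when the generator's EMG drift (the reality gap)
is enabled. Absolute error magnitudes in this synthetic world are smaller
than on human data — the generator is cleaner than reality — and the
physics baseline here *over*-predicts (its anthropometric strength is
uncalibrated relative to the sampled MVC) rather than under-predicting;
the direction of the learning comparisons is the transferable result.

```{r, eval = FALSE}
bench <- run_transfer_benchmark(seeds = 1:3)
summarize_benchmark(bench$results)
```

# Numerical and design choices, collected

* Truncated-normal sampling by inverse CDF (exact, no rejection loop).
* Static optimization solved per distinct target level; clamp order is
  deterministic (largest coefficient first, name order on ties).
* Forward Euler with compartment clipping and renormalization; compartment
  sum conserved to 1e-9 per step.
* An alternative fatigue application — multiplicative residual-capacity
  scaling of the excitation rather than target-load tracking — is a
  documented config switch away (`apply_fatigue` on scaled excitations);
  the tracking form is the default because it matches the pipeline role of
  "fatigued excitations" as the achievable active fraction.
* Group aggregation weights: fmax (option: simple mean).
* All randomness flows through explicit integer seeds; samplers snapshot
  and restore the caller's RNG state.
* Trial length 300 and channel order (BRA, TRI, BIC, BRD) are contracts of
  the `flex_trial` container, validated at construction.

# Known limitations

* The elbow model is algebraic: no tendon compliance, activation dynamics,
  force–length/velocity effects, or posture variation.
* Convergence failures are purely strength-limited; real torque-tracking
  simulations fail for other reasons too.
* The EMG generator's noise parameters are plausible placeholders, not fits
  to any hardware; conclusions about absolute error magnitudes do not
  transfer to human data.
* Training budgets are desk-scale (hundreds of epochs, tens of subjects);
  the benchmark is designed to show direction, not to saturate performance.
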