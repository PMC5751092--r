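---
title: "Methods: two-stage sit-to-stand detection on synthetic orthosis signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage sit-to-stand detection on synthetic orthosis signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sistand` detects the initiation of sit-to-stand (SiSt) posture transitions
from a 14-channel sensor array on a knee–ankle–foot orthosis. This vignette
is the package's own account of the method: the model, the synthetic data it
is exercised on, every tunable that matters, and the numerical choices made
where the design was genuinely open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The recognition model

The pipeline classifies non-overlapping 0.2 s epochs (100 samples at
500 Hz) in two gated stages.

**Stage 1 (sitting detector)** classifies *every* epoch as sitting vs
other. A state machine turns these per-epoch decisions into a context:
after `gate_enter = 3` consecutive sitting decisions the system enters the
SITTING state; after `gate_hangover = 15` consecutive non-sitting decisions
without a detection it leaves it.

**Stage 2 (SiSt detector)** runs only in the SITTING state. Its first
positive decision emits a detection and exits the state until re-entry, so
a single sitting bout produces at most one trigger. The hangover matters:
as the wearer starts rising, stage 1 naturally flips to "non-sitting", and
stage 2 must stay live through the onset. At 0.2 s epochs the default
hangover spans 3 s — the longest transition the simulator can draw — so the
gate cannot close before a slow transition completes. Both gate parameters
are configurable in `cascade_control()`.

The cascade is the false-positive mechanism: during walking and standing
the gate is closed and stage 2 is structurally silent, so those activities
cannot produce SiSt triggers at all. This is asserted as a property
(`detect_stream()` with a stage 1 that never says "sitting" makes zero
stage-2 calls) and observed in the leave-one-subject-out experiment.

### Features

Each epoch yields 11 features per channel (154 total): standard deviation,
Shannon entropy, coefficient of variation, mean, maximum, minimum, median,
slope, max-to-RMS ratio, RMS-to-mean ratio, and fractal dimension. Choices
the feature list leaves open:

* **Entropy** — Shannon entropy in bits of a 10-bin equal-width histogram
  over the epoch's own range; 0 for constant epochs. The cheapest
  defensible estimator at 100 samples.
* **Fractal dimension** — Higuchi's method with `k_max = 8`, the standard
  estimator for short physiological windows; constant epochs return 1 (a
  smooth line).
* **Slope** — ordinary-least-squares slope against the sample index,
  reported per second (multiplied by the sampling rate) so its units do not
  depend on the epoch length.
* **Ratio guards** — coefficient of variation, RMS/mean and max/RMS replace
  a denominator whose magnitude is below 1e−12 with 1e−12, so constant-zero
  epochs stay finite.

Features are normalized to [−1, 1] by x′ = 2(x − min)/(max − min) − 1 with
bounds fitted **per training fold** (never on held-out subjects — the
alternative, global bounds, changes numbers and leaks). Degenerate columns
(max = min) map to 0, a neutral value for an uninformative feature. Test
values outside the training range extrapolate beyond [−1, 1] and are not
clipped. Lagged-epoch matrices concatenate rows e−k+1 … e (k = 1…10,
causal); rows before the k-th repeat the first row, preserving row count
while keeping every output row a function of past epochs only.

### Feature selection

mRMR ranks the 154·k lagged columns by the first-order incremental
difference criterion: the first feature maximizes the mutual information
I(x; c) with the class; each next maximizes I(x; c) − (1/|S|) Σ I(x; s)
over the selected set S. Mutual information uses the plug-in estimator on
10 equal-width bins over the normalized training range (the classic mRMR
practice; bin count configurable). Criterion ties break first toward lower
accumulated redundancy, then toward the lowest column index. The
redundancy-first tie-break is deliberate: with the difference criterion an
exact copy of an already-selected feature and an uninformative novel
feature can both score exactly zero, and the minimal-redundancy reading
should prefer the novel one; index-only tie-breaking would pick whichever
comes first.

For tractability the ranking operates on a candidate pool of the 300
lagged columns with the highest relevance, and the ranking is taken 40
deep; wrapper forward feature selection (FFS) then scans that list in
order, keeping a candidate iff it strictly improves validation F1 of a
small seeded ELM (100 hidden neurons), stopping after 8 consecutive
non-improvements or 30 features. The validation split is one held-out
*training* subject (falling back to a seeded 75/25 row split when only one
training subject exists); wrapper training keeps every minority-class row
and caps the rest at 20 000, because with ~3% transition prevalence the F1
signal is otherwise drowned and FFS degenerates to two or three features.

### Classifiers

The **ELM** is a single-hidden-layer network with logistic activation:
input weights and biases drawn uniform(−1, 1) under a seed (one
weight-plus-bias block per neuron, so models with shared seeds are nested
by hidden-layer prefix — this makes the training residual provably
non-increasing in L on fixed data), and output weights solved in closed
form, β = H⁺T, via a Moore–Penrose pseudoinverse with relative singular
value cutoff 1e−10. With L = N the fit is exact (zero training error), a
property the tests assert. Targets are coded {−1, +1} with decision
threshold 0.

`train_elm()` also accepts an optional per-sample ridge penalty
(β = (H′H + λNI)⁻¹H′T). The plain pseudoinverse remains the default for
the operation itself, but the cascade pipeline sets λ = 0.03: with pure
least squares the decision scores of *subjects unseen at training* drift
near the 0 threshold — the marginal postures (legs-extended sitting, the
lowest-amplitude transitions) then flip sides fold by fold. The penalty is
the standard regularised-ELM remedy and was fixed after a sweep on
3-subject pilot data, then validated unchanged on full 10-subject runs.

The **MLP** has one hidden sigmoid layer (Z = f(Wx − θ)), a sigmoid output
unit, {0, 1} coding with threshold 0.5, and is trained by full-batch
backpropagation with momentum (defaults: rate 0.01, momentum 0.9, 500
epochs, early-stopping patience 20 on a 10% validation split — all
unstated in the underlying design and therefore fixed in
`mlp_control()`).

`select_hidden_neurons()` chooses the width by stratified 5-fold
cross-validation (lowest mean misclassification error, ties to the smaller
count). The LOSO pipeline itself uses a fixed width of 300 with the ridge
above rather than re-running the grid search in every fold: the search
multiplies runtime by the grid size while the regularised solution is flat
in L over the 150–600 range on this data, so the conclusions do not move.

## 2. The synthetic data generator

No recordings of the original experiment are available, so the simulator
*is* the study population here. It reproduces the protocol: per subject,
activities 2, 3, 4, 6, 7, 8 once per each of five initial seated leg
positions plus activities 1, 5, 9, 10 once — 34 one-minute trials; ten
subjects give ≈5.7 h. Ground truth (transition intervals, per-sample
posture) is recorded exactly.

* **Knee trajectory.** Each SiSt follows a logistic from the
  position-dependent seated angle to the standing angle (~5°). The drawn
  "truth" duration is the central part of the curve where the angular
  velocity exceeds 5% of its peak; the full logistic window is a factor
  steepness/u₀₅ ≈ 1.12 longer, with steepness 4.9 chosen so the endpoint
  offsets stay below 1° for spans up to ~105°. Stand-to-sits are the
  mirrored curve; they exist as realistic negatives, not as a detection
  target.
* **Durations.** Drawn from a normal truncated to [0.5, 3.0] s whose
  parameters (μ₀ = 0.8277, σ₀ = 0.8565) are moment-matched in closed form
  so the *truncated* law has mean 1.30 s and SD 0.55 s — the dataset-level
  statistics the generator is calibrated to. Naively truncating
  normal(1.30, 0.55²) would bias the mean to 1.38 s. "Fast transition"
  activities share this distribution: only pooled duration statistics are
  available to calibrate against, and a separate faster law would move the
  pooled mean away from them (a simulator limitation).
* **Seated angles.** Position 0 (legs extended) 50°, position 1 (bent
  under the chair) 110°, positions 2–4 90°, each with ±3° subject jitter;
  the 50° convention for position 0 keeps 45° strictly inside every
  transition so one annotation rule covers all positions.
* **Other channels.** Segment inclinations are derived from the knee angle
  (thigh toward horizontal when seated, shank unwinding a position-dependent
  offset); accelerometers see the gravity projection of those inclinations
  plus a small motion term and slow sinusoidal drift; gyroscopes see the
  inclination rate; insole forces ramp from a seated baseline to
  body-weight-proportional standing loads and oscillate at the
  speed-dependent cadence during gait. Additive white noise: 0.05 g
  (accelerometers), 5°/s (gyroscopes), 0.5° (potentiometers), 2 N
  (forces).
* **Scripts.** Activities 3 and 7 insert a 2 s standing pause between
  rising and walking — a natural balance pause that also keeps the
  transition's logistic tail free of gait oscillation.

**What the simulator does not emulate.** Biomechanical fidelity beyond the
logistic knee model; trunk dynamics; impaired or elderly movement;
inter-trial variability of sensor placement; transition styles that differ
from a monotone knee extension. Passing tests on this generator therefore
demonstrates that the pipeline's machinery is correct and that the cascade
eliminates false positives *under these conditions*; it does not establish
performance on real orthosis recordings.

## 3. Preprocessing and annotation

**Denoising** is translation-invariant wavelet shrinkage: an orthogonal
wavelet with 4 vanishing moments, 4 levels, soft universal threshold
(σ estimated by the MAD of the finest-detail coefficients pooled over all
shifts), cycle-spun over all 2⁴ = 16 decimation phases — for a periodic
transform, averaging the 16 phases makes the operator exactly covariant
under circular shifts. By default the signal is reflection-padded (512
samples) and cropped after reconstruction: trials that begin and end in
different postures otherwise inherit a wrap-around step whose ringing
looks like a knee drop in the final epochs. `boundary = "periodic"`
preserves the exact shift covariance when that property is wanted.

**Annotation** replaces the original manual raters. SiSt midpoints are
downward 45° crossings of the denoised knee angle; each crossing grows into
a region bounded where the knee angular-velocity magnitude falls below 5%
of the event's peak. Numerically the 5% rule is delicate: for a slow
(3 s) transition the velocity lingers near the threshold, and boundary
estimates from a smoothed derivative jitter by hundreds of milliseconds.
The annotator therefore uses the velocity scan (0.2 s running-mean
derivative, sub-0.1 s dips bridged) only as a coarse pass, then fits a
four-parameter logistic to the knee curve around the event and evaluates
the 5% rule on the *fitted* velocity profile, falling back to the coarse
boundaries if the fit fails. On simulated trials this recovers the ground
truth interval to under 0.06 s. Epoch labels follow the majority rule —
an epoch is positive iff at least half its samples lie in a region, with
exact ties labelled 1 (favouring sensitivity); trailing partial epochs are
discarded.

## 4. Evaluation conventions

* **Epoch level.** True positives and false negatives are counted on
  labelled epochs; an epoch that merely overlaps a region is granted grace
  (a positive there is a TP, never an FP); false positives are counted only
  wholly outside regions. F1 = 2TP/(2TP + FP + FN). Because the cascade
  disarms after its first in-bout detection, most in-region epochs after a
  detection are never classified positive — epoch-level TPR is therefore
  structurally low (~0.15) even when every transition is detected, and F1
  exceeds TPR whenever FP ≈ 0.
* **Transition level.** One correctly detected epoch suffices: a
  transition trial with ≥1 in-region detection is a TP; with none it is
  Failed to Detect. A non-transition trial with any detection is an FP.
  Counts are summed over LOSO folds (rates are averaged).
* **Detection time.** From the annotated region onset to the start of the
  first positively classified in-region epoch, floored at 0 (a detection
  in the onset epoch is immediate); also reported as % of region duration.
  FTD trials contribute no detection time.
* **Paired t-test** on per-subject F1 compares classifiers; degenerate
  branches are defined explicitly (all-zero differences: p = 1; constant
  non-zero differences: p = 0, flagged).

## 5. Problem sizes and runtime

The shipped experiment uses the full protocol — 10 subjects, 340 trials,
102 000 epochs — with the lag-8 ELM cascade under 10-fold LOSO; this is the
configuration both the acceptance test and `scripts/acceptance.R` run, and
it completes in roughly seven minutes on one CPU (simulation ≈ 20 s,
denoising + features ≈ 3 min, the ten folds ≈ 4 min). Unit and property
tests run on single trials or small hand-built feature sets instead, so the
rest of the suite stays in seconds.

## 6. Known limitations

* The zero-false-positive result is demonstrated on the synthetic
  population; real recordings bring artifacts (sensor slippage, atypical
  transitions) the generator does not model.
* Stage 2 never sees stand-to-sit epochs at training (its context is
  sitting-or-SiSt); StSi robustness rests entirely on the gate being closed
  while standing.
* The greedy incremental mRMR is an approximation to subset-optimal
  ranking; tests check ≥90% agreement with exhaustive search on small
  instances rather than assuming equivalence.
* Detection latency trades off against the false-positive margin through
  the ridge penalty: larger λ widens cross-subject margins but detects
  slightly later (~0.27 s ≈ 17% into the transition at the default).
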