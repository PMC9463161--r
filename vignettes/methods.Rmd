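---
title: "Scoring parkinsonian gait severity from a lumbar IMU: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring parkinsonian gait severity from a lumbar IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigdgan)
```

## The problem

Levodopa-treated Parkinson's disease patients cycle between an ON state
(drug active, milder symptoms) and an OFF state (drug worn off, worse
symptoms). The postural instability and gait disorder (PIGD) sub-score of
the UPDRS motor exam — five clinician-rated items, each 0–4, so 0–20 in
total — summarizes how impaired gait and balance are, but it is only
available at clinic visits. `pigdgan` implements a pipeline that estimates
the PIGD score from a single lumbar-worn inertial sensor recorded during a
walk test, and judges a model by whether its predicted scores order a
subject's OFF visit above their ON visit.

The pipeline has four stages, each exposed as ordinary R functions and
wired together by `run_pipeline()`:

1. **simulate** — a synthetic gait-cohort generator (`simulate_cohort()`),
2. **preprocess** — turn excision and log-spectral featurization
   (`preprocess_cohort()`),
3. **train** — a small 1-D convolutional regressor trained plainly
   (`train_cnn()`) or adversarially with a generator (`train_gan()`),
4. **evaluate** — per-visit score aggregation and ON/OFF discrimination
   (`score_visits()`, `build_report()`).

## Why a simulator

The clinical recordings this class of method is developed on are access
restricted, so the package ships a generative stand-in. The simulator is
not a biomechanical gait model; it reproduces exactly the statistical
structure the downstream method relies on:

- **Quasi-periodic walking.** Vertical acceleration during a straight-walk
  bout is a three-harmonic series on a cadence fundamental (defaults:
  2.0 Hz at PIGD 0, amplitudes 1 : 0.5 : 0.25), with lateral sway at the
  stride rate (half cadence) and a weaker antero-posterior component.
  Per-step cadence jitter (coefficient of variation 3 % at PIGD 0, growing
  by 0.35 points per PIGD point) broadens the spectral peaks the way
  impaired gait does.
- **Severity dependence.** Cadence falls by 0.025 Hz and vertical amplitude
  by 0.012 g per PIGD point; a narrowband 4–6 Hz tremor component grows
  with severity. These slopes are conventional gait-literature magnitudes,
  not fitted to any cohort: the cohorts this emulates publish no cadence or
  amplitude statistics to fit.
- **Paired ON/OFF design.** Each subject carries a latent (ON-state)
  severity trait drawn from a right-skewed gamma (shape 2, scale 2 PIGD
  points, matching the low-score-heavy distributions typical of such
  cohorts). An OFF visit expresses the trait plus a medication gap
  (default 6 points); TRANSITIONING visits half the gap. The clinician
  score is the expressed severity rounded and clipped to 0–20.
- **Turns.** Between straight-walk bouts the first gyroscope channel
  carries a raised-cosine angular-rate pulse integrating to 150–200
  degrees — comfortably above the 120-degree detection threshold — with
  alternating sign, as a subject walking back and forth would produce.
- **Nuisance structure.** A 1 g gravity offset plus a slow 0.05 Hz drift on
  the vertical channel, and white measurement noise (0.02 g), give the
  high-pass filter real work to do.

What the simulator deliberately does not model: freezing-of-gait episodes,
double-support asymmetries, magnetometer channels, or realistic torso
kinematics during the turn itself. Consequently, passing tests on synthetic
cohorts demonstrate that the pipeline recovers severity structure *of the
kind assumed*, not that it would reach any particular accuracy on clinical
recordings.

## Feature processing

`preprocess_cohort()` converts each six-channel recording into fixed-size
examples:

1. **Turn detection** (`detect_turns()`): angular rate about the sensor's
   first axis is integrated by the trapezoidal rule over a sliding 2-s
   window; wherever the windowed rotation magnitude exceeds 120 degrees the
   whole contributing window is marked, and marked stretches closer than
   0.5 s are merged. Marking the full window (rather than only the crossing
   samples) guarantees detected intervals cover the turns they flag, at the
   cost of trimming up to one window length from the adjacent walk.
2. **Segmentation** (`segment_walks()`): the complement of the turn
   intervals; snippets shorter than the 3-s truncation length are dropped
   and counted.
3. **Truncation** (`truncate_segment()`): the first 384 samples (3 s at
   128 Hz) of each snippet, so every example has identical dimensions.
4. **High-pass filtering** (`highpass_segment()`): a 4th-order Butterworth
   high-pass, 0.25 Hz cutoff, applied forward–backward for zero phase. The
   cutoff is interpreted in Hz: a normalized reading (0.25 × Nyquist
   = 16 Hz) would destroy the 1.5–2.5 Hz gait band, while 0.25 Hz cleanly
   separates gravity and drift from gait. Both the interpretation and the
   order are arguments. Because the filter's impulse response outlasts a
   3-s segment, each pass starts from steady-state initial conditions (the
   classic `lfilter_zi` construction) after odd-reflection edge extension;
   without this, start-up transients would dominate the whole segment.
5. **Log spectra** (`log_spectrum()`): per channel, the natural log of the
   384-point DFT magnitude plus a floor of 1e-8. All 384 (conjugate
   symmetric) bins are kept, so the feature tensor is 3 × 384 — the
   dimensionality the generator's 1152-unit output reshapes to. A
   half-spectrum variant (positive frequencies, zero-padded back to 384)
   is available via `half_spectrum = TRUE`; the full symmetric spectrum is
   the default. No per-example amplitude normalization is applied —
   amplitude carries severity information here, and filtering has already
   removed offsets.

## Networks

The **discriminator/regressor** (`init_discriminator()`,
`discriminator_forward()`) is deliberately shallow: two 1-D convolutional
layers (32 filters of length 3, stride 1, padding 1, so the 384-sample axis
is preserved), a 512-unit dense layer, and a 2-unit output head. Output
unit 1 is the PIGD score with no activation — scores may go slightly
negative on degenerate inputs, and evaluation clips nothing, since clipping
would bias within-subject differences. Output unit 2 passes through a
sigmoid to give the real-example probability used in adversarial training;
plain CNN training ignores it. ReLU activations and dropout (probability
0.5) follow each of the three hidden layers; dropout is active only in
training mode. All hidden layers use weight normalization (a learned scale
`g` times a unit direction) instead of batch normalization, so inference is
deterministic and no cross-example noise enters the regression. The
**generator** (`init_generator()`, `generator_forward()`) maps 100
uniform-[0,1] noise inputs through two weight-normalized 512-unit ReLU
layers to a linear 1152-unit output, reshaped to 3 × 384 — a fake
log-spectral example. Its output layer carries an L2 weight penalty.

Initialization: convolutional directions are semi-orthogonal (SVD of a
Gaussian draw — orthonormal along whichever dimension is smaller, which for
the 32 × 9 first-layer matrix means orthonormal columns); dense directions
are He-uniform (bounds ±sqrt(6/fan-in)); biases start at 0 and weight-norm
scales at 1.

The layers are implemented directly on BLAS matrix operations with
hand-written backward passes (C++ kernels in `src/fastnn.cpp` for the
convolutions, weight-norm algebra, fused ReLU/dropout, and the fused Adam
update). The networks are small enough that this keeps the package free of
deep-learning framework dependencies while every gradient remains auditable
— the test suite checks each backward pass against central finite
differences.

## Losses

`loss_train(pred, batch, alpha, beta)` is the paired-visit regression loss:
`alpha` times the mean squared error of predictions against clinician
scores, plus `beta` times the mean squared error of *predicted
within-subject visit differences* against clinician-scored differences.
Every example in a mini-batch is paired with an example from the same
subject's opposite visit, and both means run over all N examples, so each
pair contributes its difference term twice — once per member. (A per-pair
normalization would differ only by a constant factor; the all-N form keeps
per-example weighting uniform and matches the printed 1/N normalization.)
The pair term is what pushes the model to track the medication state within
a subject instead of only separating subjects.

For adversarial training, `loss_disc()` adds a least-squares real/fake
term: `gamma * loss_train + delta * (mean((D(x) - 1)^2) + mean(D(G(z))^2))`,
and the generator minimizes `loss_gen = mean((D(G(z)) - 1)^2)`. Fake
examples carry no PIGD label and never enter the regression term.

`historical_average_penalty()` adds an L2 cost on the drift of the current
parameters from an exponential moving average of recent parameters
(decay 0.999, coefficient 1e-3 by default, applied to the
discriminator/CNN only). It damps the oscillations the adversarial game
otherwise produces. All three knobs are exposed in `train_config()`.

## Training

`train_cnn()` and `train_gan()` share one loop. Per step: a paired
mini-batch is drawn (`batch_pairs` selections, each joined by a uniform
draw from the same subject's opposite visit; subjects may repeat), the
discriminator takes one Adam step (learning rate 0.01; standard moment
defaults 0.9/0.999/1e-8), and in GAN mode the generator then takes one Adam
step against the just-updated discriminator. One epoch is
`ceil(n_train / batch)` steps, making a fixed epoch budget data
proportional. The update order (discriminator first, one step each) is a
convention; nothing in the game forces it.

A development set of `dev_subject_count` subjects (10 by default) is split
off by subject before training — once, frozen thereafter — and its plain
unpaired MSE is recorded each epoch. `check_convergence()` declares a trace
steady when its trailing-20-epoch relative fluctuation (max − min)/max
falls below 5 %; both knobs are configurable.

Two kinds of per-epoch traces are recorded. The `*_batch` traces are means
of the mini-batch losses actually optimized; they carry sampling and
dropout noise whose variance is set by the batch size, so on small cohorts
their fluctuation has a floor unrelated to convergence (a mini-batch MSE
over n residuals fluctuates by roughly sqrt(2/n) in relative terms). The
primary traces (`train_loss`, `disc_loss`, `gen_loss`, `dev_mse`) are
therefore evaluated at each epoch's end in inference mode on a fixed
evaluation batch and a fixed noise draw: they are deterministic functions
of the parameters, and their steadiness measures whether the *model* has
stopped moving — which is what a convergence rule is after.

Every random stream (splits, batches, dropout masks, noise) draws its own
sub-seed from the master seed via `derive_seed()`, so runs are exactly
reproducible, and GAN training with `delta = 0` consumes the discriminator
streams identically to CNN training — the test suite exploits this to check
that the two trainers coincide in that limit.

Numerical guards: the sigmoid output is clamped to (1e-12, 1 − 1e-12) so
the least-squares adversarial terms and their (0,1) preconditions stay
defined when a logit saturates; saturation itself (vanishing `p(1-p)`
gradient) is inherent to least-squares-on-sigmoid adversarial objectives
and is damped here by the generator L2 penalty and historical averaging.
Training aborts with a diagnostic if any loss goes non-finite.

## Evaluation

`score_visits()` averages inference-mode score-head predictions over all
walks of a visit. `build_report()` then aggregates per subject: the
multi-visit protocol drops TRANSITIONING visits and keeps every subject
with at least one ON and one OFF visit; the paired protocol additionally
requires exactly one of each. ON/OFF accuracy is the fraction of counted
subjects with mean OFF prediction strictly above mean ON prediction — ties
count as incorrect, the conservative reading of a strict inequality. The
same rule applied to clinician scores gives the clinician's accuracy.
Agreement with the clinician is summarized by the coefficient of
determination `1 − SS_res/SS_tot` over the per-subject state means; this
penalizes miscalibrated-but-correlated predictors, and a squared-Pearson
alternative is available via `r2_method = "pearson"`.

## Reference study conditions

The package's own acceptance checks (see `scripts/acceptance.R` and
`tests/testthat/test-acceptance.R`) run the full pipeline on a fixed
synthetic design chosen once: 35 subjects with paired ON/OFF visits, a
medication gap of 6 PIGD points, two 6-s walk bouts per recording (100
training examples after a 10-subject development split), GAN training for
100 epochs with mini-batches of 10 pairs — the mini-batch is scaled to the
cohort so that the number of optimizer steps per epoch matches the
batch-to-dataset proportion the method was designed around. Generator L2 of
1e-3 and a historical-averaging coefficient of 1e-2 are used there; both
are stability choices within the ranges the method leaves open. At these
sizes a full GAN run takes a few minutes on one CPU core; the unit-test
fixtures are smaller still.

## Known limitations

- The simulator's severity signal (amplitude, cadence, spectral sharpness,
  tremor) is stronger and cleaner than clinical reality; synthetic
  accuracies should be read as plumbing checks, not clinical performance.
- Least-squares adversarial training can still saturate the real/fake
  sigmoid in long runs; the generator then stops receiving gradient. Mode
  collapse is not quantified.
- Scores are unbounded: a model can emit values outside 0–20 on inputs far
  from the training distribution.
- The turn detector assumes turns appear as large cumulative rotation about
  one known axis; sensors mounted differently would need the axis argument
  re-mapped.
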