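---
title: "Methods: simulating, classifying and redesigning drug schedules in 3D cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, classifying and redesigning drug schedules in 3D cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camsched)
```

camsched implements a closed analysis loop for drug-schedule design in
simulated 3D cancer-cell cultures: a lattice culture simulator produces
multivariate time series under doxorubicin/BAPN schedules; a multi-scale 1D
convolutional network classifies each simulation's treatment outcome; class
activation maps (CAMs) localize the temporal features that define each
outcome class; and those features motivate alternative administration
schedules whose effect is quantified as a shift in outcome prevalence. This
vignette records the models, the tunable parameters and the design choices
behind each stage, and what the shipped tests do and do not establish.

## The waveform benchmark

Before trusting CAMs on simulation data, the pipeline is validated on a
controlled benchmark where the ground truth location of class information is
known. Each trace has three channels of 300 samples (sampled at 100 Hz, so
3 s of signal) split into three equal regions R1/R2/R3. R1 and R3 are a
constant zero baseline; R2 carries one of three waveforms — sine, square or
sawtooth — with frequency drawn uniformly on the grid 0.5–5 Hz (step 0.1),
amplitude on 1–100 (step 0.1) and phase uniform in [0, 2π), independently
per channel. Because the only class-dependent structure lies in R2, a
correct explanation method must concentrate relevance there.

Choices worth stating explicitly:

* **Trace length and region bounds** (300 samples, equal thirds) are package
  defaults chosen to make the three-region structure unambiguous while
  keeping network training fast; they are configurable in `signal_config()`.
* **Three channels per trace** make the benchmark genuinely multivariate:
  each channel draws its own frequency/amplitude/phase of the *same* class
  waveform.
* **Random phase** prevents the classifier from keying on phase alignment
  rather than wave shape.
* **An optional noise knob** (`noise_sd`, default 0) adds Gaussian noise for
  robustness experiments; the validation property is stated for the
  noiseless benchmark.
* **Z-normalization** standardizes each channel of each trace to mean 0 and
  unit *sample* standard deviation (divisor n−1), so `[1, 2, 3]` maps to
  `[−1, 0, 1]`; a constant channel maps to zeros. The convention is fixed
  here because both conventions appear in the wild and tests freeze this
  one.
* **Class balance**: `n_traces` is split as evenly as possible; remainders
  go to the earlier classes in the order sine, square, sawtooth, so the
  500-trace default yields 167/167/166 deterministically.

The train/test split assigns `round(0.7 n)` traces to training uniformly at
random without stratification, mirroring common practice for this kind of
benchmark.

## The classifier

The network is an inception-style multi-scale 1D CNN for multivariate
series. Each block applies a 1×1 bottleneck convolution followed by three
parallel convolutions with distinct kernel lengths (defaults 10, 20, 40) and
a max-pool branch with its own 1×1 convolution; the four branches are
concatenated and rectified, and a projected shortcut joins every third
block. All convolutions use same padding, so feature maps keep the input's
temporal length — a property the CAM computation relies on. Global average
pooling (GAP) over time feeds a single linear softmax layer.

Training uses softmax cross-entropy with Adam (learning rate 1e-3, halved
after 50 epochs without improvement, floor 1e-5), minibatches of 64 and a
default budget of 1500 epochs; the ensemble protocol fits the same
architecture five times with independently derived seeds and deploys the
fit that maximizes (accuracy, precision, recall) lexicographically on the
evaluation set, ties resolving to the lowest fit index. Following the
study protocol this selection is made on the test set; that reuses the test
set for a (mild, one-in-five) selection decision, which is reported here as
a caveat — an honest alternative is to pass a held-out validation set to
`select_best()`.

Forward and backward passes are written in the package (RcppArmadillo
kernels; per-slice im2col so each layer is a cache-resident GEMM), with a
pure-R reference implementation of the loss and gradient kept alongside.
The test suite checks the compiled gradients against both the R reference
and central finite differences, and checks the GAP identity — the time mean
of the unnormalized CAM equals the class logit minus its bias — to 1e-5.

Metrics: accuracy is the fraction of correctly classified traces; precision
`TP/(TP+FP)` and recall `TP/(TP+FN)` are computed one-vs-rest per class and
macro-averaged over classes with nonzero support (a class never predicted
contributes precision 0). Macro averaging is chosen because the simulation
dataset is imbalanced and micro averaging would hide minority classes. The
label space always keeps all four outcome classes, so a class with zero
prevalence (complete response, typically) still has a logit; metrics simply
skip zero-support classes.

## Class activation maps

For class c, `CAM_c(t) = Σ_m w_m^c · A_m(t)` where `A_m` are the last
block's feature maps and `w^c` the output-layer weights — exact, not
interpolated, because feature maps retain the input length. Per class, the
CAMs of all traces of that (true) class are averaged pointwise, smoothed
with a centered moving mean of window 3 (shrunken windows at the edges, so
`[0, 3, 0]` becomes `[1.5, 1, 1.5]`), and min–max normalized to [0, 1].
Normalization after averaging is what makes a fixed relevance threshold of
0.5 meaningful across classes; a constant CAM is degenerate and maps to
zeros with a warning flag. `relevant_regions()` reports the maximal runs of
samples at or above the threshold as half-open 0-based intervals, and
`region_relevance()` averages relevance over named windows such as R1/R2/R3.
Averaging before smoothing, normalizing per class average (not per trace),
and using true-class rather than predicted-class CAMs are all deliberate,
test-frozen choices; predicted-class grouping is available behind the
`use_predicted` flag.

## The culture simulator

The simulator is a deliberately compact behavioral surrogate of a hybrid
discrete/continuous cellular automaton of 3D cultures: it reproduces the
qualitative biology needed by the downstream analysis, not any published
parameterization. Cells occupy at most one voxel of a 20³ lattice and are
advanced in 0.5 h steps for 72 h, sampled hourly (73 samples); five series
are emitted — living cells, dead cells, mean glucose, mean oxygen and mean
matrix Young's modulus.

Per step, in order: scheduled doses are added uniformly to the drug fields;
all fields take one explicit 6-neighbour diffusion step (reflecting
boundaries; oxygen and glucose additionally have their boundary faces
clamped to the replenishment concentration — the explicit scheme requires
`D·dt ≤ 1/6` and the package refuses to run otherwise); living cells consume
oxygen and glucose from their voxel and take up doxorubicin (removing it
from the field); each living cell dies with `death_probability()` (with a
starvation term below the survival thresholds), surviving cells divide into
a random free neighbour voxel with probability scaled by local
oxygen·glucose saturation; hypoxic sensitive cells switch to the resistant
phenotype with a small per-step probability; and living cells deposit
stiffness, at a rate attenuated by BAPN (LOX inhibition slows matrix
crosslinking).

The pharmacology couples three mechanisms, all driven by cumulative BAPN
exposure `E` (mM·h) through Hill curves:

1. **Kill sigmoid.** Death probability is
   `base + (1−base)·dox^h/(dox^h + EC50^h)` with Hill exponent 1.5 on the
   local extracellular concentration.
2. **Penetration.** LOX inhibition softens the matrix and improves drug
   penetration for *every* cell: the sensitive EC50 declines with `E` to a
   floor (45 % of its drug-naive value at saturation), on a slow scale
   (half effect at 95 mM·h) because bulk ECM turnover is slow.
3. **Resensitization.** Resistant cells additionally have their EC50 pulled
   from `dox_ec50_resistant` toward the (current) sensitive value, with a
   sharp switch (Hill 8, half effect at 68 mM·h) reflecting a thresholded
   pathway; the resistant EC50 never falls below the sensitive one.

Because cells sequester doxorubicin, the drug field is transient (effective
lifetime on the order of a day at default occupancy) while BAPN's action
matures over a similar timescale. This combination is what gives
administration *timing* its leverage: doxorubicin given at t = 0 acts
before BAPN has softened the matrix or resensitized resistant cells and is
largely gone afterwards, whereas doxorubicin delayed to 17 h meets a
maximally drug-accessible culture. No pharmacokinetic clearance is modeled.

Each run also draws a lognormal multiplier (log-sd 0.15) on the division
rate, emulating replicate-to-replicate variability in proliferative
capacity; without it, replicates of a condition are nearly interchangeable
and outcome prevalences jump discontinuously as means cross class
boundaries, which no real biological replicate set does.

Default rates were calibrated once, as a set, to the qualitative regimes the
surrogate must reproduce — untreated cultures grow (PNG); 0.3 µg/ml
doxorubicin shrinks fully sensitive cultures by ≥ 30 %; BAPN alone is
non-cytotoxic; resistant cultures escape doxorubicin alone; and delaying
doxorubicin to 17 h (protocol T2) increases PR and decreases PNG prevalence
relative to simultaneous administration (T1) in every resistance stratum —
and then verified on master seeds not used during calibration. The defaults
are not estimates of any measured biology; every one is exposed in
`sim_params()`.

What the surrogate does **not** emulate: cell migration, scaffold geometry,
mechanically coupled ECM (stiffness is tracked but does not feed back on
diffusion or division), drug clearance, and any quantitative match to
published prevalence tables. Passing tests therefore establish the
direction and structure of schedule effects under this model, not their
magnitudes in any real culture.

## Outcomes, protocols and prevalence reports

Outcome classes partition all (initial > 0, final ≥ 0) population pairs:
complete response (CR, final = 0, checked first), partial response (PR,
change ≤ −30 %, boundary inclusive per "at least"), progressive neoplastic
growth (PNG, change > +20 %, boundary exclusive per "over"), and stable
neoplastic growth (SNG) in between. The initial count is the population at
t = 0, not at first administration.

The five named protocols per-administration doses (a repeated
administration adds the same dose again):

| protocol | BAPN | doxorubicin |
|---|---|---|
| T1 | 0 h | 0 h |
| T2 | 0 h | 17 h |
| T3 | 0 h, 17 h | 17 h |
| T4 | 0 h | 0 h, 17 h |
| T5 | 0 h, 17 h | 0 h, 17 h |

`prevalence_table()` reports class percentages per protocol within each
resistance stratum (rows sum to 100). `percent_change_vs_reference()`
normalizes by the reference protocol's *class count* — the convention under
which a PR count rising from 40 to 66 reads +65 % — not by the total number
of simulations; a zero reference count with a positive protocol count is
reported as undefined with a flag, never silently divided. Published
schedule comparisons restrict to runs where both drugs are present; this is
the `both_drugs_only` flag (default `TRUE`) rather than a hard-coded
subset.

## Problem sizes and numerical choices

The shipped tests run the full 500-trace benchmark but a reduced network
profile (2 blocks, 4 filters per branch, 200 epochs, 5 fits) — chosen as the
smallest configuration that cleanly recognizes the benchmark — and compare
T1 against T2 with 12 replicates per condition over the 6 both-drug dose
combinations in each stratum. The full study design (1800 runs, 1500
epochs, the default 6×32 architecture) is available through the same
functions and validated structurally (design enumeration, channel counts,
seed derivation). Seeds: every stochastic routine takes an explicit seed;
per-run seeds derive deterministically from (master seed, condition index,
replicate index), so factorial datasets are reproducible run-by-run and
protocol contrasts are seed-paired. Degenerate inputs have defined
behavior throughout: constant channels normalize to zeros, constant CAMs
normalize to zeros with a flag, empty cultures yield an `NA` outcome label,
and the diffusion step refuses coefficients beyond its stability bound.

## Known limitations

* The simulator is a surrogate: directions and class structure are
  meaningful, absolute prevalences are not.
* Model selection on the test set follows the study protocol but leaks the
  test set into one selection decision; use a validation split for honest
  generalization estimates.
* CAM relevance is architecture-tied (GAP + linear head); it explains this
  classifier, not the data generating process.
* Training is single-threaded CPU code sized for hundreds of traces of
  hundreds of samples; it is not a general-purpose deep-learning stack.
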