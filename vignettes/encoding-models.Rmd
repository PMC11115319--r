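---
title: "Point-readout encoding models of spike counts: methods and design"
author: "spikefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-readout encoding models of spike counts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spikefit)
```

This vignette is the package's account of its science: the model and its
assumptions, the estimators, the synthetic ground truth used to validate
everything, the parameters that matter, and the numerical choices made where
the design was genuinely open.

## The model

An encoding model for a population of visually driven neurons has two parts.

**A frozen core** maps a grayscale image to a stack of feature maps
Φ raw ∈ R^(h×w×c). The core's parameters are never updated during fitting:
the scientific question is what a *fixed* feature space can explain, so all
learning is confined to the readout side. The package ships two desk-scale
cores — a Gabor filter bank (`gabor_core()`; zero-mean, unit-norm filters
over an orientation × frequency × phase grid) and a seeded random
convolutional network (`random_convnet_core()`; the classic untrained
control) — plus `custom_core()` for any external feature extractor. Cores
can be concatenated channel-wise (`concat_core()`) for joint readouts; all
members then receive the identical input and must produce feature maps of
equal spatial size.

**A shared feature head** applies per-channel batch normalization with
trainable scale γ and shift β, then rectifies:
`max(γ·(x − μ)/σ + β, 0)`. During training μ, σ are batch statistics and
running statistics are blended with momentum 0.1; at evaluation the stored
running statistics make the head a fixed affine map. Normalizing every
channel to zero mean and unit variance before rectification is what makes a
*single* L1 penalty on the readout weights meaningful — unequal channel
variances would implicitly penalize channels unequally.

**A Gaussian point readout per neuron** restricts all spatial pooling to a
single continuous location, so every spatial nonlinearity is attributable to
the core rather than the readout. Neuron *n* has a position mean μ_n in
relative coordinates ([−1, 1]², map center at (0, 0)), an isotropic position
variance σ²_n, channel weights w_n, and a bias b_n — c + 4 parameters per
neuron. During training a location is sampled per image,
p = μ_n + σ_n·ε with ε ~ N(0, I) (the reparameterization makes both μ_n and
σ²_n differentiable); at evaluation the readout deterministically uses μ_n.
Features are interpolated bilinearly over the 2×2 pixel neighborhood of the
location, combined linearly, and passed through ELU + 1 so predicted rates
are strictly positive.

The training objective is the summed Poisson loss plus an L1 penalty on the
readout feature weights (the bias is not penalized):

L = Σ_n (r̂_n − r_n log r̂_n) + λ Σ_{n,k} |w_{nk}|.

## Training procedure

Recording sessions see different training images, so one gradient step
cycles through all sessions: one batch per session drawn without
replacement, gradients accumulated, a single Adam update at the end of the
cycle. An epoch ends when the longest session's pool is exhausted; a shorter
session that runs out restarts from its full pool. After each epoch the
model is switched to evaluation mode (frozen batch-norm statistics) and the
mean single-trial Poisson loss on the entire validation set is computed; the
L1 term is excluded from this criterion since model selection should
reflect predictive fit. If validation fails to improve for `patience`
consecutive epochs, the weights are restored to the best so far and the
learning rate is scaled by `decay`; after `max_events` such decays fitting
stops, and the returned model carries the best-validation weights.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lr` | 3e-4 | initial Adam learning rate |
| `decay` | 0.3 | learning-rate factor per early-stopping event |
| `patience` | 5 epochs | stale epochs before a decay |
| `max_events` | 4 | decay events before stopping |
| `batch_size` | 64 | images per session per cycle |
| `beta1` | 0.1 | Adam first-moment coefficient ("momentum") |
| `lambda` | per fit | L1 penalty on readout weights |

The defaults mirror the standard protocol for these models at full scale.
The desk-scale experiments in this package (synthetic recovery, pair-model
comparisons) use `lr = 1e-2`, `batch_size = 32`, `patience` 6–8 and 2–3
decay events: with a few hundred parameter updates rather than tens of
thousands, a larger step size and a tighter stopping rule reach the same
optima in minutes on one CPU. Problem sizes used by the shipped experiments:
images ≤ 40×40 px, ≤ 2 sessions × 1000 images, ≤ 40 neurons, 16–24
channels.

### Initialization

Three initialization choices matter, and two of them are this package's own
design decisions where the standard recipe is tied to large-scale training:

1. **Readout bias** starts at each neuron's mean training response, mapped
   through the inverse of ELU + 1. With a zero start, the early gradient is
   dominated by mean-rate mismatch; at a small update budget this reliably
   drives the head into a degenerate optimum (β grows, γ shrinks, the
   rectification effectively linearizes) from which stimulus tuning is not
   recovered.
2. **Position mean** defaults to `position_init = "rf"`: each neuron starts
   at the feature-map pixel whose channel activations best correlate with
   its training responses (the sum over channels of squared Pearson
   correlations — the model-space analogue of the receptive-field mapping
   that experimenters perform before centering their stimuli). The
   alternative `"center"` start (map center plus jitter) relies on broad
   position sampling to *find* the receptive field, which demonstrably
   fails at desk scale: on synthetic ground truth the center start leaves a
   median position error of ~0.8 relative units where the RF start reaches
   ~0.013.
3. **Position variance** starts at σ = 0.1 under the RF start (refinement
   around a good guess) and σ = 0.5 — a sampling cloud covering about 25%
   of the map width, large enough for gradients to reach the whole map —
   under the center start.

## Reliability and performance estimators

All estimators operate on repeated-trial test responses and use unbiased
variance estimators.

- **Noise variance** (`noise_variance`): the variance across repeats of the
  same image, averaged over images — response variability no model can
  explain.
- **Explainable variance** (`explainable_variance`): total single-trial
  variance minus noise variance; the EV ratio divides by the total.
  Neurons with EV below 0.15 are conventionally removed
  (`filter_reliable`; a neuron exactly at threshold is retained, matching
  the "below 0.15 removed" rule).
- **FEVE** (`feve`): 1 − Var_res/Var_exp, where the residual variance is
  the mean squared single-trial residual corrected by the noise variance.
  The residual is computed on single trials grouped by image (squared
  residuals averaged over repeats within an image, then over images); the
  repeat handling is left implicit in the usual image-indexed formula, and
  this grouping reduces to it when repeats are collapsed. FEVE ≤ 1 with
  equality iff the noise-corrected residual vanishes; neurons with
  non-positive explainable variance get `NA` and a warning, never a silent
  drop.
- **Test correlation** (`mean_test_correlation`): per-neuron Pearson
  correlation between predictions and repeat-averaged responses; the
  population aggregate is the mean over neurons.
- **Selectivity index** (`selectivity_index`): for 100 evenly spaced
  thresholds between a neuron's minimum and maximum response, the fraction
  of images above threshold is computed; A is the area under this curve
  (rectangle rule — the quadrature is unstated in the standard procedure,
  and the mean over thresholds is the natural choice), and SI = 1 − 2A.
  SI ≈ 0 for uniform response distributions, → 1 for sparse neurons, and is
  invariant to positive affine rescaling.

## Multi-core readouts and training strategies

A pair (triplet) model reads from the channel-concatenation of two (three)
frozen cores through a single point readout per neuron — one position, one
variance, one bias spanning the concatenated feature space, because the
concatenation *is* one feature space. Five strategies control
initialization and trainability (`pair_strategies()`): from scratch;
initialize block 1 (2) from its fitted single-core model — including that
block's head parameters and running statistics, and the neuron positions —
zero the other block, and tune only the other block; or initialize one
block and tune everything. Block weights initialized with zeros make the
warm-started pair's predictions *exactly* equal to the single model's
before training, which yields a useful guarantee: since the epoch-0
validation loss participates in best-weight tracking, a warm-started pair
can never end worse than the single model it started from. Positions are
trainable whenever any block's weights are (the unstated alternative —
freezing them during pair fine-tuning — is less general). λ for pair models
is re-validated on the same grid used for singles.

## Synthetic ground truth

The generator (`sim_images`, `make_population`, `simulate_responses`,
`assemble_area_dataset`) emulates the structure the analysis assumes:

- **Images**: 1/f-filtered Gaussian noise plus a few randomly oriented
  Gabor patches, affinely mapped to 8-bit [0, 255] — broadband spatial
  statistics with oriented energy, enough to drive both Gabor-bank and
  convolutional cores. It does not emulate natural-scene semantics, object
  content, or color; conclusions about category-selective computations are
  outside what these tests can support.
- **Neurons**: positions uniform in [−1, 1]², sparse zero-mean Gaussian
  channel weights (expected nonzero fraction = `weight_sparsity`, scale
  1/√(c·sparsity)), bias, and a gain applied outside ELU + 1. Responses
  are Poisson counts around the deterministic rate.
- **Sessions**: each session draws its own disjoint train/validation images
  (default 20% validation), while one shared test set (default 75 images ×
  45 repeats — the midpoint of the 40–50 range typical of such recordings)
  is simulated in every session. Session neuron sets are disjoint subsets
  of one population.
- **Gain default 6**: chosen so the simulated EV distribution (mean ≈ 0.33)
  matches the reliability statistics of real recorded populations (average
  EV ≈ 0.31) while median counts (~5) stay in the 0–10 per-presentation
  regime of cortical spike counts.

Passing parameter-recovery tests on this generator shows the estimators,
gradients and optimizer are correct and consistent; it does not show that
any particular core explains real neurons — real data add non-Poisson
variability, adaptation, eye-movement jitter and correlated noise that the
generator deliberately omits.

## Numerical choices

- Logarithm guard: the Poisson loss uses log(r̂ + 1e-8); ELU + 1 outputs can
  underflow toward zero.
- σ²_n is carried through a softplus parameterization to remain
  nonnegative; positions sampled outside [−1, 1]² are clamped (with zero
  gradient on the clamped axis), and μ_n itself is clamped into the valid
  domain after each update.
- Bilinear interpolation uses the align-corners convention (pixel j of W at
  −1 + 2(j−1)/(W−1)), so a location at a grid point reads that pixel
  exactly.
- Batch normalization normalizes with biased batch variance and blends
  running variance with the unbiased estimate (momentum 0.1, ε = 1e-5
  inside the square root). The batch-norm momentum is unstated in the
  standard protocol; 0.1 is the common default and is configurable.
- The L1 gradient uses the subgradient sign(w); with Adam this behaves as
  expected and exact zeros are not required (sparsity is soft).
- Image resampling is separable Keys cubic convolution (a = −0.5) with
  kernel-width anti-aliasing when downsampling; bilinear is available. At
  equal source and target size the resampler is exactly the identity.
- Convolution uses replicate (edge) padding so zero-mean filters respond
  with exact zeros to constant inputs everywhere, including map borders;
  small kernels go through vectorized shift-and-add, large ones through
  per-image FFT.
- Wilcoxon signed-rank tests, Holm correction, Bartlett and Levene tests
  are delegated to `stats` and `car`; the specialization index applies
  Fisher's z-transform to correlation scores on request before
  normalization. Both the baseline-increment normalization and the plain
  mean normalization are available because the two published descriptions
  of the index differ; the increment convention is the default. Bartlett
  and Levene are reported side by side, neither privileged.
- Ties in hyperparameter grid selection break toward the smallest λ, then
  the earliest layer — preferring the simpler model.

## Known limitations

- Optimization is plain R; fits beyond ~10⁴ images × 10² neurons are
  outside the intended scale.
- The external-core adapter passes features through as-is; pretrained
  network weights are not bundled, and no deep architecture is
  implemented.
- Datasets and fitted models serialize with `saveRDS`/`readRDS`
  (`save_object`/`load_object`); the in-memory layout mirrors the grouped
  structure described in the function documentation.
- The generator's Poisson observation model makes EV and FEVE behave
  ideally; real overdispersion biases both downward.
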