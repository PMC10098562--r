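---
title: "Methods: joint spectrum-label augmentation for small-sample Vis-NIR calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint spectrum-label augmentation for small-sample Vis-NIR calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the parameters that matter, the
numerical conventions, and the design choices behind `soilspecaug`. It is
the package's reference for *why* things are the way they are; the README
shows *how* to run them.

## The joint representation

A preprocessed dataset is a samples × 746 matrix: 745 reflectance
channels (356–1100 nm at 1 nm) followed by one scaled nutrient label.
Preprocessing is strictly invertible so that anything generated in the
joint space can be mapped back to physical units:

1. **Savitzky–Golay smoothing** (`sg_smooth()`): local least-squares
   polynomial fit of order 2 in a sliding window. The window length is a
   free parameter; the default of 11 channels (11 nm) is a common
   chemometrics choice that suppresses detector noise without flattening
   the broad absorption features of soil spectra. The filter reproduces
   polynomials up to its order exactly, which the tests exploit.
2. **Edge trimming** (`trim_edges()`): the closed interval [356, 1100] nm
   is retained. The 320–355 nm edge of silicon-array instruments has a
   poor signal-to-noise ratio; trimming it turns a full 320–1100 nm grid
   into exactly 745 channels, which fixes the joint width at 746.
3. **Min–max normalization** (`minmax_normalize()`): by default *global*
   over the whole matrix, so differences in overall brightness between
   samples survive; per-spectrum scaling is available but cannot be
   inverted for generated rows (each generated row has no "its own"
   min/max), so the pipeline keeps global scope. A constant input has no
   defined range and is rejected rather than silently mapped.
4. **Label scaling** (`scale_labels()`): division by a fixed power of
   ten per nutrient — 100 for TK₂O and SOM, 10 for TN and TP₂O₅ — puts
   g/kg concentrations into (0, 1). Values at or above the divisor are
   rejected, not clipped: clipping would silently corrupt the inverse
   mapping of generated labels.

The 7:3 train/validation split takes the training size as
`ceiling(0.7 * n)` (42 → 30/12) via a uniform random permutation under a
mandatory seed; no stratification is attempted at these sample sizes.

## Least-squares GAN on joint vectors

Both networks are small fully connected nets: generator
100 → 256 → 512 → 746 and discriminator 746 → 512 → 256 → 1 by default,
sigmoid activations throughout. The sigmoid output layer is what
guarantees every generated entry lies in (0, 1), matching the joint
representation. The objectives are least-squares:
`mean((D(x)-1)^2) + mean(D(G(z))^2)` for D and `mean((D(G(z))-1)^2)`
for G — the natural reading of "mean squared error loss" with a sigmoid
discriminator. Optimization is Adam with learning rate 2·10⁻⁴ and
β₁ = 0.5 (the GAN-standard momentum reduction), one discriminator step
then one generator step per epoch on the full batch: with ~30 training
rows minibatching would add noise without saving work, and it keeps
"epoch" meaning one pass over the data.

Every 100 epochs the generator emits 300 joint vectors, so a 2000-epoch
run yields 20 checkpoints (the untrained epoch-0 state can be stored
behind a flag but is excluded from default listings). Training is fully
deterministic given the config seed under single-threaded BLAS.

Layer widths, the noise dimension, the update schedule and the Adam
moments are genuinely open choices (nothing in the problem pins them);
they are all recorded in `gan_config()` and changing them changes only
capacity/runtime, not any interface.

## EMSC and EMSA

EMSC decomposes a measured spectrum against the reference
m(ṽ) (the mean spectrum) as
`A = a + b·m + d₁ṽ + d₂ṽ² + … + e`, solved per spectrum by least
squares. Numerical conventions:

- the abscissa ṽ is the *normalized channel position* in [0, 1] — the
  instrument's wavelength units cancel in the polynomial terms, and the
  [0, 1] axis keeps the design matrix well conditioned;
- the default polynomial degree is 2 (baseline, linear, quadratic tilt),
  the conventional EMSC choice; degree is configurable;
- a rank-deficient design (reference collinear with the polynomial
  columns) is reported as such, and fits with |b| below 10⁻¹² refuse the
  correction division.

EMSA perturbs the fitted parameters with zero-mean Gaussian deviations
whose standard deviations are the across-training-set standard
deviations of each parameter, cycling source rows round-robin, and
re-synthesizes `A_new = a′ + b′·m + d₁′ṽ + … + e·b′/b`. Because the
source residual e is orthogonal to the design columns, refitting EMSC on
a generated row recovers the perturbed parameters exactly (to floating
point); the tests assert this at 10⁻⁸. Generated rows are *not* clipped
to [0, 1] by default — clipping would break that recovery property — but
a `clip` flag exists for feeding the CNN.

**Label channel.** The joint-matrix reading of EMSA fits the model over
all 746 channels, label slot included; that is `emsa_generate()`'s
default, as the most literal interpretation of augmenting the joint
matrix "the same way". It has a physically odd consequence: the
generated label is re-synthesized from global distortion parameters
rather than inherited, which decouples it from the absorption features
of its spectrum. In our expansion experiments this decoupling made
joint-mode EMSA pools actively harmful to the CNN, so the package's own
study scripts use the alternative `spectra_only = TRUE` mode, which fits
the 745 spectral channels and copies the source label unchanged. Both
modes are implemented and tested; which one the original workflow used
cannot be determined from its description.

## Evaluating generated checkpoints

- **PC1 contribution** (`pc1_reduce()`): data are centred and projected
  on the leading covariance eigenvector (computed via SVD); the
  contribution rate is λ₁/Σλ. PCA is sign-ambiguous, so the loading sign
  is fixed by making its largest-magnitude element positive. Table-style
  per-dataset contributions are computed on each dataset separately;
  diversity comparisons ("violin lengths", i.e. score ranges) use one
  PCA fitted on the concatenation of real and generated rows so both
  score sets share a coordinate system — per-dataset scores would not be
  comparable.
- **Label statistics** (`label_summary()`): min, linear-interpolation
  quartiles (the convention is stated because quartile definitions
  differ), median, mean, sd, range; optionally after removing values
  outside [Q1 − 1.5·IQR, Q3 + 1.5·IQR]. The IQR rule is the package's
  formalization of "outlier removal" — it is consistent with a 300-row
  checkpoint losing a handful of rows.
- **Epoch selection** (`select_epoch()`): the original workflow judged
  checkpoint quality visually from boxplots; this package formalizes it
  as `distance = (|mean_g − mean_r| + |median_g − median_r| +
  |sd_g − sd_r|) / sd_r`, i.e. an L1 distance over the three moments the
  boxplot comparison emphasizes, scaled by the real sd so the distance
  is unit-free. Ties break to the smallest epoch (earlier checkpoints
  are cheaper to justify); the selection is invariant to archive
  listing order.

## The 1-D CNN regressor

Architecture: Gaussian input noise (σ = 0.01, training only) → conv
(32 filters, kernel 7, stride 1, ReLU) → conv (16, 5, 1, ReLU) →
flatten → dropout 0.045 (training only) → dense 64 (ReLU) → single
linear neuron. The "pooling layer with a rate" in the source description
can only be dropout — pooling layers have no rate — and is implemented
as such. The loss is Huber with δ = 1 and the optimizer Adadelta with
its canonical ρ = 0.95, ε = 10⁻⁶, step scale 1; training is full-batch
for 800 epochs by default. Convolutions are implemented as k shifted
dense matrix products on a flattened (samples × positions·channels)
layout, so everything runs through BLAS; the conv hyperparameters are
open choices sized for ~745-channel inputs and ≤300 samples.

**Fit-time standardization.** Between-sample reflectance differences are
tiny compared with the mean spectrum level, and the scaled label
occupies a narrow sub-interval of (0, 1). With raw inputs, full-batch
Adadelta spends almost all its budget learning the mean level. By
default `train_regressor()` therefore z-scores each input channel and
the target at fit time, stores the scalers in the model and inverts them
at prediction. This changes the optimization, not the model family or
any interface; it can be switched off (`standardize = FALSE`), and the
divisor-scaled-label path (train on y/c, report in g/kg) composes with
it.

**Metrics.** RMSE is `sqrt(mean((Y − y)²))`. Two R² variants exist
because the printed formula in the source material,
`Σ(Y − ȳ)²/Σ(y − ȳ)²`, is the regression-sum-of-squares ratio, which
only coincides with the coefficient of determination for unbiased
least-squares predictions. The package defaults to the standard
`1 − SSE/SST` and exposes the literal form as `variant = "paper_eq8"`;
both are oracle-tested. A constant truth vector leaves R² undefined and
errors.

## The expansion experiment

`build_expansion_plan()` samples n generated rows per entry uniformly
*without replacement* from the pool under a seed
(n ∈ {0, 15, 30, 60, 120, 240} by default, giving training sizes
30…270); `run_expansion()` trains a fresh CNN per entry and augmenter on
the real rows plus the sampled rows and evaluates the fixed validation
set, whose content is digest-checked to be identical across entries. A
single stochastic training run is not a stable basis for conclusions, so
the module supports `repeats` with derived seeds and reports mean ± sd —
the single-run default mirrors the original protocol. The best entry
maximizes mean validation R², with ties broken by lower RMSE, then
smaller n. `refine_interval(center, step)` produces
{center − step, center, center + step, center + 2·step,
center + 3·step} clipped at 0, reproducing the refined ladders
(25…45 around 30 with step 5; 50…90 around 60 with step 10).

## The synthetic-data generator

The generator exists so that every module is testable without the
undeposited field data; its defaults *are* the study conditions. Each
clean spectrum is a slowly rising sigmoid-plus-slope base curve
(≈0.10 reflectance at 320 nm to ≈0.45 at 1100 nm, the generic soil
shape) minus Gaussian absorption features at 450, 600, 850 and 1000 nm
whose depths are proportional to the sample's label — depths are sized
(≈0.06 reflectance units at the nutrient's maximum content) so features
stay visible but never dominate. Per-sample distortions follow the EMSC
forward model exactly — baseline a ~ N(0, 0.02), multiplicative
b ~ N(1, 0.05), linear/quadratic tilt N(0, 0.02)/N(0, 0.01) on the
normalized axis — plus white noise (σ = 0.002). Labels are truncated
normals matching the real-data summary table for each nutrient
(e.g. TK₂O on [13.790, 21.610] g/kg with mean 18.995 and sd 2.167).

What the generator does *not* emulate: real absorption-band positions
and shapes for these nutrients (TK₂O and TP₂O₅ notoriously lack clean
Vis–NIR features), wavelength-dependent scattering beyond a quadratic,
instrument-specific noise structure, or any spatial/covariate structure
between samples. Passing tests therefore demonstrate that the
*machinery* behaves as specified under a controlled, linear
spectrum-label link — not that any particular accuracy is attainable on
real soils.

## Problem sizes in tests and the study script

The package's own study runs are sized for a desk: unit tests use
reduced wavelength grids (40–160 channels) and small nets; the
acceptance-style checks train the GAN at the full 746-channel width for
the full 2000 epochs but with reduced hidden widths (64/128 against the
256/512 defaults) over three seeds, train the CNN on 200 simulated
samples at a 151-channel grid for 200 epochs, and run the expansion
sweep with a shortened ladder. `scripts/acceptance.R` uses the full
746-wide pipeline with the GAN at the same reduced hidden widths, a
CNN budget of 150 epochs and n ∈ {0, 30, 120}, one run per
configuration. These sizes are the package's choices for a reproducible
desk-scale study; all of them are plain config arguments.

## Known limitations

- The GAN at desk scale under-disperses: generated label sd is well
  below the real sd early in training, and checkpoint quality is
  seed-dependent. The epoch-selection distance makes this visible rather
  than hiding it.
- Single-run expansion results are noisy; use `repeats` before reading
  anything into small differences between entries.
- Per-spectrum normalization scope cannot be inverted for generated
  rows; the pipeline intentionally defaults to global scope.
- Joint-mode EMSA (label channel perturbed) is faithful to the literal
  joint-matrix description but harmful as an augmentation pool; see the
  EMSA section.
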