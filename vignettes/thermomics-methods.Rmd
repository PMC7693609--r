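---
title: "Thermomics: models, parameters and design choices"
author: "thermomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thermomics)
```

# The screening problem

Malignant and pre-malignant breast tissue runs hotter and more
heterogeneously than healthy tissue: tumor metabolism, angiogenesis and
nitric-oxide-driven vasodilation raise local perfusion and heat delivery to
the skin. Dynamic infrared thermography records this as a short sequence of
surface temperature maps (here 23 frames by default). The package turns such
a sequence into a small set of quantitative descriptors — *thermomics*, by
analogy with radiomics — and a subject-level classification:

1. **Heat matrix.** The cropped sequence is vectorized into a pixels-by-frames
   matrix (p × n, p > n) and centred per pixel over time, so the
   decomposition that follows maximizes variance *across acquisition time*
   rather than spatial contrast.
2. **Low-rank avatar.** Principal component thermography (PCT, an economy
   SVD) or its sparse elastic-net variant extracts spatial basis images; the
   first three, min–max normalized and resized, become the three channels of
   a square "avatar" image that stands in for an RGB photograph.
3. **Deep thermomics.** A ResNet-50-architecture convolutional backbone maps
   the 224 × 224 × 3 avatar to the 2048-wide global-average-pool activation
   vector.
4. **Latent thermomics.** A sparse deep autoencoder
   (2048–1024–256–64–16, mirrored) compresses the features 128-fold to a
   16-dimensional code, trained with a binary cross-entropy reconstruction
   loss and an ℓ1 activity penalty on the first hidden code.
5. **Stratification.** A random forest with leave-one-out cross-validation
   classifies subjects from the latent codes and/or clinical covariates
   (age, family history), with a percentile-bootstrap accuracy interval and
   a pooled out-of-fold ROC curve.

Because clinical infrared archives cannot ship with a package, a
finite-difference Pennes bioheat phantom generates labeled synthetic cohorts
with known ground truth; every stage is tested against that simulator and
against closed-form or brute-force oracles.

# The Pennes phantom

The simulator integrates the Pennes bioheat equation

$$\rho_t c_t \frac{\partial T}{\partial t}
  = \nabla\!\cdot\!(k_t \nabla T) + \omega_b c_b (T_a - T) + q_m$$

on a 2-d grid by explicit forward Euler with a 5-point Laplacian and
insulated (zero-flux) boundaries. The grid is the observed skin plane: all
downstream stages consume 2-d frames, so the 3-d tissue volume is collapsed
into the plane the camera sees. Face conductivities are arithmetic means of
adjacent cells, which makes interior fluxes exactly antisymmetric: a
source-free insulated phantom conserves energy to round-off, one of the
package's standing tests.

Defaults (literature-typical soft tissue; units in the `TissueGrid` help
page): ρ = 1050 kg/m³, c = 3600 J/(kg·K), k = 0.48 W/(m·K),
c_b = 3617 J/(kg·K), T_a = 37 °C, ω_b = 0.5 kg/(m³·s), cell size 2.5 mm,
uniform 30 °C initial field (a post-acclimatization surrogate). Metabolic
heat is 2 × 10⁴ W/m³ in normal breast tissue; tumor cells draw
q_m ~ U[10⁵, 1.2 × 10⁶] W/m³ — the range reported for cancerous tissue —
with perfusion locally tripled as a vasodilation surrogate. The explicit
scheme's stability bound (`maxStableDt`) is enforced with an informative
error; the default step is half the bound, rounded so an integer number of
substeps fits each 15 s frame interval.

Deliberate simplifications, and what they imply for the tests: the 2-d
collapse places the heat source in the observed plane, so tumor contrast is
several kelvin rather than the sub-kelvin contrast of real 3-d anatomy;
radiative/evaporative skin physics and breathing/motion artifacts are
absent; camera noise is ideal Gaussian at the sensor's 0.04 °C sensitivity.
A green end-to-end test therefore shows the pipeline recovers a strong,
well-posed heterogeneity signal — it does not certify clinical accuracy on
real cohorts. Covariates are sampled to match the reference screening
demographics (age centred on 60, diabetes family history 25 %, hypertension
2.4 %, leukemia 0.5 %, hormone replacement 18.3 %) and are
label-independent by default, so the clinical-only classifier should sit at
chance on synthetic cohorts; `ageShift` can inject covariate signal for
additive-information experiments.

The acquisition protocol (static vs. dynamic cooling, frame interval) is
not standardized across archives, so the simulator exposes `nFrames` and
`frameInterval` as configuration rather than asserting a protocol; defaults
are 23 frames every 15 s.

# Decompositions

`pct()` is a thin, deterministic wrapper over the economy SVD: full singular
spectrum, first k left singular vectors reshaped to the ROI, and a sign
convention (largest-magnitude entry positive) that removes the SVD sign
ambiguity so repeated runs are bit-identical.

`sparsePct()` maximizes the explained variance vᵀXXᵀv under elastic-net-style
penalties by a soft-threshold power iteration: each power step Σv (computed
implicitly as X(Xᵀv), never forming the p × p covariance) is ridge-shrunk by
1/(1 + λ2), soft-thresholded at λ1 · max|Σv| and renormalized; an optional
hard cardinality cap keeps the top entries by magnitude (truncated power
method). Components are extracted sequentially with projection deflation.
Choices worth stating:

* The ℓ1 threshold is *relative* to the largest entry of the current power
  step, making λ1 scale-free (λ1 ∈ [0, 1)) and the zero-count monotone in
  λ1; both properties are tested.
* With λ1 = λ2 = 0 the iteration starts at the exact leading singular
  direction (computed from the small n × n Gram matrix) and is a fixed
  point, so the penalty-free limit reproduces `pct()` to machine precision.
* A cardinality constraint stated as a lower bound is infeasible as a
  sparsity device; it is implemented as a cap (`card`), and the capped
  solution is verified against exhaustive support enumeration on small
  problems.
* Convergence is measured by the sign-invariant change of direction between
  iterates; defaults `maxIter = 1000`, `tol = 1e-6`. Trailing components at
  the noise floor can oscillate between near-tied supports under
  thresholding; that is reported as a warning with the final tolerance and
  the result is still returned.
* Row-centring makes every heat matrix rank-deficient (the all-ones time
  vector is annihilated), so a centred p × n matrix has at most n − 1
  informative components; oracle tests compare the informative spectrum.

The 80 %-of-variance component count (`varianceFraction`) is a diagnostic
only: the avatar always uses exactly three bases because the backbone input
has exactly three channels.

`makeAvatar()` min–max normalizes each basis to [0, 1] (constant bases map
to zero), centre-crops to a square and resizes bilinearly to 224 × 224.
Normalization lives here, not in the backbone: backbone-specific input
standardization (pretraining channel statistics) is applied inside feature
extraction and only in pretrained mode.

# The backbone and parameter accounting

`canonicalResNet50Spec()` is a declarative layer table — stem, bottleneck
stages of 3/4/6/3 blocks with widths growing 64 → 2048, global average
pool, 1000-class head — from which `countParameters()` sums parameters in
closed form, with no framework instantiation. The counting convention is
fixed and documented because frameworks disagree: convolutions carry
biases, batch-norm scale/offset are trainable, batch-norm moving statistics
are non-trainable (2 per channel each way). Under exactly this convention
the table reproduces the published totals, 25,583,592 trainable and 53,120
non-trainable parameters; conventions that omit convolution biases will
not. The head is kept for accounting and dropped for extraction, whose tap
is the 2048-wide pooled activation.

The same mirrored dense schedule used by the autoencoder
(2048-1024-256-64-16-64-256-1024-2048, all biased) sums to 4,758,160
trainable parameters by the same closed form (`denseStackSpec`).

`realizeBackbone()` instantiates the network. The default,
`weights = "seeded_random"`, draws He-scaled weights (s.d. √(2/fan-in))
under a fixed seed, zero biases, identity batch-norm — a deterministic
random-projection feature extractor that needs no download and preserves
class structure well enough for the synthetic screening task (this is
verified end to end). Pretrained ImageNet weights are a documented opt-in
requiring a local weights file; nothing in the package depends on them.
The forward pass is plain R: im2col plus BLAS matrix multiplication per
convolution, max-pooling by shifted-slice maxima, inference-mode batch
normalization. One avatar takes a few seconds on one CPU core.

# The sparse autoencoder

Training minimizes mean binary cross-entropy between the min–max-scaled
2048-d features and their sigmoid reconstructions, plus λ · mean‖h₁‖₁ on
the first hidden code (default λ = 10⁻⁵). Architecture: four rectified
dense layers down (1024, 256, 64, 16), mirrored decoder, sigmoid output;
eight dense layers in all. The decoder is untied by default — the mirrored
schedule's parameter count implies independent decoder weights — with a
tied variant behind `tiedWeights`. Optimization is Adam (β₁ = 0.9,
β₂ = 0.999), batch size 128, 500 epochs by default, seeded initialization
and shuffling so loss curves reproduce exactly run-to-run. Divergence
(non-finite loss) aborts with advice to lower the learning rate rather than
returning garbage.

Numerical conventions: predictions are clipped to [10⁻⁷, 1 − 10⁻⁷] inside
the loss, so "perfect" reconstruction reaches the clipping floor rather
than exactly zero; constant feature columns scale to zero and are flagged
as non-invertible in the scaler. The standing tests drive a repeated input
vector to within 5 % of its analytic entropy floor, check the 10-epoch
moving average of the loss is non-increasing, and verify the ℓ1 penalty
monotonically shrinks the first-layer code over a λ grid.

# Classification and uncertainty

`loocvRandomForest()` trains one forest per held-out subject (default 1000
trees, √d features per split — the forest hyperparameters are unexceptional
defaults, as none are dictated by the screening protocol) and reports the
fraction of correct out-of-fold predictions. The accuracy interval is a
percentile bootstrap (2000 resamples) over the per-subject correctness
vector: reproducible, assumption-light, and honest about small-n width. An
alternative would be repeated-seed forest variability; the bootstrap was
chosen because it also reflects sampling noise, not just algorithmic
noise. The ROC curve and area are computed from the pooled out-of-fold
class-1 probabilities. Subjects are processed in canonical id order, making
reports invariant to row order under a fixed seed. Family history is
encoded any-vs-none by default (per-condition one-hot available): the
screening covariate of interest is "any family history", and one-hot
encoding of rare categories (leukemia at 0.5 %) adds near-constant columns.

Two cautions that the tests make explicit: with a leave-one-out split on a
balanced cohort the held-out subject's class is always the minority of the
training set, so an *uninformative* feature set is biased below 50 %, not
toward it; and at very small n (≲ 10) this inversion can reach 0 %. Chance
bounds in the tests ([25 %, 75 %] at n = 40–60) account for this.

# Run orchestration

`runPipeline()` chains the stages under one seed, logs each stage, writes
every intermediate as CSV/JSON (each re-ingestible by its producing
module's reader) plus a manifest with package/R versions, config and seed.
Runs are recomputed in full rather than cached: under fixed seeds the run
is deterministic, and at these problem sizes (minutes end to end) a
content-hash cache would add complexity without changing any result. The
default configuration — 30 healthy plus 30 symptomatic subjects, 64 × 64
frames, 23 frames at 15 s, sparse PCT, 500 epochs — is also the cohort
used by the package's end-to-end tests and by `scripts/acceptance.R`;
`method = "both"` adds the PCT branch and a ranked comparison table. The
64 × 64 default grid keeps a full run at desk scale; `shape = c(480, 640)`
reproduces the camera resolution when fidelity matters more than turnaround.

# Known limitations

* The synthetic cohort is a strong-effect construction: the 2-d phantom
  exaggerates tumor contrast, so near-perfect synthetic accuracy is
  expected and says nothing about accuracy on clinical data.
* Seeded-random backbone features are a random projection; they are not
  ImageNet features, and absolute feature values have no transferable
  meaning across seeds.
* The sparse-PCT solver is a local ascent method; for adversarial spectra
  with near-tied leading directions the recovered support can depend on
  initialization (deterministic here, but not globally optimal).
* No automatic breast segmentation: ROIs come from configuration (a
  centred square by default), matching the manual-cropping practice of the
  field.
* PNG output is 8-bit (the underlying writer's limit); use the TIFF or
  binary dialects for quantitative storage.
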