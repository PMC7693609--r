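# thermomics

Deep-learning thermomics for dynamic infrared breast-thermography
screening, with a Pennes bioheat phantom simulator so the whole pipeline is
developable and testable without clinical data.

## The problem and the method

Tumor metabolism and nitric-oxide-driven vasodilation make malignant breast
tissue warmer and more thermally heterogeneous than healthy tissue, and a
dynamic infrared acquisition (a short stack of surface temperature frames)
records that heterogeneity over time. This package implements a pipeline
that turns such sequences into subject-level screening calls:

1. **Heat matrix** — each cropped sequence becomes a pixels × frames matrix
   *X* (p × n, p > n), centred per pixel over time.
2. **Low-rank avatar** — principal component thermography
   (*X = UΓVᵀ*, economy SVD) or sparse PCT (elastic-net-penalized variance
   maximization `max vᵀXXᵀv, ‖v‖₂ = 1`, solved by soft-threshold power
   iteration with projection deflation) yields spatial bases β₁, β₂, β₃;
   normalized and resized they form the channels of a 224 × 224 × 3
   *avatar* image.
3. **Deep thermomics** — a ResNet-50-architecture backbone (25,583,592
   trainable / 53,120 non-trainable parameters under the biased-convolution
   counting convention) maps the avatar to its 2048-wide
   global-average-pool activations. Seeded random He-initialized weights
   make this a deterministic, download-free feature extractor; pretrained
   weights are an opt-in.
4. **Latent thermomics** — a sparse deep autoencoder
   (2048–1024–256–64–16, mirrored; binary cross-entropy + ℓ1 activity
   penalty on the first code, Adam, batch 128) compresses features 128× to
   16 latent descriptors.
5. **Screening** — a random forest with leave-one-out cross-validation
   classifies healthy vs. symptomatic subjects from latent codes and/or
   clinical covariates, with percentile-bootstrap accuracy intervals and a
   pooled out-of-fold ROC curve.

The phantom simulator integrates the Pennes bioheat equation
`ρc ∂T/∂t = ∇·(k∇T) + ω_b c_b (T_a − T) + q_m` by explicit finite
differences; symptomatic subjects get a randomly placed tumor disc with
metabolic heat in 10⁵–1.2 × 10⁶ W/m³ (vs. 2 × 10⁴ for normal breast) and
locally elevated perfusion, plus 0.04 °C camera noise.

## Worked example

```r
library(thermomics)

cfg <- defaultRunConfig(seed = 1)   # 30 healthy + 30 symptomatic subjects
res <- runPipeline(cfg, outDir = "run1")
res$comparison
```

```
      method           featureSet  accuracy        lo  hi  auc
1 sparse_pct latent_plus_clinical 100.00000 100.00000 100 1.00
2 sparse_pct          latent_only 100.00000 100.00000 100 1.00
3 sparse_pct        clinical_only  53.33333  41.66667  65 0.53
```

Reading this: on the default synthetic cohort the 16 latent thermomics
separate the classes completely (accuracy 100 %, AUC 1.0 — the phantom's
2-d geometry makes tumor contrast strong by construction), while the
clinical covariates alone sit at chance (53 %), as they should: the
simulator draws them independently of the label. The bracketed `lo`–`hi`
columns are 95 % percentile-bootstrap intervals over the per-subject
out-of-fold correctness.

Single stages are plain functions on S4 objects:

```r
co  <- generateCohort(2, 2, seed = 7)          # ThermalSequence list + covariates
hm  <- buildHeatMatrix(co$sequences[[1]])      # 2304 x 23 heat matrix
bs  <- sparsePct(hm, k = 3, lambda1 = 0.05)    # three sparse spatial bases
av  <- makeAvatar(bs)                          # 224 x 224 x 3 avatar
f   <- extractFeatures(av, realizeBackbone(seed = 7))  # length-2048 vector
```

A thin command-line front end over the same functions lives in
`inst/scripts/thermomics.R` (`simulate` and `run` subcommands, YAML
configuration).

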