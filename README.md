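# sevgrade

Five-level severity grading of local psoriasis images from PASI erythema
and scaling sub-scores, built around a **multi-scale deformable attention
module (MS-DAM)** fused over hierarchical CNN features, a **severity-max
CutMix** augmentation, and a focal-loss training recipe — for researchers
in medical image analysis who want a fully reproducible, dependency-light
R implementation of the method together with the audits and experiments
that validate it.

## The method

A dermatologist grades a local lesion image with two 0–4 sub-scores
(erythema, scaling); their sum bands into five groups: healthy (0),
mild (1–2), moderate (3–4), severe (5–6), very severe (7–8). Two
ingredients address the *multiple-severity* problem — one image
containing regions of different severities, graded clinically by its
most severe ("representative") region:

**Severity-max CutMix.** A mixed image
x̃ = M ⊙ x_A + (1 − M) ⊙ x_B (binary mask M, 1 outside the pasted
patch) is labeled by the *higher* severity, ỹ = y_A if y_A > y_B else
y_B, independent of patch area, and applied per sample with execution
probability P = 0.3.

**MS-DAM.** On each backbone stage (strides 8/16/32): a 1×1 projection,
three parallel *deformable* convolutions with kernels {3, 5, 7} —
y(p₀) = Σₙ w(pₙ) x(p₀ + pₙ + Δpₙ), the offsets Δpₙ predicted by a
zero-initialized sibling convolution and sampled bilinearly — then
channel concatenation, 1×1 fusion, a residual add giving R, and a
strictly positive channel attention softplus(W·GAP(R) + b) applied to
the L2-normalized R. Stage outputs are fused on the stride-16 grid and
classified by a GAP head. Training uses focal loss (γ = 1, no class
weighting), rectified Adam, and a warmup/cosine learning-rate schedule
between 1e-6 and 2e-3. Grad-CAM plus a patch-localization statistic
verifies that trained models attend to the higher-severity region of
mixed images.

The deformable convolution, all network layers and their backward
passes are implemented from scratch in this package (Rcpp/RcppArmadillo
kernels); the patient dataset behind the method is not publicly
available, so a severity-graded synthetic lesion generator reproduces
the study's dataset structure (640 train / 152 test images, class
counts 41/141/186/206/66 and 16/20/45/52/19, patient-disjoint splits)
and drives every experiment and test.

## Worked example

```r
library(sevgrade)

# architecture audit: EfficientNet-B1 with the 5-class head
print(cmd_stats("efficientnet_b1", 300))
#> Params: 6,519,589 (6.52M)  MACs @ 300px: 1,082,059,728 (1.08G)
#> Conventions: trainable parameters only (batch-norm statistics excluded);
#>   MACs from conv/dense multiplies only (no activations, no normalization)

# desk-scale end-to-end experiment: 500 synthetic 96x96 images, tiny
# backbone + MS-DAM + severity-max CutMix (P = 0.3) + focal loss,
# 5 epochs, against the identical no-MS-DAM baseline
res <- run_benchmark(seed = 1)
c(msdam = res$f1_msdam, baseline = res$f1_baseline)
#>     msdam  baseline
#> 0.8154680 0.6882176

print(res$reports$msdam)
#> Accuracy: 89.00%  macro PR 0.9112  RE 0.8031  F1 0.8155
#>     pred
#> true 0  1  2  3 4
#>    0 4  6  0  0 0
#>    1 0 13  0  0 0
#>    2 0  0 30  0 0
#>    3 0  0  0 34 0
#>    4 0  0  0  5 8

# does the trained model attend to the higher-severity region of mixes?
loc <- localization_experiment(res$net, res$test_images, n = 50, seed = 1)
c(median = loc$median_score, frac_above_1 = loc$frac_above_1)
#>       median frac_above_1
#>     1.638388         0.74
```

The parameter count is the printed size of this baseline (6.52 M); the
benchmark shows the attention module lifting held-out macro F1 well
above the matched baseline at identical budget; a localization score
above 1 means the Grad-CAM heat concentrates in the higher-severity
parent's region of a mixed image.

A command-line front end wraps the same functions:

```sh
exec/sevgrade generate-data --config cfg.yaml
exec/sevgrade stats --model efficientnet_b1 --input-size 300
exec/sevgrade train
exec/sevgrade ablate            # baseline / +focal / +CutMix / +MS-DAM arms
```

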