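---
title: "Opportunistic osteoporosis screening on synthetic vertebral phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opportunistic osteoporosis screening on synthetic vertebral phantoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oppscreen)
```

## The screening problem

Quantitative CT (QCT) measures trabecular bone mineral density (BMD, in
mg/cm^3^) in the vertebral cancellous bone. Guideline thresholds turn the
subject-level density `BMD_individual` — the mean of the L1 and L2
vertebral measurements — into a three-class bone-mass status:

* **normal**: `BMD_individual` > 120 mg/cm^3^,
* **osteopenia**: 80 ≤ `BMD_individual` ≤ 120 mg/cm^3^ (both bounds
  inclusive),
* **osteoporosis**: `BMD_individual` < 80 mg/cm^3^.

Opportunistic screening extracts this diagnosis from chest CT acquired for
other reasons. The pipeline implemented here has two learned stages: an
encoder–decoder network segments the vertebral body on the axial slice,
and a residual network classifies bone-mass status from the segmented
vertebral image — either from the L1+L2 pair stacked as a two-channel
"fusion feature image" (model 1) or from L1 alone (model 2), the variant
that would let the scan stop at the L1 level. Around these sit the QCT
measurement itself (`measure_roi_bmd()`, `classify_bmd()`) and the full
evaluation toolbox: Dice similarity, one-vs-rest ROC/AUC with DeLong
confidence intervals, the paired DeLong test, ratio-based dataset
splitting, and contingency/summary-statistics tests.

Because no public cohort exists for this problem, the package is exercised
end to end on a built-in synthetic phantom generator whose cohort-level
statistics mirror the published screening population. Everything below is
computed by the package's own tests and scripts; no empirical claims are
made beyond what those runs produce.

## The phantom generator

`generate_subject()` renders an axial slice as an elliptical vertebral
body on a soft-tissue background:

* a **trabecular interior** whose mean intensity encodes BMD through a
  linear calibration (default slope 1, intercept 0, so intensity equals
  BMD numerically; the vendor calibration of a real scanner is an
  unidentifiable nuisance here and removing it makes labeling directly
  checkable);
* a **bright cortical rim** (default intensity 420, strictly above the
  trabecular mean for any BMD up to 295.1 mg/cm^3^, the highest density
  the generator is calibrated for);
* per-pixel Gaussian **texture** (SD 20) plus three smooth low-frequency
  blobs at 15% of the texture SD — enough spatially correlated structure
  that ROI means are not trivially exact, while keeping ROI repeatability
  near the 1–2 mg/cm^3^ of careful QCT practice (a 100-seed Monte-Carlo
  gives measurement error SD 1.45 mg/cm^3^, MAE 1.1, maximum 3.9);
* an optional low-intensity **basivertebral vessel** (probability 0.5) in
  the posterior third of the body, which ROI placement must avoid;
* a **background** at level 60 with SD 10. For low-density subjects the
  trabecular interior is close to the background level, so the rim — not
  raw brightness — is what delimits the body; this is the main way the
  phantoms stay non-trivial for segmentation.

The ground-truth mask is the set of pixels strictly inside the inner
ellipse (the cortical rim's inner edge), matching how vertebral bodies are
annotated along the inner cortical margin.

`generate_cohort()` draws subject-level densities from per-class truncated
normal distributions. The class mix and the per-class mean ± SD default to
the published cohort (normal 168.33 ± 23.12, osteopenia 99.35 ± 10.91,
osteoporosis 60.32 ± 16.48 mg/cm^3^; mix 621 : 296 : 131, scaled to the
requested size by largest remainder). Truncation bounds respect the label
thresholds, and by default the *parent* parameters are moment-matched so
the truncated distribution itself has the stated mean and SD — the printed
numbers describe the observed (bounded) population, so matching them after
truncation is the faithful reading; without this, truncation would shift
the osteoporosis class mean by ≈ 3.6 mg/cm^3^. Each subject's L1 and L2
densities are `bmd ± d` with `d ~ N(0, 6)` mg/cm^3^ — a realistic
adjacent-vertebra difference — so their mean equals the subject draw
exactly and the label stays consistent by construction. Optional age/sex
demographics are sampled from the published age-decade × sex table and
feed only the statistics reports, never the models.

What the phantoms deliberately do **not** model: trabecular
microarchitecture, ribs/lungs/mediastinum, scanner physics (beam
hardening, dose, partial volume), 3-D continuity between slices, and
anatomical variation beyond ellipse jitter. Passing benchmarks on
phantoms therefore demonstrates that the pipeline's machinery — learning,
measurement, statistics — works as specified, not that the trained
weights would transfer to clinical CT.

## The segmentation network

`seg_model_config()` describes the encoder–decoder. The architecture
prose it implements is ambiguous in two places; the chosen reading is:

* Encoder layers 1 … depth−2 each apply a 1×1 convolution (channel mixing
  and extra nonlinearity) followed by a 3×3 residual block; a stride-2
  2×2 convolution sits **between** consecutive layers and does the
  downsampling. The last two encoder layers consist of the stride-2 2×2
  convolution alone. This yields depth−1 halvings, hence the requirement
  that the input size be divisible by 2^(depth−1).
* The decoder mirrors with stride-2 2×2 transposed convolutions. At the
  deepest skip the channel-attention fusion applies: concatenate skip and
  upsampled maps, global average pool, two 1×1 convolutions (ReLU, then
  sigmoid), multiply the per-channel weights onto the *skip* (low-level)
  map and add the upsampled (high-level) map. Upper skips use plain
  concatenation + 3×3 convolution. `use_attention = FALSE` gives the
  plain-concatenation U-Net-style baseline.

Channel widths are not published; the default is 16 at layer 1, doubling
and capped from layer depth−2 (so a depth-7 model runs
16/32/64/128/256/256/256). Every convolution is followed by batch
normalization and ReLU (also unpublished; this is the standard choice).
The loss is soft-Dice plus binary cross-entropy — it optimizes the
reported metric directly while BCE keeps early gradients well-scaled —
with plain Dice or BCE selectable. The output logit is thresholded at
probability 0.5. Model selection keeps the checkpoint with the best
tuning-set mean DSC (the training history records every epoch, so
last-epoch selection is also available).

Training is plain SGD (learning rate 0.001 as published; momentum is not
published and defaults to 0.98 — at a fixed small learning rate the
momentum term sets the effective step size, and the desk-scale update
budget of ~1500 steps sits far below the published 500-epoch schedule); a
small batch of 4 is used in the desk profile for the same reason, trading
matrix-multiply efficiency for update count. On desk-scale phantoms the
training shows a characteristic two-phase trajectory: brightness-based
segmentation saturates early at a tuning DSC near 0.75 (low-density
vertebrae, whose interior intensity is close to soft tissue, are missed),
then the rim cue is acquired and the tuning DSC moves above 0.95.
Augmentation draws one affine transform per image — vertical flip,
left-right mirror, rotation within ±15°, crop of 90–100% rescaled back —
and applies it identically to image (bilinear) and mask (nearest
neighbour, so masks stay binary). The drawn parameters are returned and
can be replayed exactly (`augment_replay()`), which is how the tests
verify the pairing.

Two named profiles ship: the **desk profile** (96-pixel phantoms, depth 5,
8 base channels, batch 4, 20 epochs) which everything in the test
suite and the acceptance script uses, and the **published-scale profile**
(512 pixels, depth 7, 500 epochs, batch 64) which is provided for
completeness but is far too heavy for a single-CPU run. Problem sizes in
the shipped benchmarks — 300 training, 25 tuning, 100 test slices for the
segmentation benchmark; a 500-subject cohort for the classification
benchmark — are the package's desk-scale study conditions.

## The classifier

`clf_model_config()` builds the residual classifier: a 7×7 stride-2 stem,
3×3 stride-2 max-pooling, four residual stages, global average pooling and
a 3-way fully connected head. The source prose names ResNet-101 but
describes stage unit counts (3, 4, 6, 3); the described counts are the
default and `variant = "resnet101"` switches to the canonical
(3, 4, 23, 3) — the description is followed rather than silently
"fixed". Each unit applies two 3×3 convolutions and one 1×1 convolution
around the skip; the first unit of stages 2–4 downsamples and projects the
skip with a 1×1 convolution so dimensions match. Model 1 (two-channel
L1+L2 input) and model 2 (L1 only) differ only in the stem's input
channels.

Classifier inputs are the original intensities multiplied by the
segmentation mask (background zeroed). Training hyperparameters are
unpublished; defaults mirror the segmentation optimizer (SGD, momentum
0.9, learning rate 0.001) with inverse-frequency class weights for the
roughly 6:3:1 imbalanced cohort, and the checkpoint with the best
validation macro one-vs-rest AUC is kept.

## Evaluation statistics

* `roc_auc()` is the Mann–Whitney form (ties counted ½) computed from
  midranks; multi-class evaluation is one-vs-rest per class, matching the
  per-class AUC rows of the published tables.
* `auc_ci()` and `delong_test()` use the DeLong structural-components
  variance (midrank implementation; the O(n²) double loop and a paired
  bootstrap serve as test oracles). A zero-variance comparison with equal
  AUCs returns Z = 0, P = 1; with unequal AUCs it is flagged degenerate
  rather than silently divided.
* `split_dataset()` apportions by largest remainder (exact for divisible
  n, e.g. 10 at 5:1:4 → 5/1/4), stratified within labels on request.
  The published segmentation counts (1096/200/800 of 2096) are not an
  exact 5:1:4 partition; the splitter documents its rounding rule rather
  than matching those counts.
* `chi_square_homogeneity()` is uncorrected Pearson (the published 0.862
  and 22.91 reproduce only without continuity correction, which is also
  the correct choice for tables larger than 2×2).
* `t_from_summary()` takes the method (`welch`/`pooled`) explicitly —
  published tables mix both conventions across rows — and
  `anova_f_from_summary()` reconstructs the one-way F from group
  summaries. Both are validated against raw-data tests on moment-matched
  samples.
* `confusion_metrics()` reports undefined ratios (zero denominators) as
  `NA`, never as 0.

## Numerical implementation

No deep-learning framework is available to R in this environment, so the
networks run on a compact engine written for this package: a reverse-mode
tape over (H, W, C, N) arrays, with im2col-based convolution, transposed
convolution (implemented exactly as the conv data-adjoint), max-pooling
and batchnorm kernels in C++ (RcppArmadillo, BLAS-backed). Every operator
is validated against central finite differences to ~1e-6 relative error
in the test suite. Double precision throughout; determinism for a fixed
seed holds in single-threaded BLAS mode (run-to-run on the same machine).
All randomness — initialisation, shuffling, augmentation, phantom
rendering — flows through R's RNG, with every entry point taking a seed
and restoring the caller's RNG state on exit. The pipeline fans a single
global seed out to per-stage seeds by hashing the stage name, so stages
can be rerun in isolation.

Degenerate inputs are refused loudly: non-finite or non-positive BMD,
empty ROIs after erosion, single-class training sets, splits smaller than
the number of parts, zero-margin contingency tables, infeasible
truncation windows.

## Known limitations

* Phantom realism is deliberately minimal (see above); the published
  cohort's exact DSC/AUC values on clinical CT are not reproducible from
  synthetic data, and the shipped benchmarks use them only as floors on
  an easier task.
* The CNN engine is single-threaded and desk-scale; the published-scale
  profile exists but training it would take orders of magnitude longer
  than the desk profile.
* 16-bit PNG output is not supported by the available PNG bindings;
  NIfTI is the lossless format and PNG output is an 8-bit preview.
* The segmentation-architecture prose admits several readings; the one
  implemented is recorded above and in `?seg_model_config`.
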