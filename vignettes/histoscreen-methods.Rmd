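---
title: "Image-based biomarker prescreening: models, quality control and screening analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based biomarker prescreening: models, quality control and screening analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoscreen)
```

## The problem

Targeted cancer therapies depend on molecular testing — for urothelial
carcinoma, detection of qualifying FGFR2/FGFR3 alterations decides
eligibility for FGFR inhibitors — but molecular tests are slow, expensive
and tissue-hungry, and in a population where only ~12–15% of patients carry
the alteration most tests come back negative. A prescreening device that
estimates the likelihood of the alteration directly from the routine
H&E-stained whole-slide image (WSI) can de-prioritize molecular testing for
patients very unlikely to be positive, or prioritize it where resources are
scarce.

`histoscreen` implements such a device end to end: tile-level quality
control, attention-based multiple-instance learning (MIL), a device wrapper
with a fixed error-message contract, and the screening analytics that turn
an operating point into expected confusion matrices, molecular-test
reduction, tier enrichment, cost and power numbers. A synthetic slide
generator makes every stage testable without patient data.

## Tile quality control

A WSI at the 10x working magnification is cut into non-overlapping
224 × 224-pixel tiles (partial edge tiles are dropped, keeping the bag
geometry fixed; coordinates are 0-based, half-open pixel intervals).
Masks for pen marks and background are computed once per slide on a
thumbnail (divisor 32 by default) and nearest-neighbor upsampled — a
speed/fidelity trade-off that matters on gigapixel inputs. Each tile then
receives four quality factors:

* `tissue_percent` — 100 × the fraction of tile pixels that are neither
  pen nor background (pen pixels are excluded from tissue; the
  alternative, binning before pen exclusion, would let a pen-covered tile
  masquerade as tissue-rich).
* `quantity_factor` — a step function of `tissue_percent`:
  0 → 0.0, (0, 10) → 0.1, [10, 80) → 0.2, [80, 100] → 1.0.
* `color_factor` — how close the tissue hues sit to the purple–pink H&E
  arc (hue 250°–350°): the mean circular hue distance `d` to the arc is
  mapped to `max(0, (90 − d)/22.5)`, so pixels on the arc contribute 4 and
  hues 90° or further contribute 0.
* `saturation_factor` — the mean of HSV saturation and value over tissue
  pixels, penalizing washed-out tiles.

These combine into the QC score

$$ \mathrm{score} \;=\; 1 - \frac{10}{10 + \mathrm{tissue\_percent}^2
  \cdot \ln(1 + \mathrm{color} \cdot \mathrm{saturation} \cdot
  \mathrm{quantity})/100}, $$

which lies in [0, 1), is monotone non-decreasing in every argument, and is
0 when the tile has no tissue or any factor is 0. Tiles enter the
prediction bag only when `score > 0.75` (strict); a slide with no
surviving tiles aborts with the fixed message
`"QC Failure – Insufficient tissue tiles."`. A useful algebraic
equivalence, exercised in the tests: a tile passes iff
`tissue_percent² · ln(1 + factor product) > 3000`.

The pen rules (relational channel tests over several threshold pairs,
e.g. green pen fires where green is high while red and blue are low), the
gray-background tolerance (pairwise channel differences ≤ 15 on the 0–255
scale), the hue arc and the factor scalings are reconstructions in the
spirit of the open-source slide-filtering helpers this kind of pipeline
builds on. The exact production constants are not public; all constants
live in one block (`qcConfig()`) and no bit-compatibility with any
deployed system is claimed.

## Attention-based multiple-instance learning

A slide is a *bag* of tile embeddings $h_1,\dots,h_N \in \mathbb{R}^{512}$
with a single label. Plain (non-gated) attention pooling computes

$$ a_k = \frac{\exp\!\big(w^\top \tanh(V h_k)\big)}
  {\sum_j \exp\!\big(w^\top \tanh(V h_j)\big)}, \qquad
  z = \sum_k a_k h_k, $$

with $V \in \mathbb{R}^{128 \times 512}$ and $w \in \mathbb{R}^{128}$
(hidden width 128, the cited attention-MIL default; gated attention is a
plausible alternative but the plain form is kept for its simplicity and
identical invariants). A two-logit softmax head on $z$ yields the slide
likelihood (positive-class probability). The weights are non-negative,
sum to 1, are permutation-equivariant, and replicating every tile $m$
times leaves the likelihood unchanged — all asserted as property tests.

**Backbone.** The backbone contract is any tile → 512-vector map. At
production scale this role is played by a pretrained convolutional trunk
used as a transfer-learning feature extractor. Here the default backbone
is deliberately frozen and handcrafted: a 26-number descriptor (connected
purple-blob count/area/compactness statistics, channel and HSV moments,
gradient energy) followed by a fixed, seeded Gaussian projection to 512
dimensions. Training then optimizes only the attention network and head
on precomputed bags — a standard MIL variant — with gradients derived by
hand (softmax-attention backpropagation through $V$, $w$ and the head).
This keeps the full train/evaluate loop deterministic and fast on one
CPU, and the descriptor responds to exactly the morphological contrast
the synthetic generator plants, so label recovery genuinely tests the MIL
machinery rather than a feature extractor's capacity.

**Training.** Class-weighted cross-entropy (weights inversely
proportional to class counts, normalized to mean 1) offsets class
imbalance; optimization is plain SGD, one slide-bag per step, with weight
decay and dropout on the bag embedding, all randomness flowing from one
config seed. The production-scale hyperparameters (learning rate 1e-5,
weight decay 1e-4, dropout 0.5) are the `milConfig()` defaults; on the
frozen 512-d bags a learning rate of 0.05 with 25–30 epochs is the
package's desk-scale choice, used throughout the tests. Features are
standardized with training-set statistics stored in the model. When
validation bags are supplied, the best-validation-loss parameters are
kept.

**Splitting and model selection.** `stratifiedSplits()` reserves a
hold-out partition (default 15%) and deals the rest into 5
cross-validation folds, stratified by label × cohort so every partition
preserves both ratios to within one slide. `selectModel()` scores each
candidate by PPV at the threshold that is the *largest* achieving
sensitivity ≥ 0.9 on its validation scores, breaking ties by higher
specificity then lower index; the winning threshold ships inside the
model and becomes the device operating threshold.

**Stain augmentation.** `stainAugmentations()` perturbs tiles in stain
space: optical densities are projected onto fixed hematoxylin / eosin /
residual direction vectors, per-stain scale (1 ± magnitude) and shift
(± magnitude) are drawn, and the tile is reconstructed. Magnitude 0 is an
exact identity; the default magnitude 0.05 changes channel means without
touching geometry.

## The device contract

`runDevice()` executes: metadata gate → slide read → masks → tile grid →
QC → strict filter → features → attention → likelihood → binarization
(and tiering when configured). Exactly six error strings can be returned,
byte for byte:

1. `Non-qualifying tissue site.` (site checked before stage)
2. `Non-qualifying disease stage.`
3. `Unsupported or missing image file.`
4. `Corrupted image file.`
5. `Required magnification unavailable.`
6. `QC Failure – Insufficient tissue tiles.`

Metadata comparison trims whitespace and folds case ("bladder " passes),
a deployment-robustness choice; a strict literal mode is available.
Boundary conventions not fixed elsewhere are chosen and documented here:
`binarize` calls positive at `likelihood ≥ threshold` (inclusive), and
the 3-tier rule is Low iff `likelihood < low_cut`, High iff
`likelihood ≥ high_cut` (inclusive), Mid otherwise — so the tiers
partition [0, 1] and `tier ≠ Low` coincides with the binary call at the
low cut. When a slide's stored raster is 20x/40x, the 10x level is
synthesized by area-averaged downsampling if resampling is enabled;
the default is to refuse with the magnification error, the conservative
reading of the device contract.

## Screening analytics

All deployment arithmetic flows from an operating point
(sensitivity $s$, specificity $e$) and a prevalence $p$:

* expected confusion (per $n$ patients): $TP = nps$, $FN = np(1-s)$,
  $TN = n(1-p)e$, $FP = n(1-p)(1-e)$ — real-valued expectations, with an
  optional integer-rounding display mode;
* molecular-test reduction = fraction predicted negative
  $= e(1-p) + (1-s)p$;
* cost model: testing everyone costs $n \cdot c$; with prescreening only
  predicted positives are tested, and with-screening cost plus savings
  equals the no-screening cost exactly (a conservation identity the tests
  check on random draws);
* 3-tier stratification: High = positive at the high-specificity cut,
  Low = negative at the high-sensitivity cut, Mid = the rest; per-tier
  prevalences follow Bayes' rule and the tier-weighted prevalences must
  mix back to the baseline (law of total probability, checked to 1e-9);
* exact binomial power: the two-sided rejection region at level α under
  $p_0$ is built with each tail ≤ α/2 (the *central* convention — the
  doubled-p-value and minimum-likelihood conventions are selectable
  because "two-sided exact test" alone does not pin one down), and power
  is the exact rejection probability under $p_1$. At $n = 150$,
  $p_0 = 0.8$, $p_1 = 0.9$, α = 0.05 the central convention gives 92.8%,
  printing as 93%.

Confidence intervals default to the normal-approximation (Wald) interval,
matching the style of deployment-report digits; the exact Clopper–Pearson
interval is available and recommended for small samples.

## The synthetic slide generator

The generator emulates just enough of H&E imagery for every pipeline
stage to be exercised honestly:

* **Hues.** Tissue is drawn in HSV around hematoxylin-purple
  (H 268–292°, S 0.5–0.65, V 0.4–0.55) and eosin-pink
  (H 330–350°, S 0.28–0.42, V 0.78–0.88) centers, inside the QC hue arc,
  so color/saturation factors respond as on real tissue.
* **Morphology classes.** Positive-class tiles (`solid_nest`) contain
  3–5 large compact purple blob clusters; negative-class tiles
  (`dispersed`) contain ~90–140 small scattered blobs. The generator's
  own compactness statistic (largest-blob share of blob area) separates
  the two populations decisively — a rank test on 50 tiles per class is
  part of the suite — guaranteeing downstream learnability.
* **Artifacts.** `background` tiles are near-uniform gray with equal
  channels (gray by construction), `pen_mark` tiles overdraw tissue with
  2–3 thick saturated red/green/blue strokes (the mask operators flag
  ≥ 5% of their pixels), and `blurred_tissue` applies a wide Gaussian.
* **Composition.** Tile counts are exact after rounding: an
  all-background slide has zero tissue tiles, a positive slide has
  `round(signal_fraction × n_tissue)` solid-nest tiles. Cohorts use a
  stratified-exact prevalence (`round(n·p)` positives, seeded placement)
  rather than Bernoulli draws so tests are count-exact; the default
  template prevalence in examples is 0.15, at the upper end of the
  realistic 12–15% range for this biomarker.
* **Determinism.** Identical spec + seed produce byte-identical output:
  pixels are quantized to the 8-bit grid at creation so the TIFF
  write/read round trip is lossless, and per-slide / per-tile seeds are
  derived from one cohort seed by a fixed integer hash. Slides are
  written as single-resolution 8-bit RGB TIFF at the 10x reference
  scale; pyramid levels are emulated by the downsampling accessor.

What the generator does **not** emulate: nuclear texture, stain-vendor
and scanner variation, tissue-boundary geometry, compression artifacts.
Passing tests therefore demonstrate that the pipeline's mechanics —
masking, scoring, filtering, pooling, training, thresholding, accounting
— are correct, not that the shipped backbone would discriminate real
FGFR biology; on real slides the backbone is the component to replace.

## Problem sizes and numerical choices

The parameter-recovery experiment uses 40 training and 20 held-out
slides of 4 × 4 tiles (896 × 896 px) at signal fraction 0.5 and 25%
background, the package's chosen desk-scale study size; the deployment
accounting batch uses 24 slides of which 2 are pure background and must
fail QC. Attention softmax is computed with max-subtraction for
stability; likelihood clipping at 1e-12 guards the log-loss; degenerate
QC inputs (no tissue pixels) short-circuit to zero factors rather than
propagating NaN; `tierPrevalences()` treats an empty tier's prevalence
as undefined (`NA`) and rejects operating-point pairs implying negative
Mid mass.

## Known limitations

* The backbone is frozen; end-to-end fine-tuning of a convolutional
  trunk is out of scope here and would require an autodiff runtime.
* QC constants are reconstructions; per-tile scores will differ from any
  production device even on identical pixels.
* No post-hoc likelihood calibration is applied before thresholding;
  thresholds selected on validation scores inherit their scale.
* The cost and tier models are expectation-level arithmetic; they ignore
  sampling variability in deployment cohorts (the power machinery is the
  tool for that question).
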