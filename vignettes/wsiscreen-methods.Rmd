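---
title: "wsiscreen: models, parameters and validation scope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wsiscreen: models, parameters and validation scope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wsiscreen)
```

This vignette is the package's account of its own science: the screening
procedure and its assumptions, the parameters that matter and why their
defaults are what they are, what the synthetic-histology generator does and
does not emulate, and the numerical and design choices made where the design
was genuinely open.

## The screening problem

The intended use is a preliminary, auditable read of H&E-stained whole-slide
images in settings where pathologist time is the bottleneck — the motivating
case is distinguishing a highly cellular aggressive lymphoma from benign
reactive lymphoid tissue. Slide-level diagnoses exist (weak labels); tile-level
annotations do not. That combination is the textbook setting for
multiple-instance learning (MIL): a slide is a *bag* of tile *instances*,
the bag label is positive if any instance is positive, and the learner must
discover which instances carry the signal.

Three properties matter for a screen more than raw accuracy:

* it should fail by *abstaining*, not by silently misclassifying;
* it must tolerate heterogeneous input — different scanners, stains, and
  whichever magnifications a clinic can produce;
* every stage must be reproducible and inspectable after the fact.

These drive the three structural choices: an ensemble with an explicit
indecision outcome, mixed-magnification bags behind an aggressive tile QC
cascade, and a pipeline in which every stage is a pure, seeded function with
a manifest.

## Preprocessing

### Tiling

Tiles are fixed-size squares on a stride grid (`stride = tile_size −
overlap`), 0-based, half-open `[x, x + size)`. Partial edge tiles are
*dropped*: QC statistics and the CNN input layer both require fixed
dimensions, and padding would manufacture artificial background precisely
where the background filter operates. The conventional operating point is
450 px (or 400 px) tiles with a 20 px overlap; the overlap imitates a
pathologist's overlapping fields of view and guarantees structures on a
stride boundary appear whole in at least one tile. A pixel inside the
overlap strip legitimately belongs to two tiles — the duplication is mild
(about 9% of columns at 450/20) and is deliberate.

Magnification pyramids are built by 2×2 area-average downsampling from the
highest available level (40x = 0.25 µm/px, halving per level to 5x =
2 µm/px), which is the correct anti-aliasing model for an ideal sensor with
square pixels. Tiles from all configured levels are pooled into one bag per
slide; the models never know which level an instance came from, which is
what lets inference accept whatever levels a user supplies.

### The QC cascade

Four filters run in a fixed order, short-circuiting at the first failure
(a rejected tile needs no further scores); `run_qc()` is a pure function of
the raster and a `qc_thresholds()` object. Order and rationale:

1. **Background / outlier** — pooled population standard deviation of all
   pixel values; default minimum 8 (8-bit units). Blank glass sits around
   σ ≈ 1; any tissue-bearing tile in practice exceeds 25. The default is
   therefore placed an order of magnitude below typical tissue, not tuned.
2. **Pen marks** — HSV box masks for green (hue 80–160°), blue (200–260°)
   and gray (saturation ≤ 0.12, value 0.2–0.8) ink, unioned; reject when
   more than 5% of pixels are inked. Hue is measured in degrees [0, 360)
   regardless of any internal 8-bit HSV encodings.
3. **Purple-to-pink ratio** — hematoxylin-band (250–310°) over eosin-band
   (310–360°) pixel counts among pixels with saturation ≥ 0.15 (near-white
   pixels carry no stain evidence and vote for neither). Default minimum
   0.3. Edge cases are defined, not left to arithmetic: no pink but some
   purple passes (ratio ∞ — maximal cellularity evidence); no qualifying
   pixels at all fails (no stain evidence whatsoever).
4. **Otsu tissue presence** — BT.601 luma, complemented so tissue (dark on
   light) becomes the high class, 256-bin Otsu threshold maximizing
   between-class variance (ties resolve to the lowest threshold, making the
   argmax deterministic); reject when fewer than 10% of pixels exceed the
   threshold. A constant tile has a degenerate one-bin histogram and is
   defined to fail with tissue fraction 0.

Every number above is a *default*, not a contract: the filter structure is
the contract, and all constants are overridable through `qc_thresholds()`.
The bands were chosen to straddle the generator's hue centers (purple 270°,
pink 330°) with wide margins; on real slides they would be recalibrated to
the lab's stain.

### Stain normalization

Reinhard-style per-channel moment matching in CIE Lab (one lightness + two
chroma channels): `out = (in − μ_tile)/σ_tile · σ_ref + μ_ref`, then back to
8-bit sRGB with clipping. Moment matching was chosen over stain-vector
deconvolution (Macenko-style) because it is deterministic, parameter-free
and closed-form; the operation signature (`normalize_tile(raster, ref)`)
would accept a deconvolution-based implementation unchanged. Pre-clipping,
the output moments equal the reference exactly; quantization then perturbs
them by well under one 8-bit step, which is why normalization is idempotent
to within one gray level.

One consequence of working in a perceptual space deserves a note: an
additive offset in 8-bit RGB is *not* an affine map in Lab (the sRGB
transfer function is nonlinear), so normalization cancels RGB brightness
offsets only approximately — empirically to a mean absolute difference
below 2 of 255 for clip-free ±20 offsets — while offsets applied to the Lab
lightness channel cancel exactly, bit for bit. The tests assert both forms.
A channel with numerically zero spread cannot be rescaled and is shifted to
the reference mean, with a logged message.

The default reference (`default_reference()`) is fitted to six clean
synthetic tiles (alternating classes, seeds 0–5). Because the generator is
deterministic, this "shipped fixture" is recomputed identically everywhere
rather than stored, and is versioned through the `reference_stats` object.

## Learning

### Bags, splits, sampling

Bags collect all QC-passing tiles of a slide across magnifications in
deterministic order (magnification, then y, then x). Splitting is at slide
level — tiles of one slide never straddle partitions — with seeded
shuffling and largest-remainder allocation of the 6:2:2 ratios. Splits are
stratified by label when labels are available: with cohorts of tens of
slides, an unstratified split has a real chance of a single-class
validation partition, which would make both early stopping and the
learnability checks meaningless. (Largest-remainder on a 90/70 cohort
gives 54/18/18 + 42/14/14 = 96/32/32.)

Per epoch, `sample_size` instances are drawn per bag uniformly *without*
replacement, resampled each epoch (so over training a model eventually sees
every tile of every slide); a bag smaller than `sample_size` contributes
all its instances exactly once — duplication would silently reweight small
bags. Validation and inference always use all instances.

### Models

No deep-learning framework is assumed: the instance encoder is a compact
CNN implemented in the package itself on base-R matrix algebra (im2col
gathers + BLAS GEMM), with numerically verified gradients (the test suite
checks analytic against finite-difference gradients for every parameter
tensor of both heads). All backbones share one architecture — three 3×3
stride-2 valid convolutions with ReLU, then global average pooling into an
embedding — and differ in width:

| preset | filters | embedding |
|---|---|---|
| `tiny-cnn` | 8/16/32 | 32 |
| `efficientnet-like` | 8/16/24 | 24 |
| `googlenet-like` | 10/20/40 | 40 |
| `resnet50-like` | 12/24/48 | 48 |

The `-like` names denote capacity presets standing at desk scale where the
corresponding full pretrained families would stand in a production setting;
backbones are pluggable behind `model_config()`, so a framework-backed
encoder can replace them without touching the MIL machinery.

Two pooling heads:

* **plain** — bag probability is the mean of instance class probabilities.
  Mean was chosen over max pooling because with small `sample_size` the max
  estimator is high-variance and its gradient touches one instance per
  step; mean keeps all sampled instances in the gradient. For a
  density-style signal (what fraction of tissue looks malignant) mean is
  also the better-matched statistic.
* **gated attention** — each embedding h_i receives a score
  wᵀ(tanh(V h_i) ⊙ sigmoid(U h_i)); softmax over the bag gives weights
  α_i summing to 1; the classifier sees Σ α_i h_i.
  `attention_head_size` is the hidden width of V and U (conventional grid
  10/50 or 16/64).

### Training protocol

Adam (lr 0.001, β = 0.9/0.999), cross-entropy on the bag probability,
mini-batches of `batch_size` bags with bag-averaged gradients, at most 20
epochs. Early stopping monitors validation loss over full bags:
"improvement" means beating the running minimum by more than 1e-6 (a pure
non-strict comparison would let float noise reset the patience counter),
patience is 5 consecutive non-improving epochs, and the returned parameters
are those of the best epoch, not the last. All shuffling, sampling and
initialization derive from `model_config()$seed`, so identical
configuration + bags reproduce identical histories bit for bit (the
implementation is pure R; there is no framework nondeterminism to allow
for).

The default ensemble (`default_ensemble_configs()`) pairs the three wider
presets with and without attention at the operating points conventional for
each variant (plain: batch 8/8/4 with sample size 20; attention: head
64/50/16 with batch 4/12/4 and sample sizes 20/20/80).

## Consensus and metrics

Each model votes by thresholding its bag probability at 0.5 (the paper-side
convention of turning a continuous score into a class; exactly 0.5 votes
positive — screening resolves the knife-edge toward sensitivity).
Confidence is defined over *hard votes*, `max count / N`: this is the only
definition under which "more than half the models" and "at least 4 of 6"
coincide, and it makes the indecision rule exact — a 3–3 split has
confidence 0.5 and abstains; any odd ensemble can never abstain. Averaging
probabilities instead would hide a 3–3 disagreement behind a spuriously
confident mean.

Ensemble accounting is three-way: correct / indecision / incorrect
percentages, integer-rounded by largest remainder so they always sum to
100 (remainder ties resolve toward the later category). Indecision slides
are excluded from any accuracy-style ratio and reported separately — an
abstention is a deferral to the pathologist, not an error. Per-model
metrics are the standard confusion-matrix set; ratios with empty
denominators are reported as absent (`NA`), never as 0. AUC uses the
rank/Mann–Whitney formulation with ties counting one half, which is exact
and O(n log n).

## The synthetic cohort: what it does and does not show

`generate_cohort()` emulates the *structure* of a two-class WSI cohort, not
histology. Each pseudo-slide is a pink stroma field (hue 330°, saturation
0.35, value 0.85, all jittered ±10%, hue ±6°) carrying purple elliptical
nucleus blobs (hue 270°) drawn until a target area fraction is covered —
0.55 for the positive class, 0.28 for the negative. Nuclear density *is*
the class signal: the positive/negative purple-to-pink ratio differs by a
factor ≈ 3, safely above the ×1.5 floor the learnability tests require,
and echoing the cellularity contrast between an aggressive lymphoma and
reactive tissue. Contamination is layered on top: near-white blank
rectangles, thick curving pen strokes cycling green/blue/gray (drawn inside
the QC ink boxes), each to a target area fraction (default 5% + 5%), and —
as standalone fixtures — low-tissue tiles holding ≤ 10% tissue on glass.
The scanty-tissue patch uses finer nucleus fragments (radius 1 px at 64 px
tiles) so that even a ~9%-area patch is compositionally representative of
its class's stain ratio rather than dominated by blob-count noise.

Everything is a pure function of its spec: identical seeds give
bit-identical rasters, per-slide seeds derive deterministically from a
cohort base seed, and every raster ships with a per-pixel truth mask
(background/tissue/pen/blank) so QC decisions can be checked against ground
truth.

What the generator deliberately does **not** model: nuclear texture and
chromatin, cell boundaries, starry-sky macrophage holes, scanner noise,
compression artifacts, focus blur, fold/tear geometry, or any real
BL-versus-tonsil morphology. Passing the synthetic suite therefore shows
that the *pipeline machinery* is correct — filters fire at the right stage,
the learners extract a planted separable signal, the consensus arithmetic
is exact — and says nothing about clinical performance. The headline
synthetic result (zero misclassified test slides, indecisions permitted)
mirrors the *shape* of the screening claim, on data designed to be
separable.

## Problem sizes and runtime

The test suite and the acceptance script run the full demo at desk scale,
chosen so the complete pipeline (40 slides of 160×160 px, 64 px tiles with
16 px overlap at 40x + 20x, six models, ≤ 20 epochs each) finishes in about
a minute on a single CPU while still exercising every stage with non-trivial
counts (≈ 400 tiles through QC, 24/8/8 bag split, ≈ 2–7 instances per bag
after contamination filtering). Oracle suites use 100–200 random cases
each. Input size for the CNNs is 64 px in tests (224 px remains the
configurable production default, with the ImageNet channel statistics).

## Known limitations

* The purple/pink "scoring factor" is implemented as a ratio of hue-band
  counts; other readings (e.g. continuous hue-deviation scores) fit the
  same operation signature.
* Background and blank-tile removal share a single standard-deviation
  criterion; a lab wanting separate outlier logic would split the stage.
* Pyramidal/vendor WSI formats (SVS, MRXS) are out of scope; input is a
  raster or a tile directory. An out-of-core pyramidal-TIFF adapter would
  slot in front of `tile_slide()`.
* Probabilities are not calibrated; votes and the 0.5 threshold are the
  interface. Weighted or learned ensembling is deliberately excluded —
  equal votes keep the abstention semantics legible.
* With very small bags (heavily contaminated slides) the per-bag instance
  sample can be the whole bag every epoch, making `sample_size` inert for
  those slides.
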