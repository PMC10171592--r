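---
title: "Methods: orbital tissue segmentation with an un-pooling encoder-decoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orbital tissue segmentation with an un-pooling encoder-decoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbitseg)
```

## The problem

Quantitative assessment of Graves' orbitopathy (GO) relies on measuring
orbital tissue on CT: the eyeball, the optic nerve, the four rectus
muscles and the lacrimal gland.  Manual delineation is slow and
observer-dependent, and GO itself deforms the very structures that must be
measured — enlarged muscle bellies, crowded apices — which is where generic
segmentation networks tend to produce ragged boundaries.  `orbitseg`
implements a semantic-segmentation model built for this setting, a
SegNet-style baseline to compare against, and the full training/evaluation
protocol, exercised end-to-end on a synthetic phantom generator so that
every stage runs and is tested without clinical data.

## Architecture

The segmentation network is a five-block encoder / five-block decoder
fully-convolutional network.  Every convolution is 3x3, stride 1,
zero-padded, followed by batch normalization and ReLU.  The first two
encoder blocks contain two such convolution layers, the last three contain
three; each block ends with a 2x2, stride-2 max pooling that records the
argmax position of every pooling window.  Five poolings reduce a
`512 x 512` input to a `16 x 16` bottleneck (1/32 scale).

The decoder mirrors the encoder.  Each decoder block first restores
resolution by *max un-pooling*: every feature value is placed back at the
argmax position its counterpart encoder pooling recorded, and all other
positions are zero-filled.  Un-pooling has no trainable parameters, so its
capacity is spent nowhere — but it leaves a sparse, rough map.  The
proposed network therefore also *concatenates* the counterpart encoder
block's pre-pool feature map (a skip connection) before the block's
convolutions, at all five scales — the full ladder 1, 1/2, 1/4, 1/8, 1/16
of the input size.  The final convolution maps to
per-pixel logits; a sigmoid (applied at inference only) gives foreground
probabilities.

The baseline (`build_segnet()`) keeps the identical encoder and the
un-pooling decoder but drops the skip concatenation: its decoder sees only
the pooling indices.  This isolates exactly the contribution of multi-scale
feature delivery.

```{r}
net <- build_proposed()
seg <- build_segnet()
count_parameters(net)
count_parameters(seg)
```

Three architecture details are deliberate choices rather than published
facts, and the parameter totals pin them down:

* **Channel widths** default to `c(64, 128, 256, 512, 512)`, the VGG-16
  family SegNet uses.  With those widths the two variants hold
  34,935,169 and 29,442,433 trainable parameters — 34 and 29 million when
  truncated to millions — consistent with the reported sizes of both
  models.
* **Skip fusion is concatenation**, with the first convolution of each
  decoder block widened to absorb the extra channels.  Additive fusion
  would contribute no parameters and could not produce the 34M-vs-29M gap,
  so concatenation is the only reading consistent with the counts.
* **Truncation, not rounding**, is used when quoting "millions of
  parameters", because truncation makes both totals consistent with the
  default architecture.

Other conventions: pooling ties resolve to the first maximum in row-major
window scan order; weights are He-initialized (`sd = sqrt(2/fan_in)`) under
a caller-supplied seed; batch-norm uses `eps = 1e-5`, momentum 0.1 and
affine parameters initialized to identity.  One network is trained per
target tissue (`num_classes = 1`); a multi-label head is available through
`net_config(num_classes = k)`.

The un-pooling pair satisfies an exact fixed point on non-negative inputs
(the only regime that occurs in the network, since pooling always follows
ReLU): `pool(unpool(pool(x))) = pool(x)`, and the un-pooled map is zero
everywhere off the recorded indices.  Both facts are asserted exactly, not
to a tolerance, in the test suite.

## Preprocessing

CT slices store integer Hounsfield units in [-1024, 3071].  Intensities
are normalized to [0, 1] with a value-of-interest window of center 0 HU and
width 200 HU:

$$y = \mathrm{clip}\!\left(\frac{x - (c - w/2)}{w},\ 0,\ 1\right)$$

This soft-tissue window spreads fat (-80), vitreous (+5), nerve (+35),
lacrimal gland (+40) and muscle (+50) across the unit interval while
saturating bone and air.  We use the plain center/width mapping; the DICOM
PS3.3 linear variant (denominator `w - 1`, offset `c - 0.5`) differs by
under 1% at width 200 and is available as `apply_window(..., ps33 = TRUE)`.

## Objective

Training minimizes the focal Tversky loss.  With soft counts
$S_{tp} = \sum p_i t_i$, $S_{fp} = \sum p_i (1 - t_i)$,
$S_{fn} = \sum (1 - p_i) t_i$ aggregated over all pixels of the batch,

$$TI = \frac{S_{tp} + \epsilon}{S_{tp} + \alpha S_{fp} + \beta S_{fn} + \epsilon},
\qquad \mathcal{L} = (1 - TI)^\gamma .$$

Defaults are $\alpha = 0.7$, $\beta = 0.3$, $\gamma = 4/3$, the values of
the originating focal-Tversky formulation; they are declared defaults, not
values inferred from any reference, and all are configurable.  The batch
is aggregated as one pooled count rather than per-image averaged, and
$\epsilon = 10^{-6}$ defines the empty-vs-empty limit ($TI \to 1$, loss
$\to 0$).  With $\alpha = \beta = 0.5$ and $\gamma = 1$ the loss reduces
exactly to $1 -$ soft Dice, which the tests verify to $10^{-10}$.  The
analytic gradient used by the training loop is checked against finite
differences.

## Training and model selection

The training protocol is: batch size 16, AdamW (decoupled weight decay)
with learning rate $10^{-3}$ and weight decay $10^{-4}$, 50 epochs, no
schedule and no early stopping.  After every epoch the aggregate focal
Tversky loss on the validation split is computed in inference mode, and the
weights finally returned are those of the epoch with minimum validation
loss (earliest epoch on ties).  The per-epoch loss trace is kept on the
fitted object and `plot()`ted directly.  Given equal seeds and
single-threaded execution, training runs are bit-reproducible; with a
multi-threaded BLAS they are reproducible only statistically.

## Evaluation protocol

Slice ids are split 0.70 / 0.15 / 0.15 into train / validation / test.
Sizes follow a floor rule — `floor(0.7 n)` and `floor(0.15 n)` with the
remainder to test — so 701 ids split as 490/105/106.  The split of
repetition $r$ is driven by `seed + r`: ten repetitions (the default)
resample all three subsets, each reproducible in isolation.

Predictions are binarized at 0.5 (ties to foreground) and scored per image
by Dice $= 2TP/(2TP+FP+FN)$ and IoU $= TP/(TP+FP+FN)$, averaged over the
test set to one value per (model, tissue, repetition).  Per-image
averaging (rather than pooling counts across images) is a protocol choice;
both metrics obey $\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$,
asserted to $10^{-12}$ on random counts.  Empty-prediction-vs-empty-truth
is defined as 1 by convention; it cannot arise in the phantom datasets,
whose masks are always non-empty.

`run_comparison()` trains every candidate model on the identical split of
each repetition and evaluates on the shared test split, so the comparison
is paired by construction.  The model with the highest mean Dice anchors
the report; every other model is compared to it with a two-sided paired
t-test over the per-repetition means (df = repetitions - 1), flagged
significant at p < 0.001.  Per-repetition means, not pooled per-image
values, are the pairing unit, because the repetition is the unit of
replication in this protocol; zero-variance difference vectors are flagged
degenerate rather than given a fabricated statistic.

## The phantom generator

`phantom_spec()` + `render_slice()` emulate the three clinical slice
types: *axial1* (largest eyeball section: two orbits, each with an eyeball
disc, a tapered optic-nerve band, and medial/lateral rectus bands flanking
it), *axial2* (lacrimal-gland crescents supero-temporal to each globe),
and *coronal* (central optic-nerve disc with the four rectus muscles at
compass positions inside a bone ring).  Tissue HU means default to
standard radiology ranges (fat -80, vitreous +5, sclera +60, muscle +50,
nerve +35, lacrimal gland +40, bone +1000); global Gaussian noise defaults
to 10 HU; geometry is jittered per slice within configurable ranges; an
`enlargement_factor >= 1` thickens the muscle bands, emulating GO.  Masks
are rendered pairwise disjoint (priority order, muscles claimed first so
enlargement is never clipped by later tissues), pixel values are integer
HU clipped to the CT range, and item $i$ of a dataset is rendered with
seed `seed + i` so any slice is independently reproducible.

What the phantom does *not* emulate is deliberate: anatomy is circles,
bands and crescents, with none of the texture, partial-volume blur,
beam-hardening or patient variability of clinical CT.  Tests that pass on
phantoms therefore demonstrate that the architecture, objective, training
loop and statistics behave as specified — not that clinical-grade accuracy
is attained.  The reported clinical performance of this family of models
is not reproducible here because the underlying patient dataset is not
public.

## Problem sizes used by the tests

The full-width network at 512 x 512 is far beyond what a CPU R session
should spend on a routine test run, so the test suite exercises the
*default* configuration only where it is cheap (construction, parameter
counting, shape contracts) and uses reduced sizes elsewhere, as its own
choice of problem scale:

* gradient checks and unit tests: widths `c(2, 3, 4, 5, 5)` at 32-64 px;
* the overfit property: widths `c(4, 8, 16, 32, 32)` at 128 x 128,
  8 axial1 phantoms, 200 AdamW steps, eyeball tissue — reaching training
  Dice >= 0.95;
* the ordering property: the same narrow widths, 60 phantoms, 3
  repetitions, 15 epochs, medial rectus muscle — checking the *direction*
  (proposed >= SegNet on mean Dice), not the magnitude, of the skip
  connections' benefit.  At 15 epochs on a ~3-px-wide band both models are
  far from converged, so absolute Dice values in this check are small and
  noisy; only the paired ordering is asserted.

## Known limitations

* Convolutions, batch-norm and pooling are implemented in C++ with
  R-level orchestration; throughput is adequate for the narrow test
  configurations but not for full-width 512 x 512 training, for which a
  GPU framework remains the right tool.
* Batch statistics with small batches (8-16) make batch norm noisy; the
  running statistics used at inference converge slowly early in training.
* DICOM input is not parsed; images enter either through the phantom
  generator or as 16-bit rasters (TIFF storing HU + 1024) listed in a
  manifest.  The windowing step assumes rescale-corrected HU values.
* The paired t-test over 3 repetitions (acceptance scale) has df = 2 and
  essentially no power; it is reported for protocol completeness, with the
  ten-repetition default recommended for real comparisons.
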