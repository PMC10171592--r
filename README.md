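# orbitseg

Semantic segmentation of orbital tissue — eyeball, optic nerve, the four
rectus muscles, lacrimal gland — in axial and coronal CT slices, aimed at
quantitative assessment of Graves' orbitopathy (GO), where muscle
enlargement deforms exactly the structures that must be measured.

The package provides, in plain R with RcppArmadillo compute kernels:

* **the segmentation network**: a five-block encoder / five-block decoder
  FCN whose decoder restores resolution by *max un-pooling* (each value
  returns to the argmax position recorded by the encoder's 2×2 pooling,
  zeros elsewhere) and fuses encoder features through skip connections at
  all five scales 1, 1/2, 1/4, 1/8, 1/16 of the input;
* **a SegNet-style baseline** with the identical encoder whose decoder uses
  only the pooling indices — isolating the contribution of multi-scale
  skip delivery;
* **the focal Tversky objective** `loss = (1 − TI)^γ` with
  `TI = S_tp / (S_tp + α·S_fp + β·S_fn)` on batch-aggregated soft counts,
  with full analytic gradients (verified against finite differences);
* **the training protocol**: AdamW (lr 1e-3, weight decay 1e-4), batch 16,
  50 epochs, checkpoint selection by minimum validation loss;
* **the evaluation protocol**: repeated 0.70/0.15/0.15 random splits,
  per-image Dice `2TP/(2TP+FP+FN)` and IoU `TP/(TP+FP+FN)` on predictions
  binarized at 0.5, and paired t-tests of every model against the
  best-performing one (significance at p < 0.001);
* **a synthetic orbital CT phantom generator** emulating the three
  clinical slice types (axial through the globes, axial through the
  lacrimal glands, coronal behind the globe) with exact ground-truth
  masks, so the entire pipeline runs and is tested with no clinical data.

## Worked example

Build both architectures and confirm their capacities:

```r
library(orbitseg)
build_proposed()
#> Orbital segmentation network (proposed variant)
#>   encoder/decoder blocks: 5 + 5; conv counts 2-2-3-3-3
#>   widths: 64, 128, 256, 512, 512; kernel 3x3; pool 2x2
#>   skip connections: five scales (1, 1/2, 1/4, 1/8, 1/16), concatenated
#>   trainable parameters: 34,935,169
build_segnet()
#> Orbital segmentation network (segnet variant)
#>   ...
#>   trainable parameters: 29,442,433
```

34,935,169 and 29,442,433 truncate to 34 and 29 million; the ~5.5M gap is
exactly the widened first convolution of each decoder block that absorbs
the concatenated skip channels.

Generate a phantom dataset, train on one tissue, evaluate:

```r
spec <- phantom_spec(image_size = 128)
render_slice(spec, "axial1", seed = 1)$masks
#> Tissue mask set (axial1):
#>   eyeball           1168 px
#>   optic_nerve        134 px
#>   MRM                204 px
#>   LRM                202 px

sls <- simulate(spec, nsim = 8, seed = 10, plane = "axial1")
tr  <- list(images = lapply(sls, function(s) s$image$hu),
            masks  = lapply(sls, function(s) s$masks$eyeball))
fit <- train_network(build_proposed(net_config(widths = c(4, 8, 16, 32, 32))),
                     tr, tr, train_config(batch_size = 8, epochs = 200))
evaluate_network(fit, tr)
#> Segmentation evaluation over 8 images: mean Dice 0.9905, mean IoU 0.9812
```

(Narrow widths keep this a few CPU-minutes; the full-width default is the
clinical-scale configuration.)  A repeated-split paired comparison of the
two architectures:

```r
man <- generate_dataset(60, spec, "axial1", "phantoms/", seed = 500)
cfg <- net_config(widths = c(4, 8, 16, 32, 32))
run_comparison(list(proposed = function(s) build_proposed(cfg, s),
                    segnet   = function(s) build_segnet(cfg, s)),
               man, "MRM", split = split_spec(seed = 11, repetitions = 3),
               config = train_config(epochs = 15, seed = 21))
#> Model comparison on tissue 'MRM' over 3 repetitions (best: proposed)
#>   proposed     Dice  10.5 +/-  4.0 %  IoU   5.6 +/-  2.2 %  (reference)
#>   segnet       Dice   6.8 +/-  3.4 %  IoU   3.5 +/-  1.8 %  p=0.423
```

At 15 epochs on a ~3-px-wide muscle band neither model is near
convergence — the check is the paired *ordering* (skip connections help),
not the magnitude.  The t-test itself:

```r
paired_t_test(c(2, 4, 6), c(1, 2, 3))
#> paired t-test: t = 3.4641, df = 2, p = 0.07418 (mean diff 2)
```

A command-line front end over the same functions is installed at
`inst/cli/orbitseg.R` (`generate | train | evaluate | compare | segment`).

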