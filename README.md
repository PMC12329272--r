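# unetbench

Benchmarking U-Net depth and width variants for chest-radiograph lung-field
segmentation, in R.

Lung segmentation assigns every pixel of a chest X-ray to lung or
background. The standard architecture is the U-Net — a contracting
convolution/max-pool path, a bottleneck, and an expanding path of learnable
2×2 transposed-convolution upsamplers with skip connections concatenating
same-resolution encoder features. `unetbench` implements a systematic
eight-member family of these networks so the effect of *depth* and *width*
can be compared under identical conditions:

| Variant | Encoder levels | Width schedule | Parameters |
|---------|---------------|----------------|-----------:|
| U-Net7  | 3 | doubling from 64 | 7,696,193 |
| U-Net9  | 4 | doubling from 32 | 7,759,521 |
| U-Net11 | 5 | doubling from 16 | 7,775,313 |
| U-Net13 | 6 | doubling from 8  | 7,779,241 |
| U-Net16 | 4 | all layers 16    | 52,993 |
| U-Net32 | 4 | all layers 32    | 210,945 |
| U-Net64 | 4 | all layers 64    | 841,729 |
| U-Net128| 4 | all layers 128   | 3,362,817 |

Every block is a 3×3 same-padding convolution + ReLU (batch normalization
available as an opt-in flag, folded into an effective per-channel affine);
the head is a 1×1 convolution + sigmoid. Evaluation uses the two standard
overlap metrics,

    IoU  = TP / (TP + FN + FP)
    Dice = 2·TP / ((TP + FN) + (TP + FP)) = 2·IoU / (1 + IoU)

reported both micro- (pooled pixel counts) and macro-averaged (mean of
per-image values). Since Dice ≥ IoU identically, the package always labels
metrics by formula.

The package contains no deep-learning framework: forward and backward
passes (convolution, transposed convolution, max-pool, Adam, binary
cross-entropy) are implemented with RcppArmadillo BLAS kernels, and the
analytic gradients are verified against finite differences in the test
suite. A closed-form parameter-count oracle, written as an independent
code path, must match the built networks for every configuration.

A seeded synthetic chest-phantom generator (ellipse lung fields with exact
ground-truth masks, rib-like stripes, Gaussian noise) makes the whole
pipeline testable without any external download.

## Worked example

```r
library(unetbench)

# audit an architecture
spec <- resolve_variant("U-Net16")
closed_form_param_count(spec)
#> [1] 52993
count_parameters(build_unet(spec, seed = 1))
#> [1] 52993

# synthetic phantom benchmark: 200 easy 64x64 phantoms, 80/20 split,
# 5 epochs (the learning rate is scaled to the short step budget; see the
# vignette)
dir <- file.path(tempdir(), "phantoms")
generate_dataset(200, phantom_params(size = 64, preset = "easy", seed = 0), dir)
cfg <- train_config(image_size = 64, epochs = 5, batch_size = 20,
                    learning_rate = 3e-3, seed = 0)
rec <- run_benchmark(c("U-Net16", "U-Net32"), dir, cfg,
                     out_dir = file.path(tempdir(), "results"))
sapply(rec, function(r) r$test_metrics$micro_dice)
#>   U-Net16   U-Net32
#> 0.9997564 0.9996483
```

`run_benchmark()` writes `params.csv` (parameter audit with informational
wall time), `metrics.csv` (train/test Dice and IoU, micro and macro) and
`panels/` with side-by-side `[image | actual mask | predicted mask]` PNGs.

A thin CLI wrapper over the same functions ships at `inst/cli/unetbench`
(`build --audit`, `generate`, `preprocess`, `evaluate`, `run`).

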