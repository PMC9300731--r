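# fundusmtl

Multi-task deep learning for glaucoma screening from color fundus images,
implemented natively in R (Rcpp/RcppArmadillo; no external deep-learning
framework).

## What it does

Glaucoma shows on a fundus photograph as *cupping*: the optic cup (OC)
enlarging inside the optic disc (OD), measured by the vertical cup-to-disc
ratio

    vCDR = OC_height / OD_height.

`fundusmtl` trains **one** shared convolutional network — a U-Net with a
VGG-16 encoder (13 conv layers, no batch norm) and a 4-stage skip-connected
decoder — on four tasks at once:

| task | head | loss |
|---|---|---|
| OD segmentation | 1x1 conv + sigmoid | pixel-averaged BCE |
| OC segmentation | 1x1 conv + sigmoid | pixel-averaged BCE |
| fovea localization | 1x1 conv (identity) | L1 **sum** to a Gaussian saliency map; prediction = center of mass |
| glaucoma | pool → 512 → 256 → 1 + sigmoid | focal loss, γ = 2 |

The full multi-task model holds **17,169,188** trainable parameters
(17.2e6); the four single-task networks it replaces hold 65,958,884
together — **3.84x** more.

Three training strategies are provided:

* `mtl_vanilla` — one update on the aggregated loss Σ c⁽ᵏ⁾ L⁽ᵏ⁾;
* `mtl_alternate` — one plain gradient step per task, each at the weights
  left by the previous task;
* `mtl_io` — alternating steps where each task's gradient passes through
  that task's **own** Adam moment estimates, so no task's momentum ever
  mixes with another's (the independent-optimizer scheme, the package's
  centerpiece).

Glaucoma is scored by averaging the network's classifier probability with a
ridge-logistic classifier on the vCDR computed from the predicted masks
(0.5 threshold, largest connected component), thresholding the average at
0.5. Metrics: Dice, Mann–Whitney AUC (with ROC), Euclidean fovea error.

A seeded synthetic-fundus generator (elliptical disc/cup with exact vCDR
ground truth, dark fovea spot, ~10% positive prevalence) makes every module
testable offline, and reads/writes the same on-disk layout as REFUGE-style
data (`images/`, tri-level `masks/`, `fovea.csv`, `labels.csv`).

## Worked example

```r
library(fundusmtl)

train_set <- generate_dataset(synth_params(n_images = 48, seed = 101))
test_set  <- generate_dataset(synth_params(n_images = 24, seed = 202))
verify_ground_truth(train_set)$n_violations
#> [1] 0

set.seed(11)
model <- build_model(model_config(input_size = 64))
count_parameters(model)
#> [1] 17169188

fit <- train(model, train_set,
             train_config(strategy = "mtl_io", learning_rate = 1e-3,
                          epochs = 8, batch_size = 4, seed = 7))
report <- evaluate(fit$model, test_set)
report$aggregate
```

`report$aggregate` lists mean ± sd Dice for disc and cup, the mean fovea
error in pixels, and the pooled ensemble AUC on the held-out images;
`report$per_image` has one row per image (probabilities, vCDR, predicted
fovea coordinates, diagnostics). Numbers and runtimes for a fuller training
budget are discussed in the methods vignette
(`vignettes/fundusmtl-methods.Rmd`).

## Command line

```sh
fundusmtl simulate     --out data/synth --n 100 --seed 1
fundusmtl train        --data data/synth --out runs/io --strategy mtl_io --epochs 30
fundusmtl evaluate     --data data/synth --checkpoint runs/io/checkpoint.rds --out runs/io
fundusmtl predict      --data data/synth --checkpoint runs/io/checkpoint.rds --out runs/io
fundusmtl count-params --size 64
fundusmtl splits       --data data/synth --k 5 --seed 1 --out folds.csv
```

(The script installs under `exec/`; equivalently call
`fundusmtl::run_cli(c("count-params"))` from R.) Options can also come from
a flat `key: value` config file via `--config`; explicit flags win. Exit
codes: 0 success, 2 usage error, 1 runtime failure.

## Using REFUGE-style data

The loader expects `images/` (PNG/JPEG), optional `masks/` (8-bit grayscale
PNG, tri-level: ≤64 cup, 65–192 disc, >192 background — thresholds
configurable via `mask_encoding()`), `fovea.csv`
(`image_id,fovea_x,fovea_y`, 0-based pixels, x = column, in the original
resolution) and `labels.csv` (`image_id,glaucoma`). To convert the REFUGE
challenge annotations: export the fovea-localization spreadsheet columns
(image name, Fovea_X, Fovea_Y) to `fovea.csv` (drop the file extension from
the id, subtract 1 if the source is 1-based), the glaucoma label list to
`labels.csv`, and place the provided Disc_Cup segmentation PNGs under
`masks/` named after the image id. An optional `splits.csv`
(`image_id,split` with train/val/test) carries the official split tags.
Everything is resized on load (bilinear for images, nearest for masks,
coordinates rescaled alongside).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

rebuilds the pinned architectures from scratch with the installed package
and recomputes the two analytic model-size quantities — the multi-task
parameter total (in millions) and the single-task/multi-task parameter
ratio — writing them as JSON.
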