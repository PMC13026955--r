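# lbpfuse

Dual-branch RGB–texture fusion networks for small multi-class clinical
image datasets, in R.

Ophthalmic conditions that present on external eye photographs — uveitis,
conjunctivitis, cataract, eyelid disorders — differ jointly in *colour*
(redness, haze) and *surface texture* (speckle, clouding, skin folds).
Colour-only CNN pipelines under-use the second signal. `lbpfuse` implements
a mid-level fusion classifier that processes each image twice:

* an **RGB branch**: a pretrained-style backbone feature extractor with
  global average pooling (1792-d under the EfficientNetV2-S feature
  contract; a compact stand-in backbone is bundled for fully offline use);
* a **texture branch**: grayscale → uniform Local Binary Pattern codes
  (P = 8, R = 1; 59 bins), rescaled to an 8-bit plane, then
  `[conv3×3 → BN → ReLU → maxpool2×2] × 3` widening 1→16→32→64, a
  squeeze-and-excitation gate (64→4→64), adaptive 4×4 pooling → 1024-d.

The branch vectors are concatenated (2816-d) and classified by an affine
head. At a pixel the LBP code is

    LBP(x_c, y_c) = Σ_{p=0..7} s(g_p − g_c) · 2^p ,   s(x) = 1 if x ≥ 0 else 0,

and codes with at most two circular bit transitions keep distinct bins
(58 of them), all others share a miscellaneous bin. The SE gate is
`s = σ(W₂ δ(W₁ z))` on the channel means `z_c = mean_{ij} x_c(i, j)`.
Training follows a fixed protocol: Adam with differential learning rates
(0.0002 backbone / 0.002 new layers), cross-entropy, batch 8, 25 epochs,
cosine annealing (T_max = 25), seeded stratified 70/15/15 splits. Ablation
variants (`rgb_only`, `lbp_only`, `no_se`, `full`) and dual-branch Grad-CAM
maps are built in.

The package targets folder-per-class JPEG/PNG datasets and is aimed at
researchers who want a tested, reproducible reference implementation of
LBP–CNN mid-level fusion — including its data pipeline, metrics and
explainability — rather than a production diagnostic tool.

## Worked example

Train the full variant with the bundled stand-in backbone on a seeded
synthetic five-class ocular fixture:

```r
library(lbpfuse)

dir <- tempfile()
generate_eye_fixture(dir, n_per_class = 8, seed = 11)

fit <- lbpfuse_fit(dir,
                   model = fusion_config(backbone_name = "tiny_cnn",
                                         pretrained = FALSE),
                   train = train_config(epochs = 3, seed = 7))
print(fit)
```

```
Dual-branch fusion classifier fit
Dual-branch fusion network (variant: full)
  backbone: tiny_cnn (built)  rgb dim 32
  texture branch: widths 16-32-64, SE 64->4->64, pool 4x4 -> lbp dim 1024
  head: 1056 -> 5 classes;  43881 parameters
epochs: 3 (best checkpoint at 1);  test accuracy: 0.200
```

Three epochs on 30 images is a smoke run, not a result — the per-epoch log
(`fit$logs`) shows the training loss falling (2.00 → 1.39) while the tiny
validation split still sits at chance; the end-to-end tests run the real
protocol (40 images/class, 25 epochs, 3 seeds) and reach ≥ 0.95 training /
≥ 0.80 test accuracy in the median. `summary(fit)` prints the per-class
precision/recall/F1 table, `plot(fit)` the training curves, and
`predict(fit, <images>)` class probabilities. The pieces are all exported
individually (`discover_dataset()`, `stratified_split()`, `lbp_transform()`,
`se_apply()`, `build_variant()`, `train_model()`, `classification_report()`,
`grad_cam()`, …) for use outside the one-call interface.

A command-line wrapper covering the same pipeline ships in
`inst/cli/lbpfuse`:

```sh
Rscript inst/cli/lbpfuse fixtures --out data --n 40 --seed 42
Rscript inst/cli/lbpfuse train --data data --out run --epochs 25
Rscript inst/cli/lbpfuse evaluate --checkpoint run/best.rds --data data --out report
Rscript inst/cli/lbpfuse gradcam --checkpoint run/best.rds --image img.png \
        --branch lbp --class uveitis --out cam.png
Rscript inst/cli/lbpfuse lbp-preview img.png --out codes.png
```

YAML configuration (strict schema: unknown keys are rejected) mirrors the
training protocol defaults; every run directory receives the resolved
config, split manifest, per-epoch CSV/JSON logs and checkpoints.

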