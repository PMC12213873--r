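# mtunet

A dual-encoder Mamba-Transformer U-Net for binary segmentation of
colorectal polyps in endoscopy images, implemented as a self-contained R
package: the network, its training loop, the combined BCE + Dice
objective, segmentation metrics, parameter/FLOP profiling, and a seeded
synthetic-data generator so everything is testable without external
datasets. Because no deep-learning framework is assumed, the package
ships its own small reverse-mode autodiff engine (hand-derived adjoints
for every composite operation, with a C++ kernel for the state-space
scan), which also makes the implementation fully inspectable.

It is aimed at researchers in medical image analysis who want a
readable, tested reference implementation of this architecture family —
cross-shaped strip attention, bidirectional selective state-space
(Mamba-style) vision blocks, and coordinate-attention feature fusion —
at desk scale on a CPU.

## The model

Five pyramid stages at resolutions `input / 2^i` with channel widths
32/64/128/256/512. Each stage feeds three parallel branches with its own
bilinearly downsampled, pointwise-projected input:

* a **cross-shape transformer**: pre-norm blocks
  `X' = CSA(LN(X)) + X`, `Y = MLP(LN(X')) + X'`, where CSA splits the
  `K` heads between non-overlapping horizontal and vertical strips of
  width `sw = 3` tokens (`softmax(QK'/sqrt(d_k))V` within each strip);
* a **Vision Mamba encoder**: bidirectional gated selective-SSM blocks
  `T_l = Vim(T_{l-1}) + T_{l-1}` built on the recurrence
  `h_t = exp(Δ_t A) h_{t-1} + Δ_t B_t x_t`, `y_t = C_t h_t + D x_t`,
  with input-dependent `B, C, Δ` (softplus-positive `Δ`);
* a **depthwise-separable auxiliary stream** providing convolutional
  inductive bias.

Per stage the first two branches are fused by the
**Mamba-Transformer-Merge** module: directional average pooling, four
fully connected reduction branches, and a rank-1-per-channel attention
map `O[h,w,c] = O_row[h,c]·O_col[w,c]` gating the fused features
(`X·σ(O) + X`). The decoder combines, per level, the fused map, the
upsampled previous decoder output and the auxiliary map through two 3×3
conv blocks, ending in a 1×1 binary-logit head at full resolution.

Training follows the published recipe: Adam at `1e-4` with polynomial
decay `(1 - t/T)^0.9`, loss `α·BCE + β·Dice` with `α = β = 1`.

## Worked example

Generate a synthetic dataset, train a width-reduced model for a couple
of minutes on a CPU, and evaluate it on its own training set:

```r
library(mtunet)

genDataset(synthConfig(image_size = 64L), n = 40,
           out_dir = "demo_data", seed = 7)

model <- buildModel(
  modelConfig(channels = c(8, 16, 32, 64, 128), depths = 1,
              heads = c(2, 4, 8, 8, 16), input_size = 64L),
  seed = 7)
paramCount(model)
#> [1] 1505361

tc <- trainConfig(lr = 1e-4, max_iters = 150L, batch_size = 4L,
                  resize = 64L, seed = 7)
fit <- trainModel(model, tc, "demo_data", augment = FALSE)
round(fit$log$loss[c(1, 50, 100, 150)], 3)
#> [1] 1.512 0.834 0.587 0.569

evaluateModel(fit$model, "demo_data")
#> MetricsReport over 40 images
#>      dice precision    recall    iou_fg      miou
#>    0.8684    0.8851    0.8680    0.7738    0.8649
```

The loss falls from 1.51 to 0.57 within 150 iterations and the train-set
Dice reaches 0.87: the lesions are found and delineated, with the
remaining error concentrated at the deliberately blurred boundaries.
(The acceptance suite trains for 300 iterations, which pushes the
train-set Dice further; it requires at least 0.85 across three seeds.)

Profiling the shipped full-size configuration:

```r
profileReport(modelConfig(), 256L)
#> Input 256 x 256
#> Parameters: 102.2 M (102208449)
#> Forward MACs: 67.6 G;  FLOPs (2/MAC): 135.1 G
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "mtunet.R", package = "mtunet")` with subcommands
`synth`, `train`, `predict`, `evaluate`, `profile`.

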