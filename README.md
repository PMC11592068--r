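# ucapsnet

Two-stage deep-learning analysis of grayscale breast ultrasound images in R:
an **enhanced U-Net** segments the lesion into a binary mask, and a
**capsule network** classifies the predicted mask as *benign* or
*malignant*. The package is aimed at researchers who want a fully
inspectable, dependency-light reimplementation of this two-stage
architecture — every layer, gradient and training step is ordinary R/C++
code — together with a synthetic phantom generator so the entire pipeline
can be trained, evaluated and regression-tested without any external
dataset.

## The model

**Stage 1 — segmentation.** An encoder–decoder U-Net with skip
connections: four encoder blocks of paired 3×3 convolutions (batch
normalization after the first, ReLU activations, He-normal initialization)
each followed by 2×2 max-pooling; a 1024-filter bottleneck; four decoder
blocks (2×2-stride-2 transpose convolution, concatenation with the matching
encoder features, two 3×3 convolutions, dropout); and a 1×1 sigmoid output
convolution. Filters start at 64 and double per block. Training minimizes
pixelwise binary cross-entropy with Adam; masks are thresholded at
p ≥ 0.5.

**Stage 2 — classification.** Predicted 256×256 masks are downsampled to
128×128, replicated to three channels, and fed to a capsule network:

- a padded stem (zero-pad 3 → 7×7 stride-2 convolution with 64 filters and
  9408 weights → batch norm → ReLU → zero-pad 1 → 3×3 stride-2 max-pool),
- a DenseNet-style block of four composite layers
  (BN → ReLU → 1×1 conv → BN → ReLU → 3×3 conv, concatenated with the layer
  input; growth rate 32, ending at 32×32×192),
- **primary capsules**: the feature volume reshaped into 24 576 vectors of
  dimension 8, each passed through the squash nonlinearity
  `squash(s) = (‖s‖²/(1+‖s‖²)) · s/(‖s‖+ε)`,
- **dynamic routing by agreement** to two 16-dimensional class capsules:
  coupling coefficients `c_i = softmax(b_i)` aggregate prediction vectors
  `û_{j|i} = W_{ij} u_i`, and logits `b_ij` grow with the agreement
  `û_{j|i} · v_j` over three iterations,
- the **margin loss**
  `L = Σ_k y_k max(0, m⁺−a_k)² + λ Σ_k (1−y_k) max(0, a_k−m⁻)²`
  on the class-capsule activations `a_k = ‖v_k‖`
  (m⁺ = 0.9, m⁻ = 0.1, λ = 0.5), with a small dense softmax head
  calibrating the activations into class probabilities.

Evaluation uses Dice, foreground mean IoU, pixel accuracy, per-class
precision/recall/F1, confusion matrices, and stratified k-fold
cross-validation.

## Worked example

Train and evaluate the whole pipeline on 150 synthetic phantoms
(50 per class; benign phantoms carry a smooth hypoechoic ellipse, malignant
ones a spiculated star, normal ones no lesion, all under multiplicative
gamma speckle):

```r
library(ucapsnet)

data <- make_dataset(50, phantom_config(size = 128, seed = 11))
manifest <- run_two_stage(
  data,
  seg_config(input_size = 128, base_filters = 8, depth = 3),
  caps_config(input_size = 64, dense_layers = 2, primary_caps_dim = 4),
  train_config(learning_rate = 1e-3, epochs = 8,  batch_size = 5),
  train_config(learning_rate = 2e-3, epochs = 15, batch_size = 10),
  seed = 123)
print(manifest)
#> two-stage run manifest
#>   master seed: 123 | train n=76, test n=24
#>   stage 1: mean Dice 0.9372, mean IoU 0.8822, pixel acc 0.9870
#>   stage 2: held-out accuracy 0.9167
```

Stage 1 recovers the lesion masks of the 24 held-out phantoms with a mean
Dice of 0.94; stage 2, trained only on the *predicted* masks, classifies
92% of them correctly (chance is 50%). The architecture trace of the
full-size classifier is available without instantiating weights:

```r
build_capsnet(caps_config())
#> network_spec: 42 layers, 6,510,534 parameters
#>          layer            kind        output_shape    params
#>          input           input (None, 128, 128, 3)         0
#>      stem_pad1        zeropad3 (None, 134, 134, 3)         0
#>      stem_conv       conv7x7s2  (None, 64, 64, 64)     9,408
#>        stem_bn       batchnorm  (None, 64, 64, 64)       256
#> ...
```

A command-line wrapper with `synth`, `inspect`, `train-seg`, `predict`,
`train-cls`, `run` and `eval` subcommands is installed at
`system.file("cli", "ucapsnet.R", package = "ucapsnet")`.

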