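---
title: "Methods: dense-block U-Net segmentation of retinal vessels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dense-block U-Net segmentation of retinal vessels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Retinal blood vessels photographed through the pupil are thin (1-8 px at
DRIVE resolution, down to a single pixel at capillary ends), darker than the
surrounding tissue, and embedded in images with low contrast and uneven
illumination. Pixel-level vessel segmentation against an expert "gold
standard" annotation is the standard computational task on such images;
`retseg` implements one complete recipe for it: classical contrast
enhancement, random patch amplification, a dense-block U-Net trained with
stochastic gradient descent on a soft Dice loss, overlap-averaged
whole-image reconstruction, and evaluation restricted to the camera's
field of view (FOV).

Everything runs on synthetic fundus-like images with exact ground truth,
so the pipeline is fully testable without clinical data.

## Preprocessing

Six deterministic stages map an RGB fundus photograph to a unit-range
matrix (`preprocess_pipeline()`), in this fixed order:

1. **Green channel.** Highest vessel/background contrast of the three.
2. **CLAHE** (clip 2.0, 8 x 8 tiles). Tile histograms are clipped at
   `clip` times the uniform level, the excess is redistributed evenly,
   and per-pixel mappings are bilinearly interpolated between tiles.
   *Numerical choice:* a tile with a single gray level has no contrast to
   equalize; it receives the identity mapping. Without this rule the
   clipped-redistribution mapping shifts constant regions by about two
   gray levels, which would break the flat-field fixed point and inject
   gradients at the FOV border.
3. **Median filter** (3 x 3, reflect padding). The smallest window that
   removes impulse noise without erasing 1-px vessels.
4. **Min-max normalization** `x_n = (x - min) / (max - min)` into [0, 1].
   A constant image maps to all zeros with a warning (declared degenerate
   rule; there is nothing to rescale).
5. **Adaptive gamma correction.** The literature this stage descends from
   does not print a formula, so the package uses the common mean-anchored
   rule `gamma = log(0.5) / log(mean(u))`, clamped to [0.5, 2.5]: an image
   darker than mid-gray gets `gamma < 1` (brightened toward mean 0.5), a
   bright image is compressed gently, and `mean = 0.5` is the exact fixed
   point `gamma = 1`. Means of 0 or 1 degenerate to the nearest bound with
   a warning.
6. **Multi-scale top-hat enhancement.**
   `f_T = I + k * sum_i w_i (WTH_i(I) - BTH_i(I))` over four disk scales,
   where `WTH = I - opening(I)` collects bright detail and
   `BTH = closing(I) - I` dark detail. The scale radii {1, 2, 3, 4},
   weights 1/4 each and `k = 1` are package defaults (the four-scale form
   is fixed; radii and weights are not published), chosen to span the
   vessel-width range. The result is clipped to [0, 1], as is the gamma
   stage; clipping is what keeps the unit-range invariant true.

Open design point resolved here: the enhancement stage operates on the
gamma-corrected image (stages run exactly in the listed order), not on the
raw green channel. The symbol `k` above is the detail factor
(`enhance_k` in configuration), unrelated to the network growth rate.

The whole pipeline is pure: identical input and configuration produce
bitwise identical output, which the tests assert.

## Patch amplification

Training does not use whole images but 48 x 48 patches whose centers are
drawn uniformly at random; at the DRIVE-default configuration 190,000
patches are drawn, 9,500 from each of 20 training images. Three decisions:

* Patch centers are restricted so the window lies fully inside the image
  (no padding scheme is invented).
* Patches are sampled from the whole rectangle, not only the FOV; the FOV
  enters at evaluation (and optionally at inference), not sampling.
* No class balancing, vessel-centered oversampling, or geometric/
  photometric augmentation — amplification is purely random cropping.

`patch_set` objects are stored *lazily*: per-patch corners plus references
to the source images, with pixels materialized per mini-batch
(`patch_arrays()`). 190,000 dense float patches would occupy ~3.5 GB;
corners occupy ~1.5 MB, and every contract (index alignment, bit-exact
conservation of label crops, exact counts, seeded reproducibility) holds
unchanged. NPZ caches (`save_patch_cache()`, datasets `patches`, `labels`,
`meta`) materialize the pixels and are meant for modest subsets.

## The network

`build_network()` assembles an encoder-decoder of dense blocks:

* **Dense block**: `L` layers, each the composite BN -> ReLU -> 3x3 conv
  emitting `k` (growth rate) channels; the input of layer `l` is the
  concatenation of the block input and all previous layer outputs, so it
  sees `k0 + k(l-1)` channels and the block emits `k0 + kL`. (The
  conventional printed channel-count formula `k0 + k(L-1)` is read as the
  input to the `L`-th layer, not the block output; the package's
  `dense_block_plan()` documents and tests this interpretation rather than
  silently "correcting" it.)
* **Transition down**: BN -> ReLU -> 1x1 conv halving the channels -> 2x2
  average pooling.
* **Transition up**: 2x2 stride-2 transposed convolution, also halving
  the channels. Symmetric 0.5 compression on both paths is the package's
  choice (only the operator type is fixed by the method description); it
  keeps the expansion path tractable on a CPU, and the channel algebra is
  frozen in `layer_plan()` which the tests check against the built weights.
* After each transition up, the pre-pooling encoder feature map is
  concatenated (U-Net skip), followed by a dense block.
* **Head**: 1x1 convolution to one channel + sigmoid, matching the scalar
  per-pixel probability in the Dice loss (not a 2-class softmax).

The reference layer diagram of the source method is not legible in print,
so the depth is parameterized (`network_spec`): defaults `k = 12`, `L = 4`,
2 down-blocks, `k0 = 16` — small enough to train on 48 x 48 patches on one
CPU. The network is fully convolutional; any input with sides divisible by
`2^n_blocks_down` is accepted, which is what makes whole-image inference
possible.

No deep-learning framework exists in the target environment, so forward
and backward passes are hand-assembled from C++ primitives (im2col + BLAS
GEMM convolutions, fused BN+ReLU). The backward pass is verified against
central finite differences through the entire network in the test suite
(worst relative error ~1e-8 at double precision); this, not a framework's
autograd, is the correctness anchor.

## Dice loss and its gradient

With predictions `p` in [0,1] and binary truth `g` over `N` pixels:

    D = (2 sum(p g) + eps) / (sum(p^2) + sum(g^2) + eps)
    dD/dp_j = 2 [ g_j (sum p^2 + sum g^2) - 2 p_j sum(p g) ]
                / (sum p^2 + sum g^2)^2

Only about 10% of fundus pixels are vessel, and a cross-entropy loss at
that imbalance is dominated by the background; the Dice overlap is
invariant to the number of true negatives, which is why it is the training
loss here. Decisions the method description leaves open:

* **Loss form**: `loss = 1 - D` (bounded in [0, 1]), not `-D` or `-log D`.
* **Smoothing**: `eps = 1` is added to numerator and denominator of the
  training loss. At 10% prevalence many 48 x 48 patches contain no vessel
  at all; with `eps = 0` their loss is undefined (0/0). `eps = 1` makes an
  all-background patch with near-zero predictions a near-zero loss. The
  printed formula is exactly recovered at `eps = 0`, which is the default
  of `dice_coefficient()`/`dice_gradient()`; only the trainer defaults to 1.
* **Aggregation**: Dice is computed per patch and averaged over the batch
  (matching patch-wise training), not pooled globally.

The gradient enters the network through the sigmoid head,
`dL/dz = -dD/dp * p(1-p)`.

## Training

Plain SGD with momentum; per-epoch reshuffling, initialization and the
loss trajectory all derive from one seed. Defaults `lr = 0.01`,
`momentum = 0.9`, `batch_size = 32`, `epochs = 20` are conventional values
(none are published for this method), all exposed in `train_config()`.
Model selection keeps the weights with the best validation Dice (the
method description is silent; best-checkpoint retention is the safe
default), written as an NPZ checkpoint with the spec embedded. There is no
learning-rate schedule. A non-finite loss aborts immediately, naming the
epoch and batch.

## Whole-image inference

Training is patch-wise and the source method does not describe
reconstruction, so `predict_image()` defines it: the image is
reflect-padded so a `patch_size` window stepped by `stride` tiles it
exactly; each pixel's probability is the mean over all covering windows;
padding is then discarded and FOV-exterior pixels are zeroed. The default
`stride = 8` smooths patch-border seams; cost grows as `1/stride^2`, and
the scaled-down tests use stride 24 for budget reasons (stride affects
seam smoothness, not the ranking quality that AUC measures, and the
stride-invariance and single-cover contracts are tested separately).
`binarize()` thresholds at 0.5 by default — the natural operating point of
a sigmoid head, configurable.

## Evaluation

Vessel is the positive class. Accuracy, specificity, sensitivity and PPV
are the exact confusion-count ratios; the ROC sweeps every distinct
probability value (ties grouped, one step per distinct value) and AUC is
the trapezoidal integral, which equals the Mann-Whitney pair-concordance
statistic with half credit for ties — the test suite checks this identity
against exhaustive pair counting.

All metrics are restricted to in-FOV pixels. The source method does not
state this, but it is the long-standing convention for DRIVE-style
evaluation; including the black region outside the camera aperture would
inflate accuracy and specificity with trivially correct negatives, so the
choice is documented prominently here. Whether published AUCs pool test
pixels or average per image is likewise unstated; `run_pipeline()` reports
the pooled value as the headline and per-image values alongside.

## The synthetic world

`generate_dataset()` emulates exactly the properties the pipeline depends
on, at DRIVE geometry (565 x 584) by default:

* branching vessel trees grown from the FOV boundary by random walks:
  per-step heading jitter, bifurcation with probability 0.08/step, both
  daughter widths scaled by 0.7, slow taper along the length, termination
  below 1 px width or at the FOV boundary — giving the 1-8 px width range
  including single-pixel terminal twigs;
* vessels rendered *darker* than background in the green channel
  (contrast 70 of 255), as in real fundus photographs;
* a radial illumination falloff (30% at the FOV edge) and additive
  Gaussian noise (sigma 8);
* a circular FOV of radius 0.48 x min(H, W);
* trees are added until the in-FOV vessel fraction reaches the 10% target
  mirroring the real class-imbalance statistic, so the Dice-vs-imbalance
  rationale is actually exercised.

What it does **not** emulate: optic disc and fovea, lesions and exudates,
texture, color fidelity, inter-image variability of real cohorts. A green
test on this world therefore establishes that the machinery — enhancement,
sampling, optimization, stitching, masked scoring — is correct and learns
a separable vascular pattern; it does not establish clinical-grade
accuracy. The published full-DRIVE figures of this method family
(Acc 0.9698, Sp 0.9896, Sn 0.7931, PPV 0.8946, AUC 0.9738) are retained in
the README as an external benchmark that requires the real dataset and an
unpublished training recipe; they are deliberately not an automated test.

## Numerical choices and degenerate inputs

* BN uses eps 1e-5 and running-statistic momentum 0.1; inference uses
  running statistics, training uses batch statistics.
* He initialization for all convolutions, from the seed.
* Ratio metrics with a zero denominator return NaN with a warning
  (all-zero confusion counts are an error); single-class ROC is an error.
* Binary masks on disk are {0, 255} 8-bit PNG and round-trip bit-exactly;
  labels with more than two raw values are rejected, not thresholded.
* All derived seeds are kept below 2^31 and fan out from one global seed
  through a portable string-label hash, so every stage is independently
  reproducible.

## Known limitations

* Image IO is PNG-only: no TIFF/GIF reader exists in the supported
  R environment, so DRIVE's native files need a one-off conversion.
* CPU-only; at full DRIVE scale (190,000 patches, default network, many
  epochs) training is out of desk-test scope by design.
* No test-time augmentation, CRF post-processing, vessel-topology metrics,
  or support for STARE/CHASE_DB1 layouts.
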