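---
title: "Dense shifted-attention regression for 3D hand pose: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense shifted-attention regression for 3D hand pose: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarn)
```

## The estimation problem

A depth camera observes a hand as a single-channel raster whose pixels
store distance in millimeters; every valid pixel is therefore a point on
the hand surface in the camera frame. The task is to recover the 3D
positions of J skeletal keypoints (joint centers and fingertips) from one
such frame. The package implements a two-stage dense-regression estimator:
rather than regressing coordinates directly, every pixel in a normalized
hand crop votes for every keypoint, and the votes are pooled by a learned
attention map. Differentiable pooling means the whole chain — backbone,
dense heads and the final coordinate estimate — trains end to end.

## Dense representation

Work happens in normalized crop coordinates: a cube of edge `cube_mm`
(default 250 mm) centered on the hand is cropped, resampled to
`out_size` (128 px by default, 64 px in the desk-scale configurations)
and depth-normalized so the cube spans $[-1, 1]$ on every axis. A
half-resolution grid stores the 3D position $p$ of each retained pixel.

For keypoint $j$ at position $p_j$, a pixel $p$ with
$\lVert p - p_j \rVert \le \theta$ is a *supporting* pixel. Its offset
$p - p_j$ is stored decomposed into

* a **spatial closeness** $S_j(p) = (\theta - \lVert p-p_j \rVert)/\theta
  \in [0,1]$, and
* a **direction** $V_j(p) = (p - p_j)/\lVert p - p_j \rVert$, a unit
  vector;

both are defined as zero outside the support. At $p = p_j$ the direction
is undefined; we set $V = 0$ there, which keeps the encoding total and —
because that pixel's offset term is multiplied by $V$ — leaves the
decoding identity exact. The support radius $\theta$ is a tunable with
default 0.64 in normalized units (≈ 80 mm for a 250 mm cube): small
enough that supports are local, large enough that every keypoint of a
hand-sized object keeps a nonempty support at half resolution.

The decoder inverts the encoding by attention-weighted voting:

$$\bar p_j = \sum_p \big( (\theta S_j(p) - \theta)\, V_j(p) + p \big)
  H_j(p),$$

where $H_j$ is a nonnegative weight map summing to one over valid
pixels. With ground-truth $S$ and $V$, every supporting pixel's vote is
exactly $p_j$, so *any* attention confined to the support reproduces the
keypoints to machine precision. This identity is the package's master
oracle: encode–decode round trips are tested to $10^{-9}$.

**Attention normalization.** The decoder needs $\sum_p H_j(p) = 1$. We
clamp negatives, zero invalid pixels and divide by the exact channel sum
(uniform over valid pixels if a channel has no mass). A softmax would
also work but destroys exact zeros outside the support, which the
identity above relies on; sum-normalization preserves them.

**Shifted attention.** The network predicts two heatmaps per keypoint: a
supervised closeness map $\bar S_j$ and an unsupervised *geometry
closeness* map $G_j$ free to discover informative pixels that are not
spatially close (e.g. palm pixels that constrain an MCP joint). They are
fused channel-wise, $H_j = \alpha_j \bar S_j + (1-\alpha_j) G_j$, with a
learnable per-keypoint, per-stage $\alpha_j$. We store $\alpha$
unconstrained and squash it through a sigmoid so the fusion stays a
convex combination throughout training; $\alpha$ is initialized at
$\operatorname{sigmoid}(2) \approx 0.88$ so early attention leans on the
supervised map while the unsupervised branch is still noise.

## Architecture

The stem is a 7×7 stride-2 convolution (+ BN + ReLU) into one
squeeze-and-excitation residual block, producing C feature maps at half
resolution. Each stage runs an SE-hourglass — a symmetric
encoder–decoder with an identity skip at every level, max-pool descent,
nearest-neighbour ascent, and SE-residual blocks throughout — followed by
a dense-extraction head: an SE-residual block and a 3×3 conv–BN–ReLU
feature layer, then three parallel 1×1 branches emitting $\bar V$ (3J
channels, linear), $\bar S$ (J channels, sigmoid) and $G$ (J channels,
sigmoid). The $\bar V$ branch is zero-initialized, so the first
integrated estimates degenerate to attention centroids of pixel
positions — a stable starting point; predictions are used raw in the
decoder (no per-pixel renormalization to unit length).

Two stages are connected by **soft input aggregation**:
$I_2 = \mathrm{conv}_a(I_1) + \mathrm{conv}_f(F_1) +
\mathrm{conv}_{vh}(\mathrm{concat}(\bar V_1, H_1)) + \beta \odot I_1$,
with a learnable channel-wise factor $\beta$ initialized at 1 (an
identity-like start). Supervision attaches to the *second* stage's dense
maps and to the integrated keypoints; the first stage's heads train
through the aggregation path.

Because no deep-learning runtime exists in this R stack, the package
carries its own reverse-mode autodiff tape and im2col/GEMM convolution
kernels (compiled C++ gathers + BLAS matrix products). Every primitive
is validated against central finite differences, as is the whole network
including $\alpha$ and $\beta$.

## Losses and optimization

Both supervisions use the smooth-L1 penalty with transition $\delta = 1$.
The dense term is the mean over all map elements of
$\mathrm{smooth}_{L1}(S - \bar S_2) + \mathrm{smooth}_{L1}(V - \bar V_2)$;
the coordinate term sums over keypoints the component-mean smooth-L1 of
$p_j - \bar p_j$ (and averages over the batch). Means keep both terms
O(1) in normalized units, so the mixing weight $\sigma = 0.5$ treats them
evenly. Optimization is Adam at learning rate 0.001, batch 20, with an
epoch-level plateau schedule on the training loss: no improvement for 3
epochs multiplies the rate by 0.7. Epoch presets: 25 for large
varied-pose data, 35 for tapping-style data; desk-scale runs below use
far fewer.

Augmentation draws an in-plane rotation in $[-180°, 180°]$, a uniform 3D
scale in $[0.9, 1.1]$ and a translation of up to ±10 crop pixels, applies
the same transform to image, point grid and keypoints, and **re-encodes**
the dense target from the transformed geometry instead of warping target
maps — exactness over speed. At the point-set level the transform is
exact; the image raster is warped by nearest neighbour, which is the same
order of approximation as the original crop resampling. Translations are
interpreted in crop pixels and converted to normalized units by
`2 * px / out_size`; scale also scales normalized depth values (the cube
follows the hand).

## Synthetic test bed

The generator replaces external benchmark data. A minimal right hand —
three thick palm capsules, a two-segment thumb, a three-segment index
finger — is posed by forward kinematics and rendered by exact
ray–capsule intersection with a z-buffer into calibrated 128×128 depth
frames (depth quantized to 1 mm, matching the 16-bit raster format).
Pose mode annotates J = 6 keypoints (palm, wrist, thumb MCP/tip, index
MCP/tip); tapping mode drives the index flexion so the thumb–index
distance follows a rectified-sinusoid open/close profile (peak =
`amplitude`, default 55 mm, ten taps by default), solving the flexion
angle per frame by monotone root finding so the commanded and realized
distances agree to $10^{-6}$ mm. An odd `frames_per_tap` (default 11)
places the apex exactly on the frame grid.

What the generator does *not* emulate: sensor noise models, forearm and
clutter, five-finger self-occlusion diversity, and real skin geometry.
Passing tests therefore demonstrate the correctness of the machinery and
the learnability of the representation on clean articulated geometry,
not benchmark-level accuracy on real depth data.

## Desk-scale study configurations

Tests and the acceptance script use a reduced configuration chosen to fit
a single CPU: C = 32 channels, 64 px crops, hourglass depth 3, J = 6,
300 training / 100 held-out frames for generalization, 8 training epochs
at batch 20, and an 8-frame / 200-step run for the overfit check. A
constant-center baseline (predicting the crop center for every keypoint)
anchors the generalization comparison.

## Numerical choices and degenerate inputs

* Pixel convention: 0-based, (u, v) = (column, row), centers on integers;
  nearest-neighbour crop resampling avoids phantom depths at silhouette
  edges.
* Out-of-cube and invalid pixels take the background value +1; the
  half-resolution validity mask is false exactly where depth is 0 or the
  back-projected point leaves the cube.
* Attention channel sums are divided exactly (no epsilon) — positivity is
  guaranteed in-network by the sigmoid heads; the standalone normalizer
  falls back to uniform on zero mass and errors when no pixel is valid.
* Max-pool ties route gradients to the first maximum in a fixed scan
  order; batch-norm uses population variance with $\varepsilon = 10^{-5}$
  and momentum 0.1 running moments for inference.
* Tap segmentation smooths the distance with a 3-frame moving average for
  extremum detection only; rest is any window whose raw range stays under
  `rest_threshold` (default 3 mm). Apex frames belong to both phases; the
  closed-position frame shared by consecutive taps is labeled as the next
  tap's 0 %.
* Velocity/acceleration errors compare the scalar distance-derivative
  series (magnitudes of the relative movement), not 3D velocity vectors.

## Known limitations

The hand-center localizer is a depth-window centroid heuristic (window
[200, 1500] mm), adequate for uncluttered synthetic scenes but not a
substitute for a learned detector on real data. Training is
single-device and double-precision; at research scale (128 px crops,
C = 128, tens of thousands of frames) a GPU framework would be the
practical choice. The success-rate default follows the stricter
worst-keypoint reading ("frames with *each* keypoint error below the
threshold"); the per-keypoint variant is available for comparability.
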