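# sarn — shifted-attention dense regression for 3D hand pose from depth images

Estimating the 3D positions of hand keypoints (fingertips and joint
centers) from a single depth frame is the core measurement problem behind
camera-based movement assessment — for example the finger-tapping test of
neurological exams, where the kinematics of the thumb–index distance
index bradykinesia. This package implements a two-stage dense-regression
estimator for that problem, together with the full preprocessing,
training, evaluation and finger-tapping analysis chain, and a synthetic
articulated-hand depth generator so everything runs end to end on one CPU
with no external data.

## The method

Every pixel of a normalized hand crop is back-projected to a 3D point
$p$ and votes for every keypoint $j$ through a dense decomposition of the
3D offset field (support radius $\theta$):

$$S_j(p) = \frac{\theta - \lVert p - p_j\rVert}{\theta}, \qquad
  V_j(p) = \frac{p - p_j}{\lVert p - p_j \rVert}
  \quad (\lVert p - p_j \rVert \le \theta,\ \text{else } 0),$$

and keypoints are recovered by attention-weighted pooling of the votes

$$\bar p_j = \sum_p \big((\theta \bar S_j(p) - \theta)\,\bar V_j(p) + p\big)\, H_j(p),$$

where the *shifted attention* heatmap
$H_j = \alpha_j \bar S_j + (1 - \alpha_j) G_j$ blends the supervised
closeness map with an unsupervised geometry-closeness map through a
learnable per-keypoint weight. The backbone is a squeeze-and-excitation
hourglass; two stages are linked by a soft input-aggregation connector
$I_2 = \mathrm{conv}(I_1) + \mathrm{conv}(F_1) +
\mathrm{conv}(\bar V_1, H_1) + \beta \odot I_1$. Training minimizes
$\sigma L_{dense} + (1-\sigma) L_{coord}$ (smooth-L1, $\sigma = 0.5$)
with Adam (lr 0.001, batch 20, plateau decay 0.7 after 3 flat epochs).
The network, its reverse-mode autodiff and the convolution kernels are
implemented in this package (R + compiled C++ gathers + BLAS); see the
methods vignette `vignettes/dense-hand-pose.Rmd` for assumptions,
parameter defaults and design rationale.

## Worked example

```r
library(sarn)

# synthetic annotated hands, desk-scale model
train <- prepare_samples(generate_pose_dataset(300, seed = 101),
                         cube_mm = 250, out_size = 64)
test  <- prepare_samples(generate_pose_dataset(100, seed = 202),
                         cube_mm = 250, out_size = 64)
cfg <- model_config(C = 32, J = 6, stages = 2, hourglass_depth = 3,
                    se_ratio = 8, theta = 0.64, out_size = 64)
fit <- train_model(train, sarn_init(cfg, seed = 1),
                   train_config(batch = 20, epochs = 8, seed = 1),
                   verbose = TRUE)
#> epoch   1  lr 1.00e-03  loss 0.12641 (dense 0.14272 coord 0.11010)
#> ...
#> epoch   8  lr 1.00e-03  loss 0.02042 (dense 0.03485 coord 0.00599)

pred <- predict_keypoints(fit$model, lapply(test, `[[`, "crop"))
truth <- array(0, dim(pred))
for (i in seq_along(test)) truth[i, , ] <- test[[i]]$keys_world
keypoint_errors(pred, truth)$overall
#> [1] 10.36
```

The per-epoch lines report the training loss and its dense/coordinate
components in normalized crop units; the final number is the all-keypoint
mean error in millimeters on 100 held-out frames — against 39.75 mm for
the constant-center baseline that predicts the crop center for every
keypoint.

For tapping analysis:

```r
ts <- generate_tap_sequence(tap_motion_config(taps = 10, seed = 1))
kin <- tap_kinematics(ts$truth)      # distance / velocity / acceleration
label_phases(kin$distance)$n_taps
#> [1] 10
```

A command-line interface wraps the same functions
(`inst/cli/sarn synth|train|predict|evaluate|tap-metrics`).

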