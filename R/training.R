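# Losses, geometric augmentation and the Adam training loop.
#
# The dense supervision attaches to the last stage's S and V maps; the
# coordinate supervision to the integrated keypoints. Both use the smooth-L1
# (Huber) penalty and are combined as sigma * L_dense + (1 - sigma) *
# L_coord. Reductions: mean over all map elements for the dense terms, sum
# over keypoints with mean over the three components (and the batch) for the
# coordinate term, keeping both O(1) in normalized crop units.

#' Loss weights
#'
#' @param sigma Weight of the dense term in the total loss, in [0, 1].
#' @param smooth_l1_delta Transition point of the smooth-L1 penalty.
#' @return A `loss_weights` object.
#' @export
loss_weights <- function(sigma = 0.5, smooth_l1_delta = 1) {
  stopifnot(sigma >= 0, sigma <= 1, smooth_l1_delta > 0)
  structure(list(sigma = sigma, smooth_l1_delta = smooth_l1_delta),
            class = "loss_weights")
}

#' Smooth-L1 (Huber) penalty
#'
#' Elementwise `0.5 x^2 / delta` for `|x| < delta`, else `|x| - delta/2`;
#' reduced by the mean unless `reduction = "sum"`.
#'
#' @param residual Numeric vector/array of residuals.
#' @param delta Transition point.
#' @param reduction `"mean"` or `"sum"`.
#' @return Scalar loss.
#' @export
smooth_l1 <- function(residual, delta = 1, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  a <- abs(residual)
  v <- ifelse(a < delta, 0.5 * residual^2 / delta, a - 0.5 * delta)
  if (reduction == "mean") mean(v) else sum(v)
}

#' Dense-map supervision loss
#'
#' `smooth_l1(S - S_pred) + smooth_l1(V - V_pred)`, each term a mean over
#' its map.
#'
#' @param S_pred,V_pred Predicted closeness and direction maps.
#' @param target A `dense_target` (or any list with `S` and `V` of matching
#'   shapes).
#' @param delta Smooth-L1 transition point.
#' @return Scalar loss (0 iff predictions equal targets).
#' @export
dense_loss <- function(S_pred, V_pred, target, delta = 1) {
  if (!identical(dim(S_pred), dim(target$S)) ||
      !identical(dim(V_pred), dim(target$V))) {
    stop("dense_loss: shape mismatch with target")
  }
  smooth_l1(target$S - S_pred, delta) + smooth_l1(target$V - V_pred, delta)
}

#' Keypoint-coordinate supervision loss
#'
#' Sum over keypoints of the smooth-L1 of the 3-vector residual, with the
#' mean taken over the three components.
#'
#' @param pred,truth J x 3 matrices of keypoint positions.
#' @param delta Smooth-L1 transition point.
#' @return Scalar loss.
#' @export
coord_loss <- function(pred, truth, delta = 1) {
  if (!all(dim(pred) == dim(truth))) stop("coord_loss: keypoint mismatch")
  sum(apply(pred - truth, 1, function(r) smooth_l1(r, delta)))
}

#' Total training loss
#'
#' @param dense,coord Scalar loss terms.
#' @param w A [loss_weights()].
#' @return `sigma * dense + (1 - sigma) * coord`.
#' @export
total_loss <- function(dense, coord, w = loss_weights()) {
  w$sigma * dense + (1 - w$sigma) * coord
}

#' Augmentation parameters
#'
#' @param rot_deg In-plane rotation range in degrees.
#' @param scale Uniform 3D scale range.
#' @param trans Translation range in crop pixels (at the crop resolution).
#' @return An `augment_params` object.
#' @export
augment_params <- function(rot_deg = c(-180, 180), scale = c(0.9, 1.1),
                           trans = c(-10, 10)) {
  stopifnot(rot_deg[1] <= rot_deg[2], scale[1] <= scale[2],
            trans[1] <= trans[2])
  structure(list(rot_deg = rot_deg, scale = scale, trans = trans),
            class = "augment_params")
}

#' Training configuration
#'
#' @param lr Initial Adam learning rate.
#' @param batch Batch size.
#' @param epochs Number of epochs.
#' @param plateau_factor Learning-rate multiplier on plateau.
#' @param plateau_patience Epochs without improvement before decaying.
#' @param schedule Logical; disable to keep the learning rate fixed.
#' @param sigma Dense/coordinate loss mix (see [loss_weights()]).
#' @param seed Integer seed controlling shuffling and augmentation.
#' @return A `train_config` object.
#' @export
train_config <- function(lr = 0.001, batch = 20L, epochs = 25L,
                         plateau_factor = 0.7, plateau_patience = 3L,
                         schedule = TRUE, sigma = 0.5, seed = 1L) {
  stopifnot(lr > 0, batch >= 1, epochs >= 1)
  structure(list(lr = lr, batch = as.integer(batch),
                 epochs = as.integer(epochs),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 schedule = isTRUE(schedule), sigma = sigma,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Plateau learning-rate scheduler
#'
#' Multiplies the learning rate by `factor` whenever the monitored loss has
#' not improved for `patience` consecutive steps.
#'
#' @param lr0 Initial learning rate.
#' @param factor Decay factor.
#' @param patience Steps without improvement tolerated before decay.
#' @return An environment with `step(loss) -> lr` and field `lr`.
#' @export
plateau_scheduler <- function(lr0 = 0.001, factor = 0.7, patience = 3L) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr0
  e$best <- Inf
  e$bad <- 0L
  e$step <- function(loss) {
    if (loss < e$best - 1e-12) {
      e$best <- loss
      e$bad <- 0L
    } else {
      e$bad <- e$bad + 1L
      if (e$bad >= patience) {
        e$lr <- e$lr * factor
        e$bad <- 0L
      }
    }
    e$lr
  }
  e
}

## ---- augmentation --------------------------------------------------------

rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

# Nearest-neighbour image warp for the crop raster under the same in-plane
# transform applied to the geometry: rotation about the crop center, zoom
# by the scale factor, translation in pixels. Depth values of valid pixels
# are scaled by s (the cube scales with the hand); background stays +1.
warp_crop_image <- function(img, valid, deg, s, t_px) {
  os <- nrow(img)
  ctr <- (os + 1) / 2
  idx <- seq_len(os) - ctr
  # inverse map: src = R(-deg) %*% ((dst - t) / s)
  co <- cos(-deg * pi / 180); si <- sin(-deg * pi / 180)
  dx <- rep(idx, each = os) - t_px[1]   # dst x (columns)
  dy <- rep(idx, os) - t_px[2]          # dst y (rows), row index grows down
  sx <- (co * dx - si * dy) / s
  sy <- (si * dx + co * dy) / s
  ci <- round(sx + ctr); ri <- round(sy + ctr)
  ok <- ci >= 1 & ci <= os & ri >= 1 & ri <= os
  out <- matrix(1, os, os)
  outv <- matrix(FALSE, os, os)
  lin <- ri[ok] + (ci[ok] - 1) * os
  src_valid <- valid[lin]
  v <- img[lin]
  v[src_valid] <- pmax(-1, pmin(1, v[src_valid] * s))
  v[!src_valid] <- 1
  out[ok] <- v
  outv[ok] <- src_valid
  list(image = out, valid = outv)
}

#' Randomly augment a crop sample and its keypoints
#'
#' Draws an in-plane rotation about the camera axis through the crop
#' center, a uniform 3D scale and an in-plane translation, applies the same
#' transform to the image, the point grid and the keypoints (exactly, at
#' the point-set level), and re-encodes the dense target from the
#' transformed geometry. Translations are drawn in crop pixels and
#' converted to normalized units as `2 * px / out_size`.
#'
#' @param crop A `crop_sample`.
#' @param keys J x 3 keypoints in normalized crop coordinates.
#' @param params An [augment_params()].
#' @param theta Codec radius used to re-encode the target.
#' @param rng_draw Optionally a pre-drawn list(deg, s, t_px) overriding the
#'   random draw (used for deterministic checks).
#' @return List with the transformed `crop`, `keys` and new `target`.
#' @export
augment_sample <- function(crop, keys, params = augment_params(),
                           theta = 0.64, rng_draw = NULL) {
  if (is.null(rng_draw)) {
    rng_draw <- list(deg = runif(1, params$rot_deg[1], params$rot_deg[2]),
                     s = runif(1, params$scale[1], params$scale[2]),
                     t_px = runif(2, params$trans[1], params$trans[2]))
  }
  deg <- rng_draw$deg; s <- rng_draw$s; t_px <- rng_draw$t_px
  os <- crop$spec$out_size
  t_norm <- c(2 * t_px / os, 0)
  R <- rot_z(deg)
  tf <- function(m) {
    sweep(s * (m %*% t(R)), 2, t_norm, "+")
  }
  hs <- os %/% 2L
  pts <- crop$points
  dim(pts) <- c(hs * hs, 3L)
  pts <- tf(pts)
  keys2 <- tf(keys)
  mask <- crop$valid_mask
  # points pushed out of the cube by the transform lose validity
  inside <- matrix(rowSums(abs(pts) > 1 + 1e-9) == 0, hs, hs)
  mask2 <- mask & inside
  pts[!as.vector(mask2), ] <- 0
  w <- warp_crop_image(crop$image, crop$image_valid, deg, s, t_px)
  crop2 <- structure(list(image = w$image, spec = crop$spec,
                          points = array(pts, c(hs, hs, 3L)),
                          valid_mask = mask2, image_valid = w$valid),
                     class = "crop_sample")
  target <- encode_dense(keys2, crop2$points, mask2, theta)
  list(crop = crop2, keys = keys2, target = target)
}

## ---- optimizer -----------------------------------------------------------

adam_init <- function(P) {
  list(m = lapply(P, function(v) v * 0),
       v = lapply(P, function(v) v * 0),
       t = 0L)
}

adam_step <- function(P, G, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (k in names(P)) {
    g <- G[[k]]
    if (is.null(g)) next
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * g
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * g * g
    P[[k]] <- P[[k]] - lr * (st$m[[k]] / bc1) /
      (sqrt(st$v[[k]] / bc2) + eps)
  }
  list(P = P, st = st)
}

## ---- loss on the tape ----------------------------------------------------

# Attach the supervision to an open forward tape. Targets: S (hs,hs,N,J),
# V (hs,hs,N,3J), keys (J,3,N) in normalized crop coordinates.
build_loss <- function(out, S_t, V_t, keys_t, sigma = 0.5, delta = 1) {
  tape <- out$tape
  nS <- length(S_t)
  nV <- length(V_t)
  N <- dim(keys_t)[3]
  ls <- tp_smoothl1(tape, out$nodes$S, S_t, delta, scale = 1 / nS)
  lv <- tp_smoothl1(tape, out$nodes$V, V_t, delta, scale = 1 / nV)
  lc <- tp_smoothl1(tape, out$nodes$keypoints, keys_t, delta,
                    scale = 1 / (3 * N))
  ld <- tp_scalar_wsum(tape, list(ls, lv), c(1, 1))
  lt <- tp_scalar_wsum(tape, list(ld, lc), c(sigma, 1 - sigma))
  list(total = lt, dense = tp_val(tape, ld), coord = tp_val(tape, lc))
}

# Stack per-sample targets into batch tensors.
stack_targets <- function(targets, keys_list) {
  N <- length(targets)
  d <- dim(targets[[1]]$S)
  hs <- d[1]; J <- d[3]
  S_t <- array(0, c(hs, hs, N, J))
  V_t <- array(0, c(hs, hs, N, 3L * J))
  K_t <- array(0, c(J, 3L, N))
  for (n in seq_len(N)) {
    S_t[, , n, ] <- targets[[n]]$S
    V_t[, , n, ] <- targets[[n]]$V
    K_t[, , n] <- keys_list[[n]]
  }
  list(S = S_t, V = V_t, keys = K_t)
}

# One optimization step on an assembled batch; returns the updated model,
# optimizer state and the loss components.
train_step <- function(model, batch, S_t, V_t, K_t, st, lr, sigma = 0.5,
                       delta = 1) {
  out <- sarn_forward(model, batch, training = TRUE)
  loss <- build_loss(out, S_t, V_t, K_t, sigma, delta)
  lt <- tp_val(out$tape, loss$total)
  if (!is.finite(lt)) stop("train_step: non-finite loss")
  grads <- tp_backward(out$tape, loss$total)
  G <- lapply(out$param_nodes, function(i) grads[[i]])
  up <- adam_step(model$params, G, st, lr)
  model$params <- up$P
  list(model = model, st = up$st, total = lt, dense = loss$dense,
       coord = loss$coord, keypoints = out$keypoints)
}

#' Train a model on a dataset of annotated crop samples
#'
#' Adam optimization of the weighted dense + coordinate loss, with an
#' epoch-level plateau schedule on the training loss (factor
#' `plateau_factor`, patience `plateau_patience`).
#'
#' @param dataset List of samples, each a list with `crop` (a
#'   `crop_sample`) and `keys` (J x 3, normalized crop coordinates).
#' @param model A `sarn_model` (see [sarn_init()]).
#' @param cfg A [train_config()].
#' @param augment An [augment_params()] or `NULL` to disable augmentation.
#' @param val Optional validation dataset in the same layout; the log then
#'   carries a per-epoch mean keypoint error in normalized units.
#' @param verbose Print one line per epoch.
#' @return List with the trained `model` and a per-epoch `log` data frame
#'   (epoch, lr, loss, dense, coord, val_err).
#' @export
train_model <- function(dataset, model, cfg = train_config(),
                        augment = NULL, val = NULL, verbose = FALSE) {
  if (length(dataset) == 0) stop("train_model: empty dataset")
  theta <- model$config$theta
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  # pre-encode targets once when no augmentation perturbs the geometry
  if (is.null(augment)) {
    fixed <- lapply(dataset, function(s) {
      encode_dense(s$keys, s$crop$points, s$crop$valid_mask, theta)
    })
  }
  st <- adam_init(model$params)
  sched <- plateau_scheduler(cfg$lr, cfg$plateau_factor,
                             cfg$plateau_patience)
  n <- length(dataset)
  log <- vector("list", cfg$epochs)
  lr <- cfg$lr
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    tot <- de <- co <- 0
    nb <- 0L
    for (start in seq(1L, n, by = cfg$batch)) {
      sel <- ord[start:min(start + cfg$batch - 1L, n)]
      if (is.null(augment)) {
        crops <- lapply(dataset[sel], `[[`, "crop")
        tgts <- fixed[sel]
        keys <- lapply(dataset[sel], `[[`, "keys")
      } else {
        aug <- lapply(dataset[sel], function(s) {
          augment_sample(s$crop, s$keys, augment, theta)
        })
        crops <- lapply(aug, `[[`, "crop")
        tgts <- lapply(aug, `[[`, "target")
        keys <- lapply(aug, `[[`, "keys")
      }
      batch <- assemble_batch(crops)
      tg <- stack_targets(tgts, keys)
      res <- train_step(model, batch, tg$S, tg$V, tg$keys, st, lr,
                        cfg$sigma)
      model <- res$model
      st <- res$st
      tot <- tot + res$total; de <- de + res$dense; co <- co + res$coord
      nb <- nb + 1L
    }
    val_err <- NA_real_
    if (!is.null(val)) {
      val_err <- evaluate_dataset(model, val)$overall_norm
    }
    log[[ep]] <- data.frame(epoch = ep, lr = lr, loss = tot / nb,
                            dense = de / nb, coord = co / nb,
                            val_err = val_err)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.5f (dense %.5f coord %.5f)%s",
                      ep, lr, tot / nb, de / nb, co / nb,
                      if (is.na(val_err)) "" else
                        sprintf("  val %.4f", val_err)))
    }
    if (cfg$schedule) lr <- sched$step(tot / nb)
  }
  list(model = model, log = do.call(rbind, log))
}

#' Predict keypoints for a list of crop samples
#'
#' @param model A trained `sarn_model`.
#' @param crops List of `crop_sample` objects.
#' @param batch Mini-batch size used for inference.
#' @param world Return world-millimeter coordinates (via each sample's crop
#'   spec) instead of normalized crop coordinates.
#' @return N x J x 3 array of predicted keypoints.
#' @export
predict_keypoints <- function(model, crops, batch = 20L, world = TRUE) {
  if (inherits(crops, "crop_sample")) crops <- list(crops)
  n <- length(crops)
  J <- model$config$J
  out <- array(0, c(n, J, 3L))
  for (start in seq(1L, n, by = batch)) {
    sel <- start:min(start + batch - 1L, n)
    fo <- sarn_forward(model, assemble_batch(crops[sel]))
    for (i in seq_along(sel)) {
      kp <- fo$keypoints[, , i]
      if (world) kp <- uncrop_keypoints(kp, crops[[sel[i]]]$spec)
      out[sel[i], , ] <- kp
    }
  }
  out
}

# Mean keypoint error of a model over an annotated dataset, in normalized
# units and (when specs carry a physical cube) in millimeters.
evaluate_dataset <- function(model, dataset, batch = 20L) {
  crops <- lapply(dataset, `[[`, "crop")
  pred_n <- predict_keypoints(model, crops, batch, world = FALSE)
  n <- length(dataset)
  errs_n <- numeric(0)
  errs_mm <- numeric(0)
  for (i in seq_len(n)) {
    dtruth <- dataset[[i]]$keys
    e <- sqrt(rowSums((pred_n[i, , ] - dtruth)^2))
    errs_n <- c(errs_n, e)
    errs_mm <- c(errs_mm, e * dataset[[i]]$crop$spec$cube_mm / 2)
  }
  list(overall_norm = mean(errs_n), overall_mm = mean(errs_mm))
}
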