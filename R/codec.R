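# The dense representation: per-pixel spatial-closeness values and
# directional unit vectors encode each keypoint's 3D offset field; a
# normalized attention heatmap turns per-pixel votes back into keypoints.
# All quantities live in the same coordinate system as the point grid
# (normalized crop coordinates in the full pipeline), with the support
# radius `theta` expressed in those units.

#' Encode keypoints into the dense representation
#'
#' For every pixel p with world/crop position inside the support sphere of
#' keypoint j (radius `theta`), the spatial closeness is
#' `S_j(p) = (theta - |p - p_j|) / theta` and the direction is the unit
#' vector `V_j(p) = (p - p_j) / |p - p_j|`; both are zero outside the
#' support and at invalid pixels. At a pixel coinciding with the keypoint,
#' S = 1 and V = 0 (the zero-distance limit of the otherwise-undefined
#' direction).
#'
#' @param keys J x 3 matrix of keypoint positions.
#' @param points h x w x 3 array of pixel positions (same units as `keys`).
#' @param valid_mask h x w logical mask of usable pixels.
#' @param theta Support radius (> 0), same units as the positions.
#' @return A `dense_target`: list with `S` (h x w x J), `V` (h x w x 3J,
#'   channel 3(j-1)+k holding coordinate k of keypoint j), `support`
#'   (h x w x J logical) and `theta`.
#' @export
encode_dense <- function(keys, points, valid_mask, theta) {
  if (theta <= 0) stop("encode_dense: theta must be > 0")
  if (is.null(dim(keys))) keys <- matrix(keys, 1L)
  d <- dim(points)
  h <- d[1]; w <- d[2]
  m <- h * w
  J <- nrow(keys)
  P <- points
  dim(P) <- c(m, 3L)
  vmask <- as.vector(valid_mask)
  S <- array(0, c(h, w, J))
  V <- array(0, c(h, w, 3L * J))
  supp <- array(FALSE, c(h, w, J))
  for (j in seq_len(J)) {
    diff <- P - matrix(keys[j, ], m, 3, byrow = TRUE)
    dist <- sqrt(rowSums(diff * diff))
    sj <- vmask & dist <= theta
    S[, , j][sj] <- (theta - dist[sj]) / theta
    supp[, , j] <- sj
    nz <- sj & dist > 0
    for (k in 1:3) {
      vk <- numeric(m)
      vk[nz] <- diff[nz, k] / dist[nz]
      V[, , 3L * (j - 1L) + k] <- vk
    }
  }
  structure(list(S = S, V = V, support = supp, theta = theta),
            class = "dense_target")
}

#' Fuse predicted spatial-closeness and geometry-closeness heatmaps
#'
#' Channel-wise convex combination `H_j = alpha_j * S_j + (1 - alpha_j) * G_j`
#' producing the shifted-attention heatmap.
#'
#' @param S_pred,G Heatmap stacks of identical shape (h x w x J, or any
#'   array whose last dimension is the keypoint channel).
#' @param alpha Effective per-channel weights in [0, 1]; scalar or length-J.
#' @return Fused heatmap stack, same shape.
#' @export
fuse_heatmaps <- function(S_pred, G, alpha) {
  if (!identical(dim(S_pred), dim(G))) {
    stop("fuse_heatmaps: shape mismatch between S and G")
  }
  d <- dim(S_pred)
  J <- d[length(d)]
  if (length(alpha) == 1) alpha <- rep(alpha, J)
  stopifnot(length(alpha) == J, all(alpha >= 0), all(alpha <= 1))
  m <- prod(d[-length(d)])
  a <- rep(alpha, each = m)
  S_pred * a + G * (1 - a)
}

#' Attention weights with an unconstrained parametrization
#'
#' Raw per-channel values squashed through a sigmoid keep the fusion of
#' [fuse_heatmaps()] a convex combination throughout training.
#'
#' @param raw Numeric vector of unconstrained weights (one per keypoint).
#' @return An `attention_weights` object with elements `raw` and `alpha`.
#' @export
attention_weights <- function(raw) {
  stopifnot(all(is.finite(raw)))
  structure(list(raw = raw, alpha = 1 / (1 + exp(-raw))),
            class = "attention_weights")
}

#' Normalize an attention heatmap stack to unit mass per channel
#'
#' Values are clamped below at zero, invalid pixels are zeroed, and each
#' keypoint channel is divided by its total mass so it sums to exactly 1.
#' A channel with no positive mass falls back to a uniform distribution
#' over the valid pixels.
#'
#' @param H h x w x J heatmap stack.
#' @param valid_mask h x w logical mask.
#' @return Normalized stack of the same shape.
#' @export
normalize_attention <- function(H, valid_mask) {
  d <- dim(H)
  nv <- sum(valid_mask)
  if (nv == 0) stop("normalize_attention: no valid pixels")
  m <- d[1] * d[2]
  J <- d[3]
  vm <- as.vector(valid_mask)
  out <- array(0, d)
  for (j in seq_len(J)) {
    hj <- pmax(H[, , j], 0)
    hj[!vm] <- 0
    s <- sum(hj)
    if (s > 1e-12) {
      out[, , j] <- hj / s
    } else {
      u <- numeric(m)
      u[vm] <- 1 / nv
      out[, , j] <- u
    }
  }
  out
}

#' Integrate dense predictions into keypoint positions
#'
#' Each pixel casts the vote `(theta * S_j(p) - theta) * V_j(p) + p` for
#' keypoint j, and votes are pooled with the normalized attention weights:
#' `pbar_j = sum_p vote_j(p) * H_j(p)`. With ground-truth S and V the vote
#' equals `p_j` at every supporting pixel, so any attention confined to the
#' support reproduces the keypoint exactly.
#'
#' @param S_pred h x w x J spatial-closeness stack.
#' @param V_pred h x w x 3J direction stack (layout as in [encode_dense()]).
#' @param H_norm h x w x J attention stack, normalized per
#'   [normalize_attention()].
#' @param points h x w x 3 pixel-position array.
#' @param theta Support radius, same units as `points`.
#' @return J x 3 matrix of keypoint positions.
#' @export
integrate_keypoints <- function(S_pred, V_pred, H_norm, points, theta) {
  d <- dim(S_pred)
  J <- d[3]
  if (!identical(dim(H_norm), d) ||
      !identical(dim(V_pred), c(d[1], d[2], 3L * J)) ||
      !identical(dim(points)[1:2], d[1:2])) {
    stop("integrate_keypoints: shape mismatch")
  }
  m <- d[1] * d[2]
  S <- S_pred; dim(S) <- c(m, J)
  Hn <- H_norm; dim(Hn) <- c(m, J)
  V <- V_pred; dim(V) <- c(m, 3L * J)
  P <- points; dim(P) <- c(m, 3L)
  out <- matrix(0, J, 3)
  for (j in seq_len(J)) {
    rad <- theta * S[, j] - theta
    for (k in 1:3) {
      out[j, k] <- sum((rad * V[, 3L * (j - 1L) + k] + P[, k]) * Hn[, j])
    }
  }
  out
}
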