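# Pinhole camera geometry and hand-crop preprocessing.
#
# Conventions: pixel indices are 0-based with (u, v) = (column, row) and the
# continuous pixel center at integer coordinates; depth values are in
# millimeters with 0 marking an invalid pixel; the world frame is the camera
# frame (x right, y down, z along the optical axis).

#' Camera intrinsics
#'
#' @param fx,fy Focal lengths in pixels (must be positive).
#' @param cx,cy Principal point in pixels.
#' @return A `camera_intrinsics` object.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy) {
  stopifnot(is.finite(fx), is.finite(fy), is.finite(cx), is.finite(cy),
            fx > 0, fy > 0)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy),
            class = "camera_intrinsics")
}

#' Calibrated depth frame
#'
#' @param depth Numeric matrix of depth values in mm; 0 marks invalid pixels.
#' @param intrinsics A [camera_intrinsics()] object.
#' @return A `depth_frame` object.
#' @export
depth_frame <- function(depth, intrinsics) {
  stopifnot(is.matrix(depth), all(is.finite(depth)), all(depth >= 0),
            nrow(depth) >= 1, ncol(depth) >= 1,
            inherits(intrinsics, "camera_intrinsics"))
  structure(list(depth = depth, intrinsics = intrinsics),
            class = "depth_frame")
}

#' @export
print.depth_frame <- function(x, ...) {
  d <- x$depth
  cat(sprintf("<depth_frame %dx%d px, %d valid px, depth %s mm>\n",
              nrow(d), ncol(d), sum(d > 0),
              if (any(d > 0)) sprintf("%.0f-%.0f", min(d[d > 0]), max(d))
              else "-"))
  invisible(x)
}

#' Crop specification
#'
#' Defines the cube-shaped region of interest around a hand and the output
#' resolution of its normalized crop.
#'
#' @param center World-space cube center, length-3 numeric (mm).
#' @param cube_mm Edge length of the crop cube in mm.
#' @param out_size Output crop resolution in pixels (must be even).
#' @return A `crop_spec` object.
#' @export
crop_spec <- function(center, cube_mm = 250, out_size = 128L) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3, all(is.finite(center)),
            cube_mm > 0, out_size %% 2 == 0)
  structure(list(center = center, cube_mm = cube_mm,
                 out_size = as.integer(out_size)),
            class = "crop_spec")
}

#' Back-project pixels to world coordinates
#'
#' @param u,v 0-based pixel coordinates (column, row); vectors allowed.
#' @param d Depth in mm (>= 0).
#' @param K A [camera_intrinsics()] object.
#' @return An n x 3 matrix of world points in mm (a 1 x 3 matrix for scalar
#'   input).
#' @export
pixel_to_world <- function(u, v, d, K) {
  stopifnot(all(is.finite(u)), all(is.finite(v)), all(is.finite(d)),
            all(d >= 0))
  cbind((u - K$cx) * d / K$fx, (v - K$cy) * d / K$fy, d, deparse.level = 0)
}

#' Project world points to pixel coordinates
#'
#' @param p World point(s) in mm: length-3 vector or n x 3 matrix with
#'   positive z.
#' @param K A [camera_intrinsics()] object.
#' @return An n x 3 matrix with columns (u, v, d).
#' @export
world_to_pixel <- function(p, K) {
  if (is.null(dim(p))) p <- matrix(p, 1L)
  stopifnot(ncol(p) == 3, all(is.finite(p)))
  if (any(p[, 3] <= 0)) {
    stop("world_to_pixel: point(s) at or behind the camera (z <= 0)")
  }
  cbind(p[, 1] * K$fx / p[, 3] + K$cx,
        p[, 2] * K$fy / p[, 3] + K$cy,
        p[, 3], deparse.level = 0)
}

#' Estimate the hand center by a depth-window centroid
#'
#' A documented heuristic standing in for a learned hand detector: the
#' centroid of the world points of all valid pixels whose depth lies inside
#' `[near, far]`.
#'
#' @param frame A [depth_frame()].
#' @param near,far Depth window in mm.
#' @return Length-3 world centroid in mm.
#' @export
estimate_hand_center <- function(frame, near = 200, far = 1500) {
  d <- frame$depth
  sel <- d > 0 & d >= near & d <= far
  if (!any(sel)) {
    stop(sprintf("estimate_hand_center: no valid pixels in depth window [%g, %g] mm",
                 near, far))
  }
  idx <- which(sel, arr.ind = TRUE)
  p <- pixel_to_world(idx[, 2] - 1, idx[, 1] - 1, d[sel], frame$intrinsics)
  colMeans(p)
}

#' Crop a hand cube and normalize depth to [-1, 1]
#'
#' Projects the crop cube into the image, resamples the covered window to
#' `out_size` pixels with nearest-neighbour lookup, and maps depth affinely
#' so `center.z - cube_mm/2 -> -1` and `center.z + cube_mm/2 -> +1`.
#' Invalid and out-of-cube pixels take the background value +1. A
#' half-resolution point grid holds the world position of the sampled source
#' pixels in normalized crop coordinates (offset from the cube center
#' divided by `cube_mm/2`), with a validity mask that is `FALSE` wherever
#' the source depth is 0 or the point falls outside the cube.
#'
#' @param frame A [depth_frame()].
#' @param spec A [crop_spec()] with `center[3] > 0`.
#' @return A `crop_sample`: list with `image` (out_size x out_size in
#'   [-1, 1]), `spec`, `points` (hs x hs x 3 array, hs = out_size/2),
#'   `valid_mask` (hs x hs logical) and `image_valid` (full-resolution
#'   logical).
#' @export
crop_and_normalize <- function(frame, spec) {
  K <- frame$intrinsics
  dep <- frame$depth
  H <- nrow(dep); W <- ncol(dep)
  ctr <- spec$center
  stopifnot(ctr[3] > 0)
  half <- spec$cube_mm / 2
  cpix <- world_to_pixel(ctr, K)
  rx <- K$fx * half / ctr[3]
  ry <- K$fy * half / ctr[3]
  os <- spec$out_size
  # continuous source coordinates of the output pixel centers
  us <- cpix[1] - rx + (seq_len(os) - 0.5) / os * (2 * rx)
  vs <- cpix[2] - ry + (seq_len(os) - 0.5) / os * (2 * ry)
  ui <- round(us); vi <- round(vs)
  if (all(ui < 0 | ui > W - 1) || all(vi < 0 | vi > H - 1)) {
    stop("crop_and_normalize: crop window lies fully outside the frame")
  }
  inside_u <- ui >= 0 & ui <= W - 1
  inside_v <- vi >= 0 & vi <= H - 1
  # gather depth for the full out_size x out_size grid (rows = v, cols = u)
  d <- matrix(0, os, os)
  if (any(inside_v) && any(inside_u)) {
    d[inside_v, inside_u] <- dep[cbind(rep(vi[inside_v] + 1,
                                           sum(inside_u)),
                                       rep(ui[inside_u] + 1,
                                           each = sum(inside_v)))]
  }
  nz <- (d - ctr[3]) / half
  in_cube <- d > 0 & abs(nz) <= 1
  img <- matrix(1, os, os)
  img[in_cube] <- nz[in_cube]
  # half-resolution point grid from every other crop pixel
  hs <- os %/% 2L
  pick <- seq(1L, os, 2L)
  usub <- ui[pick]; vsub <- vi[pick]; dsub <- d[pick, pick]
  pw <- pixel_to_world(rep(usub, each = hs), rep(vsub, hs),
                       as.vector(dsub), K)
  pts <- (pw - matrix(ctr, nrow(pw), 3, byrow = TRUE)) / half
  eps <- 1e-9
  valid <- as.vector(dsub) > 0 &
    apply(abs(pts) <= 1 + eps, 1, all)
  pts[!valid, ] <- 0
  points <- array(pts, dim = c(hs, hs, 3))
  structure(list(image = img, spec = spec, points = points,
                 valid_mask = matrix(valid, hs, hs),
                 image_valid = in_cube),
            class = "crop_sample")
}

#' Map normalized crop coordinates back to world millimeters
#'
#' Exact inverse of the keypoint normalization used when building dense
#' targets: `p_world = center + coords * cube_mm/2`.
#'
#' @param coords J x 3 matrix of normalized crop coordinates.
#' @param spec The [crop_spec()] used for the forward crop.
#' @return J x 3 matrix of world coordinates in mm.
#' @export
uncrop_keypoints <- function(coords, spec) {
  if (is.null(dim(coords))) coords <- matrix(coords, 1L)
  stopifnot(ncol(coords) == 3)
  coords * (spec$cube_mm / 2) +
    matrix(spec$center, nrow(coords), 3, byrow = TRUE)
}

#' Normalize world keypoints into crop coordinates
#'
#' @param keys J x 3 matrix of world keypoints in mm.
#' @param spec A [crop_spec()].
#' @return J x 3 matrix of normalized crop coordinates.
#' @export
normalize_keypoints <- function(keys, spec) {
  if (is.null(dim(keys))) keys <- matrix(keys, 1L)
  stopifnot(ncol(keys) == 3)
  (keys - matrix(spec$center, nrow(keys), 3, byrow = TRUE)) /
    (spec$cube_mm / 2)
}
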