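# Synthetic articulated-hand depth data: a small capsule skeleton posed by
# forward kinematics and rendered with exact ray-capsule intersections into
# calibrated depth frames, plus cyclic finger-tapping sequences with exact
# fingertip ground truth. This is the package's test bed: it produces the
# annotated data the estimator assumes without any external dataset.

#' Default hand skeleton
#'
#' A minimal right-hand model: a thick three-capsule palm, a two-segment
#' thumb and a three-segment index finger. Joints carry rest offsets
#' relative to their parent (mm), a local flexion axis and joint limits;
#' each non-root joint also defines the capsule from its parent with the
#' given radius. Fingers point along +y, the palm faces the camera.
#'
#' @return A `hand_skeleton`: data frame of joints plus a keypoint map.
#' @export
hand_skeleton <- function() {
  j <- function(name, parent, off, radius, axis = c(1, 0, 0),
                lim = c(0, 0)) {
    data.frame(name = name, parent = parent,
               ox = off[1], oy = off[2], oz = off[3], radius = radius,
               ax = axis[1], ay = axis[2], az = axis[3],
               lim_lo = lim[1], lim_hi = lim[2],
               stringsAsFactors = FALSE)
  }
  joints <- rbind(
    j("wrist", NA, c(0, 0, 0), 0),
    j("palm", "wrist", c(0, 45, 0), 20),
    j("palm_l", "wrist", c(-22, 40, 0), 14),
    j("palm_r", "wrist", c(20, 42, 0), 14),
    j("index_mcp", "palm", c(12, 32, 0), 11),
    j("index_pip", "index_mcp", c(0, 26, 0), 7, lim = c(0, 1.7)),
    j("index_dip", "index_pip", c(0, 22, 0), 6, lim = c(0, 1.6)),
    j("index_tip", "index_dip", c(0, 18, 0), 5.5, lim = c(0, 1.4)),
    j("thumb_mcp", "wrist", c(-24, 12, -4), 10),
    j("thumb_ip", "thumb_mcp", c(14, 36, -6), 7,
      axis = c(0.707, 0.707, 0), lim = c(0, 0.5)),
    j("thumb_tip", "thumb_ip", c(20, 36, -8), 5.5,
      axis = c(0.707, 0.707, 0), lim = c(0, 0.4))
  )
  structure(list(joints = joints,
                 keypoints_pose = c("palm", "wrist", "thumb_mcp",
                                    "thumb_tip", "index_mcp", "index_tip"),
                 keypoints_tap = c("thumb_tip", "index_tip")),
            class = "hand_skeleton")
}

#' Pose parameters
#'
#' @param flexion Named numeric vector of per-joint flexion angles (rad);
#'   names must match skeleton joints. A joint's flexion rotates the
#'   subtree below it about its local axis.
#' @param translation Global translation in mm (hand root position).
#' @param rotation In-plane (about the camera axis) rotation in rad.
#' @return A `pose_params` object.
#' @export
pose_params <- function(flexion = numeric(0),
                        translation = c(0, 0, 550), rotation = 0) {
  structure(list(flexion = flexion, translation = as.numeric(translation),
                 rotation = rotation),
            class = "pose_params")
}

rot_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle); C <- 1 - c
  x <- a[1]; y <- a[2]; z <- a[3]
  matrix(c(x * x * C + c, x * y * C + z * s, x * z * C - y * s,
           x * y * C - z * s, y * y * C + c, y * z * C + x * s,
           x * z * C + y * s, y * z * C - x * s, z * z * C + c),
         3, 3)
}

#' Pose a skeleton by forward kinematics
#'
#' Walks the joint hierarchy accumulating each joint's flexion rotation,
#' then applies the global in-plane rotation and translation. A zero pose
#' reproduces the rigidly transformed rest shape.
#'
#' @param skel A [hand_skeleton()].
#' @param pose A [pose_params()]; flexion angles must lie within the
#'   joint limits.
#' @return Named J_all x 3 matrix of world joint positions (mm).
#' @export
pose_skeleton <- function(skel, pose) {
  js <- skel$joints
  n <- nrow(js)
  fl <- pose$flexion
  bad <- setdiff(names(fl), js$name)
  if (length(bad)) stop("pose_skeleton: unknown joints: ",
                        paste(bad, collapse = ", "))
  pos <- matrix(0, n, 3, dimnames = list(js$name, NULL))
  rot <- vector("list", n)
  names(rot) <- js$name
  Rg <- rot_axis(c(0, 0, 1), pose$rotation)
  for (i in seq_len(n)) {
    nm <- js$name[i]
    ang <- if (nm %in% names(fl)) fl[[nm]] else 0
    if (ang < js$lim_lo[i] - 1e-9 || ang > js$lim_hi[i] + 1e-9) {
      stop(sprintf("pose_skeleton: flexion %.3f rad out of limits [%g, %g] for %s",
                   ang, js$lim_lo[i], js$lim_hi[i], nm))
    }
    if (is.na(js$parent[i])) {
      R <- Rg %*% rot_axis(c(js$ax[i], js$ay[i], js$az[i]), -ang)
      pos[i, ] <- pose$translation
      rot[[nm]] <- R
    } else {
      pr <- js$parent[i]
      Rp <- rot[[pr]]
      off <- c(js$ox[i], js$oy[i], js$oz[i])
      pos[i, ] <- pos[pr, ] + as.vector(Rp %*% off)
      rot[[nm]] <- Rp %*% rot_axis(c(js$ax[i], js$ay[i], js$az[i]), -ang)
    }
  }
  pos
}

# Capsule list (A, B, r) for a posed skeleton.
posed_capsules <- function(skel, pos) {
  js <- skel$joints
  caps <- list()
  for (i in seq_len(nrow(js))) {
    if (is.na(js$parent[i])) next
    caps[[length(caps) + 1]] <- list(A = pos[js$parent[i], ],
                                     B = pos[js$name[i], ],
                                     r = js$radius[i])
  }
  caps
}

#' Render a posed skeleton to a calibrated depth frame
#'
#' Per-pixel nearest ray-capsule intersection (z-buffer); the depth value
#' is the z-coordinate of the hit in mm, quantized to integer millimeters;
#' background pixels are 0.
#'
#' @param capsules List of capsules `list(A, B, r)` in world mm, all in
#'   front of the camera.
#' @param K A [camera_intrinsics()].
#' @param size Image size in pixels (height = width = `size`).
#' @return A [depth_frame()].
#' @export
render_depth <- function(capsules, K, size = 128L) {
  for (cp in capsules) {
    if (cp$A[3] <= cp$r || cp$B[3] <= cp$r) {
      stop("render_depth: geometry at or behind the camera")
    }
  }
  # unnormalized ray directions, z component 1: depth along ray = t
  u <- matrix(rep(0:(size - 1), each = size), size)   # columns
  v <- matrix(rep(0:(size - 1), size), size)          # rows
  dx <- (u - K$cx) / K$fx
  dy <- (v - K$cy) / K$fy
  zbuf <- matrix(Inf, size, size)
  for (cp in capsules) {
    t_hit <- ray_capsule(dx, dy, cp$A, cp$B, cp$r)
    upd <- is.finite(t_hit) & t_hit < zbuf
    zbuf[upd] <- t_hit[upd]
  }
  dep <- matrix(0, size, size)
  hit <- is.finite(zbuf)
  dep[hit] <- round(zbuf[hit])
  depth_frame(dep, K)
}

# Smallest positive t with |t*D - closest point on segment AB| = r, for all
# pixel rays D = (dx, dy, 1). Returns Inf where the ray misses.
ray_capsule <- function(dx, dy, A, B, r) {
  d2 <- dx * dx + dy * dy + 1
  t_best <- array(Inf, dim(dx))
  sphere_hit <- function(C) {
    b <- -2 * (dx * C[1] + dy * C[2] + C[3])
    cc <- sum(C * C) - r * r
    disc <- b * b - 4 * d2 * cc
    ok <- disc >= 0
    t <- array(Inf, dim(dx))
    t[ok] <- (-b[ok] - sqrt(disc[ok])) / (2 * d2[ok])
    t[t <= 0] <- Inf
    t
  }
  ab <- B - A
  L <- sqrt(sum(ab * ab))
  if (L > 1e-9) {
    ux <- ab / L
    # perpendicular components of D and A w.r.t. the axis
    du <- dx * ux[1] + dy * ux[2] + ux[3]
    au <- sum(A * ux)
    px <- dx - du * ux[1]; py <- dy - du * ux[2]; pz <- 1 - du * ux[3]
    qx <- A[1] - au * ux[1]; qy <- A[2] - au * ux[2]; qz <- A[3] - au * ux[3]
    a <- px * px + py * py + pz * pz
    b <- -2 * (px * qx + py * qy + pz * qz)
    cc <- sum(c(qx, qy, qz)^2) - r * r
    disc <- b * b - 4 * a * cc
    ok <- disc >= 0 & a > 1e-12
    t <- array(Inf, dim(dx))
    t[ok] <- (-b[ok] - sqrt(disc[ok])) / (2 * a[ok])
    t[t <= 0] <- Inf
    # keep only hits whose axial coordinate lies within the segment
    s <- t * du - au
    t[!(s >= 0 & s <= L)] <- Inf
    t_best <- pmin(t_best, t)
  }
  t_best <- pmin(t_best, sphere_hit(A))
  pmin(t_best, sphere_hit(B))
}

#' Default synthetic camera
#' @return A [camera_intrinsics()] for a 128 x 128 depth sensor.
#' @export
synthetic_camera <- function() camera_intrinsics(200, 200, 63.5, 63.5)

#' Generate a dataset of annotated hand poses
#'
#' Samples random flexions within the joint limits, a random in-plane
#' rotation and a random translation within a working volume, renders each
#' pose and annotates the pose-mode keypoints (two fingertips, two MCP
#' joints, palm and wrist). Poses whose keypoints would project outside
#' the image are re-drawn.
#'
#' @param n Number of frames.
#' @param skel A [hand_skeleton()].
#' @param K A [camera_intrinsics()].
#' @param size Image size in pixels.
#' @param depth_range Range of hand root depths (mm).
#' @param rot_deg Range of global in-plane rotations (degrees).
#' @param seed Integer seed; the generator is reproducible.
#' @return List of `synthetic_frame`s: each a list with `frame` (a
#'   [depth_frame()]), `keys` (J x 3 world mm), and `pose`.
#' @export
generate_pose_dataset <- function(n, skel = hand_skeleton(),
                                  K = synthetic_camera(), size = 128L,
                                  depth_range = c(400, 700),
                                  rot_deg = c(-180, 180), seed = 1L) {
  stopifnot(n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  js <- skel$joints
  kp <- skel$keypoints_pose
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      fl <- stats::setNames(
        stats::runif(nrow(js), js$lim_lo, js$lim_hi), js$name)
      fl <- fl[js$lim_hi > js$lim_lo]
      z <- stats::runif(1, depth_range[1], depth_range[2])
      # keep the hand roughly centered so the crop covers it
      xy_max <- 0.25 * z / K$fx * size
      tr <- c(stats::runif(2, -xy_max, xy_max) - c(0, 40), z)
      pose <- pose_params(fl, tr,
                          stats::runif(1, rot_deg[1], rot_deg[2]) * pi / 180)
      pos <- pose_skeleton(skel, pose)
      keys <- pos[kp, , drop = FALSE]
      px <- world_to_pixel(keys, K)
      if (all(px[, 1] >= 2 & px[, 1] <= size - 3 &
              px[, 2] >= 2 & px[, 2] <= size - 3)) break
    }
    frame <- render_depth(posed_capsules(skel, pos), K, size)
    out[[i]] <- structure(list(frame = frame, keys = keys, pose = pose),
                          class = "synthetic_frame")
  }
  out
}

#' Tapping motion configuration
#'
#' @param taps Number of taps (opening/closing cycles).
#' @param frames_per_tap Frames per tap (>= 4; odd values place the apex
#'   exactly on the frame grid).
#' @param amplitude Peak fingertip opening in mm.
#' @param rest_frames Number of resting (closed) frames between taps.
#' @param noise_sd Standard deviation of additive fingertip position noise
#'   in mm (0 disables noise).
#' @param seed Integer seed.
#' @return A `tap_motion_config` object.
#' @export
tap_motion_config <- function(taps = 10L, frames_per_tap = 11L,
                              amplitude = 55, rest_frames = 0L,
                              noise_sd = 0, seed = 1L) {
  stopifnot(taps >= 1, frames_per_tap >= 4, amplitude > 0, rest_frames >= 0,
            noise_sd >= 0)
  structure(list(taps = as.integer(taps),
                 frames_per_tap = as.integer(frames_per_tap),
                 amplitude = amplitude, rest_frames = as.integer(rest_frames),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "tap_motion_config")
}

# Fingertip distance as a function of the shared index flexion angle
# (distributed over the three index joints as 1 : 0.9 : 0.8).
tap_distance_at <- function(skel, phi, base_pose) {
  fl <- base_pose$flexion
  fl[c("index_pip", "index_dip", "index_tip")] <-
    phi * c(1, 0.9, 0.8)
  pos <- pose_skeleton(skel, pose_params(fl, base_pose$translation,
                                         base_pose$rotation))
  sqrt(sum((pos["index_tip", ] - pos["thumb_tip", ])^2))
}

#' Generate a cyclic finger-tapping sequence
#'
#' The fingertip distance follows a rectified-sinusoid open/close profile:
#' within each tap of F frames, the target distance is
#' `d_min + (amplitude - d_min) * sin(pi * (f - 1) / (F - 1))`, reaching
#' the configured amplitude at the apex and the closed distance `d_min` at
#' the tap boundaries; optional rest frames hold the closed position
#' between taps. The index-finger flexion realizing each target distance
#' is solved exactly (monotone 1-D root finding), the posed hand is
#' rendered, and the exact fingertip trajectories are returned as ground
#' truth. With `noise_sd > 0`, zero-mean Gaussian noise is added to the
#' commanded distance before solving, emulating pose jitter.
#'
#' @param cfg A [tap_motion_config()].
#' @param skel A [hand_skeleton()].
#' @param K A [camera_intrinsics()].
#' @param size Image size in pixels.
#' @param render Logical; skip depth rendering (frames = NULL) when only
#'   the kinematic ground truth is needed.
#' @return List with `frames` (list of [depth_frame()] or NULL), `truth`
#'   (a [tap_sequence()] of thumb/index tips, mm), `distance_target` (the
#'   commanded profile) and `cfg`.
#' @export
generate_tap_sequence <- function(cfg = tap_motion_config(),
                                  skel = hand_skeleton(),
                                  K = synthetic_camera(), size = 128L,
                                  render = TRUE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  base <- pose_params(numeric(0), c(0, -40, 550), 0)
  phi_max <- 1.7
  d_open <- tap_distance_at(skel, 0, base)
  d_min <- tap_distance_at(skel, phi_max, base)
  if (cfg$amplitude > d_open - 1e-6) {
    stop(sprintf("generate_tap_sequence: amplitude %.1f mm exceeds the reachable opening %.1f mm",
                 cfg$amplitude, d_open))
  }
  F <- cfg$frames_per_tap
  prof <- d_min + (cfg$amplitude - d_min) *
    sin(pi * (seq_len(F) - 1) / (F - 1))
  target <- numeric(0)
  for (k in seq_len(cfg$taps)) {
    # consecutive taps share their boundary frame (closed position)
    add <- if (k == 1 || cfg$rest_frames > 0) prof else prof[-1]
    target <- c(target, add)
    if (cfg$rest_frames > 0 && k < cfg$taps) {
      target <- c(target, rep(d_min, cfg$rest_frames))
    }
  }
  noisy <- target
  if (cfg$noise_sd > 0) {
    noisy <- pmin(pmax(target + stats::rnorm(length(target), 0,
                                             cfg$noise_sd),
                       d_min), d_open)
  }
  Tn <- length(noisy)
  tips <- array(0, c(Tn, 2, 3))
  frames <- if (render) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    phi <- stats::uniroot(function(p) tap_distance_at(skel, p, base) -
                            noisy[t],
                          c(0, phi_max), tol = 1e-10)$root
    fl <- base$flexion
    fl[c("index_pip", "index_dip", "index_tip")] <- phi * c(1, 0.9, 0.8)
    pos <- pose_skeleton(skel, pose_params(fl, base$translation,
                                           base$rotation))
    tips[t, 1, ] <- pos["thumb_tip", ]
    tips[t, 2, ] <- pos["index_tip", ]
    if (render) {
      frames[[t]] <- render_depth(posed_capsules(skel, pos), K, size)
    }
  }
  list(frames = frames, truth = tap_sequence(tips),
       distance_target = target, cfg = cfg)
}

#' Turn synthetic frames into network-ready training samples
#'
#' Crops each frame around a ground-truth-derived center (the keypoint
#' centroid) and expresses the keypoints in normalized crop coordinates.
#'
#' @param frames List of `synthetic_frame`s from
#'   [generate_pose_dataset()].
#' @param cube_mm Crop cube edge (mm).
#' @param out_size Crop resolution (px).
#' @return List of samples `list(crop, keys)` as consumed by
#'   [train_model()].
#' @export
prepare_samples <- function(frames, cube_mm = 250, out_size = 64L) {
  lapply(frames, function(sf) {
    ctr <- colMeans(sf$keys)
    spec <- crop_spec(ctr, cube_mm, out_size)
    crop <- crop_and_normalize(sf$frame, spec)
    list(crop = crop, keys = normalize_keypoints(sf$keys, spec),
         keys_world = sf$keys, spec = spec)
  })
}
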