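test_that("zero pose reproduces the rigidly transformed rest shape", {
  sk <- hand_skeleton()
  tr <- c(12, -30, 500)
  pos <- pose_skeleton(sk, pose_params(numeric(0), tr, 0))
  js <- sk$joints
  # accumulate rest offsets down the hierarchy by hand
  rest <- matrix(0, nrow(js), 3, dimnames = list(js$name, NULL))
  for (i in seq_len(nrow(js))) {
    off <- c(js$ox[i], js$oy[i], js$oz[i])
    rest[i, ] <- if (is.na(js$parent[i])) off else rest[js$parent[i], ] + off
  }
  expect_close(pos, rest + matrix(tr, nrow(js), 3, byrow = TRUE), 1e-9)
  # global in-plane rotation spins the rest shape about the root
  pos90 <- pose_skeleton(sk, pose_params(numeric(0), tr, pi / 2))
  rel <- sweep(pos, 2, tr); rel90 <- sweep(pos90, 2, tr)
  expect_close(rel90, cbind(-rel[, 2], rel[, 1], rel[, 3]), 1e-9)
})

test_that("flexing one joint rotates its subtree in the flexion plane", {
  sk <- hand_skeleton()
  phi <- pi / 2
  p0 <- pose_skeleton(sk, pose_params(numeric(0), c(0, 0, 500), 0))
  p1 <- pose_skeleton(sk, pose_params(c(index_pip = phi), c(0, 0, 500), 0))
  # pip position unchanged; tip rotates about the pip's x axis by -phi
  expect_close(p1["index_pip", ], p0["index_pip", ], 1e-9)
  rel <- p0["index_tip", ] - p0["index_pip", ]
  want <- c(rel[1],
            cos(phi) * rel[2] + sin(phi) * rel[3],
            -sin(phi) * rel[2] + cos(phi) * rel[3])
  expect_close(p1["index_tip", ] - p1["index_pip", ], want, 1e-9)
  expect_error(pose_skeleton(sk, pose_params(c(index_pip = 3),
                                             c(0, 0, 500), 0)),
               "limits")
  expect_error(pose_skeleton(sk, pose_params(c(nope = 0.1),
                                             c(0, 0, 500), 0)),
               "unknown")
})

test_that("bone lengths are invariant under any admissible pose", {
  sk <- hand_skeleton()
  js <- sk$joints
  lens <- function(pos) {
    sapply(which(!is.na(js$parent)), function(i) {
      sqrt(sum((pos[js$name[i], ] - pos[js$parent[i], ])^2))
    })
  }
  rest <- pose_skeleton(sk, pose_params(numeric(0), c(0, 0, 500), 0))
  set.seed(8)
  for (k in 1:5) {
    fl <- setNames(runif(nrow(js), js$lim_lo, js$lim_hi), js$name)
    fl <- fl[js$lim_hi > 0]
    pos <- pose_skeleton(sk, pose_params(fl, runif(3, -20, 20) +
                                           c(0, 0, 520),
                                         runif(1, -pi, pi)))
    expect_close(lens(pos), lens(rest), 1e-9)
  }
})

test_that("sphere rendering hits the closed-form depth at the center", {
  K <- synthetic_camera()
  z0 <- 500; r <- 30
  caps <- list(list(A = c(0, 0, z0), B = c(0, 0, z0), r = r))
  fr <- render_depth(caps, K, 128)
  # principal point is between pixels 63 and 64 (cx = 63.5); both rays
  # pass within 0.5 px of the axis
  expect_lt(abs(fr$depth[64, 64] - (z0 - r)), 1.1)
  expect_error(render_depth(list(list(A = c(0, 0, 10), B = c(0, 0, 10),
                                      r = 20)), K),
               "behind")
})

test_that("empty scenes render to all-invalid frames", {
  fr <- render_depth(list(), synthetic_camera(), 32)
  expect_true(all(fr$depth == 0))
})

test_that("rendered silhouette area matches the projected capsule", {
  K <- synthetic_camera()
  z0 <- 500; r <- 20; L <- 100
  caps <- list(list(A = c(-L / 2, 0, z0), B = c(L / 2, 0, z0), r = r))
  fr <- render_depth(caps, K, 128)
  px_per_mm <- K$fx / z0
  analytic <- (2 * r * L + pi * r^2) * px_per_mm^2
  got <- sum(fr$depth > 0)
  expect_lt(abs(got - analytic) / analytic, 0.1)
})

test_that("keypoints are consistent with the rendered surface", {
  fr <- generate_pose_dataset(5, seed = 51)
  for (sf in fr) {
    K <- sf$frame$intrinsics
    d <- sf$frame$depth
    radii <- c(20, 10, 10, 5.5, 11, 5.5)  # palm, wrist-ish, mcp/tips
    for (j in seq_len(nrow(sf$keys))) {
      uv <- world_to_pixel(sf$keys[j, ], K)
      u <- round(uv[1]) + 1; v <- round(uv[2]) + 1
      # search the 3x3 pixel footprint for a surface point near the key
      win <- d[max(1, v - 1):min(nrow(d), v + 1),
               max(1, u - 1):min(ncol(d), u + 1)]
      win <- win[win > 0]
      expect_gt(length(win), 0)
      expect_lt(min(abs(win - sf$keys[j, 3])), 25 + 1)
    }
  }
})

test_that("pose dataset generation is reproducible and in-frame", {
  a <- generate_pose_dataset(3, seed = 12)
  b <- generate_pose_dataset(3, seed = 12)
  expect_identical(lapply(a, `[[`, "keys"), lapply(b, `[[`, "keys"))
  expect_identical(a[[2]]$frame$depth, b[[2]]$frame$depth)
  cc <- generate_pose_dataset(3, seed = 13)
  expect_false(identical(a[[1]]$keys, cc[[1]]$keys))
  smp <- prepare_samples(a, cube_mm = 250, out_size = 32)
  for (s in smp) expect_true(all(abs(s$keys) <= 1))
})

test_that("tap sequences follow the commanded open/close profile", {
  cfg <- tap_motion_config(taps = 10, frames_per_tap = 11, amplitude = 55,
                           noise_sd = 0, seed = 14)
  ts <- generate_tap_sequence(cfg, render = FALSE)
  d <- tap_kinematics(ts$truth)$distance
  expect_close(max(d), 55, 1e-6)          # peak = amplitude
  # exactly ten local maxima
  n <- length(d)
  ismax <- d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] > d[3:n]
  expect_equal(sum(ismax), 10)
  # commanded and realized distances agree (the flexion solve is exact)
  expect_close(d, ts$distance_target, 1e-6)
  # determinism
  t2 <- generate_tap_sequence(cfg, render = FALSE)
  expect_identical(ts$truth$frames, t2$truth$frames)
})

test_that("rendered tap frames carry fingertips on the surface", {
  cfg <- tap_motion_config(taps = 1, frames_per_tap = 5, seed = 15)
  ts <- generate_tap_sequence(cfg, render = TRUE)
  expect_length(ts$frames, 5)
  for (t in c(1, 3, 5)) {
    d <- ts$frames[[t]]$depth
    expect_gt(sum(d > 0), 100)
    K <- ts$frames[[t]]$intrinsics
    for (tip in 1:2) {
      uv <- world_to_pixel(ts$truth$frames[t, tip, ], K)
      win <- d[round(uv[2]) + 0:2, round(uv[1]) + 0:2]
      expect_lt(min(abs(win[win > 0] - uv[3])), 5.5 + 1)
    }
  }
})

test_that("amplitude beyond the reachable opening is rejected", {
  expect_error(generate_tap_sequence(tap_motion_config(amplitude = 90),
                                     render = FALSE),
               "reachable")
})
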