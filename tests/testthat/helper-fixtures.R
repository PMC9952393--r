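# Shared fixture builders. Everything is generated in code at test time.

tiny_config <- function(...) {
  args <- list(C = 8L, J = 3L, stages = 2L, hourglass_depth = 2L,
               se_ratio = 4L, theta = 0.8, out_size = 16L)
  args[names(list(...))] <- list(...)
  do.call(model_config, args)
}

# Random point cloud + mask + keypoints in normalized crop coordinates.
random_cloud <- function(hs = 12L, J = 4L, seed = 1L,
                         valid_frac = 0.9) {
  set.seed(seed)
  list(points = array(runif(hs * hs * 3, -1, 1), c(hs, hs, 3)),
       mask = matrix(runif(hs * hs) < valid_frac, hs, hs),
       keys = matrix(runif(J * 3, -0.5, 0.5), J, 3))
}

# Random batch in the network's tensor layout, with matching dense targets.
random_batch <- function(cfg, N = 2L, seed = 1L) {
  set.seed(seed)
  os <- cfg$out_size
  hs <- os %/% 2L
  J <- cfg$J
  list(img = array(runif(os * os * N, -1, 1), c(os, os, N, 1L)),
       points = array(runif(hs * hs * N * 3, -1, 1), c(hs, hs, N, 3L)),
       mask = array(runif(hs * hs * N) < 0.9, c(hs, hs, N)),
       S = array(runif(hs * hs * N * J), c(hs, hs, N, J)),
       V = array(runif(hs * hs * N * 3 * J, -1, 1), c(hs, hs, N, 3L * J)),
       K = array(runif(J * 3 * N, -0.5, 0.5), c(J, 3L, N)))
}

# A flat-plane depth frame at constant depth (mm).
flat_frame <- function(depth_mm = 500, size = 64L,
                       K = camera_intrinsics(300, 300,
                                             (size - 1) / 2,
                                             (size - 1) / 2)) {
  depth_frame(matrix(depth_mm, size, size), K)
}

expect_close <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
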