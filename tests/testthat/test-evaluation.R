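test_that("keypoint errors average Euclidean distances", {
  t1 <- array(0, c(1, 1, 3))
  p1 <- array(c(3, 4, 0), c(1, 1, 3))
  r <- keypoint_errors(p1, t1)
  expect_equal(r$overall, 5)
  expect_equal(r$per_keypoint, 5)

  p <- array(0, c(2, 1, 3)); tr <- p
  p[1, 1, 1] <- 2; p[2, 1, 1] <- 4
  r2 <- keypoint_errors(p, tr)
  expect_equal(r2$overall, 3)
  expect_equal(r2$n_frames, 2)

  set.seed(1)
  a <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  expect_equal(keypoint_errors(a, a)$overall, 0)
  expect_error(keypoint_errors(a, a[1:2, , ]), "mismatch")
})

test_that("success rate matches enumeration and is monotone", {
  # frames with max errors 4, 6, 11 mm
  tr <- array(0, c(3, 2, 3))
  p <- tr
  p[1, 1, 1] <- 4; p[2, 1, 2] <- 6; p[3, 2, 3] <- 11
  sc <- success_rate(p, tr, c(5, 10, 12))
  expect_equal(sc$fraction, c(1 / 3, 2 / 3, 1))
  expect_equal(success_rate(p, tr, 10)$fraction, 2 / 3)
  # extremes
  expect_equal(success_rate(p, tr, 1e-6)$fraction, 0)
  expect_equal(success_rate(p, tr, 1e6)$fraction, 1)
  # per-keypoint mode counts pairs
  # per-pair errors: (4,0), (6,0), (0,11) -> four of six below 5 mm
  sc2 <- success_rate(p, tr, 5, mode = "per_keypoint")
  expect_equal(sc2$fraction, 4 / 6)
  # monotone in threshold for random errors
  set.seed(2)
  pr <- array(rnorm(20 * 3 * 3, sd = 5), c(20, 3, 3))
  tz <- array(0, c(20, 3, 3))
  fr <- success_rate(pr, tz, seq(0, 20, 0.5))$fraction
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_error(success_rate(p, tr, numeric(0)), "empty")
  expect_error(success_rate(p, tr, c(3, 1)), "ascend")
})

test_that("tap kinematics are successive finite differences", {
  mk <- function(d) {
    f <- array(0, c(length(d), 2, 3))
    f[, 2, 1] <- d
    tap_sequence(f)
  }
  k <- tap_kinematics(mk(c(10, 12, 14)))
  expect_equal(k$distance, c(10, 12, 14))
  expect_equal(k$velocity, c(2, 2))
  expect_equal(k$acceleration, 0)

  k2 <- tap_kinematics(mk(c(0, 5, 0)))
  expect_equal(k2$velocity, c(5, -5))
  expect_equal(k2$acceleration, -10)

  cst <- tap_kinematics(mk(rep(7, 5)))
  expect_true(all(cst$velocity == 0) && all(cst$acceleration == 0))

  short <- tap_kinematics(mk(c(1, 2)))
  expect_true(short$short)
  expect_length(short$acceleration, 0)
})

test_that("tap error report behaves under exactness and constant offsets", {
  ts <- generate_tap_sequence(tap_motion_config(taps = 3, seed = 2),
                              render = FALSE)
  tr <- ts$truth
  r0 <- tap_errors(tr, tr)
  expect_equal(r0$pos$mean, 0)
  expect_equal(r0$dis$mean, 0)
  expect_equal(r0$vel$mean, 0)
  expect_equal(r0$acc$mean, 0)

  # constant offset along the separation axis shifts distance only
  pr <- tr
  f <- pr$frames
  dirv <- (f[, 2, ] - f[, 1, ])
  dirn <- dirv / sqrt(rowSums(dirv^2))
  cshift <- 2.5
  f[, 2, ] <- f[, 2, ] + dirn * cshift
  pr$frames <- f
  r1 <- tap_errors(tap_sequence(f), tr)
  expect_close(r1$dis$mean, cshift, 1e-9)
  expect_close(r1$dis$sd, 0, 1e-9)
  expect_close(r1$vel$mean, 0, 1e-9)
  expect_close(r1$acc$mean, 0, 1e-9)
  expect_error(tap_errors(tap_sequence(f[1:4, , , drop = FALSE]), tr),
               "length")
})

test_that("distance noise yields the folded-normal error mean", {
  set.seed(33)
  n <- 2000
  base <- 30 + 10 * sin(seq_len(n) / 5)
  f <- array(0, c(n, 2, 3))
  f[, 2, 1] <- base
  truth <- tap_sequence(f)
  fp <- f
  fp[, 2, 1] <- base + rnorm(n, 0, 1)
  r <- tap_errors(tap_sequence(fp), truth)
  expect_lt(abs(r$dis$mean - sqrt(2 / pi)) / sqrt(2 / pi), 0.15)
})

test_that("phase labels reproduce the seven-frame worked example", {
  d <- c(2, 20, 38, 55, 38, 20, 2)
  lb <- label_phases(d, rest_threshold = 3)
  expect_equal(lb$n_taps, 1L)
  expect_close(lb$percent, c(0, 50 / 3, 100 / 3, 50, 200 / 3, 250 / 3, 100),
               1e-9)
  expect_equal(unique(lb$tap_id), 1L)
  # symmetric triangle: labels symmetric about the apex
  expect_close(lb$percent + rev(lb$percent), 100, 1e-9)
})

test_that("phase labeling segments a ten-tap signal into ten taps", {
  ts <- generate_tap_sequence(tap_motion_config(taps = 10, seed = 3),
                              render = FALSE)
  kd <- tap_kinematics(ts$truth)$distance
  lb <- label_phases(kd)
  expect_equal(lb$n_taps, 10L)
  # every labeled tap is nondecreasing from 0; the closed-position frame
  # shared by consecutive taps is labeled as the next tap's 0%, so only
  # the final tap owns its 100% frame outright
  for (id in 1:10) {
    pc <- lb$percent[which(lb$tap_id == id)]
    pc <- pc[!is.na(pc)]
    expect_true(all(diff(pc) >= 0))
    expect_equal(min(pc), 0)
    expect_gte(max(pc), 90)
  }
  expect_equal(max(lb$percent, na.rm = TRUE), 100)
})

test_that("rest periods are removed before segmentation", {
  ts <- generate_tap_sequence(tap_motion_config(taps = 4, rest_frames = 9,
                                                seed = 4),
                              render = FALSE)
  kd <- tap_kinematics(ts$truth)$distance
  lb <- label_phases(kd)
  expect_equal(lb$n_taps, 4L)
  expect_true(any(lb$rest_mask))
  expect_true(all(is.na(lb$percent[lb$rest_mask])))
})

test_that("phase error bands conserve frames and recover structure", {
  d <- c(2, 20, 38, 55, 38, 20, 2)
  lb <- label_phases(d, rest_threshold = 3)
  # uniform error: every non-empty bin reports it with zero spread
  b <- phase_error_bands(rep(2, 7), lb, bins = 4)
  expect_true(all(b$mean[b$n > 0] == 2))
  expect_true(all(b$sd[b$n > 0] == 0))
  expect_equal(sum(b$n), sum(!is.na(lb$percent)))
  # empty bins are NA, not zero
  b2 <- phase_error_bands(rep(1, 7), lb, bins = 50)
  expect_true(any(b2$n == 0))
  expect_true(all(is.na(b2$mean[b2$n == 0])))
  # a ramp in error over percent is recovered by the bin means
  errs <- lb$percent
  b3 <- phase_error_bands(errs, lb, bins = 2)
  expect_true(b3$mean[2] > b3$mean[1])
  expect_error(phase_error_bands(1:3, lb), "length")
})
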