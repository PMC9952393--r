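# Accuracy metrics for keypoint predictions and kinematic metrics for the
# finger-tapping test: relative fingertip distance, its frame-to-frame
# velocity and acceleration (finite differences, sampling interval
# ignored), and the tap-phase analysis that maps each tap to percentages
# 0-100 (0 = start of opening, 50 = apex/maximal opening, 100 = closed).

#' Per-keypoint and overall mean keypoint error
#'
#' @param pred,truth frames x J x 3 arrays of positions in mm (a J x 3
#'   matrix is treated as a single frame).
#' @return An `error_report`: list with `per_keypoint` (J mean errors, mm),
#'   `overall` (all-keypoint mean error, mm) and `n_frames`.
#' @export
keypoint_errors <- function(pred, truth) {
  if (length(dim(pred)) == 2) pred <- array(pred, c(1L, dim(pred)))
  if (length(dim(truth)) == 2) truth <- array(truth, c(1L, dim(truth)))
  if (!all(dim(pred) == dim(truth))) stop("keypoint_errors: shape mismatch")
  d2 <- (pred - truth)^2
  e <- sqrt(d2[, , 1] + d2[, , 2] + d2[, , 3])   # frames x J
  e <- matrix(e, dim(pred)[1], dim(pred)[2])
  structure(list(per_keypoint = colMeans(e), overall = mean(e),
                 n_frames = nrow(e)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("All-keypoint mean error: %.2f mm over %d frames\n",
              x$overall, x$n_frames))
  cat("Per-keypoint (mm):", paste(sprintf("%.2f", x$per_keypoint),
                                  collapse = " "), "\n")
  invisible(x)
}

#' Success rate over error thresholds
#'
#' In `"worst"` mode (the default) a frame counts as a success at a
#' threshold when its maximum keypoint error is below it; in
#' `"per_keypoint"` mode every (frame, keypoint) pair is counted
#' separately.
#'
#' @param pred,truth frames x J x 3 arrays (mm).
#' @param thresholds Ascending numeric vector of thresholds (mm).
#' @param mode `"worst"` or `"per_keypoint"`.
#' @return A `success_curve`: list with `thresholds`, `fraction` and
#'   `mode`.
#' @export
success_rate <- function(pred, truth, thresholds,
                         mode = c("worst", "per_keypoint")) {
  mode <- match.arg(mode)
  if (length(thresholds) == 0) stop("success_rate: empty thresholds")
  if (is.unsorted(thresholds)) stop("success_rate: thresholds must ascend")
  if (length(dim(pred)) == 2) pred <- array(pred, c(1L, dim(pred)))
  if (length(dim(truth)) == 2) truth <- array(truth, c(1L, dim(truth)))
  d2 <- (pred - truth)^2
  e <- matrix(sqrt(d2[, , 1] + d2[, , 2] + d2[, , 3]),
              dim(pred)[1], dim(pred)[2])
  v <- if (mode == "worst") apply(e, 1, max) else as.vector(e)
  frac <- vapply(thresholds, function(th) mean(v < th), numeric(1))
  structure(list(thresholds = thresholds, fraction = frac, mode = mode),
            class = "success_curve")
}

#' Finger-tapping sequence
#'
#' @param frames T x 2 x 3 array of thumb-tip and index-tip positions (mm),
#'   in that order along the second dimension.
#' @param frame_index Optional integer frame indices.
#' @return A `tap_sequence` object.
#' @export
tap_sequence <- function(frames, frame_index = NULL) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[2] == 2,
            dim(frames)[3] == 3)
  if (is.null(frame_index)) frame_index <- seq_len(dim(frames)[1])
  structure(list(frames = frames, frame_index = as.integer(frame_index)),
            class = "tap_sequence")
}

#' Distance/velocity/acceleration kinematics of a tapping sequence
#'
#' Distance is the Euclidean distance between the two fingertips; velocity
#' and acceleration are its first and second finite differences between
#' consecutive frames, ignoring the sampling interval.
#'
#' @param seq A [tap_sequence()] (T >= 2; acceleration needs T >= 3).
#' @return A `tap_kinematics` list with `distance` (T), `velocity` (T-1,
#'   mm/frame), `acceleration` (T-2, mm/frame^2) and `short` flagging a
#'   sequence too short for the derivative series.
#' @export
tap_kinematics <- function(seq) {
  f <- seq$frames
  d <- sqrt(rowSums((f[, 1, ] - f[, 2, ])^2))
  short <- length(d) < 3
  structure(list(distance = d,
                 velocity = if (length(d) >= 2) diff(d) else numeric(0),
                 acceleration = if (!short) diff(d, differences = 2)
                 else numeric(0),
                 short = short),
            class = "tap_kinematics")
}

#' Kinematic error report for a tapping sequence
#'
#' `Pos` is the all-keypoint mean error over the two fingertips; `Dis`,
#' `Vel` and `Acc` are the mean and standard deviation of the absolute
#' differences between the predicted and ground-truth distance series and
#' its finite-difference derivatives.
#'
#' @param pred,truth [tap_sequence()] objects of equal length.
#' @return A `tap_error_report` with elements `pos`, `dis`, `vel`, `acc`,
#'   each a list with `mean` and `sd`.
#' @export
tap_errors <- function(pred, truth) {
  if (dim(pred$frames)[1] != dim(truth$frames)[1]) {
    stop("tap_errors: sequence length mismatch")
  }
  ep <- sqrt(rowSums((pred$frames - truth$frames)^2, dims = 2))
  kp <- tap_kinematics(pred)
  kt <- tap_kinematics(truth)
  band <- function(a, b) {
    d <- abs(a - b)
    list(mean = mean(d), sd = if (length(d) > 1) stats::sd(d) else 0)
  }
  structure(list(pos = list(mean = mean(ep),
                            sd = if (length(ep) > 1) stats::sd(as.vector(ep))
                            else 0),
                 dis = band(kp$distance, kt$distance),
                 vel = band(kp$velocity, kt$velocity),
                 acc = band(kp$acceleration, kt$acceleration)),
            class = "tap_error_report")
}

#' @export
print.tap_error_report <- function(x, ...) {
  f <- function(b) sprintf("%.2f +/- %.2f", b$mean, b$sd)
  cat("Tap error report (mm, per-frame units):\n")
  cat("  Pos Err:", f(x$pos), "\n  Dis Err:", f(x$dis),
      "\n  Vel Err:", f(x$vel), "\n  Acc Err:", f(x$acc), "\n")
  invisible(x)
}

# moving-average smoothing with edge-shrinking window
smooth_ma <- function(x, window = 3L) {
  if (window <= 1L || length(x) < 3L) return(x)
  k <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - k):min(n, i + k)])
  }, numeric(1))
}

#' Label tapping frames with movement-phase percentages
#'
#' Rest periods (where the smoothed distance varies less than
#' `rest_threshold` over a sliding window) are removed; the remaining
#' signal is segmented into taps at local minima of the smoothed distance,
#' with the apex (maximal opening) at the local maximum inside each tap.
#' Frames are labeled linearly 0 -> 50 across the opening phase and
#' 50 -> 100 across the closing phase; apex frames belong to both.
#'
#' @param distance Numeric fingertip-distance series (mm).
#' @param rest_threshold Range below which a window counts as rest (mm).
#' @param window Smoothing window (frames) for extremum detection.
#' @return A `phase_labels` list with `percent` (NA during rest), `tap_id`
#'   (NA outside taps), `rest_mask`, and `n_taps`; `n_taps = 0` flags an
#'   empty segmentation.
#' @export
label_phases <- function(distance, rest_threshold = 3, window = 3L) {
  n <- length(distance)
  sm <- smooth_ma(distance, window)
  # rest: sliding window over which the raw signal stays nearly constant
  rw <- max(window, 5L)
  rest <- rep(FALSE, n)
  if (n >= rw) {
    half <- rw %/% 2L
    for (i in seq_len(n)) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      rest[i] <- (max(distance[lo:hi]) - min(distance[lo:hi])) <
        rest_threshold
    }
  }
  act <- which(!rest)
  percent <- rep(NA_real_, n)
  tap_id <- rep(NA_integer_, n)
  if (length(act) < 3) {
    return(structure(list(percent = percent, tap_id = tap_id,
                          rest_mask = rest, n_taps = 0L),
                     class = "phase_labels"))
  }
  # segment contiguous active runs, then split each run at local minima
  runs <- split(act, cumsum(c(1, diff(act) != 1)))
  tap <- 0L
  for (run in runs) {
    if (length(run) < 3) next
    s <- sm[run]
    m <- length(s)
    is_min <- c(TRUE, s[2:(m - 1)] <= s[1:(m - 2)] &
                  s[2:(m - 1)] <= s[3:m], TRUE)
    # collapse plateaus of minima
    mins <- which(is_min)
    keep <- mins[c(TRUE, diff(mins) > 1)]
    if (length(keep) < 2) next
    for (b in seq_len(length(keep) - 1)) {
      lo <- keep[b]; hi <- keep[b + 1]
      seg <- lo:hi
      apex <- seg[which.max(s[seg])]
      if (apex == lo || apex == hi) next   # no opening or no closing
      tap <- tap + 1L
      open <- lo:apex
      close <- apex:hi
      idx_open <- run[open]; idx_close <- run[close]
      percent[idx_open] <- 50 * (seq_along(open) - 1) / (length(open) - 1)
      percent[idx_close] <- 50 + 50 * (seq_along(close) - 1) /
        (length(close) - 1)
      tap_id[run[lo:hi]] <- tap
    }
  }
  structure(list(percent = percent, tap_id = tap_id, rest_mask = rest,
                 n_taps = tap),
            class = "phase_labels")
}

#' Mean/sd error bands by movement-phase percentage
#'
#' @param errors Per-frame errors aligned with the series that produced
#'   `labels`.
#' @param labels A [label_phases()] result.
#' @param bins Number of percentage bins partitioning [0, 100].
#' @return Data frame with bin boundaries, per-bin mean, sd and count;
#'   empty bins carry NA means rather than zeros.
#' @export
phase_error_bands <- function(errors, labels, bins = 10L) {
  if (length(errors) != length(labels$percent)) {
    stop("phase_error_bands: errors and labels length mismatch")
  }
  sel <- !is.na(labels$percent)
  p <- labels$percent[sel]
  e <- errors[sel]
  edges <- seq(0, 100, length.out = bins + 1)
  b <- pmin(findInterval(p, edges, rightmost.closed = TRUE), bins)
  out <- data.frame(bin = seq_len(bins), lo = edges[-(bins + 1)],
                    hi = edges[-1], mean = NA_real_, sd = NA_real_,
                    n = 0L)
  for (k in seq_len(bins)) {
    v <- e[b == k]
    out$n[k] <- length(v)
    if (length(v) > 0) {
      out$mean[k] <- mean(v)
      out$sd[k] <- if (length(v) > 1) stats::sd(v) else 0
    }
  }
  out
}
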