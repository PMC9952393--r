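# Dataset plumbing: 16-bit depth rasters, a line-delimited manifest format,
# run configuration with override precedence, and the command-line entry
# points used by the inst/cli/sarn script.

#' Read / write a depth raster
#'
#' Depth frames are stored as single-channel 16-bit grayscale TIFF with
#' pixel value = depth in integer millimeters (0 = invalid). Values are
#' quantized to 1 mm on write; the round trip is exact for depths up to
#' 65535 mm.
#'
#' @param frame A [depth_frame()].
#' @param path File path (.tif).
#' @return `read_depth_raster` returns the depth matrix in mm (intrinsics
#'   live in the manifest).
#' @export
write_depth_raster <- function(frame, path) {
  d <- round(frame$depth)
  if (any(d > 65535)) stop("write_depth_raster: depth exceeds 65535 mm")
  tiff::writeTIFF(d / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_depth_raster
#' @export
read_depth_raster <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  round(x * 65535)
}

#' Write / read a dataset manifest
#'
#' Line-delimited JSON: a header line with the schema version and keypoint
#' count, then one record per line with the depth file path, camera
#' intrinsics, flattened keypoints (mm, world) and optional tags. The
#' round trip is lossless; loading verifies that every referenced depth
#' file exists and that all records share the same J.
#'
#' @param records List of records: each a list with `depth` (relative file
#'   path), `fx`, `fy`, `cx`, `cy`, `keys` (J x 3 matrix), and optional
#'   `tags` (named list).
#' @param path Manifest file path; depth paths are resolved relative to
#'   its directory.
#' @return `read_manifest` returns a `dataset_manifest`: list with
#'   `records`, `J` and `dir`.
#' @export
write_manifest <- function(records, path) {
  js <- vapply(records, function(r) {
    jsonlite::toJSON(list(depth = r$depth, fx = r$fx, fy = r$fy,
                          cx = r$cx, cy = r$cy,
                          keys = as.vector(t(r$keys)),
                          tags = if (is.null(r$tags)) NULL else r$tags),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  J <- unique(vapply(records, function(r) nrow(r$keys), numeric(1)))
  if (length(J) != 1) stop("write_manifest: mixed keypoint counts")
  hdr <- jsonlite::toJSON(list(schema = "sarn-manifest-v1", J = J),
                          auto_unbox = TRUE)
  writeLines(c(hdr, js), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("read_manifest: no such file: ", path)
  ln <- readLines(path)
  if (length(ln) < 1) stop("read_manifest: empty manifest")
  hdr <- jsonlite::fromJSON(ln[1])
  if (!identical(hdr$schema, "sarn-manifest-v1")) {
    stop("read_manifest: unsupported schema: ",
         if (is.null(hdr$schema)) "<missing>" else hdr$schema)
  }
  dir <- dirname(path)
  records <- lapply(ln[-1], function(l) {
    r <- jsonlite::fromJSON(l)
    r$keys <- matrix(r$keys, ncol = 3, byrow = TRUE)
    r
  })
  Js <- vapply(records, function(r) nrow(r$keys), numeric(1))
  if (length(unique(Js)) > 1) {
    stop("read_manifest: inconsistent keypoint counts across records")
  }
  if (length(records) > 0 && !identical(unique(Js), as.numeric(hdr$J))) {
    stop("read_manifest: records disagree with header J")
  }
  for (r in records) {
    f <- file.path(dir, r$depth)
    if (!file.exists(f)) {
      stop("read_manifest: missing depth file: ", f)
    }
  }
  structure(list(records = records, J = as.integer(hdr$J), dir = dir),
            class = "dataset_manifest")
}

#' Save synthetic frames as an on-disk dataset
#'
#' @param frames List of `synthetic_frame`s.
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest.
#' @export
save_dataset <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fn <- sprintf("frame_%05d.tif", i)
    write_depth_raster(frames[[i]]$frame, file.path(dir, fn))
    K <- frames[[i]]$frame$intrinsics
    records[[i]] <- list(depth = fn, fx = K$fx, fy = K$fy, cx = K$cx,
                         cy = K$cy, keys = frames[[i]]$keys)
  }
  write_manifest(records, file.path(dir, "manifest.jsonl"))
}

#' Load an on-disk dataset back into memory
#'
#' @param path Manifest path.
#' @return List of `synthetic_frame`-like lists with `frame` and `keys`.
#' @export
load_dataset <- function(path) {
  man <- read_manifest(path)
  lapply(man$records, function(r) {
    dep <- read_depth_raster(file.path(man$dir, r$depth))
    list(frame = depth_frame(dep, camera_intrinsics(r$fx, r$fy, r$cx,
                                                    r$cy)),
         keys = r$keys)
  })
}

config_defaults <- function() {
  list(
    model = list(C = 128L, J = 6L, stages = 2L, hourglass_depth = 4L,
                 se_ratio = 16L, theta = 0.64, out_size = 128L),
    train = list(lr = 0.001, batch = 20L, epochs = 25L,
                 plateau_factor = 0.7, plateau_patience = 3L,
                 sigma = 0.5, seed = 1L),
    augment = list(rot_deg = c(-180, 180), scale = c(0.9, 1.1),
                   trans = c(-10, 10)),
    codec = list(cube_mm = 250)
  )
}

#' Load a run configuration
#'
#' Precedence: built-in defaults, overwritten by the YAML file, overwritten
#' by explicit overrides (named list with `section.key` names). Unknown
#' sections or keys are rejected.
#'
#' @param path YAML config path, or `NULL` for defaults only.
#' @param overrides Named list, e.g. `list("train.lr" = 0.01)`.
#' @return Nested list with sections `model`, `train`, `augment`, `codec`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  apply_kv <- function(cfg, section, key, value) {
    if (!section %in% names(cfg)) {
      stop("load_config: unknown section: ", section)
    }
    if (!key %in% names(cfg[[section]])) {
      stop(sprintf("load_config: unknown key: %s.%s", section, key))
    }
    mode(value) <- mode(cfg[[section]][[key]])
    cfg[[section]][[key]] <- value
    cfg
  }
  if (!is.null(path)) {
    f <- yaml::read_yaml(path)
    for (sec in names(f)) {
      for (k in names(f[[sec]])) {
        cfg <- apply_kv(cfg, sec, k, f[[sec]][[k]])
      }
    }
  }
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop("load_config: override keys use section.key form: ", nm)
    }
    cfg <- apply_kv(cfg, parts[1], parts[2], overrides[[nm]])
  }
  cfg
}

## ---- command line --------------------------------------------------------

cli_log <- function(...) message("[sarn] ", sprintf(...))

parse_opts <- function(args) {
  opts <- list()
  pos <- character(0)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        opts[[key]] <- TRUE
        i <- i + 1
      } else {
        opts[[key]] <- args[i + 1]
        i <- i + 2
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1
    }
  }
  list(opts = opts, pos = pos)
}

opt_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

opt_chr <- function(opts, key, default = NULL) {
  v <- opts[[key]]
  if (is.null(v)) default else as.character(v)
}

#' Command-line entry point
#'
#' Subcommands: `synth` (generate pose or tapping datasets), `train`,
#' `predict` (manifest to keypoint table), `evaluate` (error report +
#' success curve) and `tap-metrics` (kinematic error report + phase
#' bands). Every subcommand takes `--seed`. Returns an exit status instead
#' of calling `quit()` so it can be driven programmatically.
#'
#' @param argv Character vector of arguments (without the program name).
#' @return Integer exit status (0 on success).
#' @export
cli_main <- function(argv) {
  status <- tryCatch({
    if (length(argv) == 0) {
      cli_log("usage: sarn <synth|train|predict|evaluate|tap-metrics> [options]")
      return(1L)
    }
    cmd <- argv[1]
    pa <- parse_opts(argv[-1])
    opts <- pa$opts
    seed <- as.integer(opt_num(opts, "seed", 1))
    switch(cmd,
      "synth" = cli_synth(opts, seed),
      "train" = cli_train(opts, seed),
      "predict" = cli_predict(opts, seed),
      "evaluate" = cli_evaluate(opts),
      "tap-metrics" = cli_tap_metrics(opts),
      { cli_log("unknown subcommand: %s", cmd); 1L })
  }, error = function(e) {
    cli_log("error: %s", conditionMessage(e))
    1L
  })
  status
}

cli_synth <- function(opts, seed) {
  mode <- opt_chr(opts, "mode", "pose")
  outdir <- opt_chr(opts, "out", "sarn_dataset")
  if (mode == "pose") {
    n <- as.integer(opt_num(opts, "n", 100))
    frames <- generate_pose_dataset(n, seed = seed)
    p <- save_dataset(frames, outdir)
    cli_log("wrote %d pose frames to %s", n, p)
  } else if (mode == "tap") {
    cfg <- tap_motion_config(taps = as.integer(opt_num(opts, "taps", 10)),
                             frames_per_tap =
                               as.integer(opt_num(opts, "frames-per-tap", 11)),
                             amplitude = opt_num(opts, "amplitude", 60),
                             noise_sd = opt_num(opts, "noise-sd", 0),
                             seed = seed)
    ts <- generate_tap_sequence(cfg)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    records <- vector("list", length(ts$frames))
    for (i in seq_along(ts$frames)) {
      fn <- sprintf("frame_%05d.tif", i)
      write_depth_raster(ts$frames[[i]], file.path(outdir, fn))
      K <- ts$frames[[i]]$intrinsics
      records[[i]] <- list(depth = fn, fx = K$fx, fy = K$fy, cx = K$cx,
                           cy = K$cy, keys = ts$truth$frames[i, , ])
    }
    p <- write_manifest(records, file.path(outdir, "manifest.jsonl"))
    write_tap_table(ts$truth, file.path(outdir, "truth_tips.csv"))
    cli_log("wrote %d tapping frames to %s", length(ts$frames), p)
  } else {
    cli_log("unknown synth mode: %s", mode)
    return(1L)
  }
  0L
}

manifest_to_samples <- function(man_path, cube_mm, out_size) {
  data <- load_dataset(man_path)
  frames <- lapply(data, function(d) {
    structure(list(frame = d$frame, keys = d$keys),
              class = "synthetic_frame")
  })
  prepare_samples(frames, cube_mm, out_size)
}

cli_train <- function(opts, seed) {
  man <- opt_chr(opts, "manifest")
  if (is.null(man)) stop("train: --manifest is required")
  cfgfile <- opt_chr(opts, "config")
  cfg <- load_config(cfgfile)
  if (!is.null(opts$epochs)) cfg$train$epochs <- as.integer(opt_num(opts, "epochs", 1))
  samples <- manifest_to_samples(man, cfg$codec$cube_mm,
                                 cfg$model$out_size)
  J <- nrow(samples[[1]]$keys)
  mc <- model_config(C = cfg$model$C, J = J, stages = cfg$model$stages,
                     hourglass_depth = cfg$model$hourglass_depth,
                     se_ratio = cfg$model$se_ratio,
                     theta = cfg$model$theta,
                     out_size = cfg$model$out_size)
  model <- sarn_init(mc, seed)
  tc <- train_config(lr = cfg$train$lr, batch = cfg$train$batch,
                     epochs = cfg$train$epochs,
                     plateau_factor = cfg$train$plateau_factor,
                     plateau_patience = cfg$train$plateau_patience,
                     sigma = cfg$train$sigma, seed = seed)
  fit <- train_model(samples, model, tc, verbose = TRUE)
  out <- opt_chr(opts, "out", "sarn_checkpoint.rds")
  save_checkpoint(fit$model, out)
  logf <- opt_chr(opts, "log", "sarn_train_log.csv")
  utils::write.csv(fit$log, logf, row.names = FALSE)
  cli_log("checkpoint: %s  log: %s  final loss %.5f", out, logf,
          utils::tail(fit$log$loss, 1))
  0L
}

cli_predict <- function(opts, seed) {
  man <- opt_chr(opts, "manifest")
  ckpt <- opt_chr(opts, "checkpoint")
  if (is.null(man) || is.null(ckpt)) {
    stop("predict: --manifest and --checkpoint are required")
  }
  model <- load_checkpoint(ckpt)
  cube <- opt_num(opts, "cube-mm", 250)
  samples <- manifest_to_samples(man, cube, model$config$out_size)
  crops <- lapply(samples, `[[`, "crop")
  pred <- predict_keypoints(model, crops)
  out <- opt_chr(opts, "out", "sarn_predictions.csv")
  write_keypoint_table(pred, out)
  cli_log("wrote %d prediction rows to %s", dim(pred)[1], out)
  0L
}

write_keypoint_table <- function(pred, path) {
  n <- dim(pred)[1]; J <- dim(pred)[2]
  m <- matrix(aperm(pred, c(1, 3, 2)), n, 3 * J)
  cols <- as.vector(t(outer(seq_len(J), c("x", "y", "z"),
                            function(j, a) paste0("k", j, "_", a))))
  df <- as.data.frame(m)
  names(df) <- cols
  df <- cbind(frame = seq_len(n), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_keypoint_table <- function(path) {
  df <- utils::read.csv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  J <- ncol(m) / 3
  aperm(array(m, c(nrow(m), 3, J)), c(1, 3, 2))
}

write_tap_table <- function(seq, path) {
  f <- seq$frames
  df <- data.frame(frame = seq$frame_index,
                   x1 = f[, 1, 1], y1 = f[, 1, 2], z1 = f[, 1, 3],
                   x2 = f[, 2, 1], y2 = f[, 2, 2], z2 = f[, 2, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_tap_table <- function(path) {
  df <- utils::read.csv(path)
  f <- array(0, c(nrow(df), 2, 3))
  f[, 1, ] <- as.matrix(df[, c("x1", "y1", "z1")])
  f[, 2, ] <- as.matrix(df[, c("x2", "y2", "z2")])
  tap_sequence(f, df$frame)
}

cli_evaluate <- function(opts) {
  man <- opt_chr(opts, "manifest")
  predf <- opt_chr(opts, "pred")
  if (is.null(man) || is.null(predf)) {
    stop("evaluate: --manifest and --pred are required")
  }
  data <- load_dataset(man)
  truth <- array(0, c(length(data), nrow(data[[1]]$keys), 3))
  for (i in seq_along(data)) truth[i, , ] <- data[[i]]$keys
  pred <- read_keypoint_table(predf)
  rep <- keypoint_errors(pred, truth)
  th <- seq(0, 80, by = 2.5)
  sc <- success_rate(pred, truth, th)
  out <- opt_chr(opts, "out", "sarn_eval")
  utils::write.csv(data.frame(keypoint = seq_along(rep$per_keypoint),
                              mean_err_mm = rep$per_keypoint),
                   paste0(out, "_errors.csv"), row.names = FALSE)
  utils::write.csv(data.frame(threshold_mm = sc$thresholds,
                              fraction = sc$fraction),
                   paste0(out, "_success.csv"), row.names = FALSE)
  cli_log("all-keypoint mean error: %.2f mm over %d frames", rep$overall,
          rep$n_frames)
  0L
}

cli_tap_metrics <- function(opts) {
  predf <- opt_chr(opts, "pred")
  truthf <- opt_chr(opts, "truth")
  if (is.null(predf) || is.null(truthf)) {
    stop("tap-metrics: --pred and --truth are required")
  }
  pred <- read_tap_table(predf)
  truth <- read_tap_table(truthf)
  rep <- tap_errors(pred, truth)
  kt <- tap_kinematics(truth)
  lb <- label_phases(kt$distance, opt_num(opts, "rest-threshold", 3))
  kp <- tap_kinematics(pred)
  bands <- phase_error_bands(abs(kp$distance - kt$distance), lb,
                             as.integer(opt_num(opts, "bins", 10)))
  out <- opt_chr(opts, "out", "sarn_tap")
  utils::write.csv(data.frame(metric = c("pos", "dis", "vel", "acc"),
                              mean = c(rep$pos$mean, rep$dis$mean,
                                       rep$vel$mean, rep$acc$mean),
                              sd = c(rep$pos$sd, rep$dis$sd, rep$vel$sd,
                                     rep$acc$sd)),
                   paste0(out, "_errors.csv"), row.names = FALSE)
  utils::write.csv(bands, paste0(out, "_phase_bands.csv"),
                   row.names = FALSE)
  print(rep)
  cli_log("detected %d taps", lb$n_taps)
  0L
}
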