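# The learnable architecture: a pre-processing stem, squeeze-and-excitation
# residual blocks, an SE-hourglass backbone per stage, a dense extraction
# head (S/V/G branches + shifted-attention fusion), and a soft input
# aggregation connector between the two stages. Parameters live in a flat
# named list keyed by dotted paths; forward functions mirror the init
# functions and run on the autodiff tape.

#' Model configuration
#'
#' @param C Stem/backbone channel width.
#' @param J Number of keypoints.
#' @param stages Number of refinement stages (1 or 2).
#' @param hourglass_depth Number of down/up levels in the hourglass.
#' @param se_ratio Squeeze-and-excitation channel reduction ratio.
#' @param theta Codec support radius in normalized crop units.
#' @param out_size Crop resolution fed to the stem; must be divisible by
#'   `2^(hourglass_depth + 1)`.
#' @return A `model_config` object.
#' @export
model_config <- function(C = 128L, J = 14L, stages = 2L,
                         hourglass_depth = 4L, se_ratio = 16L,
                         theta = 0.64, out_size = 128L) {
  stopifnot(C >= 1, J >= 1, stages >= 1, stages <= 2, hourglass_depth >= 1,
            theta > 0, out_size %% (2^(hourglass_depth + 1)) == 0)
  structure(list(C = as.integer(C), J = as.integer(J),
                 stages = as.integer(stages),
                 hourglass_depth = as.integer(hourglass_depth),
                 se_ratio = as.integer(se_ratio), theta = theta,
                 out_size = as.integer(out_size)),
            class = "model_config")
}

## ---- initialization ------------------------------------------------------

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

init_conv <- function(P, name, kh, kw, cin, cout) {
  P[[paste0(name, ".w")]] <- he_init(kh, kw, cin, cout)
  P[[paste0(name, ".b")]] <- numeric(cout)
  P
}

init_bn <- function(P, name, c) {
  P[[paste0(name, ".g")]] <- rep(1, c)
  P[[paste0(name, ".beta")]] <- numeric(c)
  P
}

init_fc <- function(P, name, cin, cout) {
  P[[paste0(name, ".w")]] <- matrix(rnorm(cin * cout, sd = sqrt(2 / cin)),
                                    cin, cout)
  P[[paste0(name, ".b")]] <- numeric(cout)
  P
}

init_se_res <- function(P, name, c, ratio) {
  cr <- max(1L, c %/% ratio)
  P <- init_conv(P, paste0(name, ".conv1"), 3, 3, c, c)
  P <- init_bn(P, paste0(name, ".bn1"), c)
  P <- init_conv(P, paste0(name, ".conv2"), 3, 3, c, c)
  P <- init_bn(P, paste0(name, ".bn2"), c)
  P <- init_fc(P, paste0(name, ".se1"), c, cr)
  P <- init_fc(P, paste0(name, ".se2"), cr, c)
  P
}

init_hourglass <- function(P, name, c, depth, ratio) {
  for (l in seq_len(depth)) {
    P <- init_se_res(P, sprintf("%s.l%d.down", name, l), c, ratio)
    P <- init_se_res(P, sprintf("%s.l%d.up", name, l), c, ratio)
  }
  init_se_res(P, paste0(name, ".inner"), c, ratio)
}

init_dense_extract <- function(P, name, C, J, ratio) {
  P <- init_se_res(P, paste0(name, ".res"), C, ratio)
  P <- init_conv(P, paste0(name, ".conv"), 3, 3, C, C)
  P <- init_bn(P, paste0(name, ".bn"), C)
  # zero-started offset head: initial votes degenerate to the attention
  # centroid of pixel positions, which keeps early integration stable
  P <- init_conv(P, paste0(name, ".v"), 1, 1, C, 3L * J)
  P[[paste0(name, ".v.w")]][] <- 0
  P <- init_conv(P, paste0(name, ".s"), 1, 1, C, J)
  P <- init_conv(P, paste0(name, ".g"), 1, 1, C, J)
  # start the fusion leaning on the supervised closeness map (alpha ~ 0.88)
  # so early attention is informative; training moves it freely
  P[[paste0(name, ".alpha")]] <- rep(2, J)
  P
}

init_stem <- function(P, name, C, ratio) {
  P <- init_conv(P, paste0(name, ".conv"), 7, 7, 1, C)
  P <- init_bn(P, paste0(name, ".bn"), C)
  init_se_res(P, paste0(name, ".res"), C, ratio)
}

init_aggregate <- function(P, name, C, J) {
  P <- init_conv(P, paste0(name, ".a"), 3, 3, C, C)
  P <- init_conv(P, paste0(name, ".f"), 3, 3, C, C)
  P <- init_conv(P, paste0(name, ".vh"), 3, 3, 4L * J, C)
  P[[paste0(name, ".beta")]] <- rep(1, C)  # identity-like start
  P
}

#' Initialize a model
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the parameter draw.
#' @return A `sarn_model`: list with `config`, flat parameter list `params`
#'   and an environment `bn` of batch-norm running moments.
#' @export
sarn_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  P <- list()
  P <- init_stem(P, "stem", config$C, config$se_ratio)
  P <- init_hourglass(P, "st1.hg", config$C, config$hourglass_depth,
                      config$se_ratio)
  P <- init_dense_extract(P, "st1.ext", config$C, config$J, config$se_ratio)
  if (config$stages >= 2) {
    P <- init_aggregate(P, "agg", config$C, config$J)
    P <- init_hourglass(P, "st2.hg", config$C, config$hourglass_depth,
                        config$se_ratio)
    P <- init_dense_extract(P, "st2.ext", config$C, config$J,
                            config$se_ratio)
  }
  structure(list(config = config, params = P,
                 bn = new.env(parent = emptyenv())),
            class = "sarn_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.sarn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cfg <- x$config
  cat(sprintf(paste0("<sarn_model: %d stage(s), C=%d, J=%d, hourglass depth ",
                     "%d, %s parameters>\n"),
              cfg$stages, cfg$C, cfg$J, cfg$hourglass_depth,
              format(np, big.mark = ",")))
  invisible(x)
}

#' Number of learnable parameters
#' @param model A `sarn_model`.
#' @return Integer count of scalar parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

## ---- forward -------------------------------------------------------------

# Register every parameter on the tape; returns a named list of node ids.
params_to_nodes <- function(tape, P) {
  lapply(P, function(v) tp_param(tape, v))
}

fwd_conv <- function(tape, Pn, name, x, stride = 1L, pad = 1L) {
  tp_conv(tape, x, Pn[[paste0(name, ".w")]], Pn[[paste0(name, ".b")]],
          stride, pad)
}

fwd_bn <- function(tape, Pn, name, x, bn, training) {
  tp_bn(tape, x, Pn[[paste0(name, ".g")]], Pn[[paste0(name, ".beta")]],
        bn, name, training)
}

# Residual block with squeeze-and-excitation gating of the conv branch:
# out = x + gate(GAP(branch)) * branch, branch = bn2(conv2(relu(bn1(conv1 x)))).
fwd_se_res <- function(tape, Pn, name, x, bn, training) {
  h <- fwd_conv(tape, Pn, paste0(name, ".conv1"), x)
  h <- fwd_bn(tape, Pn, paste0(name, ".bn1"), h, bn, training)
  h <- tp_relu(tape, h)
  h <- fwd_conv(tape, Pn, paste0(name, ".conv2"), h)
  h <- fwd_bn(tape, Pn, paste0(name, ".bn2"), h, bn, training)
  g <- tp_gap(tape, h)
  g <- tp_fc(tape, g, Pn[[paste0(name, ".se1.w")]],
             Pn[[paste0(name, ".se1.b")]])
  g <- tp_relu(tape, g)
  g <- tp_fc(tape, g, Pn[[paste0(name, ".se2.w")]],
             Pn[[paste0(name, ".se2.b")]])
  g <- tp_sigmoid(tape, g)
  h <- tp_scale_chan(tape, h, g)
  tp_add(tape, x, h)
}

# Recursive hourglass level: identity skip at full resolution, SE-residual
# processing on the pooled path, nearest-neighbour upsampling back.
fwd_hourglass <- function(tape, Pn, name, x, depth, bn, training,
                          level = 1L) {
  lo <- tp_maxpool2(tape, x)
  lo <- fwd_se_res(tape, Pn, sprintf("%s.l%d.down", name, level), lo, bn,
                   training)
  mid <- if (level < depth) {
    fwd_hourglass(tape, Pn, name, lo, depth, bn, training, level + 1L)
  } else {
    fwd_se_res(tape, Pn, paste0(name, ".inner"), lo, bn, training)
  }
  up <- fwd_se_res(tape, Pn, sprintf("%s.l%d.up", name, level), mid, bn,
                   training)
  tp_add(tape, x, tp_upsample2(tape, up))
}

fwd_stem <- function(tape, Pn, x, bn, training) {
  h <- fwd_conv(tape, Pn, "stem.conv", x, stride = 2L, pad = 3L)
  h <- fwd_bn(tape, Pn, "stem.bn", h, bn, training)
  h <- tp_relu(tape, h)
  fwd_se_res(tape, Pn, "stem.res", h, bn, training)
}

# Dense extraction head: feature extractor then three parallel 1x1 conv
# branches (V linear; S and G sigmoid) and the channel-wise fusion
# H = alpha * S + (1 - alpha) * G with stage-wise learnable alpha.
fwd_dense_extract <- function(tape, Pn, name, q, bn, training) {
  f <- fwd_se_res(tape, Pn, paste0(name, ".res"), q, bn, training)
  f <- fwd_conv(tape, Pn, paste0(name, ".conv"), f)
  f <- fwd_bn(tape, Pn, paste0(name, ".bn"), f, bn, training)
  f <- tp_relu(tape, f)
  v <- fwd_conv(tape, Pn, paste0(name, ".v"), f, pad = 0L)
  s <- tp_sigmoid(tape, fwd_conv(tape, Pn, paste0(name, ".s"), f, pad = 0L))
  g <- tp_sigmoid(tape, fwd_conv(tape, Pn, paste0(name, ".g"), f, pad = 0L))
  alpha <- tp_sigmoid(tape, Pn[[paste0(name, ".alpha")]])
  h <- tp_add(tape, tp_scale_chan(tape, s, alpha),
              tp_scale_chan(tape, g, tp_affine(tape, alpha, -1, 1)))
  list(F = f, S = s, V = v, G = g, H = h, alpha = alpha)
}

# Soft input aggregation:
# I2 = conv_a(I1) + conv_f(F1) + conv_vh(concat(V1, H1)) + beta (.) I1.
fwd_aggregate <- function(tape, Pn, i1, f1, v1, h1) {
  a <- fwd_conv(tape, Pn, "agg.a", i1)
  f <- fwd_conv(tape, Pn, "agg.f", f1)
  vh <- tp_concat_chan(tape, list(v1, h1))
  vh <- fwd_conv(tape, Pn, "agg.vh", vh)
  sc <- tp_scale_chan(tape, i1, Pn[["agg.beta"]])
  tp_add(tape, tp_add(tape, a, f), tp_add(tape, vh, sc))
}

# Attention normalization inside the graph: clamp, mask, divide by the
# per-channel mass (strictly positive here since S and G are sigmoids and
# every sample has at least one valid pixel).
fwd_norm_attention <- function(tape, h, mask_full) {
  r <- tp_relu(tape, h)
  r <- tp_mul_const(tape, r, mask_full)
  s <- tp_chan_sum(tape, r)
  sv <- tp_val(tape, s)
  if (any(sv <= 0)) stop("attention mass vanished; no valid pixels?")
  tp_div_chan(tape, r, s)
}

#' Assemble a batch from crop samples
#'
#' @param samples List of `crop_sample` objects (see
#'   [crop_and_normalize()]), all with the same `out_size`.
#' @return List with `img` (os x os x N x 1), `points` (hs x hs x N x 3)
#'   and `mask` (hs x hs x N logical).
#' @export
assemble_batch <- function(samples) {
  if (inherits(samples, "crop_sample")) samples <- list(samples)
  N <- length(samples)
  os <- samples[[1]]$spec$out_size
  hs <- os %/% 2L
  img <- array(0, c(os, os, N, 1L))
  pts <- array(0, c(hs, hs, N, 3L))
  msk <- array(FALSE, c(hs, hs, N))
  for (n in seq_len(N)) {
    s <- samples[[n]]
    img[, , n, 1L] <- s$image
    pts[, , n, ] <- s$points
    msk[, , n] <- s$valid_mask
  }
  list(img = img, points = pts, mask = msk)
}

#' Run the two-stage forward pass
#'
#' stem -> stage-1 (hourglass + dense extraction) -> soft input aggregation
#' -> stage-2 (hourglass + dense extraction) -> attention normalization ->
#' pixel-wise integration on the last stage's outputs. Keypoints are
#' returned in normalized crop coordinates.
#'
#' @param model A `sarn_model`.
#' @param batch A batch from [assemble_batch()], or a single `crop_sample`,
#'   or a list of them.
#' @param training Logical; batch-norm uses batch statistics and running
#'   moments are updated when `TRUE`.
#' @param tape Optionally a pre-made tape (with parameters already pushed
#'   via `nodes`); when `NULL` a fresh tape is used internally.
#' @return A `sarn_outputs` list: `keypoints` (J x 3 x N, normalized crop
#'   coordinates), per-stage outputs `stages` (each with S, V, G, H, F, Q
#'   numeric arrays), `H_norm`, and — for training — `tape`, `param_nodes`
#'   and the node ids `nodes` of the keypoints and last-stage S/V.
#' @export
sarn_forward <- function(model, batch, training = FALSE, tape = NULL) {
  cfg <- model$config
  if (!is.list(batch) || is.null(batch$img)) batch <- assemble_batch(batch)
  d <- dim(batch$img)
  if (d[1] != cfg$out_size || d[2] != cfg$out_size) {
    stop(sprintf("sarn_forward: input is %dx%d but the model expects %dx%d",
                 d[1], d[2], cfg$out_size, cfg$out_size))
  }
  N <- d[3]
  hs <- cfg$out_size %/% 2L
  if (is.null(tape)) tape <- tape_new()
  Pn <- params_to_nodes(tape, model$params)
  x <- tp_const(tape, batch$img)
  mask_full <- array(rep(as.numeric(batch$mask), cfg$J),
                     c(hs, hs, N, cfg$J))
  i1 <- fwd_stem(tape, Pn, x, model$bn, training)
  q1 <- fwd_hourglass(tape, Pn, "st1.hg", i1, cfg$hourglass_depth,
                      model$bn, training)
  e1 <- fwd_dense_extract(tape, Pn, "st1.ext", q1, model$bn, training)
  stages <- list(list(Q = q1, ext = e1))
  if (cfg$stages >= 2) {
    i2 <- fwd_aggregate(tape, Pn, i1, e1$F, e1$V, e1$H)
    q2 <- fwd_hourglass(tape, Pn, "st2.hg", i2, cfg$hourglass_depth,
                        model$bn, training)
    e2 <- fwd_dense_extract(tape, Pn, "st2.ext", q2, model$bn, training)
    stages <- c(stages, list(list(Q = q2, ext = e2)))
  }
  last <- stages[[length(stages)]]$ext
  hn <- fwd_norm_attention(tape, last$H, mask_full)
  kp <- tp_integrate(tape, last$S, last$V, hn, batch$points, cfg$theta)
  out <- list(
    keypoints = tp_val(tape, kp),
    H_norm = tp_val(tape, hn),
    stages = lapply(stages, function(st) {
      e <- st$ext
      list(Q = tp_val(tape, st$Q), F = tp_val(tape, e$F),
           S = tp_val(tape, e$S), V = tp_val(tape, e$V),
           G = tp_val(tape, e$G), H = tp_val(tape, e$H),
           alpha = tp_val(tape, e$alpha))
    }),
    tape = tape, param_nodes = Pn,
    nodes = list(keypoints = kp, S = last$S, V = last$V, H_norm = hn)
  )
  class(out) <- "sarn_outputs"
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds every parameter, the configuration and the
#' batch-norm running moments; save followed by load is bit-exact.
#'
#' @param model A `sarn_model`.
#' @param path File path.
#' @return `load_checkpoint` returns the restored `sarn_model`.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(config = unclass(model$config), params = model$params,
              bn = as.list(model$bn))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  bn <- new.env(parent = emptyenv())
  for (k in names(obj$bn)) bn[[k]] <- obj$bn[[k]]
  structure(list(config = do.call(model_config, obj$config),
                 params = obj$params, bn = bn),
            class = "sarn_model")
}
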