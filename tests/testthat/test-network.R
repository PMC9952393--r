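test_that("stem halves resolution and produces C channels", {
  for (co in list(c(16L, 64L), c(32L, 64L))) {
    cfg <- tiny_config(C = co[1], out_size = co[2], hourglass_depth = 3L)
    model <- sarn_init(cfg, seed = 1)
    b <- random_batch(cfg, N = 1L, seed = 2)
    tape <- tape_new()
    Pn <- sarn:::params_to_nodes(tape, model$params)
    x <- tp_const(tape, b$img)
    i1 <- sarn:::fwd_stem(tape, Pn, x, model$bn, FALSE)
    expect_equal(dim(tp_val(tape, i1)),
                 c(co[2] / 2, co[2] / 2, 1, co[1]))
  }
  # wrong input size is rejected
  cfg <- tiny_config()
  model <- sarn_init(cfg, seed = 1)
  bad <- random_batch(tiny_config(out_size = 32L), N = 1L)
  expect_error(sarn_forward(model, bad), "expects")
})

test_that("SE-residual block reduces to its shortcut when the branch is zero", {
  cfg <- tiny_config()
  model <- sarn_init(cfg, seed = 5)
  # zero the conv branch of one block: output must equal input exactly
  for (nm in c("st1.ext.res.conv1.w", "st1.ext.res.conv1.b",
               "st1.ext.res.conv2.w", "st1.ext.res.conv2.b",
               "st1.ext.res.bn1.beta", "st1.ext.res.bn2.beta")) {
    model$params[[nm]][] <- 0
  }
  x <- array(rnorm(8 * 8 * 2 * cfg$C), c(8, 8, 2, cfg$C))
  tape <- tape_new()
  Pn <- sarn:::params_to_nodes(tape, model$params)
  xn <- tp_const(tape, x)
  y <- sarn:::fwd_se_res(tape, Pn, "st1.ext.res", xn, model$bn, TRUE)
  expect_close(tp_val(tape, y), x, 1e-12)
})

test_that("SE gate forced open reproduces the plain residual block", {
  cfg <- tiny_config()
  model <- sarn_init(cfg, seed = 6)
  model$params[["st1.ext.res.se1.w"]][] <- 0
  model$params[["st1.ext.res.se1.b"]][] <- 0
  model$params[["st1.ext.res.se2.w"]][] <- 0
  model$params[["st1.ext.res.se2.b"]][] <- 40  # sigmoid(40) ~ 1
  x <- array(rnorm(8 * 8 * 2 * cfg$C), c(8, 8, 2, cfg$C))
  tape <- tape_new()
  Pn <- sarn:::params_to_nodes(tape, model$params)
  y <- sarn:::fwd_se_res(tape, Pn, "st1.ext.res", tp_const(tape, x),
                         model$bn, TRUE)
  # plain residual: x + bn2(conv2(relu(bn1(conv1 x)))) computed by hand
  P <- model$params
  st <- new.env()
  h <- conv_fwd(x, P[["st1.ext.res.conv1.w"]],
                P[["st1.ext.res.conv1.b"]], 1L, 1L)$y
  t2 <- tape_new()
  h <- tp_val(t2, tp_bn(t2, tp_const(t2, h),
                        tp_const(t2, P[["st1.ext.res.bn1.g"]]),
                        tp_const(t2, P[["st1.ext.res.bn1.beta"]]),
                        st, "a", TRUE))
  h <- h * (h > 0)
  h <- conv_fwd(h, P[["st1.ext.res.conv2.w"]],
                P[["st1.ext.res.conv2.b"]], 1L, 1L)$y
  h <- tp_val(t2, tp_bn(t2, tp_const(t2, h),
                        tp_const(t2, P[["st1.ext.res.bn2.g"]]),
                        tp_const(t2, P[["st1.ext.res.bn2.beta"]]),
                        st, "b", TRUE))
  expect_close(tp_val(tape, y), x + h, 1e-9)
})

test_that("hourglass preserves shape at all depths", {
  for (depth in 1:3) {
    cfg <- tiny_config(hourglass_depth = depth,
                       out_size = as.integer(2^(depth + 1) * 4))
    model <- sarn_init(cfg, seed = 2)
    hs <- cfg$out_size / 2
    x <- array(rnorm(hs * hs * 1 * cfg$C), c(hs, hs, 1, cfg$C))
    tape <- tape_new()
    Pn <- sarn:::params_to_nodes(tape, model$params)
    y <- sarn:::fwd_hourglass(tape, Pn, "st1.hg", tp_const(tape, x),
                              depth, model$bn, FALSE)
    expect_equal(dim(tp_val(tape, y)), dim(x))
  }
  expect_error(model_config(C = 8, J = 2, out_size = 24,
                            hourglass_depth = 4), "out_size")
})

test_that("dense extraction emits (3J, J, J, J) channels in range", {
  cfg <- tiny_config(J = 5L)
  model <- sarn_init(cfg, seed = 4)
  b <- random_batch(cfg, N = 2L, seed = 3)
  out <- sarn_forward(model, b)
  e <- out$stages[[2]]
  hs <- cfg$out_size / 2
  expect_equal(dim(e$V), c(hs, hs, 2, 15))
  expect_equal(dim(e$S), c(hs, hs, 2, 5))
  expect_equal(dim(e$G), c(hs, hs, 2, 5))
  expect_equal(dim(e$H), c(hs, hs, 2, 5))
  expect_true(all(e$S >= 0 & e$S <= 1))   # sigmoid range (closed in fp)
  expect_true(all(e$G >= 0 & e$G <= 1))
  # H is the alpha-fused convex combination
  expect_true(all(e$H >= pmin(e$S, e$G) - 1e-12 &
                    e$H <= pmax(e$S, e$G) + 1e-12))
})

test_that("alpha saturated high collapses the fusion onto S", {
  cfg <- tiny_config()
  model <- sarn_init(cfg, seed = 8)
  model$params[["st2.ext.alpha"]][] <- 40   # sigmoid -> 1
  b <- random_batch(cfg, N = 1L, seed = 5)
  out <- sarn_forward(model, b)
  e <- out$stages[[2]]
  expect_close(e$H, e$S, 1e-12)
})

test_that("soft aggregation with zero convs and unit beta is the identity", {
  cfg <- tiny_config()
  model <- sarn_init(cfg, seed = 9)
  for (nm in c("agg.a.w", "agg.a.b", "agg.f.w", "agg.f.b", "agg.vh.w",
               "agg.vh.b")) {
    model$params[[nm]][] <- 0
  }
  model$params[["agg.beta"]][] <- 1
  hs <- cfg$out_size / 2
  mk <- function(ch) array(rnorm(hs * hs * 2 * ch), c(hs, hs, 2, ch))
  i1v <- mk(cfg$C); f1v <- mk(cfg$C); v1v <- mk(3 * cfg$J)
  h1v <- mk(cfg$J)
  tape <- tape_new()
  Pn <- sarn:::params_to_nodes(tape, model$params)
  i2 <- sarn:::fwd_aggregate(tape, Pn, tp_const(tape, i1v),
                             tp_const(tape, f1v), tp_const(tape, v1v),
                             tp_const(tape, h1v))
  expect_close(tp_val(tape, i2), i1v, 1e-12)
  # beta = 0 zeroes the output entirely
  model$params[["agg.beta"]][] <- 0
  tape <- tape_new()
  Pn <- sarn:::params_to_nodes(tape, model$params)
  i2 <- sarn:::fwd_aggregate(tape, Pn, tp_const(tape, i1v),
                             tp_const(tape, f1v), tp_const(tape, v1v),
                             tp_const(tape, h1v))
  expect_close(tp_val(tape, i2), 0 * i1v, 1e-12)
})

test_that("soft aggregation is linear in its input when biases vanish", {
  cfg <- tiny_config()
  model <- sarn_init(cfg, seed = 10)
  model$params[["agg.a.b"]][] <- 0
  hs <- cfg$out_size / 2
  zero <- array(0, c(hs, hs, 1, cfg$C))
  zjv <- array(0, c(hs, hs, 1, 3 * cfg$J))
  zjh <- array(0, c(hs, hs, 1, cfg$J))
  i1v <- array(rnorm(hs * hs * cfg$C), c(hs, hs, 1, cfg$C))
  run <- function(iv) {
    # keep F/V/H at zero so only conv_a and beta act (conv biases zeroed)
    m <- model
    m$params[["agg.f.b"]][] <- 0
    m$params[["agg.vh.b"]][] <- 0
    tape <- tape_new()
    Pn <- sarn:::params_to_nodes(tape, m$params)
    tp_val(tape, sarn:::fwd_aggregate(tape, Pn, tp_const(tape, iv),
                                      tp_const(tape, zero),
                                      tp_const(tape, zjv),
                                      tp_const(tape, zjh)))
  }
  y1 <- run(i1v)
  y2 <- run(2.5 * i1v)
  expect_close(y2, 2.5 * y1, 1e-9)
})

test_that("forward pass is deterministic and bounded in inference mode", {
  cfg <- tiny_config()
  model <- sarn_init(cfg, seed = 11)
  b <- random_batch(cfg, N = 2L, seed = 6)
  o1 <- sarn_forward(model, b)
  o2 <- sarn_forward(model, b)
  expect_identical(o1$keypoints, o2$keypoints)
  expect_true(all(is.finite(o1$keypoints)))
  # Eq-(6) bound: |pbar| <= max |p| + theta * (1 + max |V|)
  bound <- max(abs(b$points)) +
    cfg$theta * (1 + max(abs(o1$stages[[2]]$V)))
  expect_true(all(abs(o1$keypoints) <= bound))
})

test_that("a one-stage model integrates its first-stage outputs", {
  cfg <- tiny_config(stages = 1L)
  model <- sarn_init(cfg, seed = 12)
  expect_false(any(grepl("^st2|^agg", names(model$params))))
  b <- random_batch(cfg, N = 2L, seed = 7)
  out <- sarn_forward(model, b)
  expect_length(out$stages, 1)
  expect_equal(dim(out$keypoints), c(cfg$J, 3, 2))
  # recomputing the integration from stage-1 outputs reproduces keypoints
  e <- out$stages[[1]]
  for (n in 1:2) {
    hn <- out$H_norm[, , n, , drop = FALSE]
    dim(hn) <- dim(hn)[c(1, 2, 4)]
    S <- e$S[, , n, , drop = FALSE]; dim(S) <- dim(hn)
    V <- e$V[, , n, , drop = FALSE]
    dim(V) <- c(dim(hn)[1:2], 3 * cfg$J)
    P <- b$points[, , n, , drop = FALSE]
    dim(P) <- c(dim(hn)[1:2], 3)
    rec <- integrate_keypoints(S, V, hn, P, cfg$theta)
    expect_close(rec, out$keypoints[, , n], 1e-9)
  }
})

test_that("oracle injection through the graph reproduces ground truth", {
  # bypass the backbone: feed ground-truth S, V and support-confined
  # attention into the integration stage ops
  cl <- random_cloud(8, 3, seed = 21)
  tg <- encode_dense(cl$keys, cl$points, cl$mask, 0.8)
  stopifnot(all(apply(tg$support, 3, sum) > 0))
  hs <- 8
  tape <- tape_new()
  S <- tp_const(tape, array(tg$S, c(hs, hs, 1, 3)))
  V <- tp_const(tape, array(tg$V, c(hs, hs, 1, 9)))
  Hn <- normalize_attention(tg$S, cl$mask)
  H <- tp_param(tape, array(Hn, c(hs, hs, 1, 3)))
  P <- array(cl$points, c(hs, hs, 1, 3))
  kp <- tp_integrate(tape, S, V, H, P, 0.8)
  expect_close(tp_val(tape, kp)[, , 1], cl$keys, 1e-6)
})

test_that("checkpoints round-trip bit-exactly", {
  cfg <- tiny_config()
  model <- sarn_init(cfg, seed = 13)
  b <- random_batch(cfg, N = 2L, seed = 8)
  invisible(sarn_forward(model, b, training = TRUE))  # populate bn stats
  f <- tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, model$params)
  expect_identical(unclass(m2$config), unclass(model$config))
  k <- sort(names(as.list(model$bn)))
  expect_identical(as.list(m2$bn)[k], as.list(model$bn)[k])
  o1 <- sarn_forward(model, b)
  o2 <- sarn_forward(m2, b)
  expect_identical(o1$keypoints, o2$keypoints)
  unlink(f)
})

test_that("shape contracts hold across the configuration grid", {
  grid <- list(list(os = 64L, C = 16L, st = 1L),
               list(os = 64L, C = 32L, st = 2L),
               list(os = 128L, C = 16L, st = 2L))
  for (g in grid) {
    cfg <- model_config(C = g$C, J = 4L, stages = g$st,
                        hourglass_depth = 3L, se_ratio = 8L,
                        theta = 0.64, out_size = g$os)
    model <- sarn_init(cfg, seed = 14)
    b <- random_batch(cfg, N = 1L, seed = 9)
    out <- sarn_forward(model, b)
    hs <- g$os / 2
    expect_equal(dim(out$keypoints), c(4, 3, 1))
    for (st in out$stages) {
      expect_equal(dim(st$Q), c(hs, hs, 1, g$C))
      expect_equal(dim(st$S), c(hs, hs, 1, 4))
      expect_equal(dim(st$V), c(hs, hs, 1, 12))
    }
    expect_length(out$stages, g$st)
  }
})
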