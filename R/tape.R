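# Minimal reverse-mode automatic differentiation on a linear tape. Every
# tp_* op appends a node holding its value, parent indices and a backward
# closure mapping the output gradient to parent gradients. tp_backward()
# sweeps the tape once in reverse. Only the few tensor primitives the
# network needs are implemented; each has a finite-difference test.

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

tp_push <- function(tape, val, parents = integer(0), backfn = NULL,
                    req = NULL) {
  if (is.null(req)) {
    req <- FALSE
    for (p in parents) if (tape$nodes[[p]]$req) { req <- TRUE; break }
  }
  i <- tape$n + 1L
  if (i > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[i]] <- list(val = val, parents = parents, backfn = backfn,
                          req = req)
  tape$n <- i
  i
}

tp_val <- function(tape, i) {
  force(i)  # nested ops may append to the tape while building the index
  tape$nodes[[i]]$val
}

tp_const <- function(tape, val) tp_push(tape, val, req = FALSE)

tp_param <- function(tape, val) tp_push(tape, val, req = TRUE)

# Reverse sweep from a scalar loss node. Returns the list of gradients
# indexed by node; leaves that were never reached have NULL gradient.
tp_backward <- function(tape, loss) {
  n <- tape$n
  grads <- vector("list", n)
  grads[[loss]] <- 1
  for (i in n:1) {
    nd <- tape$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g) || is.null(nd$backfn) || !nd$req) next
    pg <- nd$backfn(g)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[k]
      if (!tape$nodes[[p]]$req || is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
    grads[i] <- list(NULL)  # free memory as we go
  }
  grads
}

## ---- primitives ----------------------------------------------------------

tp_conv <- function(tape, x, w, b, stride = 1L, pad = 1L) {
  xv <- tp_val(tape, x); wv <- tp_val(tape, w); bv <- tp_val(tape, b)
  f <- conv_fwd(xv, wv, bv, stride, pad)
  xdim <- dim(xv)
  col <- f$col
  tp_push(tape, f$y, c(x, w, b), function(gy) {
    g <- conv_bwd(gy, col, wv, xdim, stride, pad)
    list(g$gx, g$gw, g$gb)
  })
}

tp_relu <- function(tape, x) {
  v <- tp_val(tape, x)
  y <- v * (v > 0)
  tp_push(tape, y, x, function(gy) list(gy * (v > 0)))
}

tp_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-tp_val(tape, x)))
  tp_push(tape, y, x, function(gy) list(gy * y * (1 - y)))
}

tp_add <- function(tape, a, b) {
  tp_push(tape, tp_val(tape, a) + tp_val(tape, b), c(a, b),
          function(gy) list(gy, gy))
}

# y = a*x + b for scalar constants a, b.
tp_affine <- function(tape, x, a = 1, b = 0) {
  tp_push(tape, a * tp_val(tape, x) + b, x, function(gy) list(a * gy))
}

# Elementwise product with a constant array (e.g. a validity mask).
tp_mul_const <- function(tape, x, m) {
  tp_push(tape, tp_val(tape, x) * m, x, function(gy) list(gy * m))
}

# Channel-wise scaling: s is a length-C vector node or an (N x C) matrix
# node (per-sample gates, as in squeeze-and-excitation).
tp_scale_chan <- function(tape, x, s) {
  xv <- tp_val(tape, x); sv <- tp_val(tape, s)
  d <- dim(xv)
  sb <- expand_chan(sv, d)
  tp_push(tape, xv * sb, c(x, s), function(gy) {
    gs_full <- gy * xv
    if (is.matrix(sv)) {
      gs <- chan_sum(gs_full)
    } else {
      gs <- colSums(matrix(gs_full, d[1] * d[2] * d[3], d[4]))
    }
    list(gy * sb, gs)
  })
}

# Per-channel division y = x / s with s an (N x C) matrix node of positive
# channel masses (attention normalization).
tp_div_chan <- function(tape, x, s) {
  xv <- tp_val(tape, x); sv <- tp_val(tape, s)
  d <- dim(xv)
  sb <- expand_chan(sv, d)
  y <- xv / sb
  tp_push(tape, y, c(x, s), function(gy) {
    gs <- -chan_sum(gy * y) / sv
    list(gy / sb, gs)
  })
}

tp_chan_sum <- function(tape, x) {
  xv <- tp_val(tape, x)
  d <- dim(xv)
  tp_push(tape, chan_sum(xv), x, function(gy) {
    list(expand_chan(gy, d))
  })
}

# Global average pooling to an N x C matrix.
tp_gap <- function(tape, x) {
  xv <- tp_val(tape, x)
  d <- dim(xv)
  m <- d[1] * d[2]
  tp_push(tape, chan_sum(xv) / m, x, function(gy) {
    list(expand_chan(gy, d) / m)
  })
}

# Fully connected on N x Cin matrices: y = x W + 1 b'.
tp_fc <- function(tape, x, w, b) {
  xv <- tp_val(tape, x); wv <- tp_val(tape, w); bv <- tp_val(tape, b)
  y <- xv %*% wv + rep(bv, each = nrow(xv))
  tp_push(tape, y, c(x, w, b), function(gy) {
    list(gy %*% t(wv), crossprod(xv, gy), colSums(gy))
  })
}

tp_maxpool2 <- function(tape, x) {
  xv <- tp_val(tape, x)
  y <- maxpool2_fwd(xv)
  tp_push(tape, y, x, function(gy) list(maxpool2_bwd(gy, xv, y)))
}

tp_upsample2 <- function(tape, x) {
  tp_push(tape, upsample2_fwd(tp_val(tape, x)), x,
          function(gy) list(upsample2_bwd(gy)))
}

tp_concat_chan <- function(tape, xs) {
  vals <- lapply(xs, function(i) tp_val(tape, i))
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[4], numeric(1))
  y <- array(unlist(vals, use.names = FALSE),
             dim = c(d1[1], d1[2], d1[3], sum(cs)))
  ends <- cumsum(cs)
  starts <- ends - cs + 1
  tp_push(tape, y, unlist(xs), function(gy) {
    lapply(seq_along(xs), function(k) {
      gy[, , , starts[k]:ends[k], drop = FALSE]
    })
  })
}

# Batch normalization over (H, W, N) per channel. `state` is an environment
# holding running moments under `key` for inference mode.
tp_bn <- function(tape, x, gamma, beta, state, key, training,
                  momentum = 0.1, eps = 1e-5) {
  xv <- tp_val(tape, x); gv <- tp_val(tape, gamma); bv <- tp_val(tape, beta)
  d <- dim(xv)
  m <- d[1] * d[2] * d[3]
  xm <- xv
  dim(xm) <- c(m, d[4])
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    va[va < 0] <- 0
    st <- state[[key]]
    if (is.null(st)) st <- list(mean = mu * 0, var = mu * 0 + 1)
    state[[key]] <- list(mean = (1 - momentum) * st$mean + momentum * mu,
                         var = (1 - momentum) * st$var + momentum * va)
  } else {
    st <- state[[key]]
    if (is.null(st)) st <- list(mean = numeric(d[4]), var = rep(1, d[4]))
    mu <- st$mean
    va <- st$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = m)) * rep(inv, each = m)
  y <- xhat * rep(gv, each = m) + rep(bv, each = m)
  dim(y) <- d
  tp_push(tape, y, c(x, gamma, beta), function(gy) {
    gym <- gy
    dim(gym) <- c(m, d[4])
    dgamma <- colSums(gym * xhat)
    dbeta <- colSums(gym)
    if (training) {
      gx <- (gym - rep(dbeta / m, each = m) -
               xhat * rep(dgamma / m, each = m)) *
        rep(gv * inv, each = m)
    } else {
      gx <- gym * rep(gv * inv, each = m)
    }
    dim(gx) <- d
    list(gx, dgamma, dbeta)
  })
}

# Pixel-wise integration of dense predictions into keypoints:
# pbar[j,] = sum_p ((theta*S_j(p) - theta) * V_j(p) + p) * H_j(p).
# S, H: (h, w, N, J); V: (h, w, N, 3J) with channel 3(j-1)+k = coordinate k
# of keypoint j; points: constant (h, w, N, 3). Output (J, 3, N).
tp_integrate <- function(tape, S, V, H, points, theta) {
  Sv <- tp_val(tape, S); Vv <- tp_val(tape, V); Hv <- tp_val(tape, H)
  d <- dim(Sv)
  J <- d[4]; N <- d[3]; m <- d[1] * d[2]
  dim(Sv) <- c(m, N, J); dim(Hv) <- c(m, N, J)
  dim(Vv) <- c(m, N, 3L * J)
  P <- points
  dim(P) <- c(m, N, 3L)
  out <- array(0, c(J, 3L, N))
  for (j in seq_len(J)) {
    rad <- theta * matrix(Sv[, , j], m, N) - theta
    hj <- matrix(Hv[, , j], m, N)
    for (k in 1:3) {
      votes <- rad * matrix(Vv[, , 3L * (j - 1L) + k], m, N) +
        matrix(P[, , k], m, N)
      out[j, k, ] <- colSums(votes * hj)
    }
  }
  tp_push(tape, out, c(S, V, H), function(gy) {
    gS <- array(0, c(m, N, J)); gV <- array(0, c(m, N, 3L * J))
    gH <- array(0, c(m, N, J))
    for (j in seq_len(J)) {
      rad <- theta * matrix(Sv[, , j], m, N) - theta
      hj <- matrix(Hv[, , j], m, N)
      for (k in 1:3) {
        gjk <- rep(gy[j, k, ], each = m)     # m x N broadcast of gy[j,k,n]
        dim(gjk) <- c(m, N)
        vch <- 3L * (j - 1L) + k
        vv <- matrix(Vv[, , vch], m, N)
        votes <- rad * vv + matrix(P[, , k], m, N)
        gH[, , j] <- gH[, , j] + gjk * votes
        gV[, , vch] <- gjk * hj * rad
        gS[, , j] <- gS[, , j] + gjk * hj * theta * vv
      }
    }
    dim(gS) <- d; dim(gH) <- d; dim(gV) <- c(d[1], d[2], N, 3L * J)
    list(gS, gV, gH)
  })
}

# Smooth-L1 (Huber) loss against a constant target, scaled by `scale`
# (reduction is chosen by the caller through the scale factor).
tp_smoothl1 <- function(tape, x, target, delta = 1, scale = 1) {
  r <- tp_val(tape, x) - target
  a <- abs(r)
  q <- pmin(a, delta)
  val <- scale * sum(0.5 * q * q / delta + (a - q))
  tp_push(tape, val, x, function(gy) {
    list(sign(r) * q / delta * (gy * scale))
  })
}

# Weighted sum of scalar nodes.
tp_scalar_wsum <- function(tape, xs, w) {
  v <- sum(w * vapply(xs, function(i) tp_val(tape, i), numeric(1)))
  tp_push(tape, v, unlist(xs), function(gy) {
    as.list(gy * w)
  })
}
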