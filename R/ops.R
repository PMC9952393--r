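# Numeric kernels for the network layers. Feature tensors are dense arrays
# with layout (H, W, N, C): spatial rows/cols, batch, channels. Column-major
# order makes the (H*W*N) x C matricization free, so a convolution is one
# compiled im2col gather plus one BLAS GEMM (and the transposed pair on the
# backward pass).

#' @noRd
zeros <- function(...) array(0, dim = c(...))

mat_to_w <- function(m, kh, kw, cin, cout) {
  dim(m) <- c(cin, kh, kw, cout)
  aperm(m, c(2L, 3L, 1L, 4L))
}

# Weight array (kh, kw, Cin, Cout) -> GEMM matrix (Cin*kh*kw, Cout), rows
# ordered c-fastest within each (dh, dw) block, matching im2col_cpp().
w_to_mat_perm <- function(w) {
  d <- dim(w)
  m <- aperm(w, c(3L, 1L, 2L, 4L))
  dim(m) <- c(d[1] * d[2] * d[3], d[4])
  m
}

# Forward convolution. Returns y plus the saved col matrix for backward.
conv_fwd <- function(x, w, b, stride = 1L, pad = 1L) {
  d <- dim(x)
  kd <- dim(w)
  stopifnot(kd[3] == d[4])
  Ho <- (d[1] + 2L * pad - kd[1]) %/% stride + 1L
  Wo <- (d[2] + 2L * pad - kd[2]) %/% stride + 1L
  col <- im2col_cpp(x, d[1], d[2], d[3], d[4], kd[1], kd[2],
                    as.integer(stride), as.integer(pad), Ho, Wo)
  wm <- w_to_mat_perm(w)
  y <- col %*% wm
  y <- y + rep(b, each = Ho * Wo * d[3])
  dim(y) <- c(Ho, Wo, d[3], kd[4])
  list(y = y, col = col)
}

conv_bwd <- function(gy, col, w, xdim, stride = 1L, pad = 1L) {
  d <- xdim
  kd <- dim(w)
  gd <- dim(gy)
  Ho <- gd[1]; Wo <- gd[2]
  gym <- gy
  dim(gym) <- c(Ho * Wo * d[3], kd[4])
  gb <- colSums(gym)
  gwm <- crossprod(col, gym)
  gw <- mat_to_w(gwm, kd[1], kd[2], kd[3], kd[4])
  wm <- w_to_mat_perm(w)
  gcol <- tcrossprod(gym, wm)
  gx <- col2im_cpp(gcol, d[1], d[2], d[3], d[4], kd[1], kd[2],
                   as.integer(stride), as.integer(pad), Ho, Wo)
  list(gx = gx, gw = gw, gb = gb)
}

# 2x2 max pooling, stride 2. H and W must be even.
maxpool2_fwd <- function(x) {
  d <- dim(x)
  s1 <- seq(1L, d[1], 2L); s2 <- seq(2L, d[1], 2L)
  t1 <- seq(1L, d[2], 2L); t2 <- seq(2L, d[2], 2L)
  a <- x[s1, t1, , , drop = FALSE]
  b <- x[s2, t1, , , drop = FALSE]
  cc <- x[s1, t2, , , drop = FALSE]
  dd <- x[s2, t2, , , drop = FALSE]
  pmax(pmax(a, b), pmax(cc, dd))
}

maxpool2_bwd <- function(gy, x, y) {
  d <- dim(x)
  s1 <- seq(1L, d[1], 2L); s2 <- seq(2L, d[1], 2L)
  t1 <- seq(1L, d[2], 2L); t2 <- seq(2L, d[2], 2L)
  gx <- zeros(d[1], d[2], d[3], d[4])
  taken <- array(FALSE, dim(y))
  put <- function(ri, ci) {
    sub <- x[ri, ci, , , drop = FALSE]
    m <- (sub == y) & !taken
    taken <<- taken | m
    g <- gy * m
    gx[ri, ci, , ] <<- g
  }
  put(s1, t1); put(s2, t1); put(s1, t2); put(s2, t2)
  gx
}

# Nearest-neighbour 2x upsampling.
upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

upsample2_bwd <- function(gy) {
  d <- dim(gy)
  s1 <- seq(1L, d[1], 2L); s2 <- seq(2L, d[1], 2L)
  t1 <- seq(1L, d[2], 2L); t2 <- seq(2L, d[2], 2L)
  gy[s1, t1, , , drop = FALSE] + gy[s2, t1, , , drop = FALSE] +
    gy[s1, t2, , , drop = FALSE] + gy[s2, t2, , , drop = FALSE]
}

# Broadcast a per-channel (length C) or per-sample-channel (N x C) factor to
# the full (H, W, N, C) shape.
expand_chan <- function(s, d) {
  if (is.matrix(s)) {
    array(rep(as.vector(s), each = d[1] * d[2]), dim = d)
  } else {
    array(rep(s, each = d[1] * d[2] * d[3]), dim = d)
  }
}

# Per-channel reduction of an (H, W, N, C) tensor to N x C.
chan_sum <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  matrix(colSums(m), d[3], d[4])
}
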