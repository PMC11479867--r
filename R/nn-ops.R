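# Low-level differentiable tensor operations.
#
# Public feature maps use dimensions (H, W, C, N): height, width, channels,
# batch. Internally the engine works in (H, W, N, C) — channels last — so
# that matricising a tensor into the (H*W*N) x C layout that im2col, batch
# normalization and the 1x1/transposed convolutions need is a plain `dim<-`
# with no data movement. `to_engine()` / `from_engine()` convert at the
# network boundary. All convolutions are stride-1 with "same" padding;
# down/upsampling is done by dedicated pool / transposed convolution
# operators. Forward functions optionally stash what their backward pass
# needs into a `cache` environment keyed by layer name, so a plain forward
# pass allocates nothing extra.

to_engine <- function(x) aperm(x, c(1, 2, 4, 3))
from_engine <- function(x) aperm(x, c(1, 2, 4, 3))

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

# x: (H, W, N, C); W: (k, k, C, O); returns (H, W, N, O).
#
# The k x k convolution is computed as a sum of k*k shifted GEMMs: for each
# kernel offset, the matching window of the padded input (flattened to
# (H*W*N) x C) is multiplied by that offset's C x O weight slice. This
# avoids materialising an im2col matrix; the backward pass re-slices the
# cached padded input.
conv2d_forward <- function(x, W, b, dilation = 1, cache = NULL, name = NULL) {
  dW <- dim(W); k <- dW[1]; C <- dW[3]; O <- dW[4]
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]
  stopifnot(d[4] == C)
  rows <- H * Wd * N
  if (k == 1) {
    M <- x
    dim(M) <- c(rows, C)
    Y <- M %*% array(W, c(C, O))
    if (any(b != 0)) Y <- Y + rep(b, each = rows)
    dim(Y) <- c(H, Wd, N, O)
  } else {
    Y <- .conv2d_fwd(x, W, b, as.integer(dilation))
  }
  if (!is.null(cache)) cache[[name]] <- list(x = x, dims = d)
  Y
}

conv2d_backward <- function(dy, W, dilation, entry) {
  dW <- dim(W); k <- dW[1]; C <- dW[3]; O <- dW[4]
  d <- entry$dims; H <- d[1]; Wd <- d[2]; N <- d[3]
  if (k > 1) return(.conv2d_bwd(entry$x, W, dy, as.integer(dilation)))
  rows <- H * Wd * N
  dyM <- dy
  dim(dyM) <- c(rows, O)
  gb <- colSums(dyM)
  M <- entry$x
  dim(M) <- c(rows, C)
  gW <- array(crossprod(M, dyM), dW)
  dx <- tcrossprod(dyM, array(W, c(C, O)))
  dim(dx) <- c(H, Wd, N, C)
  list(dx = dx, dW = gW, db = gb)
}

# Batch normalization over a samples x channels matrix; the 4-D wrapper
# flattens (H, W, N, C) -> (H*W*N, C). Biased variance in the forward pass,
# running statistics for inference.
bn_mat_forward <- function(xm, gamma, beta, state, name, train,
                           eps = 1e-5, momentum = 0.1, cache = NULL) {
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    st <- state[[name]]
    state[[name]] <- list(mean = (1 - momentum) * st$mean + momentum * mu,
                          var  = (1 - momentum) * st$var + momentum * v)
  } else {
    st <- state[[name]]
    mu <- st$mean
    v <- st$var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = nrow(xm))) * rep(ivar, each = nrow(xm))
  ym <- xhat * rep(gamma, each = nrow(xm)) + rep(beta, each = nrow(xm))
  if (!is.null(cache)) cache[[name]] <- list(xhat = xhat, ivar = ivar)
  ym
}

bn_mat_backward <- function(dym, gamma, entry) {
  m <- nrow(dym)
  xhat <- entry$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = m)
  dx <- (dxhat - rep(colMeans(dxhat), each = m) -
           xhat * rep(colMeans(dxhat * xhat), each = m)) *
    rep(entry$ivar, each = m)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bn_forward <- function(x, gamma, beta, state, name, train,
                       eps = 1e-5, momentum = 0.1, cache = NULL) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  ym <- bn_mat_forward(xm, gamma, beta, state, name, train, eps, momentum, cache)
  if (!is.null(cache)) cache[[name]]$dims <- d
  dim(ym) <- d
  ym
}

bn_backward <- function(dy, gamma, entry) {
  d <- entry$dims
  dym <- dy
  dim(dym) <- c(d[1] * d[2] * d[3], d[4])
  r <- bn_mat_backward(dym, gamma, entry)
  dim(r$dx) <- d
  r
}

relu_forward <- function(x, cache = NULL, name = NULL) {
  mask <- x > 0
  if (!is.null(cache)) cache[[name]] <- mask
  x * mask
}

relu_backward <- function(dy, mask) dy * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# 2x2 max pooling, stride 2 (any trailing dims). Ties resolve to the first
# window position in (top-left, bottom-left, top-right, bottom-right) order.
maxpool2_forward <- function(x, cache = NULL, name = NULL) {
  d <- dim(x)
  ro <- seq(1, d[1], 2); re <- seq(2, d[1], 2)
  co <- seq(1, d[2], 2); ce <- seq(2, d[2], 2)
  s <- list(x[ro, co, , , drop = FALSE], x[re, co, , , drop = FALSE],
            x[ro, ce, , , drop = FALSE], x[re, ce, , , drop = FALSE])
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  if (!is.null(cache)) {
    pick <- array(4L, dim(y))
    pick[s[[3]] == y] <- 3L
    pick[s[[2]] == y] <- 2L
    pick[s[[1]] == y] <- 1L
    cache[[name]] <- list(pick = pick, dims = d)
  }
  y
}

maxpool2_backward <- function(dy, entry) {
  d <- entry$dims
  pick <- entry$pick
  dx <- array(0, d)
  ro <- seq(1, d[1], 2); re <- seq(2, d[1], 2)
  co <- seq(1, d[2], 2); ce <- seq(2, d[2], 2)
  z <- array(0, dim(dy))
  for (kk in 1:4) {
    contrib <- z
    sel <- pick == kk
    contrib[sel] <- dy[sel]
    ri <- if (kk %in% c(1L, 3L)) ro else re
    ci <- if (kk %in% c(1L, 2L)) co else ce
    dx[ri, ci, , ] <- dx[ri, ci, , ] + contrib
  }
  dx
}

# Transposed convolution, kernel 2, stride 2 (resolution x2, no overlap).
# Kernel stored as (2, 2, C_in, C_out); x channels-last (H, W, N, C).
convt2_forward <- function(x, W, b, cache = NULL, name = NULL) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  O <- dim(W)[4]
  xm <- x
  dim(xm) <- c(H * Wd * N, C)
  y <- array(0, c(2 * H, 2 * Wd, N, O))
  for (a in 1:2) {
    for (bb in 1:2) {
      Yab <- xm %*% array(W[a, bb, , ], c(C, O))
      Yab <- Yab + rep(b, each = nrow(Yab))
      dim(Yab) <- c(H, Wd, N, O)
      y[seq(a, 2 * H, 2), seq(bb, 2 * Wd, 2), , ] <- Yab
    }
  }
  if (!is.null(cache)) cache[[name]] <- list(xm = xm, dims = d)
  y
}

convt2_backward <- function(dy, W, entry) {
  d <- entry$dims; H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  O <- dim(W)[4]
  gW <- array(0, dim(W))
  gb <- numeric(O)
  dxm <- matrix(0, H * Wd * N, C)
  for (a in 1:2) {
    for (bb in 1:2) {
      dyab <- dy[seq(a, 2 * H, 2), seq(bb, 2 * Wd, 2), , , drop = FALSE]
      dim(dyab) <- c(H * Wd * N, O)
      gW[a, bb, , ] <- crossprod(entry$xm, dyab)
      gb <- gb + colSums(dyab)
      dxm <- dxm + tcrossprod(dyab, array(W[a, bb, , ], c(C, O)))
    }
  }
  dim(dxm) <- c(H, Wd, N, C)
  list(dx = dxm, dW = gW, db = gb)
}

# He-uniform weight initialisation (bound sqrt(6 / fan_in)), zero biases.
init_conv <- function(k, C, O) {
  bound <- sqrt(6 / (k * k * C))
  array(stats::runif(k * k * C * O, -bound, bound), c(k, k, C, O))
}

init_convt2 <- function(C, O) {
  bound <- sqrt(6 / (4 * C))
  array(stats::runif(4 * C * O, -bound, bound), c(2, 2, C, O))
}
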