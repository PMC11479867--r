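# DRAU-Net: an encoder-decoder segmentation network for multi-focal brain
# metastasis MRI. Each encoder level is a two-layer conv block followed by
# a dilated residual (DResConv) block whose second 3x3 convolution uses a
# level-dependent dilation rate; skip connections pass through a
# multi-branch weighted attention (MBWA) module that gates rows and
# columns of the feature map before concatenation with the upsampled
# decoder feature. Two sigmoid heads emit overlapping binary maps
# (whole tumor, tumor core).

#' Network configuration for DRAU-Net
#'
#' @param in_channels Number of input modalities (default 2: t1c + t2f).
#' @param out_channels Number of output heads (default 2: WT and TC, each a
#'   per-pixel sigmoid probability; the labels may overlap so the heads are
#'   independent binary classifiers rather than softmax classes).
#' @param base_width Channel width of the first encoder level; level `l`
#'   uses `base_width * 2^(l-1)` channels and the bottleneck twice the
#'   deepest level.
#' @param depth Number of encoder levels (and 2x downsamplings).
#' @param dilation_schedule Integer dilation rate of the second convolution
#'   in the DResConv block at each level, defaults to the level index.
#' @param attention_reduction Channel reduction ratio of the shared 1x1
#'   convolution inside MBWA; the reduced width is floored at 8 channels.
#' @return An object of class `drau_config`.
#' @export
network_config <- function(in_channels = 2L, out_channels = 2L,
                           base_width = 32L, depth = 4L,
                           dilation_schedule = seq_len(depth),
                           attention_reduction = 8L) {
  stopifnot(in_channels >= 1, out_channels >= 1, base_width >= 1, depth >= 1,
            attention_reduction >= 1)
  if (length(dilation_schedule) != depth)
    stop("dilation_schedule must have one entry per encoder level (depth = ",
         depth, ")")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 dilation_schedule = as.integer(dilation_schedule),
                 attention_reduction = as.integer(attention_reduction)),
            class = "drau_config")
}

drau_widths <- function(config) {
  config$base_width * 2^(seq_len(config$depth) - 1L)
}

mbwa_reduced <- function(C, reduction) max(8L, C %/% reduction)

add_conv <- function(P, name, k, C, O) {
  P[[paste0(name, ".W")]] <- init_conv(k, C, O)
  P[[paste0(name, ".b")]] <- numeric(O)
  P
}

add_bn <- function(P, S, name, C) {
  P[[paste0(name, ".g")]] <- rep(1, C)
  P[[paste0(name, ".be")]] <- rep(0, C)
  S[[name]] <- list(mean = rep(0, C), var = rep(1, C))
  P
}

add_cbr <- function(P, S, name, C, O) {
  P <- add_conv(P, paste0(name, ".conv"), 3L, C, O)
  add_bn(P, S, paste0(name, ".bn"), O)
}

add_conv_block <- function(P, S, name, C, O) {
  P <- add_cbr(P, S, paste0(name, ".c1"), C, O)
  add_cbr(P, S, paste0(name, ".c2"), O, O)
}

add_dres <- function(P, name, C) {
  P <- add_conv(P, paste0(name, ".f"), 3L, C, C)
  add_conv(P, paste0(name, ".s"), 3L, C, C)
}

add_mbwa <- function(P, S, name, C, reduction) {
  Cr <- mbwa_reduced(C, reduction)
  P <- add_conv(P, paste0(name, ".red"), 1L, C, Cr)
  P <- add_bn(P, S, paste0(name, ".redbn"), Cr)
  P <- add_conv(P, paste0(name, ".h"), 1L, Cr, C)
  P <- add_bn(P, S, paste0(name, ".hbn"), C)
  P <- add_conv(P, paste0(name, ".v"), 1L, Cr, C)
  add_bn(P, S, paste0(name, ".vbn"), C)
}

#' Build a DRAU-Net
#'
#' Instantiates all parameters (He-uniform weights, unit batch-norm scale)
#' for the configured architecture. The returned object holds a named flat
#' parameter list and an environment of batch-norm running statistics.
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed pinning the weight initialisation.
#' @return An object of class `drau_net` with elements `config`, `params`
#'   (named list of arrays) and `state` (environment of running statistics).
#' @export
drau_net <- function(config = network_config(), seed = NULL) {
  if (!inherits(config, "drau_config")) stop("config must be a drau_config")
  if (!is.null(seed)) set.seed(seed)
  w <- drau_widths(config)
  D <- config$depth
  wb <- w[D] * 2L
  P <- list()
  S <- new.env(parent = emptyenv())
  cin <- config$in_channels
  for (l in seq_len(D)) {
    P <- add_conv_block(P, S, paste0("e", l, ".block"), cin, w[l])
    P <- add_dres(P, paste0("e", l, ".res"), w[l])
    cin <- w[l]
  }
  P <- add_conv_block(P, S, "bott", w[D], wb)
  cur <- wb
  for (l in rev(seq_len(D))) {
    P[[paste0("d", l, ".up.W")]] <- init_convt2(cur, w[l])
    P[[paste0("d", l, ".up.b")]] <- numeric(w[l])
    P <- add_mbwa(P, S, paste0("d", l, ".att"), w[l], config$attention_reduction)
    P <- add_conv(P, paste0("d", l, ".fuse"), 1L, 2L * w[l], w[l])
    P <- add_conv_block(P, S, paste0("d", l, ".block"), w[l], w[l])
    P <- add_dres(P, paste0("d", l, ".res"), w[l])
    cur <- w[l]
  }
  P <- add_conv(P, "head", 1L, w[1], config$out_channels)
  structure(list(config = config, params = P, state = S), class = "drau_net")
}

#' Total number of trainable parameters
#' @param net A [drau_net()].
#' @return Integer count of scalar parameters (batch-norm running statistics
#'   are not trainable and are excluded).
#' @export
n_parameters <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

## ---- forward / backward ----------------------------------------------------

cbr_forward <- function(x, P, S, name, train, cache) {
  y <- conv2d_forward(x, P[[paste0(name, ".conv.W")]],
                      P[[paste0(name, ".conv.b")]], 1L, cache,
                      paste0(name, ".conv"))
  y <- bn_forward(y, P[[paste0(name, ".bn.g")]], P[[paste0(name, ".bn.be")]],
                  S, paste0(name, ".bn"), train, cache = cache)
  relu_forward(y, cache, paste0(name, ".relu"))
}

cbr_backward <- function(dy, P, name, cache, G) {
  dy <- relu_backward(dy, cache[[paste0(name, ".relu")]])
  r <- bn_backward(dy, P[[paste0(name, ".bn.g")]], cache[[paste0(name, ".bn")]])
  G[[paste0(name, ".bn.g")]] <- r$dgamma
  G[[paste0(name, ".bn.be")]] <- r$dbeta
  r2 <- conv2d_backward(r$dx, P[[paste0(name, ".conv.W")]], 1L,
                        cache[[paste0(name, ".conv")]])
  G[[paste0(name, ".conv.W")]] <- r2$dW
  G[[paste0(name, ".conv.b")]] <- r2$db
  r2$dx
}

#' Two-layer convolution block (3x3 conv + BN + ReLU, twice)
#'
#' Spatial dimensions are preserved (padding 1); the output is non-negative
#' because the block ends in a ReLU.
#'
#' @param x Feature map array `(H, W, C, N)`.
#' @param net A [drau_net()] whose parameters contain the named block.
#' @param name Block prefix inside the parameter list, e.g. `"e1.block"`.
#' @param train Logical; use batch statistics and update running statistics.
#' @return Feature map `(H, W, O, N)`.
#' @export
conv_block <- function(x, net, name, train = FALSE) {
  from_engine(conv_block_forward(to_engine(x), net$params, net$state, name,
                                 train, NULL))
}

conv_block_forward <- function(x, P, S, name, train, cache) {
  y <- cbr_forward(x, P, S, paste0(name, ".c1"), train, cache)
  cbr_forward(y, P, S, paste0(name, ".c2"), train, cache)
}

conv_block_backward <- function(dy, P, name, cache, G) {
  dy <- cbr_backward(dy, P, paste0(name, ".c2"), cache, G)
  cbr_backward(dy, P, paste0(name, ".c1"), cache, G)
}

#' Dilated residual convolution block
#'
#' `output = Conv3x3(dilation = i)(Conv3x3(dilation = 1)(x)) + x`. Both
#' convolutions preserve the channel count and spatial size (padding equals
#' the dilation), so zeroed branch weights make the block an exact identity.
#'
#' @param x Feature map `(H, W, C, N)`.
#' @param net A [drau_net()].
#' @param name Block prefix, e.g. `"e2.res"`.
#' @param dilation Dilation rate of the second convolution.
#' @param train Unused (the block has no batch normalization); kept for
#'   interface symmetry.
#' @return Feature map with the same shape as `x`.
#' @export
dresconv_block <- function(x, net, name, dilation, train = FALSE) {
  from_engine(dres_forward(to_engine(x), net$params, name, dilation, NULL))
}

dres_forward <- function(x, P, name, dilation, cache) {
  f <- conv2d_forward(x, P[[paste0(name, ".f.W")]], P[[paste0(name, ".f.b")]],
                      1L, cache, paste0(name, ".f"))
  s <- conv2d_forward(f, P[[paste0(name, ".s.W")]], P[[paste0(name, ".s.b")]],
                      dilation, cache, paste0(name, ".s"))
  s + x
}

dres_backward <- function(dy, P, name, dilation, cache, G) {
  r <- conv2d_backward(dy, P[[paste0(name, ".s.W")]], dilation,
                       cache[[paste0(name, ".s")]])
  G[[paste0(name, ".s.W")]] <- r$dW
  G[[paste0(name, ".s.b")]] <- r$db
  r2 <- conv2d_backward(r$dx, P[[paste0(name, ".f.W")]], 1L,
                        cache[[paste0(name, ".f")]])
  G[[paste0(name, ".f.W")]] <- r2$dW
  G[[paste0(name, ".f.b")]] <- r2$db
  r2$dx + dy
}

#' Multi-branch weighted attention (MBWA)
#'
#' Average-pools the input along each spatial axis, mixes the row and column
#' descriptors through a shared channel-reducing 1x1 convolution (+ BN +
#' ReLU), splits them back, restores the channel count with two 1x1
#' convolutions (+ BN + sigmoid) into row weights `wh` and column weights
#' `wv`, and rescales the input as `O = I * (wh + wv)`. Because both weight
#' maps lie in (0, 1), `|O| <= 2 |I|` elementwise.
#'
#' @param x Feature map `(H, W, C, N)`.
#' @param net A [drau_net()].
#' @param name Module prefix, e.g. `"d1.att"`.
#' @param train Logical batch-norm mode.
#' @return Feature map with the same shape as `x`.
#' @export
mbwa <- function(x, net, name, train = FALSE) {
  from_engine(mbwa_forward(to_engine(x), net$params, net$state, name, train,
                           NULL))
}

# Engine layout (H, W, N, C) throughout; row descriptors are (H*N, C)
# matrices with the row index varying fastest.
mbwa_forward <- function(x, P, S, name, train, cache) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  # axis-wise average pooling: rows (H, N, C) and columns (W, N, C)
  x1 <- colMeans(matrix(aperm(x, c(2, 1, 3, 4)), Wd, H * N * C))
  x2 <- colMeans(matrix(x, H, Wd * N * C))
  dim(x1) <- c(H, N, C)
  dim(x2) <- c(Wd, N, C)
  u <- array(0, c(H + Wd, N, C))
  u[seq_len(H), , ] <- x1
  u[H + seq_len(Wd), , ] <- x2
  um <- u
  dim(um) <- c((H + Wd) * N, C)
  Wr <- P[[paste0(name, ".red.W")]]; Cr <- dim(Wr)[4]
  tm <- um %*% array(Wr, c(C, Cr))
  tm <- tm + rep(P[[paste0(name, ".red.b")]], each = nrow(tm))
  tm <- bn_mat_forward(tm, P[[paste0(name, ".redbn.g")]],
                       P[[paste0(name, ".redbn.be")]], S,
                       paste0(name, ".redbn"), train, cache = cache)
  relu_mask <- tm > 0
  tm <- tm * relu_mask
  # split row / column descriptors: rows of tm are ordered (position, batch)
  tarr <- array(tm, c(H + Wd, N, Cr))
  xh <- matrix(tarr[seq_len(H), , , drop = FALSE], H * N, Cr)
  xv <- matrix(tarr[H + seq_len(Wd), , , drop = FALSE], Wd * N, Cr)
  branch <- function(zm, side) {
    Wk <- array(P[[paste0(name, ".", side, ".W")]], c(Cr, C))
    am <- zm %*% Wk + rep(P[[paste0(name, ".", side, ".b")]], each = nrow(zm))
    am <- bn_mat_forward(am, P[[paste0(name, ".", side, "bn.g")]],
                         P[[paste0(name, ".", side, "bn.be")]], S,
                         paste0(name, ".", side, "bn"), train, cache = cache)
    sigmoid(am)
  }
  wh <- branch(xh, "h")                       # (H*N, C)
  wv <- branch(xv, "v")                       # (W*N, C)
  WH <- aperm(array(wh, c(H, N, C, Wd)), c(1, 4, 2, 3))
  WV <- aperm(array(wv, c(Wd, N, C, H)), c(4, 1, 2, 3))
  gate <- WH + WV
  if (!is.null(cache)) {
    cache[[name]] <- list(x = x, um = um, relu_mask = relu_mask, xh = xh,
                          xv = xv, wh = wh, wv = wv, gate = gate, dims = d)
  }
  x * gate
}

mbwa_backward <- function(dy, P, name, cache, G) {
  e <- cache[[name]]
  d <- e$dims; H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  Cr <- dim(P[[paste0(name, ".red.W")]])[4]
  dx <- dy * e$gate
  dgate <- dy * e$x
  # reduce the broadcast: row weights summed over columns, and vice versa
  dwh <- rowSums(matrix(aperm(dgate, c(1, 3, 4, 2)), H * N * C, Wd))
  dim(dwh) <- c(H * N, C)
  dwv <- colSums(matrix(dgate, H, Wd * N * C))
  dim(dwv) <- c(Wd * N, C)
  branch_back <- function(dwm, wm, zm, side) {
    dam <- dwm * wm * (1 - wm)
    r <- bn_mat_backward(dam, P[[paste0(name, ".", side, "bn.g")]],
                         cache[[paste0(name, ".", side, "bn")]])
    G[[paste0(name, ".", side, "bn.g")]] <- r$dgamma
    G[[paste0(name, ".", side, "bn.be")]] <- r$dbeta
    Wk <- array(P[[paste0(name, ".", side, ".W")]], c(Cr, C))
    G[[paste0(name, ".", side, ".W")]] <- array(crossprod(zm, r$dx),
                                                c(1, 1, Cr, C))
    G[[paste0(name, ".", side, ".b")]] <- colSums(r$dx)
    tcrossprod(r$dx, Wk)
  }
  dxh <- branch_back(dwh, e$wh, e$xh, "h")
  dxv <- branch_back(dwv, e$wv, e$xv, "v")
  dtarr <- array(0, c(H + Wd, N, Cr))
  dtarr[seq_len(H), , ] <- array(dxh, c(H, N, Cr))
  dtarr[H + seq_len(Wd), , ] <- array(dxv, c(Wd, N, Cr))
  dtm <- matrix(dtarr, (H + Wd) * N, Cr)
  dtm <- dtm * e$relu_mask
  r <- bn_mat_backward(dtm, P[[paste0(name, ".redbn.g")]],
                       cache[[paste0(name, ".redbn")]])
  G[[paste0(name, ".redbn.g")]] <- r$dgamma
  G[[paste0(name, ".redbn.be")]] <- r$dbeta
  Wr <- array(P[[paste0(name, ".red.W")]], c(C, Cr))
  G[[paste0(name, ".red.W")]] <- array(crossprod(e$um, r$dx), c(1, 1, C, Cr))
  G[[paste0(name, ".red.b")]] <- colSums(r$dx)
  du <- tcrossprod(r$dx, Wr)                   # ((H+W)*N, C)
  dim(du) <- c(H + Wd, N, C)
  dx1 <- du[seq_len(H), , , drop = FALSE]      # (H, N, C)
  dx2 <- du[H + seq_len(Wd), , , drop = FALSE] # (W, N, C)
  # distribute the pooling means back over the pooled axis
  dx <- dx + aperm(array(dx1 / Wd, c(H, N, C, Wd)), c(1, 4, 2, 3))
  dx + aperm(array(dx2 / H, c(Wd, N, C, H)), c(4, 1, 2, 3))
}

#' Forward pass of DRAU-Net
#'
#' @param net A [drau_net()].
#' @param x Input array `(H, W, in_channels, N)` with `H` and `W` divisible
#'   by `2^depth`.
#' @param train Logical; batch-norm training mode.
#' @param cache Optional environment collecting intermediate values for
#'   [drau_backward()].
#' @return Array `(H, W, out_channels, N)` of sigmoid probabilities.
#' @export
drau_forward <- function(net, x, train = FALSE, cache = NULL) {
  cfg <- net$config
  d <- dim(x)
  if (length(d) != 4 || d[3] != cfg$in_channels)
    stop("input must be (H, W, ", cfg$in_channels, ", N)")
  if (d[1] %% 2^cfg$depth != 0 || d[2] %% 2^cfg$depth != 0)
    stop("spatial dimensions (", d[1], " x ", d[2], ") must be divisible by ",
         "2^depth = ", 2^cfg$depth)
  P <- net$params; S <- net$state
  D <- cfg$depth
  dil <- cfg$dilation_schedule
  skips <- vector("list", D)
  h <- to_engine(x)
  for (l in seq_len(D)) {
    h <- conv_block_forward(h, P, S, paste0("e", l, ".block"), train, cache)
    h <- dres_forward(h, P, paste0("e", l, ".res"), dil[l], cache)
    skips[[l]] <- h
    h <- maxpool2_forward(h, cache, paste0("pool", l))
  }
  h <- conv_block_forward(h, P, S, "bott", train, cache)
  for (l in rev(seq_len(D))) {
    up <- convt2_forward(h, P[[paste0("d", l, ".up.W")]],
                         P[[paste0("d", l, ".up.b")]], cache,
                         paste0("d", l, ".up"))
    att <- mbwa_forward(skips[[l]], P, S, paste0("d", l, ".att"), train, cache)
    dd <- dim(att)
    cat2 <- array(0, c(dd[1], dd[2], dd[3], 2L * dd[4]))
    cat2[, , , seq_len(dd[4])] <- att
    cat2[, , , dd[4] + seq_len(dd[4])] <- up
    h <- conv2d_forward(cat2, P[[paste0("d", l, ".fuse.W")]],
                        P[[paste0("d", l, ".fuse.b")]], 1L, cache,
                        paste0("d", l, ".fuse"))
    h <- conv_block_forward(h, P, S, paste0("d", l, ".block"), train, cache)
    h <- dres_forward(h, P, paste0("d", l, ".res"), dil[l], cache)
  }
  logits <- conv2d_forward(h, P[["head.W"]], P[["head.b"]], 1L, cache, "head")
  y <- sigmoid(logits)
  if (!is.null(cache)) cache[["head.sigmoid"]] <- y
  from_engine(y)
}

# Backpropagate dL/dP (gradient w.r.t. the sigmoid probabilities) through the
# whole network; returns an environment of gradients keyed like net$params.
drau_backward <- function(net, dP, cache) {
  cfg <- net$config
  P <- net$params
  D <- cfg$depth
  dil <- cfg$dilation_schedule
  G <- new.env(parent = emptyenv())
  y <- cache[["head.sigmoid"]]
  dy <- to_engine(dP) * y * (1 - y)
  r <- conv2d_backward(dy, P[["head.W"]], 1L, cache[["head"]])
  G[["head.W"]] <- r$dW; G[["head.b"]] <- r$db
  dh <- r$dx
  dskips <- vector("list", D)
  # decoder ran for l = D..1, so undo l = 1..D, collecting skip gradients
  for (l in seq_len(D)) {
    dh <- dres_backward(dh, P, paste0("d", l, ".res"), dil[l], cache, G)
    dh <- conv_block_backward(dh, P, paste0("d", l, ".block"), cache, G)
    r <- conv2d_backward(dh, P[[paste0("d", l, ".fuse.W")]], 1L,
                         cache[[paste0("d", l, ".fuse")]])
    G[[paste0("d", l, ".fuse.W")]] <- r$dW
    G[[paste0("d", l, ".fuse.b")]] <- r$db
    dd <- dim(r$dx)
    C <- dd[4] %/% 2L
    datt <- r$dx[, , , seq_len(C), drop = FALSE]
    dup <- r$dx[, , , C + seq_len(C), drop = FALSE]
    dskips[[l]] <- mbwa_backward(datt, P, paste0("d", l, ".att"), cache, G)
    ru <- convt2_backward(dup, P[[paste0("d", l, ".up.W")]],
                          cache[[paste0("d", l, ".up")]])
    G[[paste0("d", l, ".up.W")]] <- ru$dW
    G[[paste0("d", l, ".up.b")]] <- ru$db
    dh <- ru$dx
  }
  dh <- conv_block_backward(dh, P, "bott", cache, G)
  for (l in rev(seq_len(D))) {
    dh <- maxpool2_backward(dh, cache[[paste0("pool", l)]])
    dh <- dh + dskips[[l]]
    dh <- dres_backward(dh, P, paste0("e", l, ".res"), dil[l], cache, G)
    dh <- conv_block_backward(dh, P, paste0("e", l, ".block"), cache, G)
  }
  G
}
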