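# Architecture contracts and differentiation correctness. Tests on tiny
# configurations exercise exactly the same code paths as the full-size
# network.

tiny_cfg <- network_config(in_channels = 2, out_channels = 2, base_width = 4,
                           depth = 2, dilation_schedule = c(1, 2),
                           attention_reduction = 2)

test_that("conv2d agrees with a naive nested-loop oracle", {
  set.seed(11)
  x <- array(stats::rnorm(7 * 6 * 2 * 3), c(7, 6, 2, 3))
  W <- array(stats::rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- stats::rnorm(4)
  for (dil in 1:3) {
    expect_equal(conv2d_forward(x, W, b, dil), naive_conv(x, W, b, dil),
                 tolerance = 1e-12)
  }
  # 1x1 convolution path
  W1 <- array(stats::rnorm(3 * 4), c(1, 1, 3, 4))
  expect_equal(conv2d_forward(x, W1, b, 1), naive_conv(x, W1, b, 1),
               tolerance = 1e-12)
})

test_that("conv block preserves spatial size and is non-negative", {
  net <- drau_net(tiny_cfg, seed = 5)
  x <- array(stats::rnorm(16 * 16 * 2 * 1), c(16, 16, 2, 1))
  y <- conv_block(x, net, "e1.block")
  expect_equal(dim(y), c(16, 16, 4, 1))
  expect_gte(min(y), 0)
})

test_that("dresconv is the exact identity when its branch is zeroed", {
  net <- drau_net(tiny_cfg, seed = 6)
  for (nm in c("e1.res.f.W", "e1.res.f.b", "e1.res.s.W", "e1.res.s.b"))
    net$params[[nm]][] <- 0
  x <- array(stats::rnorm(12 * 12 * 4 * 2), c(12, 12, 4, 2))
  expect_identical(dresconv_block(x, net, "e1.res", dilation = 2), x)
  # shape preservation under large dilation
  x2 <- array(stats::rnorm(40 * 40 * 4 * 1), c(40, 40, 4, 1))
  expect_equal(dim(dresconv_block(x2, net, "e1.res", dilation = 3)),
               dim(x2))
})

test_that("dresconv branch receptive field spans 3 + 2 * dilation pixels", {
  set.seed(21)
  for (dil in 1:4) {
    P <- list()
    P <- add_dres(P, "r", 1L)
    x0 <- array(0, c(31, 31, 1, 1))
    x1 <- x0; x1[16, 16, 1, 1] <- 1
    dy <- dres_forward(x1, P, "r", dil, NULL) -
      dres_forward(x0, P, "r", dil, NULL)
    rows <- range(which(apply(abs(dy[, , 1, 1]), 1, max) > 1e-12))
    cols <- range(which(apply(abs(dy[, , 1, 1]), 2, max) > 1e-12))
    expect_equal(diff(rows) + 1, 3 + 2 * dil)
    expect_equal(diff(cols) + 1, 3 + 2 * dil)
  }
})

test_that("MBWA keeps shape, obeys the elementwise gate bound, and is
           row-permutation equivariant", {
  net <- drau_net(tiny_cfg, seed = 7)
  set.seed(30)
  x <- array(stats::rnorm(16 * 16 * 4 * 2), c(16, 16, 4, 2))
  y <- mbwa(x, net, "d1.att")
  expect_equal(dim(y), dim(x))
  # wh, wv in (0,1) so |O| <= 2 |I|
  expect_true(all(abs(y) <= 2 * abs(x) + 1e-12))
  # permuting input rows permutes the output identically (column means are
  # permutation-invariant, row descriptors permute along)
  perm <- sample(16)
  y_perm <- mbwa(x[perm, , , , drop = FALSE], net, "d1.att")
  expect_equal(y_perm, y[perm, , , , drop = FALSE], tolerance = 1e-12)
})

test_that("forward pass honours the shape contract and sigmoid range", {
  net <- drau_net(tiny_cfg, seed = 8)
  x <- array(stats::rnorm(32 * 32 * 2 * 2), c(32, 32, 2, 2))
  y <- drau_forward(net, x)
  expect_equal(dim(y), c(32, 32, 2, 2))
  expect_true(all(y > 0 & y < 1))
  expect_error(drau_forward(net, array(0, c(30, 32, 2, 1))), "divisible")
  expect_error(drau_forward(net, array(0, c(32, 32, 3, 1))), "input must be")
})

test_that("forward outputs stay finite across many random inputs", {
  net <- drau_net(tiny_cfg, seed = 9)
  for (s in 1:100) {
    set.seed(s)
    x <- array(stats::rnorm(16 * 16 * 2, sd = 3), c(16, 16, 2, 1))
    y <- drau_forward(net, x)
    expect_true(all(is.finite(y)))
  }
})

test_that("trainable parameter count matches the layer algebra", {
  n_conv <- function(k, C, O) k * k * C * O + O
  n_bn <- function(C) 2 * C
  n_cbr <- function(C, O) n_conv(3, C, O) + n_bn(O)
  n_block <- function(C, O) n_cbr(C, O) + n_cbr(O, O)
  n_dres <- function(C) 2 * n_conv(3, C, C)
  n_mbwa <- function(C, r) {
    Cr <- max(8, C %/% r)
    n_conv(1, C, Cr) + n_bn(Cr) + 2 * (n_conv(1, Cr, C) + n_bn(C))
  }
  expected <- function(cfg) {
    w <- cfg$base_width * 2^(seq_len(cfg$depth) - 1)
    total <- 0
    cin <- cfg$in_channels
    for (l in seq_len(cfg$depth)) {
      total <- total + n_block(cin, w[l]) + n_dres(w[l])
      cin <- w[l]
    }
    wb <- 2 * w[cfg$depth]
    total <- total + n_block(w[cfg$depth], wb)
    cur <- wb
    for (l in rev(seq_len(cfg$depth))) {
      total <- total + (4 * cur * w[l] + w[l]) +       # transposed conv
        n_mbwa(w[l], cfg$attention_reduction) +
        n_conv(1, 2 * w[l], w[l]) +                    # fuse
        n_block(w[l], w[l]) + n_dres(w[l])
      cur <- w[l]
    }
    total + n_conv(1, w[1], cfg$out_channels)
  }
  expect_equal(n_parameters(drau_net(tiny_cfg, seed = 1)),
               expected(tiny_cfg))
  default_net <- drau_net(network_config(), seed = 1)
  expect_equal(n_parameters(default_net), expected(network_config()))
  # frozen regression constant for the default configuration
  expect_equal(n_parameters(default_net), 10328386L)
})

test_that("analytic gradients match finite differences through the whole
           network", {
  set.seed(71)
  net <- drau_net(tiny_cfg, seed = 11)
  x <- array(stats::rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  t <- array(stats::rbinom(8 * 8 * 2 * 2, 1, 0.3), c(8, 8, 2, 2))
  lcfg <- loss_config()
  loss_of <- function(params) {
    net2 <- net
    net2$params <- params
    S <- new.env()
    for (nm in ls(net$state)) S[[nm]] <- get(nm, net$state)
    net2$state <- S
    combined_loss(drau_forward(net2, x, train = TRUE), t, lcfg)
  }
  cache <- new.env(parent = emptyenv())
  state_backup <- as.list(net$state)
  p <- drau_forward(net, x, train = TRUE, cache = cache)
  G <- drau_backward(net, combined_loss_grad(p, t, lcfg), cache)
  for (nm in names(state_backup)) net$state[[nm]] <- state_backup[[nm]]
  eps <- 1e-5
  for (nm in sample(names(net$params), 12)) {
    for (i in sample(length(net$params[[nm]]),
                     min(2, length(net$params[[nm]])))) {
      pp <- net$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- net$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      an <- G[[nm]][i]
      # relative error with an absolute floor (some gradients are ~0)
      expect_lt(abs(fd - an) / max(1e-4, abs(fd), abs(an)), 1e-3)
    }
  }
})

test_that("checkpoints round-trip through save and load", {
  net <- drau_net(tiny_cfg, seed = 12)
  x <- array(stats::rnorm(16 * 16 * 2), c(16, 16, 2, 1))
  y1 <- drau_forward(net, x)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  expect_equal(drau_forward(net2, x), y1, tolerance = 1e-15)
  expect_error(load_checkpoint({
    p <- tempfile(fileext = ".rds"); saveRDS(list(a = 1), p); p
  }), "incompatible checkpoint")
})
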