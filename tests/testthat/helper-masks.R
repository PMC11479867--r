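# Mask-building helpers shared across tests.

blank_mask <- function(...) array(0, c(...))

add_rect <- function(mask, r1, r2, c1, c2) {
  mask[r1:r2, c1:c2] <- 1
  mask
}

add_disc <- function(mask, center, radius) {
  d <- dim(mask)
  dr <- outer(seq_len(d[1]) - center[1], rep(1, d[2]))
  dc <- outer(rep(1, d[1]), seq_len(d[2]) - center[2])
  mask[(dr^2 + dc^2) <= radius^2] <- 1
  mask
}

# Random binary mask pair of identical shape (for metric property tests).
random_mask_pair <- function(dims = c(12, 12), p = 0.3) {
  a <- array(as.numeric(stats::runif(prod(dims)) < p), dims)
  b <- array(as.numeric(stats::runif(prod(dims)) < p), dims)
  list(a = a, b = b)
}

# Random multi-lesion GT / degraded prediction pair for MSIM oracle tests:
# the prediction reproduces each GT disc (jittered) with probability
# `p_keep` and adds a few spurious components.
random_lesion_pair <- function(grid = NULL) {
  if (is.null(grid)) grid <- sample(32:64, 1)
  d <- c(grid, grid)
  gt <- blank_mask(d[1], d[2])
  pred <- blank_mask(d[1], d[2])
  m <- sample(0:4, 1)
  for (i in seq_len(m)) {
    r <- sample(2:6, 1)
    ctr <- c(sample(seq(r + 2, d[1] - r - 2), 1),
             sample(seq(r + 2, d[2] - r - 2), 1))
    gt <- add_disc(gt, ctr, r)
    if (stats::runif(1) < 0.7) {
      jit <- sample(-2:2, 2, replace = TRUE)
      pr <- max(1, r + sample(-1:1, 1))
      pred <- add_disc(pred, pmin(pmax(ctr + jit, pr + 1), d - pr - 1), pr)
    }
  }
  for (i in seq_len(sample(0:2, 1))) {
    r <- sample(1:3, 1)
    ctr <- c(sample(seq(r + 1, d[1] - r - 1), 1),
             sample(seq(r + 1, d[2] - r - 1), 1))
    pred <- add_disc(pred, ctr, r)
  }
  list(gt = gt, pred = pred)
}
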