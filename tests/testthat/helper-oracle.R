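# Independent reference implementations used to validate the package:
# BFS flood-fill component labeling, definition-style morphology, an
# exhaustive (maximum bipartite matching) lesion matcher, and a naive
# nested-loop convolution. These deliberately share no code with the
# package internals.

# Queue-based flood fill; returns integer label array.
flood_fill_components <- function(mask, connectivity = 8) {
  d <- dim(mask)
  nd <- length(d)
  offs <- expand.grid(rep(list(-1:1), nd))
  ord <- rowSums(abs(offs))
  max_ord <- switch(as.character(connectivity),
                    "4" = 1, "8" = 2, "6" = 1, "18" = 2, "26" = 3)
  offs <- as.matrix(offs[ord > 0 & ord <= max_ord, , drop = FALSE])
  labels <- array(0L, d)
  nextlab <- 0L
  fg <- which(mask > 0)
  for (start in fg) {
    if (labels[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    labels[start] <- nextlab
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        nb <- cc + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- nb[1] + sum((nb[-1] - 1) * cumprod(d)[-nd])
        if (mask[lin] > 0 && labels[lin] == 0L) {
          labels[lin] <- nextlab
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

# Definition-style closing with a city-block (cross) element of radius 1.
oracle_closing <- function(mask) {
  d <- dim(mask)
  offs <- rbind(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  p <- 1L
  pd <- d + 2L * p
  padded <- array(FALSE, pd)
  padded[p + seq_len(d[1]), p + seq_len(d[2])] <- mask > 0
  apply_op <- function(m, op) {
    out <- array(FALSE, pd)
    for (i in seq_len(pd[1])) for (j in seq_len(pd[2])) {
      vals <- logical(nrow(offs))
      for (r in seq_len(nrow(offs))) {
        ii <- i + offs[r, 1]; jj <- j + offs[r, 2]
        vals[r] <- ii >= 1 && ii <= pd[1] && jj >= 1 && jj <= pd[2] &&
          m[ii, jj]
      }
      out[i, j] <- op(vals)
    }
    out
  }
  dil <- apply_op(padded, any)
  ero <- apply_op(dil, all)
  array(as.numeric(ero[p + seq_len(d[1]), p + seq_len(d[2])]), d)
}

# Maximum bipartite matching (Kuhn's augmenting paths) on the success
# graph: the largest achievable number of successfully matched ground-truth
# lesions over all injective GT -> prediction pairings.
max_matching <- function(edges, u, v) {
  if (v == 0) return(0L)
  env <- new.env()
  env$match_p <- rep(0L, v)
  aug <- function(i) {
    for (j in which(edges[i, ])) {
      if (env$seen[j]) next
      env$seen[j] <- TRUE
      if (env$match_p[j] == 0L || aug(env$match_p[j])) {
        env$match_p[j] <- i
        return(TRUE)
      }
    }
    FALSE
  }
  count <- 0L
  for (i in seq_len(u)) {
    env$seen <- rep(FALSE, v)
    if (aug(i)) count <- count + 1L
  }
  count
}

# Exhaustive-optimum MSIM on 2-D masks: flood-fill labeling, size / core
# filtering, definition-style closing per GT component, then the maximum
# number of per-lesion Dice > theta successes over all injective pairings.
# Returns list(msim, u, ambiguous): `ambiguous` flags instances where some
# component has more than one success-capable partner.
oracle_msim <- function(gt, pred, delta = 0, theta = 0.7, core_mask = NULL) {
  d <- dim(gt)
  glab <- flood_fill_components(gt, 8)
  plab <- flood_fill_components(pred, 8)
  gids <- setdiff(sort(unique(as.vector(glab))), 0L)
  gsets <- list()
  for (id in gids) {
    pix <- which(glab == id)
    if (length(pix) < delta) next
    if (!is.null(core_mask) && sum(core_mask[pix]) < 1) next
    m <- array(0, d)
    m[pix] <- 1
    gsets[[length(gsets) + 1]] <- which(oracle_closing(m) > 0)
  }
  pids <- setdiff(sort(unique(as.vector(plab))), 0L)
  psets <- lapply(pids, function(id) which(plab == id))
  u <- length(gsets)
  v <- length(psets)
  if (u == 0) return(list(msim = NA_real_, u = 0L, ambiguous = FALSE))
  edges <- matrix(FALSE, u, v)
  if (v > 0) {
    for (i in seq_len(u)) for (j in seq_len(v)) {
      dd <- 2 * length(intersect(gsets[[i]], psets[[j]])) /
        (length(gsets[[i]]) + length(psets[[j]]))
      edges[i, j] <- dd > theta
    }
  }
  best <- if (v == 0) 0L else max_matching(edges, u, v)
  ambiguous <- any(rowSums(edges) > 1) || (v > 0 && any(colSums(edges) > 1))
  list(msim = best / u, u = u, ambiguous = ambiguous)
}

# Naive direct convolution in the engine's channels-last layout
# (H, W, N, C), "same" padding, arbitrary dilation.
naive_conv <- function(x, W, b, dil = 1) {
  k <- dim(W)[1]; C <- dim(W)[3]; O <- dim(W)[4]
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]
  y <- array(0, c(H, Wd, N, O))
  half <- (k - 1) / 2
  for (n in seq_len(N)) for (o in seq_len(O)) for (i in seq_len(H))
    for (j in seq_len(Wd)) {
      acc <- b[o]
      for (cc in seq_len(C)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
        ii <- i + (ki - 1 - half) * dil
        jj <- j + (kj - 1 - half) * dil
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd)
          acc <- acc + x[ii, jj, n, cc] * W[ki, kj, cc, o]
      }
      y[i, j, n, o] <- acc
    }
  y
}
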