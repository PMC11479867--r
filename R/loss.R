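# Combined soft-Dice + binary cross-entropy training loss. The Dice term
# dominates (alpha = 0.7) so that the optimizer chases overlap rather than
# per-pixel accuracy, which matters when lesions occupy a tiny fraction of
# the image; the BCE term (beta = 0.3) keeps gradients informative early in
# training when predicted and true masks barely overlap.

#' Loss configuration
#'
#' @param alpha Weight on the soft-Dice term (default 0.7).
#' @param beta Weight on the binary cross-entropy term (default 0.3).
#' @param smooth Small positive constant added to numerator and denominator
#'   of the soft-Dice ratio; keeps the loss finite on empty masks.
#' @param eps Probability clipping bound for the BCE logarithms.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.7, beta = 0.3, smooth = 1e-5, eps = 1e-7) {
  stopifnot(alpha >= 0, beta >= 0, alpha + beta > 0, smooth > 0, eps > 0)
  structure(list(alpha = alpha, beta = beta, smooth = smooth, eps = eps),
            class = "loss_config")
}

check_same_shape <- function(a, b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(da, db))
    stop("shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binary cross-entropy loss
#'
#' Mean over all elements of `-(T log P + (1 - T) log(1 - P))`, with `P`
#' clipped to `[eps, 1 - eps]`.
#'
#' @param p Predicted probabilities, any numeric array in `[0, 1]`.
#' @param t Binary targets of the same shape.
#' @param eps Clipping bound.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(p, t, eps = 1e-7) {
  check_same_shape(p, t)
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(t * log(pc) + (1 - t) * log(1 - pc))
}

# Soft-Dice on one flattened channel/sample slab.
soft_dice_one <- function(p, t, smooth) {
  1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
}

#' Soft-Dice loss
#'
#' `1 - (2 sum(P T) + s) / (sum P + sum T + s)`, computed per output channel
#' and per sample, then averaged. For arrays of shape `(H, W, C, N)` this
#' yields the mean over the `C x N` channel/sample slabs; lower-dimensional
#' inputs are treated as a single slab.
#'
#' @param p Predicted probabilities in `[0, 1]`.
#' @param t Binary targets, same shape.
#' @param smooth Smoothing constant (see [loss_config()]).
#' @return Scalar in `[0, 1]`.
#' @export
soft_dice_loss <- function(p, t, smooth = 1e-5) {
  check_same_shape(p, t)
  d <- dim(p)
  if (is.null(d) || length(d) < 3) return(soft_dice_one(p, t, smooth))
  if (length(d) == 3) { dim(p) <- c(d, 1L); d <- dim(p) }
  vals <- numeric(0)
  for (n in seq_len(d[4]))
    for (cc in seq_len(d[3]))
      vals <- c(vals, soft_dice_one(p[, , cc, n], t[, , cc, n], smooth))
  mean(vals)
}

#' Combined segmentation loss
#'
#' `alpha * soft_dice_loss + beta * bce_loss`.
#'
#' @param p Predicted probabilities.
#' @param t Binary targets, same shape.
#' @param config A [loss_config()].
#' @return Scalar loss.
#' @export
combined_loss <- function(p, t, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"))
  config$alpha * soft_dice_loss(p, t, config$smooth) +
    config$beta * bce_loss(p, t, config$eps)
}

#' Analytic gradient of the combined loss
#'
#' Returns `d loss / d p` with the same shape as `p`. Elements clipped by
#' the BCE bound contribute zero BCE gradient.
#'
#' @inheritParams combined_loss
#' @return Array like `p`.
#' @export
combined_loss_grad <- function(p, t, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"))
  check_same_shape(p, t)
  d0 <- dim(p)
  d <- d0
  smooth <- config$smooth
  grad_dice_one <- function(pp, tt) {
    den <- sum(pp) + sum(tt) + smooth
    num <- 2 * sum(pp * tt) + smooth
    -(2 * tt * den - num) / den^2
  }
  if (is.null(d) || length(d) < 3) {
    gd <- grad_dice_one(p, t)
    nslab <- 1
  } else {
    if (length(d) == 3) { dim(p) <- c(d, 1L); dim(t) <- c(d, 1L); d <- dim(p) }
    gd <- array(0, d)
    for (n in seq_len(d[4]))
      for (cc in seq_len(d[3]))
        gd[, , cc, n] <- grad_dice_one(p[, , cc, n], t[, , cc, n])
    nslab <- d[3] * d[4]
  }
  eps <- config$eps
  pc <- pmin(pmax(p, eps), 1 - eps)
  gb <- (-t / pc + (1 - t) / (1 - pc)) / length(p)
  gb[p < eps | p > 1 - eps] <- 0
  g <- config$alpha * gd / nslab + config$beta * gb
  if (!is.null(d0)) dim(g) <- d0
  g
}
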