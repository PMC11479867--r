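# Training loop (Adam, fixed learning rate) and evaluation over phantom or
# preprocessed datasets. Everything is seed-pinned and CPU-deterministic:
# identical (config, seed) pairs reproduce identical loss curves.

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr = 3e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# Stack a list of (H, W, C) sample arrays into one (H, W, C, N) batch.
stack_batch <- function(lst) {
  d <- dim(lst[[1]])
  array(unlist(lst, use.names = FALSE), c(d, length(lst)))
}

sample_targets <- function(samples) {
  stack_batch(lapply(samples, function(s)
    array(c(s$wt_mask, s$tc_mask), c(dim(s$wt_mask), 2L))))
}

batch_dice <- function(prob, target, threshold = 0.5) {
  pred <- array(as.numeric(prob >= threshold), dim(prob))
  d <- dim(prob)
  vapply(seq_len(d[3]), function(cc) {
    p <- pred[, , cc, , drop = FALSE]
    t <- target[, , cc, , drop = FALSE]
    den <- sum(p) + sum(t)
    if (den == 0) NA_real_ else 2 * sum(p * t) / den
  }, numeric(1))
}

#' Train DRAU-Net
#'
#' Full-batch-per-step Adam training over a list of samples (each with an
#' `image` array `(H, W, C)` and `wt_mask` / `tc_mask`). One epoch iterates
#' the shuffled samples in batches of `batch_size`.
#'
#' @param net A [drau_net()].
#' @param samples List of training samples.
#' @param epochs Number of epochs (the reference schedule is 150).
#' @param batch_size Batch size (reference: 8).
#' @param lr Adam learning rate (reference: 3e-4, constant).
#' @param loss_cfg A [loss_config()].
#' @param seed Seed for batch shuffling.
#' @param val_samples Optional held-out samples; per-epoch validation Dice
#'   is logged when supplied.
#' @param target_dice Optional early-stop: training stops once the epoch's
#'   training WT Dice reaches this value.
#' @param verbose Print a line per epoch.
#' @return List with the trained `net` and `log`, a data frame of epoch,
#'   mean training loss, training Dice per head and (if requested)
#'   validation Dice per head.
#' @export
train_drau <- function(net, samples, epochs = 150L, batch_size = 8L,
                       lr = 3e-4, loss_cfg = loss_config(), seed = 1L,
                       val_samples = NULL, target_dice = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(net, "drau_net"), length(samples) >= 1)
  set.seed(seed)
  opt <- adam_init(net$params)
  logs <- vector("list", epochs)
  n <- length(samples)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    dsum <- c(0, 0); dn <- c(0, 0)
    for (start in seq(1, n, batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      x <- stack_batch(lapply(samples[idx], `[[`, "image"))
      t <- sample_targets(samples[idx])
      cache <- new.env(parent = emptyenv())
      p <- drau_forward(net, x, train = TRUE, cache = cache)
      losses <- c(losses, combined_loss(p, t, loss_cfg))
      bd <- batch_dice(p, t)
      ok <- !is.na(bd)
      dsum[ok] <- dsum[ok] + bd[ok]; dn[ok] <- dn[ok] + 1
      dP <- combined_loss_grad(p, t, loss_cfg)
      G <- drau_backward(net, dP, cache)
      grads <- mget(names(net$params), envir = G)
      st <- adam_step(net$params, grads, opt, lr)
      net$params <- st$params
      opt <- st$opt
    }
    row <- data.frame(epoch = ep, loss = mean(losses),
                      train_dice_wt = if (dn[1] > 0) dsum[1] / dn[1] else NA,
                      train_dice_tc = if (dn[2] > 0) dsum[2] / dn[2] else NA)
    if (!is.null(val_samples)) {
      vx <- stack_batch(lapply(val_samples, `[[`, "image"))
      vt <- sample_targets(val_samples)
      vp <- drau_forward(net, vx, train = FALSE)
      vd <- batch_dice(vp, vt)
      row$val_dice_wt <- vd[1]
      row$val_dice_tc <- vd[2]
    }
    logs[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  dice WT %.3f TC %.3f", ep,
                      row$loss, row$train_dice_wt, row$train_dice_tc))
    if (!is.null(target_dice) && !is.na(row$train_dice_wt) &&
        row$train_dice_wt >= target_dice) {
      logs <- logs[seq_len(ep)]
      break
    }
  }
  list(net = net, log = do.call(rbind, logs))
}

#' Evaluate a network on a dataset
#'
#' Runs inference case by case, binarizes the sigmoid outputs at
#' `threshold`, and reports global overlap metrics per head plus the
#' lesion-wise MSIM (WT head against the WT ground truth, with the TC
#' ground truth available as core mask if the configuration requires it).
#'
#' @param net Trained [drau_net()].
#' @param samples List of samples with `image`, `wt_mask`, `tc_mask`.
#' @param msim_cfg An [msim_config()].
#' @param threshold Binarization threshold on the sigmoid outputs.
#' @return List with `per_case` (data frame) and `summary` (macro means of
#'   defined metrics plus micro/macro MSIM).
#' @export
evaluate_drau <- function(net, samples, msim_cfg = msim_config(),
                          threshold = 0.5) {
  rows <- vector("list", length(samples))
  reports <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    x <- stack_batch(list(s$image))
    p <- drau_forward(net, x, train = FALSE)
    wt_pred <- array(as.numeric(p[, , 1, 1] >= threshold), dim(s$wt_mask))
    tc_pred <- array(as.numeric(p[, , 2, 1] >= threshold), dim(s$tc_mask))
    mw <- evaluate_masks(wt_pred, s$wt_mask)
    mt <- evaluate_masks(tc_pred, s$tc_mask)
    core <- if (msim_cfg$require_core) s$tc_mask else NULL
    rep <- msim(s$wt_mask, wt_pred, core_mask = core, config = msim_cfg)
    reports[[i]] <- rep
    rows[[i]] <- data.frame(
      case = i,
      dice_wt = mw$dice, ppv_wt = mw$ppv, sensitivity_wt = mw$sensitivity,
      jaccard_wt = mw$jaccard,
      dice_tc = mt$dice, ppv_tc = mt$ppv, sensitivity_tc = mt$sensitivity,
      jaccard_tc = mt$jaccard,
      msim = rep$msim, msim_u = rep$u, msim_successes = rep$successes)
  }
  per_case <- do.call(rbind, rows)
  agg <- msim_dataset(reports)
  summary <- c(lapply(per_case[, setdiff(names(per_case),
                                         c("case", "msim_u",
                                           "msim_successes"))],
                      function(v) mean(v, na.rm = TRUE)),
               list(msim_micro = agg$msim_micro, msim_macro = agg$msim_macro))
  list(per_case = per_case, summary = summary, reports = reports)
}

#' Save / load a checkpoint
#'
#' Checkpoints are RDS files holding the parameters, batch-norm running
#' statistics and configuration.
#'
#' @param net A [drau_net()].
#' @param path Destination file.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(config = unclass(net$config), params = net$params,
               state = as.list(net$state)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the restored `drau_net`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$config) || is.null(ck$params))
    stop("incompatible checkpoint: ", path,
         " (missing config or parameters)")
  S <- new.env(parent = emptyenv())
  for (nm in names(ck$state)) S[[nm]] <- ck$state[[nm]]
  structure(list(config = structure(ck$config, class = "drau_config"),
                 params = ck$params, state = S),
            class = "drau_net")
}
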