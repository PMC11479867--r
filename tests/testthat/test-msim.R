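cfg0 <- msim_config(delta = 0)

test_that("worked lesion-matching cases score as hand-derived", {
  # identity with three lesions
  gt <- blank_mask(60, 60)
  gt <- add_rect(gt, 5, 14, 5, 14)
  gt <- add_rect(gt, 30, 39, 5, 14)
  gt <- add_rect(gt, 5, 14, 40, 49)
  expect_equal(msim(gt, gt, config = cfg0)$msim, 1)
  # empty prediction: all lesions missed
  r <- msim(gt, blank_mask(60, 60), config = cfg0)
  expect_equal(r$msim, 0)
  expect_equal(r$u, 3)
  # one of two 10x10 squares reproduced exactly
  gt2 <- add_rect(add_rect(blank_mask(40, 40), 5, 14, 5, 14), 25, 34, 25, 34)
  pred2 <- add_rect(blank_mask(40, 40), 5, 14, 5, 14)
  r2 <- msim(gt2, pred2, config = cfg0)
  expect_equal(r2$msim, 0.5)
  expect_equal(sort(r2$matches$dice), c(0, 1))
  # 60-pixel overlap of a 100-pixel square: per-lesion Dice 0.6 < 0.7
  gt3 <- add_rect(blank_mask(30, 30), 6, 15, 6, 15)
  pred3 <- add_rect(blank_mask(30, 30), 6, 15, 2, 11)
  r3 <- msim(gt3, pred3, config = cfg0)
  expect_equal(r3$matches$dice, 0.6)
  expect_equal(r3$msim, 0)
})

test_that("success requires Dice strictly above theta", {
  gt <- add_rect(blank_mask(20, 20), 5, 14, 5, 14)
  pred <- add_rect(blank_mask(20, 20), 5, 14, 5, 14)
  r <- msim(gt, pred, config = msim_config(delta = 0, theta = 1))
  expect_equal(r$matches$dice, 1)
  expect_equal(r$msim, 0)  # dice == theta is a failure
})

test_that("area filter drops small ground-truth components", {
  comps <- connected_components(
    add_rect(add_rect(blank_mask(30, 30), 2, 11, 2, 11), 20, 22, 20, 22)
  )$components
  kept <- filter_gt_components(comps, 10)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$size, 100)
  expect_length(filter_gt_components(comps, 0), 2)
  expect_error(filter_gt_components(comps, 0, require_core = TRUE),
               "core_mask")
  # a 50-px component with no core overlap is deleted
  core <- blank_mask(30, 30)
  expect_length(filter_gt_components(comps, 0, core, TRUE), 0)
  core2 <- add_rect(blank_mask(30, 30), 5, 6, 5, 6)
  expect_length(filter_gt_components(comps, 0, core2, TRUE), 1)
})

test_that("smoothing fills pinholes in a component", {
  holed <- add_rect(blank_mask(12, 12), 4, 8, 4, 8)
  holed[6, 6] <- 0
  comp <- connected_components(holed)$components[[1]]
  sm <- smooth_component(comp, c(12, 12))
  expect_equal(sm$size, 25)
})

test_that("prediction components are consumed at most once", {
  # one big predicted blob covering two GT lesions can satisfy only one
  gt <- add_rect(add_rect(blank_mask(30, 60), 10, 19, 5, 14), 10, 19, 30, 39)
  pred <- blank_mask(30, 60)
  pred[10:19, 5:39] <- 1
  r <- msim(gt, pred, config = cfg0)
  expect_lte(r$successes, 1)
  expect_equal(anyDuplicated(stats::na.omit(r$matches$pred_id)), 0)
  # a genuinely consumable prediction: two exact squares plus the blob case
  gt2 <- add_rect(add_rect(blank_mask(30, 60), 10, 19, 5, 14),
                  10, 19, 30, 39)
  r2 <- msim(gt2, gt2, config = cfg0)
  expect_equal(r2$successes, 2)
  expect_equal(anyDuplicated(stats::na.omit(r2$matches$pred_id)), 0)
})

test_that("dataset aggregation is a micro-average over lesions", {
  mk_case <- function(u, s) {
    g <- blank_mask(64, 64); p <- blank_mask(64, 64)
    for (i in seq_len(u)) {
      ro <- 10 * i
      g <- add_rect(g, ro, ro + 4, 5, 9)
      if (i <= s) p <- add_rect(p, ro, ro + 4, 5, 9)
    }
    msim(g, p, config = cfg0)
  }
  reports <- list(mk_case(2, 2), mk_case(1, 0), mk_case(1, 1), mk_case(1, 1))
  agg <- msim_dataset(reports)
  expect_equal(agg$msim_micro, 4 / 5)
  expect_equal(agg$msim_macro, mean(c(1, 0, 1, 1)))
  expect_equal(agg$total_u, 5)
})

test_that("msim is invariant to common translation", {
  set.seed(301)
  for (i in 1:10) {
    pr <- random_lesion_pair(40)
    base <- msim(pr$gt, pr$pred, config = cfg0)
    shift <- function(m, dr, dc) {
      out <- blank_mask(dim(m)[1] + 6, dim(m)[2] + 6)
      out[dr + seq_len(dim(m)[1]), dc + seq_len(dim(m)[2])] <- m
      out
    }
    moved <- msim(shift(pr$gt, 4, 3), shift(pr$pred, 4, 3), config = cfg0)
    expect_equal(moved$msim, base$msim)
    expect_equal(moved$u, base$u)
  }
})

test_that("raising delta never increases u; raising theta never raises msim", {
  set.seed(302)
  for (i in 1:15) {
    pr <- random_lesion_pair(48)
    us <- vapply(c(0, 4, 10, 30), function(dl)
      msim(pr$gt, pr$pred, config = msim_config(delta = dl))$u, integer(1))
    expect_true(all(diff(us) <= 0))
    ms <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th)
      msim(pr$gt, pr$pred,
           config = msim_config(delta = 0, theta = th))$msim, numeric(1))
    ms <- ms[!is.na(ms)]
    if (length(ms) > 1) expect_true(all(diff(ms) <= 1e-12))
  }
})

test_that("slice mode pools lesion counts over axial slices", {
  vol_gt <- array(0, c(30, 30, 2))
  vol_gt[5:14, 5:14, 1] <- 1
  vol_gt[5:14, 5:14, 2] <- 1
  vol_gt[20:24, 20:24, 2] <- 1
  vol_pred <- vol_gt
  vol_pred[20:24, 20:24, 2] <- 0   # miss one lesion on slice 2
  r <- msim(vol_gt, vol_pred,
            config = msim_config(delta = 0, mode = "slice"))
  expect_equal(r$u, 3)
  expect_equal(r$msim, 2 / 3)
  # volume mode sees two 3-D components (the slab spans both slices)
  rv <- msim(vol_gt, vol_pred, config = cfg0)
  expect_equal(rv$u, 2)
  expect_equal(rv$msim, 1 / 2)
})

test_that("shape mismatches and invalid configs are rejected", {
  expect_error(msim(blank_mask(8, 8), blank_mask(8, 9), config = cfg0),
               "shape mismatch")
  expect_error(msim_config(theta = 0), "theta")
  expect_error(msim_config(delta = -1), "delta")
})
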