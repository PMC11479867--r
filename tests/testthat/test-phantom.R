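small_cfg <- phantom_config(grid = c(64, 64), n_lesions = c(3, 3),
                            lesion_radius = c(2, 8), min_separation = 6)

test_that("samples are deterministic and structurally consistent", {
  s1 <- generate_sample(small_cfg, seed = 42)
  s2 <- generate_sample(small_cfg, seed = 42)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$wt_mask, s2$wt_mask)
  s3 <- generate_sample(small_cfg, seed = 43)
  expect_false(identical(s1$image, s3$image))
  # core inside whole tumor; component count equals catalogue length
  expect_true(all(s1$tc_mask <= s1$wt_mask))
  cc <- connected_components(s1$wt_mask, 8)
  expect_length(cc$components, nrow(s1$lesions))
  expect_equal(nrow(s1$lesions), 3)
})

test_that("a noiseless phantom is recovered exactly by thresholding", {
  cfg <- phantom_config(grid = c(64, 64), n_lesions = c(2, 2),
                        lesion_radius = c(3, 7), noise_sigma = 0)
  s <- generate_sample(cfg, seed = 7)
  # channel 2 is brain + contrast over WT: threshold above brain intensity
  thr <- cfg$brain_intensity + 0.5 * cfg$contrast[2]
  rec <- array(as.numeric(s$image[, , 2] > thr), dim(s$wt_mask))
  expect_equal(rec, s$wt_mask)
  expect_equal(dice(rec, s$wt_mask), 1)
})

test_that("generator and metrics are self-consistent", {
  for (seed in c(1, 9, 23)) {
    s <- generate_sample(small_cfg, seed = seed)
    expect_equal(msim(s$wt_mask, s$wt_mask,
                      config = msim_config(delta = 0))$msim, 1)
    expect_equal(dice(s$wt_mask, s$wt_mask), 1)
  }
})

test_that("deleting the smallest lesion moves msim by exactly 1/u but global
           Dice by less", {
  s <- generate_sample(small_cfg, seed = 15)
  cc <- connected_components(s$wt_mask, 8)
  u <- length(cc$components)
  sizes <- vapply(cc$components, `[[`, numeric(1), "size")
  smallest <- cc$components[[which.min(sizes)]]
  pred <- s$wt_mask
  pred[smallest$pixels] <- 0
  r <- msim(s$wt_mask, pred, config = msim_config(delta = 0))
  expect_equal(r$msim, (u - 1) / u)
  d <- dice(pred, s$wt_mask)
  expect_lt(1 - d, 1 / u)
})

test_that("datasets have reproducible manifests and component totals", {
  ds1 <- generate_dataset(small_cfg, n_cases = 5, seed = 99)
  ds2 <- generate_dataset(small_cfg, n_cases = 5, seed = 99)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_equal(nrow(ds1$manifest), 5)
  total <- sum(vapply(ds1$samples, function(s)
    length(connected_components(s$wt_mask, 8)$components), integer(1)))
  expect_equal(total, sum(ds1$manifest$n_lesions))
})

test_that("phantom datasets round-trip through NIfTI", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(small_cfg, n_cases = 2, seed = 4)
  write_phantom_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_phantom_dataset(dir)
  expect_length(back$samples, 2)
  expect_equal(back$samples[[1]]$wt_mask,
               array(ds$samples[[1]]$wt_mask, c(64, 64)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$samples[[1]]$image, ds$samples[[1]]$image,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("impossible placements fail with a helpful error", {
  cfg <- phantom_config(grid = c(24, 24), n_lesions = c(8, 8),
                        lesion_radius = c(6, 8), min_separation = 10,
                        max_tries = 20)
  expect_error(generate_sample(cfg, seed = 1), "fewer or smaller")
})
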