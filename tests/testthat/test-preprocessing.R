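test_that("zscore standardizes the brain region and keeps background zero", {
  v <- array(0, c(3, 3))
  v[1, 1] <- 2; v[2, 2] <- 4; v[3, 3] <- 6
  z <- zscore(v)
  got <- sort(z[v != 0])
  expect_equal(got, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_true(all(z[v == 0] == 0))
  expect_equal(mean(z[v != 0]), 0, tolerance = 1e-6)
  # idempotence (with the brain mask held fixed, and generically where no
  # standardized voxel lands exactly on zero)
  z2 <- zscore(z, mask = v != 0)
  expect_equal(as.vector(z2), as.vector(z), tolerance = 1e-6)
  set.seed(12)
  vr <- array(0, c(8, 8)); vr[2:7, 2:7] <- stats::runif(36, 1, 5)
  zr <- zscore(vr)
  expect_equal(as.vector(zscore(zr)), as.vector(zr), tolerance = 1e-6)
  expect_error(zscore(array(5, c(3, 3))), "constant")
})

test_that("center crop keeps the central window and records offsets", {
  v <- array(seq_len(240 * 240), c(240, 240))
  cr <- center_crop(v, c(160, 160))
  expect_equal(dim(cr), c(160, 160))
  expect_equal(attr(cr, "crop_offset"), c(40, 40))
  expect_equal(cr[1, 1], v[41, 41])
  expect_equal(cr[160, 160], v[200, 200])
  # identity case
  v160 <- array(stats::rnorm(160 * 160), c(160, 160))
  cr160 <- center_crop(v160)
  expect_equal(as.vector(cr160), as.vector(v160))
  # pad path for small inputs
  v150 <- array(1, c(150, 150))
  cr150 <- center_crop(v150)
  expect_equal(dim(cr150), c(160, 160))
  expect_equal(sum(cr150), 150 * 150)
  expect_equal(cr150[6, 6], 1)  # centered
  expect_equal(cr150[5, 6], 0)
})

test_that("uncrop inverts the crop inside the window", {
  v <- array(stats::rnorm(200 * 180), c(200, 180))
  cr <- center_crop(v, c(160, 160))
  back <- uncrop(cr)
  expect_equal(dim(back), dim(v))
  off <- attr(cr, "crop_offset")
  expect_equal(back[off[1] + seq_len(160), off[2] + seq_len(160)],
               array(cr, c(160, 160)))
  # padded inputs restore exactly
  v2 <- array(stats::rnorm(150 * 150), c(150, 150))
  expect_equal(uncrop(center_crop(v2)), v2, ignore_attr = TRUE)
})

test_that("label regrouping follows WT = label 2, TC = labels 1 + 3", {
  lab <- array(c(0, 1, 2, 3, 2, 1, 0, 3, 0), c(3, 3))
  m <- regroup_labels(lab)
  expect_equal(m$wt, array(as.numeric(lab == 2), c(3, 3)))
  expect_equal(m$tc, array(as.numeric(lab %in% c(1, 3)), c(3, 3)))
  # conventional union on request
  mo <- regroup_labels(lab, orthodox_wt = TRUE)
  expect_equal(mo$wt, array(as.numeric(lab > 0), c(3, 3)))
  # masks never exceed the original foreground
  expect_true(all((m$wt + m$tc) <= (lab > 0)))
  empty <- regroup_labels(array(0, c(4, 4)))
  expect_equal(sum(empty$wt) + sum(empty$tc), 0)
  expect_error(regroup_labels(array(c(0, 4), c(1, 2))), "unexpected label")
})

test_that("NIfTI round trip and full case preprocessing", {
  dir <- withr::local_tempdir()
  set.seed(55)
  g <- c(40, 40)
  brain <- array(0, g); brain[10:30, 10:30] <- stats::runif(21 * 21, 1, 3)
  lab <- array(0, g); lab[15:18, 15:18] <- 2; lab[16:17, 16:17] <- 1
  lab[22:24, 22:24] <- 3
  p1 <- file.path(dir, "t1c.nii.gz"); write_volume(brain, p1)
  p2 <- file.path(dir, "t2f.nii.gz"); write_volume(brain * 1.5, p2)
  pl <- file.path(dir, "seg.nii.gz"); write_volume(lab, pl)
  expect_equal(read_volume(p1), brain, tolerance = 1e-6, ignore_attr = TRUE)
  case <- preprocess_case(p1, p2, pl, size = c(32, 32))
  expect_equal(dim(case$image), c(32, 32, 2))
  expect_equal(dim(case$wt), c(32, 32))
  # z-scored over brain: mean ~0 on nonzero region
  ch1 <- case$image[, , 1]
  expect_lt(abs(mean(ch1[ch1 != 0])), 0.1)
  expect_equal(sum(case$tc), sum(lab %in% c(1, 3)))
  expect_error(preprocess_case(p1, p2, file.path(dir, "nope.png")))
})
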