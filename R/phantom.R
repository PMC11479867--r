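# Synthetic multi-lesion phantom slices. Each sample is a two-channel
# image over a circular "brain" region containing several small bright
# disc lesions: the whole-tumor (WT) mask is the full disc, the tumor-core
# (TC) mask a concentric inner disc. Channel 1 mimics post-contrast T1
# (brightest at the core), channel 2 mimics T2-FLAIR (bright over the whole
# lesion). Radii are drawn log-uniformly so small lesions dominate, the
# regime where lesion-wise evaluation and global Dice disagree most.

#' Phantom generator configuration
#'
#' @param grid In-plane size, default `c(160, 160)`.
#' @param n_lesions Integer range (min, max) of lesions per sample,
#'   default 1--6.
#' @param lesion_radius WT radius range in pixels, default 2--12, sampled
#'   log-uniformly (skewed toward small metastases).
#' @param core_fraction TC radius as a fraction of the WT radius
#'   (default 0.5; the core is never smaller than 1 pixel).
#' @param contrast Length-2 intensity added by a lesion in channels 1 and 2.
#'   Channel 1 gains `contrast[1]` inside the core only; channel 2 gains
#'   `contrast[2]` over the whole lesion.
#' @param brain_intensity Baseline intensity of the brain disc.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param min_separation Minimum gap in pixels between lesion boundaries
#'   (keeps lesions disconnected so the mask component count equals the
#'   catalogue length).
#' @param max_tries Placement retries per lesion before giving up.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(160L, 160L), n_lesions = c(1L, 6L),
                           lesion_radius = c(2, 12), core_fraction = 0.5,
                           contrast = c(2, 1.5), brain_intensity = 1,
                           noise_sigma = 0.1, min_separation = 3L,
                           max_tries = 200L) {
  stopifnot(length(grid) == 2, all(grid >= 16),
            n_lesions[1] >= 1, n_lesions[2] >= n_lesions[1],
            lesion_radius[1] >= 1, lesion_radius[2] >= lesion_radius[1],
            core_fraction > 0, core_fraction <= 1,
            noise_sigma >= 0, min_separation >= 1)
  structure(list(grid = as.integer(grid), n_lesions = as.integer(n_lesions),
                 lesion_radius = lesion_radius,
                 core_fraction = core_fraction, contrast = contrast,
                 brain_intensity = brain_intensity,
                 noise_sigma = noise_sigma,
                 min_separation = as.integer(min_separation),
                 max_tries = as.integer(max_tries)),
            class = "phantom_config")
}

disc_mask <- function(grid, center, radius) {
  dr <- outer(seq_len(grid[1]) - center[1], rep(1, grid[2]))
  dc <- outer(rep(1, grid[1]), seq_len(grid[2]) - center[2])
  (dr^2 + dc^2) <= radius^2
}

#' Generate one phantom sample
#'
#' Deterministic for a fixed seed. Lesion centers are drawn uniformly
#' inside the brain disc with rejection sampling enforcing
#' `min_separation` pixels between lesion boundaries.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed for this sample.
#' @return List of class `phantom_sample`: `image` (array
#'   `(H, W, 2)`), binary `wt_mask` and `tc_mask` (`tc` inside `wt`), and
#'   `lesions`, a data frame of centers and radii.
#' @export
generate_sample <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(seed)
  g <- config$grid
  brain_center <- (g + 1) / 2
  brain_radius <- 0.45 * min(g)
  brain <- disc_mask(g, brain_center, brain_radius)
  n <- if (config$n_lesions[1] == config$n_lesions[2]) config$n_lesions[1]
       else sample(config$n_lesions[1]:config$n_lesions[2], 1)
  centers <- matrix(0, 0, 2)
  radii <- numeric(0)
  for (i in seq_len(n)) {
    r <- exp(stats::runif(1, log(config$lesion_radius[1]),
                          log(config$lesion_radius[2])))
    placed <- FALSE
    for (try in seq_len(config$max_tries)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * (brain_radius - r - 1)
      ctr <- brain_center + rad * c(cos(ang), sin(ang))
      ok <- TRUE
      if (length(radii) > 0) {
        dists <- sqrt(rowSums((centers - matrix(ctr, nrow(centers), 2,
                                                byrow = TRUE))^2))
        ok <- all(dists >= radii + r + config$min_separation)
      }
      if (ok) {
        centers <- rbind(centers, ctr)
        radii <- c(radii, r)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place lesion ", i, " of ", n, " after ",
           config$max_tries, " tries; use fewer or smaller lesions")
  }
  wt <- array(FALSE, g)
  tc <- array(FALSE, g)
  core_radii <- pmax(1, config$core_fraction * radii)
  for (i in seq_along(radii)) {
    wt <- wt | disc_mask(g, centers[i, ], radii[i])
    tc <- tc | disc_mask(g, centers[i, ], core_radii[i])
  }
  ch1 <- config$brain_intensity * brain + config$contrast[1] * tc +
    0.3 * config$contrast[1] * (wt & !tc)
  ch2 <- config$brain_intensity * brain + config$contrast[2] * wt
  img <- array(0, c(g, 2L))
  img[, , 1] <- ch1 + stats::rnorm(prod(g), 0, config$noise_sigma) * brain
  img[, , 2] <- ch2 + stats::rnorm(prod(g), 0, config$noise_sigma) * brain
  lesions <- data.frame(center_row = centers[, 1], center_col = centers[, 2],
                        wt_radius = radii, tc_radius = core_radii)
  structure(list(image = img, wt_mask = array(as.numeric(wt), g),
                 tc_mask = array(as.numeric(tc), g), lesions = lesions,
                 seed = seed),
            class = "phantom_sample")
}

#' Generate a phantom dataset
#'
#' Per-case seeds are derived deterministically from the master seed, so a
#' fixed master seed reproduces the full dataset bitwise.
#'
#' @param config A [phantom_config()].
#' @param n_cases Number of samples.
#' @param seed Master seed.
#' @return List with `samples` (list of `phantom_sample`) and `manifest`, a
#'   data frame of case id, per-case seed and lesion count (the metric
#'   ground truth for component counting).
#' @export
generate_dataset <- function(config = phantom_config(), n_cases = 20L,
                             seed = 1L) {
  case_seed <- (as.integer(seed) + 7919L * seq_len(n_cases)) %% 2147483647L
  samples <- lapply(seq_len(n_cases), function(i)
    generate_sample(config, case_seed[i]))
  manifest <- data.frame(
    case_id = sprintf("case_%03d", seq_len(n_cases)),
    seed = case_seed,
    n_lesions = vapply(samples, function(s) nrow(s$lesions), integer(1)))
  list(samples = samples, manifest = manifest)
}

#' Write a phantom dataset as NIfTI files
#'
#' Each case produces `<id>_t1c.nii.gz`, `<id>_t2f.nii.gz`,
#' `<id>_wt.nii.gz` and `<id>_tc.nii.gz` plus a `manifest.csv`, mirroring a
#' two-modality clinical layout so the full CLI path runs on phantoms.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    id <- dataset$manifest$case_id[i]
    write_volume(s$image[, , 1], file.path(dir, paste0(id, "_t1c.nii.gz")))
    write_volume(s$image[, , 2], file.path(dir, paste0(id, "_t2f.nii.gz")))
    write_volume(s$wt_mask, file.path(dir, paste0(id, "_wt.nii.gz")))
    write_volume(s$tc_mask, file.path(dir, paste0(id, "_tc.nii.gz")))
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a phantom dataset written by [write_phantom_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return List with `samples` (each with `image`, `wt_mask`, `tc_mask`)
#'   and the manifest.
#' @export
read_phantom_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  samples <- lapply(manifest$case_id, function(id) {
    t1c <- read_volume(file.path(dir, paste0(id, "_t1c.nii.gz")))
    t2f <- read_volume(file.path(dir, paste0(id, "_t2f.nii.gz")))
    img <- array(c(t1c, t2f), c(dim(t1c), 2L))
    list(image = img,
         wt_mask = read_volume(file.path(dir, paste0(id, "_wt.nii.gz")),
                               as_mask = TRUE),
         tc_mask = read_volume(file.path(dir, paste0(id, "_tc.nii.gz")),
                               as_mask = TRUE))
  })
  list(samples = samples, manifest = manifest)
}
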