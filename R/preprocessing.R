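# Input pipeline for BraTS-style NIfTI volumes: modality selection,
# Z-score normalization over the brain (nonzero) region, 160x160 center
# cropping, and regrouping of the BraTS2023 labels into the two binary
# training targets (whole tumor = label 2, tumor core = labels 1 + 3).

#' Z-score normalization over the brain region
#'
#' Standardizes intensities to zero mean and unit standard deviation
#' computed over the nonzero voxels only. BraTS volumes are skull-stripped,
#' so including the background zeros would bias the statistics; background
#' voxels remain exactly zero in the output. The population (1/n) standard
#' deviation is used.
#'
#' @param volume Numeric array with more than one voxel.
#' @param mask Optional logical array selecting the region to standardize
#'   over; defaults to `volume != 0`.
#' @return Array of the same shape with attributes `zscore_mean` and
#'   `zscore_sd` recording the statistics.
#' @export
zscore <- function(volume, mask = NULL) {
  if (length(volume) <= 1) stop("volume must have more than one voxel")
  if (is.null(mask)) mask <- volume != 0
  vals <- volume[mask]
  if (length(vals) < 2) stop("brain region has fewer than two voxels")
  m <- mean(vals)
  s <- sqrt(mean((vals - m)^2))
  if (s == 0) stop("degenerate input: constant brain region (sd = 0)")
  out <- volume
  out[mask] <- (vals - m) / s
  attr(out, "zscore_mean") <- m
  attr(out, "zscore_sd") <- s
  out
}

#' Center crop (or pad) the in-plane dimensions
#'
#' Crops the first two dimensions to `size`, keeping the central region;
#' dimensions smaller than the target are first zero-padded symmetrically.
#' The crop/pad offsets are recorded so [uncrop()] can restore the original
#' frame.
#'
#' @param volume 2-D or 3-D array (plane dims first).
#' @param size Target in-plane size, default `c(160, 160)`.
#' @return Cropped array with attributes `crop_offset` (0-based offset of
#'   the output window in the padded frame), `pad_before` and `orig_dim`.
#' @export
center_crop <- function(volume, size = c(160L, 160L)) {
  d <- dim(volume)
  if (is.null(d) || length(d) < 2) stop("volume must be 2-D or 3-D")
  orig <- d
  pad_before <- integer(2)
  for (k in 1:2) {
    if (d[k] < size[k]) {
      pad_before[k] <- (size[k] - d[k]) %/% 2
      newd <- d; newd[k] <- size[k]
      padded <- array(0, newd)
      idx <- lapply(seq_along(d), function(j) {
        if (j == k) pad_before[k] + seq_len(d[k]) else seq_len(d[j])
      })
      padded <- do.call(`[<-`, c(list(padded), idx, list(value = volume)))
      volume <- padded
      d <- newd
    }
  }
  off <- c((d[1] - size[1]) %/% 2, (d[2] - size[2]) %/% 2)
  idx <- c(list(off[1] + seq_len(size[1]), off[2] + seq_len(size[2])),
           lapply(d[-(1:2)], seq_len))
  out <- do.call(`[`, c(list(volume), idx, list(drop = FALSE)))
  if (length(orig) == 2) dim(out) <- size
  attr(out, "crop_offset") <- off
  attr(out, "pad_before") <- pad_before
  attr(out, "orig_dim") <- orig
  out
}

#' Invert a center crop
#'
#' Embeds a cropped array back into its original frame (zeros outside the
#' crop window), using the offsets recorded by [center_crop()].
#'
#' @param cropped Output of [center_crop()] (attributes intact), or any
#'   array plus explicit `offset`/`orig_dim`.
#' @param offset,pad_before,orig_dim Override the recorded attributes.
#' @return Array with the original dimensions.
#' @export
uncrop <- function(cropped, offset = attr(cropped, "crop_offset"),
                   pad_before = attr(cropped, "pad_before"),
                   orig_dim = attr(cropped, "orig_dim")) {
  if (is.null(offset) || is.null(orig_dim))
    stop("crop offsets missing; pass offset/orig_dim explicitly")
  d <- dim(cropped)
  padded_dim <- orig_dim
  padded_dim[1:2] <- pmax(orig_dim[1:2] + 2 * pad_before, d[1:2] + offset)
  full <- array(0, padded_dim)
  idx <- c(list(offset[1] + seq_len(d[1]), offset[2] + seq_len(d[2])),
           lapply(padded_dim[-(1:2)], seq_len))
  full <- do.call(`[<-`, c(list(full), idx, list(value = cropped)))
  idx2 <- c(list(pad_before[1] + seq_len(orig_dim[1]),
                 pad_before[2] + seq_len(orig_dim[2])),
            lapply(padded_dim[-(1:2)], seq_len))
  out <- do.call(`[`, c(list(full), idx2, list(drop = FALSE)))
  dim(out) <- orig_dim
  out
}

#' Regroup BraTS2023 labels into WT / TC masks
#'
#' The three BraTS2023 brain-metastasis labels (1 = non-enhancing tumor
#' core, 2 = surrounding FLAIR hyperintensity, 3 = enhancing tumor) are
#' regrouped into two binary targets: whole tumor = label 2 and tumor core
#' = labels 1 + 3. Note this WT definition is the FLAIR-hyperintensity
#' region alone; set `orthodox_wt = TRUE` for the conventional BraTS union
#' (labels 1, 2 and 3).
#'
#' @param label Integer array with values in `{0, 1, 2, 3}`.
#' @param orthodox_wt Use the conventional WT = 1 u 2 u 3 union instead.
#' @return List with binary arrays `wt` and `tc`.
#' @export
regroup_labels <- function(label, orthodox_wt = FALSE) {
  bad <- setdiff(unique(as.vector(label)), 0:3)
  if (length(bad) > 0)
    stop("unexpected label values: ", paste(sort(bad), collapse = ", "),
         " (expected 0, 1, 2, 3)")
  wt_ids <- if (orthodox_wt) 1:3 else 2L
  list(wt = binarize(label, wt_ids), tc = binarize(label, c(1L, 3L)))
}

#' Read a mask or image volume from NIfTI or PNG
#'
#' @param path File ending in `.nii`, `.nii.gz` or `.png` (single-channel;
#'   gray values are rounded to integers for masks).
#' @param as_mask Round to integer values.
#' @return Numeric array (2-D for PNG, as stored for NIfTI).
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    v <- img
    if (as_mask) v <- round(v * 255)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- as.array(RNifti::readNifti(path))
    if (as_mask) v <- round(v)
  } else stop("unsupported mask format: ", path,
              " (expected .nii, .nii.gz or .png)")
  v
}

#' Write a volume as NIfTI
#'
#' @param volume Numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(volume, path) {
  a <- array(as.numeric(volume), dim(volume))
  RNifti::writeNifti(RNifti::asNifti(a), path)
  invisible(path)
}

#' Preprocess one BraTS-style case
#'
#' Loads the two input modalities, Z-scores each over its brain region,
#' center-crops to `size`, regroups the label volume into WT / TC masks and
#' crops those identically.
#'
#' @param t1c_path,t2f_path,label_path NIfTI paths sharing one grid.
#' @param size In-plane target size.
#' @param orthodox_wt See [regroup_labels()].
#' @return List with `image` (array `(H, W, 2)` for 2-D inputs or
#'   `(H, W, D, 2)` for 3-D), `wt`, `tc`, and the normalization / crop
#'   metadata.
#' @export
preprocess_case <- function(t1c_path, t2f_path, label_path,
                            size = c(160L, 160L), orthodox_wt = FALSE) {
  t1c <- zscore(read_volume(t1c_path))
  t2f <- zscore(read_volume(t2f_path))
  lab <- read_volume(label_path, as_mask = TRUE)
  if (!identical(dim(t1c), dim(t2f)) || !identical(dim(t1c), dim(lab)))
    stop("modalities and label must share one grid")
  t1c_c <- center_crop(t1c, size)
  t2f_c <- center_crop(t2f, size)
  masks <- regroup_labels(lab, orthodox_wt)
  wt_c <- center_crop(masks$wt, size)
  tc_c <- center_crop(masks$tc, size)
  nd <- length(dim(t1c_c))
  image <- array(c(t1c_c, t2f_c), c(dim(t1c_c), 2L))
  list(image = image, wt = array(as.numeric(wt_c), dim(wt_c)),
       tc = array(as.numeric(tc_c), dim(tc_c)),
       crop_offset = attr(t1c_c, "crop_offset"),
       pad_before = attr(t1c_c, "pad_before"),
       orig_dim = attr(t1c_c, "orig_dim"),
       zscore = list(t1c = c(mean = attr(t1c, "zscore_mean"),
                             sd = attr(t1c, "zscore_sd")),
                     t2f = c(mean = attr(t2f, "zscore_mean"),
                             sd = attr(t2f, "zscore_sd"))))
}
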