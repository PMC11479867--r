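# Connected-component labeling and binary morphology on 2-D / 3-D grids.
#
# Labeling uses iterative minimum-label propagation: every foreground cell
# starts with its own linear index as label and repeatedly takes the minimum
# over its neighborhood until a fixed point. This is vectorised over whole
# arrays (one shifted copy per neighbor offset per sweep) and converges in
# O(longest geodesic path) sweeps, which is small for compact lesions.
# Morphology is implemented by the same shifted-copy trick (dilation = OR of
# shifts, erosion = AND of shifts over the structuring element).

# Neighbor offsets (excluding the origin) for a given connectivity.
# 2-D: 4 (edge) or 8 (edge + vertex); 3-D: 6, 18 or 26.
connectivity_offsets <- function(connectivity, ndim) {
  if (ndim == 2) {
    valid <- c(4, 8)
  } else if (ndim == 3) {
    valid <- c(6, 18, 26)
  } else stop("masks must be 2-D or 3-D")
  if (!connectivity %in% valid)
    stop("connectivity ", connectivity, " invalid for a ", ndim,
         "-D grid (valid: ", paste(valid, collapse = ", "), ")")
  grid <- as.matrix(expand.grid(rep(list(-1:1), ndim)))
  ord <- rowSums(abs(grid))
  max_ord <- switch(as.character(connectivity),
                    "4" = 1, "8" = 2, "6" = 1, "18" = 2, "26" = 3)
  grid[ord > 0 & ord <= max_ord, , drop = FALSE]
}

# Shift an array by an integer offset, filling exposed cells with `fill`.
shift_array <- function(a, offset, fill) {
  d <- dim(a)
  idx <- lapply(seq_along(d), function(k) {
    i <- seq_len(d[k]) - offset[k]
    i[i < 1 | i > d[k]] <- NA
    i
  })
  out <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  out[is.na(out)] <- fill
  out
}

#' Label connected components of a binary mask
#'
#' @param mask Binary array, 2-D or 3-D.
#' @param connectivity Neighborhood order: 4 or 8 in 2-D (default 8), 6, 18
#'   or 26 in 3-D (default 26). Lesions are compact blobs, so the fullest
#'   neighborhood is the default.
#' @return A list with `labels` (integer array, 0 = background, components
#'   numbered 1..K in order of their smallest linear index) and `components`,
#'   a list of lesion components each holding `id`, `pixels` (linear indices
#'   into the grid), `size` and `bbox` (per-axis min/max matrix).
#' @export
connected_components <- function(mask, connectivity = NULL) {
  d <- dim(mask)
  if (is.null(d)) stop("mask must be an array")
  check_binary(mask)
  if (is.null(connectivity)) connectivity <- if (length(d) == 2) 8 else 26
  offs <- connectivity_offsets(connectivity, length(d))
  fg <- mask > 0
  lab <- array(Inf, d)
  lab[fg] <- which(fg)
  if (any(fg)) {
    repeat {
      new <- lab
      for (r in seq_len(nrow(offs))) {
        new <- pmin(new, shift_array(lab, offs[r, ], Inf))
      }
      new[!fg] <- Inf
      if (identical(new, lab)) break
      lab <- new
    }
  }
  roots <- sort(unique(lab[fg]))
  labels <- array(0L, d)
  labels[fg] <- match(lab[fg], roots)
  components <- lapply(seq_along(roots), function(k) {
    pix <- which(labels == k)
    coords <- arrayInd(pix, d)
    bbox <- rbind(apply(coords, 2, min), apply(coords, 2, max))
    rownames(bbox) <- c("min", "max")
    list(id = k, pixels = pix, size = length(pix), bbox = bbox)
  })
  list(labels = labels, components = components)
}

# Offsets of a cross/star structuring element of the given radius:
# all cells within city-block distance <= radius (includes the origin).
cross_offsets <- function(radius, ndim) {
  grid <- as.matrix(expand.grid(rep(list(-radius:radius), ndim)))
  grid[rowSums(abs(grid)) <= radius, , drop = FALSE]
}

box_offsets <- function(radius, ndim) {
  as.matrix(expand.grid(rep(list(-radius:radius), ndim)))
}

structuring_offsets <- function(shape, radius, ndim) {
  switch(shape,
         cross = cross_offsets(radius, ndim),
         box = box_offsets(radius, ndim),
         stop("unknown structuring element shape: ", shape))
}

binary_dilate <- function(mask, offs) {
  out <- array(FALSE, dim(mask))
  for (r in seq_len(nrow(offs)))
    out <- out | shift_array(mask > 0, offs[r, ], FALSE)
  out
}

binary_erode <- function(mask, offs) {
  out <- array(TRUE, dim(mask))
  for (r in seq_len(nrow(offs)))
    out <- out & shift_array(mask > 0, offs[r, ], FALSE)
  out
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with a cross ("plus"-shaped) or box
#' structuring element. The grid is padded by `radius * iterations` cells
#' before the operation and cropped afterwards, so components touching the
#' image border are not eaten by the erosion step.
#'
#' @param mask Binary array.
#' @param shape `"cross"` (default) or `"box"`.
#' @param radius Structuring element radius (default 1: the 3x3 cross in
#'   2-D).
#' @param iterations Number of dilation passes followed by the same number
#'   of erosion passes.
#' @return Binary (0/1 numeric) array of the same shape; a superset of any
#'   closing-invariant shape and never empty if the input is non-empty.
#' @export
morphological_closing <- function(mask, shape = "cross", radius = 1L,
                                  iterations = 1L) {
  d <- dim(mask)
  if (is.null(d)) stop("mask must be an array")
  if (iterations < 1) return(array(as.numeric(mask > 0), d))
  offs <- structuring_offsets(shape, radius, length(d))
  p <- radius * iterations
  padded <- array(FALSE, d + 2 * p)
  idx <- lapply(d, function(n) p + seq_len(n))
  padded <- do.call(`[<-`, c(list(padded), idx, list(value = mask > 0)))
  for (i in seq_len(iterations)) padded <- binary_dilate(padded, offs)
  for (i in seq_len(iterations)) padded <- binary_erode(padded, offs)
  out <- do.call(`[`, c(list(padded), idx, list(drop = FALSE)))
  array(as.numeric(out), d)
}
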