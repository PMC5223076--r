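# Partial Volume Effect experiment: locate a two-pixel boundary layer
# between fat and muscle in a labeled image, remove those pixels from the
# histogram at their own HU values, and redistribute each to the fat or
# muscle mean HU, whichever is closer.

#' Label an HU image by tissue interval
#'
#' Applies [classify_hu] voxelwise inside the mask; voxels outside the
#' mask (or with HU outside `[-200, 200]`) become `background`.
#'
#' @param hu_image numeric 2D matrix or 3D array of HU values.
#' @param mask binary matrix/array of the same shape; voxels with
#'   `mask > 0` are labeled.
#' @return character array of the same shape with values `fat`,
#'   `connective`, `muscle` or `background`.
#' @export
label_image <- function(hu_image, mask) {
  if (!identical(dim(hu_image), dim(mask)))
    stop("hu_image and mask shapes differ", call. = FALSE)
  labels <- array("background", dim = dim(hu_image))
  sel <- mask > 0 & hu_image >= HU_RANGE[1] & hu_image <= HU_RANGE[2]
  labels[sel] <- as.character(classify_hu(hu_image[sel]))
  labels
}

#' Fat/muscle boundary layer
#'
#' Marks fat- or muscle-labeled pixels lying within Chebyshev
#' (8/26-connectivity) distance `width` of a pixel of the *other* of
#' those two labels. Connective and background pixels are never marked.
#' The default `width = 2` reproduces the two-pixel-wide boundary layer
#' of the reference PVE experiment.
#'
#' @param labels character label array (2D or 3D) as from [label_image].
#' @param width layer half-width in pixels, `>= 1`.
#' @return logical array of the same shape.
#' @export
boundary_mask <- function(labels, width = 2L) {
  if (width < 1) stop("width must be >= 1", call. = FALSE)
  d <- dim(labels)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("labels must be a 2D matrix or 3D array", call. = FALSE)
  near_other <- function(target, other) {
    # does a pixel of label `other` lie within Chebyshev distance `width`?
    is_other <- labels == other
    hit <- array(FALSE, dim = d)
    offsets <- expand.grid(rep(list(seq(-width, width)), length(d)))
    for (r in seq_len(nrow(offsets)))
      hit <- hit | shift_array(is_other, as.integer(offsets[r, ]))
    (labels == target) & hit
  }
  near_other("fat", "muscle") | near_other("muscle", "fat")
}

# Shift a logical array by an integer offset, padding with FALSE. A TRUE
# at position p in the result means the source had TRUE at p - offset.
shift_array <- function(x, offset) {
  d <- dim(x)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", length(d))
  for (k in seq_along(d)) {
    o <- offset[k]
    src[[k]] <- seq_len(d[k] - abs(o)) + max(-o, 0)
    dst[[k]] <- seq_len(d[k] - abs(o)) + max(o, 0)
    if (d[k] <= abs(o)) return(out)
  }
  out[matrix_index(dst, d)] <- x[matrix_index(src, d)]
  out
}

matrix_index <- function(idx, d) {
  if (length(d) == 2L) as.matrix(expand.grid(idx[[1]], idx[[2]]))
  else as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]]))
}

#' Partial-volume correction of an HU histogram
#'
#' Builds the 128-bin histogram of all labeled (non-background) pixels,
#' then moves each boundary-layer pixel's count from the bin of its own
#' HU value to the bin containing the fat mean HU or the muscle mean HU —
#' whichever mean is closer to the pixel's HU value (HU-space proximity;
#' ties go to fat). The means are computed over *non-boundary* fat and
#' muscle pixels. Total count is conserved exactly. Boundary pixels whose
#' HU lies outside `[-200, 200]` were never part of the histogram and are
#' left out (reported, not moved).
#'
#' @param hu_image numeric HU matrix/array.
#' @param labels character label array of the same shape. For the PVE
#'   experiment these are typically geometry ground-truth labels (e.g.
#'   from [generate_phantom]), so that blended intermediate-HU pixels
#'   keep their true fat/muscle identity.
#' @param boundary logical array as from [boundary_mask]; computed from
#'   `labels` with half-width `width` when `NULL`.
#' @param width passed to [boundary_mask] when `boundary` is `NULL`.
#' @return list with `histogram` (corrected `hu_histogram`),
#'   `uncorrected` (`hu_histogram` before correction), and `report`: a
#'   list with `n_boundary`, `n_moved`, `n_to_fat`, `n_to_muscle`,
#'   `n_out_of_range`, `fat_mean_hu`, `muscle_mean_hu`.
#' @export
pve_correct <- function(hu_image, labels, boundary = NULL, width = 2L) {
  if (!identical(dim(hu_image), dim(labels)))
    stop("hu_image and labels shapes differ", call. = FALSE)
  if (is.null(boundary)) boundary <- boundary_mask(labels, width)
  if (!identical(dim(boundary), dim(labels)))
    stop("boundary and labels shapes differ", call. = FALSE)

  fat_core <- labels == "fat" & !boundary
  muscle_core <- labels == "muscle" & !boundary
  if (!any(fat_core) || !any(muscle_core))
    stop("no fat or no muscle pixels remain outside the boundary layer; ",
         "tissue means are undefined", call. = FALSE)
  fat_mean <- mean(hu_image[fat_core])
  muscle_mean <- mean(hu_image[muscle_core])

  in_mask <- labels != "background"
  uncorrected <- build_histogram(hu_image[in_mask])

  bnd_hu <- hu_image[boundary]
  counts <- uncorrected$counts
  n_to_fat <- n_to_muscle <- 0L
  bnd_in_range <- bnd_hu[bnd_hu >= HU_RANGE[1] & bnd_hu <= HU_RANGE[2]]
  if (length(bnd_in_range)) {
    to_fat <- abs(bnd_in_range - fat_mean) <= abs(bnd_in_range - muscle_mean)
    dest_hu <- ifelse(to_fat, fat_mean, muscle_mean)
    rm_idx <- hu_bin_index(bnd_in_range)
    add_idx <- hu_bin_index(dest_hu)
    counts <- counts - tabulate(rm_idx, nbins = N_BINS) +
      tabulate(add_idx, nbins = N_BINS)
    n_to_fat <- sum(to_fat)
    n_to_muscle <- sum(!to_fat)
  }
  corrected <- hu_histogram(counts,
                            n_out_of_range = uncorrected$n_out_of_range)
  list(
    histogram = corrected,
    uncorrected = uncorrected,
    report = list(
      n_boundary = sum(boundary),
      n_moved = length(bnd_in_range),
      n_to_fat = n_to_fat,
      n_to_muscle = n_to_muscle,
      n_out_of_range = sum(boundary) - length(bnd_in_range),
      fat_mean_hu = fat_mean,
      muscle_mean_hu = muscle_mean
    )
  )
}

# 1-based canonical bin index of in-range HU values
hu_bin_index <- function(hu) {
  idx <- floor((hu - HU_RANGE[1]) / BIN_WIDTH)
  idx[idx == N_BINS] <- N_BINS - 1L
  as.integer(idx) + 1L
}

#' Write a PVE correction report as JSON
#'
#' @param pve result of [pve_correct].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_pve_report <- function(pve, path) {
  jsonlite::write_json(pve$report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
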