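# 128-bin HU histogram construction, tissue-interval classification and I/O.

#' CT bin index to HU value
#'
#' The linear transform `HU = CT * 3.125 - 200` that maps CT bin indices
#' 0..128 onto the soft-tissue window. Indices are interpreted as bin
#' *edges*: index 0 is the edge at -200 HU and index 128 the edge at
#' 200 HU, giving 128 uniform bins of width 3.125 HU.
#'
#' @param ct integer bin index (or vector), each in `0..128`.
#' @return HU value(s).
#' @export
#' @examples
#' ct_index_to_hu(0)    # -200
#' ct_index_to_hu(64)   # 0
#' ct_index_to_hu(128)  # 200
ct_index_to_hu <- function(ct) {
  if (any(!is.finite(ct)) || any(ct < 0 | ct > N_BINS) || any(ct != floor(ct)))
    stop("ct must be integer indices in 0..", N_BINS, call. = FALSE)
  ct * BIN_WIDTH + HU_RANGE[1]
}

#' Canonical HU bin edges and centers
#'
#' @return `hu_bin_edges()`: the 129 edges from -200 to 200 in steps of
#'   3.125 HU. `hu_bin_centers()`: the 128 bin midpoints.
#' @export
hu_bin_edges <- function() ct_index_to_hu(0:N_BINS)

#' @rdname hu_bin_edges
#' @export
hu_bin_centers <- function() {
  e <- hu_bin_edges()
  (e[-1] + e[-length(e)]) / 2
}

#' Construct an HU histogram object
#'
#' Low-level constructor; most users call [build_histogram]. Counts are
#' non-negative and may be real-valued (e.g. after partial-volume
#' correction of weighted data).
#'
#' @param counts numeric vector of 128 non-negative bin counts.
#' @param n_out_of_range number of input values discarded for lying
#'   outside `[-200, 200]` HU.
#' @return an object of class `hu_histogram` with fields `bin_edges`
#'   (129 values), `counts` (128 values), `n_total` (sum of counts) and
#'   `n_out_of_range`.
#' @export
hu_histogram <- function(counts, n_out_of_range = 0L) {
  counts <- as.numeric(counts)
  if (length(counts) != N_BINS)
    stop("counts must have length ", N_BINS, call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  structure(list(bin_edges = hu_bin_edges(), counts = counts,
                 n_total = sum(counts),
                 n_out_of_range = as.numeric(n_out_of_range)),
            class = "hu_histogram")
}

#' @export
print.hu_histogram <- function(x, ...) {
  cat(sprintf("HU histogram: %d bins over [%g, %g] HU (width %g), %g counts",
              N_BINS, HU_RANGE[1], HU_RANGE[2], BIN_WIDTH, x$n_total))
  if (x$n_out_of_range > 0)
    cat(sprintf(" (%g values out of range discarded)", x$n_out_of_range))
  cat("\n")
  invisible(x)
}

#' Bin voxel HU values into the canonical 128-bin histogram
#'
#' Bins are half-open `[edge_i, edge_{i+1})` except the last, which is
#' closed at 200 HU. Values outside `[-200, 200]` are discarded (not
#' clipped) and their number recorded in `n_out_of_range`: the window is a
#' soft-tissue window by construction.
#'
#' @param hu_values numeric vector of voxel HU values.
#' @return an `hu_histogram` object; `n_total` equals the number of
#'   retained (in-range) values.
#' @export
build_histogram <- function(hu_values) {
  hu_values <- as.numeric(hu_values)
  if (length(hu_values) == 0)
    stop("empty input: no HU values supplied", call. = FALSE)
  if (any(!is.finite(hu_values)))
    stop("HU values must be finite", call. = FALSE)
  in_range <- hu_values >= HU_RANGE[1] & hu_values <= HU_RANGE[2]
  kept <- hu_values[in_range]
  if (length(kept) == 0)
    stop("all ", length(hu_values), " HU values are out of range [",
         HU_RANGE[1], ", ", HU_RANGE[2], "]", call. = FALSE)
  idx <- floor((kept - HU_RANGE[1]) / BIN_WIDTH)
  idx[idx == N_BINS] <- N_BINS - 1L  # close the last bin at 200 HU
  counts <- tabulate(idx + 1L, nbins = N_BINS)
  hu_histogram(counts, n_out_of_range = sum(!in_range))
}

#' Classify HU values into tissue types
#'
#' Maps each in-window HU value to one of the three tissue intervals:
#' fat `[-200, -10]`, loose connective tissue and atrophic muscle
#' `[-9, 40]`, normal muscle `[41, 200]`. For non-integer values falling
#' between the printed integer bounds, the thresholds are the midpoints
#' -9.5 and 40.5 HU.
#'
#' @param hu HU value(s) in `[-200, 200]`.
#' @return factor with levels `fat`, `connective`, `muscle`.
#' @export
#' @examples
#' classify_hu(c(-80, 0, 55))
classify_hu <- function(hu) {
  if (any(!is.finite(hu)) || any(hu < HU_RANGE[1] | hu > HU_RANGE[2]))
    stop("HU values must lie in [", HU_RANGE[1], ", ", HU_RANGE[2], "]",
         call. = FALSE)
  lab <- ifelse(hu < FAT_CONNECTIVE_SPLIT, "fat",
                ifelse(hu < CONNECTIVE_MUSCLE_SPLIT, "connective", "muscle"))
  factor(lab, levels = TISSUES)
}

#' Per-tissue voxel counts
#'
#' @param hu_values numeric vector of HU values; values outside
#'   `[-200, 200]` are discarded as in [build_histogram].
#' @return named numeric vector `(fat, connective, muscle, out_of_range)`;
#'   the first three sum to the number of in-range values.
#' @export
tissue_counts <- function(hu_values) {
  hu_values <- as.numeric(hu_values)
  if (length(hu_values) == 0)
    stop("empty input: no HU values supplied", call. = FALSE)
  in_range <- hu_values >= HU_RANGE[1] & hu_values <= HU_RANGE[2]
  kept <- hu_values[in_range]
  if (length(kept) == 0)
    stop("all HU values are out of range [", HU_RANGE[1], ", ", HU_RANGE[2],
         "]", call. = FALSE)
  tab <- table(classify_hu(kept))
  c(fat = as.numeric(tab[["fat"]]),
    connective = as.numeric(tab[["connective"]]),
    muscle = as.numeric(tab[["muscle"]]),
    out_of_range = sum(!in_range))
}

#' Tissue interval of each histogram bin
#'
#' Classifies the canonical bin centers; used to slice a histogram into
#' its fat / connective / muscle regions.
#'
#' @return factor of length 128 with levels `fat`, `connective`, `muscle`.
#' @export
bin_tissue <- function() classify_hu(hu_bin_centers())

# ---- file I/O ---------------------------------------------------------------

#' Read a flat list of HU values from CSV/TSV
#'
#' One value per line; an optional single header line is detected (a first
#' token that does not parse as a number) and skipped.
#'
#' @param path file path.
#' @return numeric vector of HU values.
#' @export
read_hu_values <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(
    strsplit(trimws(first), "[,\t;]")[[1]][1])))
  vals <- utils::read.table(path, header = has_header, sep = "",
                            comment.char = "")[[1]]
  # read.table with sep = "" splits on whitespace; retry with comma for CSV
  if (is.character(vals) || is.factor(vals)) {
    vals <- utils::read.csv(path, header = has_header)[[1]]
  }
  as.numeric(vals)
}

#' Read and write pre-binned histogram CSV
#'
#' Format: two columns `bin_center,count` with a header line. On read, the
#' bin centers must match the canonical 128-bin grid within 1e-9 HU.
#'
#' @param path file path.
#' @param hist an `hu_histogram` (for writing).
#' @return `read_histogram_csv`: an `hu_histogram`;
#'   `write_histogram_csv`: `path`, invisibly.
#' @export
read_histogram_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE)
  if (!all(c("bin_center", "count") %in% names(df)))
    stop("histogram CSV must have columns 'bin_center' and 'count'",
         call. = FALSE)
  if (nrow(df) != N_BINS)
    stop("histogram CSV must have ", N_BINS, " rows, found ", nrow(df),
         call. = FALSE)
  if (max(abs(df$bin_center - hu_bin_centers())) > 1e-9)
    stop("bin centers do not match the canonical 128-bin grid over [-200, 200]",
         call. = FALSE)
  hu_histogram(df$count)
}

#' @rdname read_histogram_csv
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "hu_histogram"))
  utils::write.csv(data.frame(bin_center = hu_bin_centers(),
                              count = hist$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a tissue-count summary CSV
#'
#' @param counts named vector as returned by [tissue_counts].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tissue_counts_csv <- function(counts, path) {
  utils::write.csv(as.data.frame(as.list(counts)), path, row.names = FALSE)
  invisible(path)
}

#' Read masked voxel HU values from a NIfTI image
#'
#' @param image_path NIfTI file with HU-valued voxels.
#' @param mask_path NIfTI binary mask of the same dimensions; voxels with
#'   `mask > 0` enter the result.
#' @return numeric vector of HU values inside the mask.
#' @export
read_nifti_hu <- function(image_path, mask_path) {
  for (p in c(image_path, mask_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  img <- RNifti::readNifti(image_path)
  mask <- RNifti::readNifti(mask_path)
  if (!identical(dim(img), dim(mask)))
    stop("image and mask dimensions differ", call. = FALSE)
  as.numeric(img[mask > 0])
}

#' Read and write a plain numeric grid CSV (toy phantom images)
#'
#' A headerless CSV of numbers, one image row per line.
#'
#' @param path file path.
#' @param grid numeric matrix (for writing).
#' @return `read_grid_csv`: a numeric matrix; `write_grid_csv`: `path`,
#'   invisibly.
#' @export
read_grid_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' @rdname read_grid_csv
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.table(grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
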