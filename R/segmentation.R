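# Cell delineation by RI thresholding. The background exclusion rule is the
# acquisition convention for holotomograms of adherent cells: culture medium
# sits near RI 1.33, cytoplasm at 1.34-1.36, so voxels below 1.34 are
# discarded and the remainder is split into connected components.

#' Segmentation parameters
#'
#' @param background_ri_threshold Voxels with RI below this are background.
#'   The comparison is inclusive: RI equal to the threshold is foreground
#'   (the delineation rule excludes values *below* the threshold). Default
#'   1.34.
#' @param min_cell_volume_um3 Components smaller than this are discarded as
#'   debris (µm³). Default 200.
#' @param connectivity 3D adjacency: 6, 18 or 26 (default 26).
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(background_ri_threshold = 1.34,
                                min_cell_volume_um3 = 200,
                                connectivity = 26) {
  if (background_ri_threshold <= 1.0 || background_ri_threshold >= 2.0)
    stop("background_ri_threshold must lie in (1, 2)", call. = FALSE)
  if (min_cell_volume_um3 < 0) stop("min_cell_volume_um3 must be >= 0",
                                    call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  structure(list(background_ri_threshold = background_ri_threshold,
                 min_cell_volume_um3 = min_cell_volume_um3,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Foreground mask from an RI tomogram
#'
#' Pure threshold, no morphology: a voxel is foreground iff its RI is greater
#' than or equal to `background_ri_threshold`.
#'
#' @param tomogram An [ri_tomogram()].
#' @param params A [segmentation_params()].
#' @return A logical 3D array.
#' @export
foreground_mask <- function(tomogram, params = segmentation_params()) {
  stopifnot(inherits(tomogram, "ri_tomogram"),
            inherits(params, "segmentation_params"))
  tomogram$values >= params$background_ri_threshold
}

# internal: label a logical mask, sort components by size desc, renumber 1..K
label_and_rank <- function(mask, connectivity, min_voxels = 1L) {
  d <- dim(mask)
  lab <- cc_label_cpp(as.logical(mask), as.integer(d), as.integer(connectivity))
  if (max(lab) == 0L)
    return(list(labels = array(lab, d), sizes = integer(0)))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  ord <- keep[order(sizes[keep], decreasing = TRUE)]
  remap <- integer(length(sizes))
  remap[ord] <- seq_along(ord)
  out <- array(0L, d)
  nz <- lab != 0L
  out[nz] <- remap[lab[nz]]
  list(labels = out, sizes = sizes[ord])
}

#' Segment cells as connected components of a foreground mask
#'
#' Components below `min_cell_volume_um3` are discarded; surviving components
#' are sorted by descending voxel count and renumbered 1..K. Enclosed
#' background (nuclei and other low-RI inclusions completely surrounded by
#' cell) is filled before statistics so that "cell volume" means whole-cell
#' volume. Touching cells are not split.
#'
#' @param mask Logical 3D array from [foreground_mask()].
#' @param params A [segmentation_params()].
#' @param spacing A [voxel_spacing()].
#' @return A list with `labels` (a [label_volume()]) and `cells` (a data frame
#'   with columns `id`, `voxel_count`, `volume_um3`, `mean_ri` (NA until
#'   computed against a tomogram — see `tomogram` argument), `centroid_z/y/x`
#'   in 0-based voxel coordinates).
#' @param tomogram Optional [ri_tomogram()]; when supplied, per-cell `mean_ri`
#'   is computed over the (hole-filled) cell mask.
#' @export
segment_cells <- function(mask, params = segmentation_params(), spacing,
                          tomogram = NULL) {
  stopifnot(inherits(params, "segmentation_params"),
            inherits(spacing, "voxel_spacing"))
  m <- as_mask_array(mask)
  d <- dim(m)
  vv <- voxel_volume(spacing)
  min_vox <- ceiling(params$min_cell_volume_um3 / vv)

  filled <- array(fill_holes_cpp(as.logical(m), as.integer(d)), d)
  lr <- label_and_rank(filled, params$connectivity, max(1L, min_vox))
  labs <- lr$labels
  k <- length(lr$sizes)

  if (k == 0L) {
    cells <- data.frame(id = integer(0), voxel_count = integer(0),
                        volume_um3 = numeric(0), mean_ri = numeric(0),
                        centroid_z = numeric(0), centroid_y = numeric(0),
                        centroid_x = numeric(0))
    return(list(labels = label_volume(labs, spacing), cells = cells))
  }

  idx <- which(labs > 0L)
  lab_at <- labs[idx]
  co <- arrayInd(idx, d) - 1L  # 0-based (z, y, x)
  cz <- tapply(co[, 1], lab_at, mean)
  cy <- tapply(co[, 2], lab_at, mean)
  cx <- tapply(co[, 3], lab_at, mean)
  mri <- rep(NA_real_, k)
  if (!is.null(tomogram)) {
    stopifnot(inherits(tomogram, "ri_tomogram"),
              identical(dim(tomogram$values), d))
    mri <- as.numeric(tapply(tomogram$values[idx], lab_at, mean))
  }
  cells <- data.frame(id = seq_len(k),
                      voxel_count = as.integer(lr$sizes),
                      volume_um3 = lr$sizes * vv,
                      mean_ri = mri,
                      centroid_z = as.numeric(cz),
                      centroid_y = as.numeric(cy),
                      centroid_x = as.numeric(cx))
  list(labels = label_volume(labs, spacing), cells = cells)
}

#' RI histogram over a mask
#'
#' Half-open bins `[lo + k*w, lo + (k+1)*w)`; counts only voxels inside the
#' mask, so the counts sum to the masked voxel count (voxels outside `range`
#' are dropped and reported via the `n_out_of_range` attribute).
#'
#' @param tomogram An [ri_tomogram()].
#' @param mask Logical 3D array or [label_volume()] (nonzero = inside).
#' @param bin_width Bin width in RI units (> 0).
#' @param range Numeric `c(lo, hi)`, `lo < hi`.
#' @return Data frame with `bin_center` and `voxel_count`.
#' @export
ri_histogram <- function(tomogram, mask, bin_width = 0.002,
                         range = c(1.30, 1.46)) {
  stopifnot(inherits(tomogram, "ri_tomogram"), bin_width > 0,
            length(range) == 2L, range[1] < range[2])
  m <- as_mask_array(mask, dim(tomogram$values))
  v <- tomogram$values[m]
  nb <- ceiling((range[2] - range[1]) / bin_width - 1e-9)
  edges_lo <- range[1] + (seq_len(nb) - 1L) * bin_width
  bin <- floor((v - range[1]) / bin_width) + 1L
  inside <- bin >= 1L & bin <= nb
  counts <- tabulate(bin[inside], nbins = nb)
  out <- data.frame(bin_center = edges_lo + bin_width / 2,
                    voxel_count = counts)
  attr(out, "n_out_of_range") <- sum(!inside)
  out
}

#' Mean RI over a cell mask
#'
#' Arithmetic mean of RI over masked voxels; the per-cell "average RI" of a
#' delineated cell.
#'
#' @param tomogram An [ri_tomogram()].
#' @param mask Logical 3D array or [label_volume()] (nonzero = inside).
#' @return Scalar RI.
#' @export
mean_cell_ri <- function(tomogram, mask) {
  stopifnot(inherits(tomogram, "ri_tomogram"))
  m <- as_mask_array(mask, dim(tomogram$values))
  if (!any(m)) stop("empty mask: mean RI undefined", call. = FALSE)
  mean(tomogram$values[m])
}
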