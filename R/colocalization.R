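# Voxel-level agreement between the fluorescence channel and the high-RI
# mask. The headline figure of merit is the fluorescence-conditional overlap
# fraction (Manders M1 on binary masks): the percentage of
# fluorescence-positive voxels that also belong to the high-RI mask — the
# validation metric for label-free detection.

#' Colocalization parameters
#'
#' @param fluor_threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fluor_threshold_value Intensity threshold, used iff `method =
#'   "fixed"`; voxels strictly above it are positive.
#' @param scope `"within_cells"` (default) restricts analysis to voxels inside
#'   segmented cells; `"whole_volume"` uses every voxel.
#' @return A `coloc_params` object.
#' @export
coloc_params <- function(fluor_threshold_method = c("otsu", "fixed"),
                         fluor_threshold_value = 0,
                         scope = c("within_cells", "whole_volume")) {
  method <- match.arg(fluor_threshold_method)
  scope <- match.arg(scope)
  if (fluor_threshold_value < 0)
    stop("fixed threshold must be >= 0", call. = FALSE)
  structure(list(fluor_threshold_method = method,
                 fluor_threshold_value = fluor_threshold_value,
                 scope = scope),
            class = "coloc_params")
}

#' Otsu threshold
#'
#' Classic between-class variance maximisation on a 256-bin histogram.
#'
#' @param x Numeric vector of intensities.
#' @param n_bins Number of histogram bins (default 256).
#' @return Threshold on the intensity scale (upper edge of the chosen bin);
#'   voxels strictly above it fall in the bright class.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(lo)
  w <- (hi - lo) / n_bins
  bin <- pmin(floor((x - lo) / w) + 1L, n_bins)
  h <- tabulate(bin, nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, Inf)
  k <- which.max(sigma_b)
  lo + k * w
}

#' Binarize a fluorescence volume
#'
#' Threshold computed by Otsu's method on the within-scope *nonzero*
#' intensity histogram (zero voxels carry no signal by construction), or a
#' fixed threshold. A voxel is positive iff its intensity strictly exceeds
#' the threshold.
#'
#' @param volume A [fluorescence_volume()].
#' @param params A [coloc_params()].
#' @param cell_labels Optional [label_volume()]; required when `scope =
#'   "within_cells"` and used to restrict the Otsu histogram.
#' @return Logical 3D array.
#' @export
binarize_fluorescence <- function(volume, params = coloc_params(),
                                  cell_labels = NULL) {
  stopifnot(inherits(volume, "fluorescence_volume"),
            inherits(params, "coloc_params"))
  v <- volume$values
  if (all(v == 0)) {
    warning("all-zero fluorescence volume: empty mask", call. = FALSE)
    return(array(FALSE, dim(v)))
  }
  if (params$fluor_threshold_method == "fixed") {
    thr <- params$fluor_threshold_value
  } else {
    scoped <- v
    if (params$scope == "within_cells" && !is.null(cell_labels)) {
      stopifnot(inherits(cell_labels, "label_volume"))
      scoped <- v[cell_labels$labels > 0L]
    }
    nz <- scoped[scoped > 0]
    if (length(nz) == 0L) {
      warning("no nonzero in-scope intensities: empty mask", call. = FALSE)
      return(array(FALSE, dim(v)))
    }
    thr <- otsu_threshold(nz)
    # degenerate split (all in-scope intensities above the threshold bin):
    # drop just below the smallest positive so every signal voxel is kept
    if (thr >= max(nz)) thr <- min(nz) * (1 - 1e-9) - 1e-300
  }
  v > thr
}

coloc_from_masks <- function(fm, hm, fluor_raw = NULL, ri_raw = NULL) {
  nf <- sum(fm); nh <- sum(hm); ov <- sum(fm & hm)
  r <- NA_real_
  if (!is.null(fluor_raw) && !is.null(ri_raw) &&
      length(fluor_raw) >= 3 && sd(fluor_raw) > 0 && sd(ri_raw) > 0)
    r <- cor(fluor_raw, ri_raw)
  data.frame(fluor_voxels = nf, high_ri_voxels = nh, overlap_voxels = ov,
             fluor_in_high_ri_fraction = if (nf > 0) 100 * ov / nf else NA_real_,
             high_ri_in_fluor_fraction = if (nh > 0) 100 * ov / nh else NA_real_,
             voxel_pearson_r = r)
}

#' Colocalize fluorescence and high-RI masks
#'
#' `fluor_in_high_ri_fraction` is `100 * |fluor ∩ high_ri| / |fluor|`
#' (M1-style, the headline metric); the converse fraction and the voxel-level
#' Pearson correlation of the raw channels (over in-scope voxels) are also
#' reported. An empty fluorescence mask yields a missing fraction, not 0.
#'
#' @param fluor_mask Logical 3D array from [binarize_fluorescence()].
#' @param high_ri_mask Logical 3D array from [high_ri_mask()].
#' @param cell_labels Optional [label_volume()]; with `scope =
#'   "within_cells"` both masks are restricted to cell voxels.
#' @param params A [coloc_params()].
#' @param tomogram,fluor Optional raw volumes; when both are given the voxel
#'   Pearson r is computed on raw intensities vs raw RI over in-scope voxels.
#' @return One-row data frame (`coloc_result`): voxel counts, both overlap
#'   fractions (%), `voxel_pearson_r`.
#' @export
colocalize <- function(fluor_mask, high_ri_mask, cell_labels = NULL,
                       params = coloc_params(), tomogram = NULL, fluor = NULL) {
  fm <- as_mask_array(fluor_mask)
  hm <- as_mask_array(high_ri_mask, dim(fm))
  scope <- array(TRUE, dim(fm))
  if (params$scope == "within_cells" && !is.null(cell_labels)) {
    stopifnot(inherits(cell_labels, "label_volume"))
    scope <- cell_labels$labels > 0L
  }
  fr <- rr <- NULL
  if (!is.null(tomogram) && !is.null(fluor)) {
    fr <- fluor$values[scope]; rr <- tomogram$values[scope]
  }
  res <- coloc_from_masks(fm & scope, hm & scope, fr, rr)
  class(res) <- c("coloc_result", class(res))
  res
}

#' Per-cell colocalization
#'
#' [colocalize()] restricted to each cell's voxels. Cells with no
#' fluorescence-positive voxels report a missing fraction and are excluded
#' from the summary mean/SD rather than dragged in as zeros.
#'
#' @inheritParams colocalize
#' @param cell_labels A [label_volume()] of segmented cells (required).
#' @return A list with `per_cell` (one row per cell, `cell_id` first) and
#'   `summary` (mean, SD and n of the nonmissing fluorescence-conditional
#'   fractions, plus the pooled whole-set fraction).
#' @export
coloc_per_cell <- function(fluor_mask, high_ri_mask, cell_labels,
                           tomogram = NULL, fluor = NULL) {
  stopifnot(inherits(cell_labels, "label_volume"))
  fm <- as_mask_array(fluor_mask)
  hm <- as_mask_array(high_ri_mask, dim(fm))
  labs <- cell_labels$labels
  k <- max(labs)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    inside <- labs == i
    fr <- rr <- NULL
    if (!is.null(tomogram) && !is.null(fluor)) {
      fr <- fluor$values[inside]; rr <- tomogram$values[inside]
    }
    rows[[i]] <- cbind(cell_id = i,
                       coloc_from_masks(fm & inside, hm & inside, fr, rr))
  }
  per_cell <- do.call(rbind, rows)
  fracs <- per_cell$fluor_in_high_ri_fraction
  ok <- !is.na(fracs)
  pooled_f <- sum(fm & labs > 0L)
  pooled_ov <- sum(fm & hm & labs > 0L)
  summary <- data.frame(
    mean_fraction = if (any(ok)) mean(fracs[ok]) else NA_real_,
    sd_fraction = if (sum(ok) > 1) sd(fracs[ok]) else NA_real_,
    n_cells = sum(ok),
    pooled_fraction = if (pooled_f > 0) 100 * pooled_ov / pooled_f else NA_real_)
  list(per_cell = per_cell, summary = summary)
}
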