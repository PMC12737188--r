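# High-RI aggregate detection and per-cell uptake metrics. Aggregates are
# connected clusters of voxels whose RI strictly exceeds the high-RI
# threshold (1.36 by default) — the label-free signature of nanoparticle
# accumulations confined in endo/lysosomal compartments. Lipid droplets
# (RI 1.37-1.49) satisfy the same criterion and are the documented
# false-positive class.

#' Aggregate detection parameters
#'
#' @param high_ri_threshold Voxels are aggregate candidates iff RI strictly
#'   exceeds this value (the detection rule counts voxels *exceeding* the
#'   threshold, so equality is excluded). Must exceed the background
#'   threshold. Default 1.36.
#' @param min_aggregate_voxels Components with fewer voxels are dropped;
#'   default 2 (suppresses single-voxel noise). Set to 1 to reproduce raw
#'   voxel counts.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param restrict_to_cells If `TRUE` (default), components whose centroid
#'   falls outside every cell get `cell_id = 0` and are excluded from
#'   per-cell statistics (they are still reported).
#' @return An `aggregate_params` object.
#' @export
aggregate_params <- function(high_ri_threshold = 1.36,
                             min_aggregate_voxels = 2L,
                             connectivity = 26,
                             restrict_to_cells = TRUE) {
  if (high_ri_threshold <= 1.0 || high_ri_threshold >= 2.0)
    stop("high_ri_threshold must lie in (1, 2)", call. = FALSE)
  if (min_aggregate_voxels < 1L)
    stop("min_aggregate_voxels must be >= 1", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  structure(list(high_ri_threshold = high_ri_threshold,
                 min_aggregate_voxels = as.integer(min_aggregate_voxels),
                 connectivity = as.integer(connectivity),
                 restrict_to_cells = isTRUE(restrict_to_cells)),
            class = "aggregate_params")
}

#' High-RI mask
#'
#' Strict threshold: voxel included iff `RI > high_ri_threshold`.
#'
#' @param tomogram An [ri_tomogram()].
#' @param params An [aggregate_params()].
#' @return Logical 3D array.
#' @export
high_ri_mask <- function(tomogram, params = aggregate_params()) {
  stopifnot(inherits(tomogram, "ri_tomogram"),
            inherits(params, "aggregate_params"))
  tomogram$values > params$high_ri_threshold
}

#' Detect high-RI aggregates
#'
#' Connected components of the high-RI mask; components smaller than
#' `min_aggregate_voxels` are dropped; each component is assigned to the cell
#' containing its centroid (`cell_id = 0` if none — an aggregate touching two
#' cells is not split).
#'
#' @param tomogram An [ri_tomogram()].
#' @param cell_labels A [label_volume()] of segmented cells (or `NULL` for
#'   whole-volume detection with all `cell_id = 0`).
#' @param params An [aggregate_params()].
#' @param spacing A [voxel_spacing()].
#' @return A list with `labels` (a [label_volume()] of aggregates) and
#'   `aggregates` (data frame: `id`, `cell_id`, `voxel_count`, `volume_um3`,
#'   `mean_ri`, `max_ri`, `centroid_z/y/x` 0-based).
#' @export
detect_aggregates <- function(tomogram, cell_labels = NULL,
                              params = aggregate_params(), spacing) {
  stopifnot(inherits(tomogram, "ri_tomogram"),
            inherits(params, "aggregate_params"),
            inherits(spacing, "voxel_spacing"))
  d <- dim(tomogram$values)
  if (!is.null(cell_labels)) {
    stopifnot(inherits(cell_labels, "label_volume"),
              identical(dim(cell_labels$labels), d))
  }
  vv <- voxel_volume(spacing)
  m <- high_ri_mask(tomogram, params)
  lr <- label_and_rank(m, params$connectivity, params$min_aggregate_voxels)
  labs <- lr$labels
  k <- length(lr$sizes)

  empty <- data.frame(id = integer(0), cell_id = integer(0),
                      voxel_count = integer(0), volume_um3 = numeric(0),
                      mean_ri = numeric(0), max_ri = numeric(0),
                      centroid_z = numeric(0), centroid_y = numeric(0),
                      centroid_x = numeric(0))
  if (k == 0L)
    return(list(labels = label_volume(labs, spacing), aggregates = empty))

  idx <- which(labs > 0L)
  lab_at <- labs[idx]
  co <- arrayInd(idx, d) - 1L
  cz <- as.numeric(tapply(co[, 1], lab_at, mean))
  cy <- as.numeric(tapply(co[, 2], lab_at, mean))
  cx <- as.numeric(tapply(co[, 3], lab_at, mean))
  ri <- tomogram$values[idx]
  mean_ri <- as.numeric(tapply(ri, lab_at, mean))
  max_ri <- as.numeric(tapply(ri, lab_at, max))

  cell_id <- integer(k)
  if (!is.null(cell_labels)) {
    # centroid containment: nearest voxel to the (0-based) centroid
    zi <- pmin(pmax(round(cz) + 1L, 1L), d[1])
    yi <- pmin(pmax(round(cy) + 1L, 1L), d[2])
    xi <- pmin(pmax(round(cx) + 1L, 1L), d[3])
    cell_id <- cell_labels$labels[cbind(zi, yi, xi)]
  }

  agg <- data.frame(id = seq_len(k),
                    cell_id = as.integer(cell_id),
                    voxel_count = as.integer(lr$sizes),
                    volume_um3 = lr$sizes * vv,
                    mean_ri = mean_ri, max_ri = max_ri,
                    centroid_z = cz, centroid_y = cy, centroid_x = cx)
  list(labels = label_volume(labs, spacing), aggregates = agg)
}

#' Per-cell uptake statistics
#'
#' Joins detected aggregates to segmented cells: aggregate count, total
#' nanoparticle volume, volume fraction (%), mean aggregate volume. Cells
#' without aggregates report count 0, fraction 0 and `NA` mean aggregate
#' volume. Aggregates with `cell_id = 0` (outside every cell) are ignored
#' here.
#'
#' @param cells Cell table from [segment_cells()].
#' @param aggregates Aggregate table from [detect_aggregates()].
#' @param spacing A [voxel_spacing()] (kept for interface symmetry; volumes
#'   are already in µm³).
#' @return Data frame: `cell_id`, `cell_volume_um3`, `mean_cell_ri`,
#'   `aggregate_count`, `total_np_volume_um3`, `np_volume_fraction` (percent),
#'   `mean_aggregate_volume_um3`.
#' @export
compute_cell_stats <- function(cells, aggregates, spacing = NULL) {
  stopifnot(is.data.frame(cells), is.data.frame(aggregates))
  inside <- aggregates[aggregates$cell_id > 0L, , drop = FALSE]
  if (nrow(inside) > 0 && !all(inside$cell_id %in% cells$id))
    stop("aggregate references unknown cell id", call. = FALSE)
  n <- nrow(cells)
  cnt <- integer(n); tot <- numeric(n)
  if (nrow(inside) > 0) {
    tc <- table(factor(inside$cell_id, levels = cells$id))
    cnt <- as.integer(tc)
    tv <- tapply(inside$volume_um3, factor(inside$cell_id, levels = cells$id),
                 sum)
    tot <- ifelse(is.na(tv), 0, as.numeric(tv))
  }
  data.frame(cell_id = cells$id,
             cell_volume_um3 = cells$volume_um3,
             mean_cell_ri = cells$mean_ri,
             aggregate_count = cnt,
             total_np_volume_um3 = tot,
             np_volume_fraction = 100 * tot / cells$volume_um3,
             mean_aggregate_volume_um3 = ifelse(cnt > 0, tot / cnt, NA_real_))
}

#' Aggregate size distribution
#'
#' Histogram and cumulative frequency of aggregate volumes, plus the fraction
#' below a size cutoff (endosomal confinement is the usual reading of a
#' sub-µm³ majority).
#'
#' @param aggregates Aggregate table (needs a `volume_um3` column) or a
#'   numeric vector of volumes.
#' @param cutoff_um3 Size cutoff in µm³ (default 1).
#' @param bin_width_um3 Histogram bin width (default 0.25).
#' @return A list with `histogram` (bin_center, count), `cumulative`
#'   (volume_um3, cum_percent — monotone, ending at 100) and
#'   `fraction_below_cutoff` in percent.
#' @export
aggregate_size_distribution <- function(aggregates, cutoff_um3 = 1,
                                        bin_width_um3 = 0.25) {
  v <- if (is.data.frame(aggregates)) aggregates$volume_um3 else aggregates
  v <- as.numeric(v)
  if (length(v) == 0L) stop("no aggregates: size distribution undefined",
                            call. = FALSE)
  stopifnot(all(is.finite(v)), all(v >= 0), cutoff_um3 > 0, bin_width_um3 > 0)
  nb <- max(1L, ceiling(max(v) / bin_width_um3))
  bin <- pmin(pmax(floor(v / bin_width_um3) + 1L, 1L), nb)
  hist <- data.frame(bin_center = (seq_len(nb) - 0.5) * bin_width_um3,
                     count = tabulate(bin, nbins = nb))
  sv <- sort(v)
  cum <- data.frame(volume_um3 = sv,
                    cum_percent = 100 * seq_along(sv) / length(sv))
  list(histogram = hist,
       cumulative = cum,
       fraction_below_cutoff = 100 * mean(v < cutoff_um3))
}
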