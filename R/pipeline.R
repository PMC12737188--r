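# End-to-end orchestration: volumes in, summary report and intermediate
# tables out, with provenance. The report is a deterministic function of
# inputs + config; all stochastic steps take seeds from the config.

#' Pipeline run configuration
#'
#' @param ri_path Path to the RI tomogram TIFF (required).
#' @param fluor_path Optional path to the co-registered fluorescence TIFF.
#' @param cells_path Optional path to a precomputed cell label TIFF; when
#'   absent, cells are segmented from the tomogram.
#' @param spacing Optional [voxel_spacing()]; defaults to the sidecar of
#'   `ri_path`.
#' @param segmentation A [segmentation_params()].
#' @param aggregates An [aggregate_params()].
#' @param coloc A [coloc_params()].
#' @param alpha Significance level (default 0.05).
#' @param out_dir Output directory (created if missing); `NULL` for
#'   in-memory results only.
#' @param seed Seed for any stochastic step (default 1; the core pipeline is
#'   deterministic).
#' @return A `run_config` object.
#' @export
run_config <- function(ri_path, fluor_path = NULL, cells_path = NULL,
                       spacing = NULL,
                       segmentation = segmentation_params(),
                       aggregates = aggregate_params(),
                       coloc = coloc_params(),
                       alpha = 0.05, out_dir = NULL, seed = 1L) {
  stopifnot(inherits(segmentation, "segmentation_params"),
            inherits(aggregates, "aggregate_params"),
            inherits(coloc, "coloc_params"))
  if (aggregates$high_ri_threshold <= segmentation$background_ri_threshold)
    stop("inconsistent thresholds: high-RI must exceed background",
         call. = FALSE)
  for (p in c(ri_path, fluor_path, cells_path))
    if (!is.null(p) && !file.exists(p))
      stop("input file not found: ", p, call. = FALSE)
  structure(list(ri_path = ri_path, fluor_path = fluor_path,
                 cells_path = cells_path, spacing = spacing,
                 segmentation = segmentation, aggregates = aggregates,
                 coloc = coloc, alpha = alpha, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

pipeline_log <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

report_to_list <- function(report) {
  # jsonlite-friendly plain list
  unclass_rec <- function(x) {
    if (is.list(x)) lapply(x, unclass_rec) else x
  }
  unclass_rec(unclass(report))
}

#' Run the full uptake-quantification pipeline
#'
#' foreground mask -> cell segmentation -> high-RI mask -> aggregate
#' detection -> (optional) fluorescence binarization + colocalization ->
#' summary report. When `out_dir` is set, every intermediate artifact is
#' written (cell labels, tables, report JSON, resolved provenance); tabular
#' outputs are byte-identical across reruns on identical inputs. Without a
#' fluorescence input the colocalization fields are reported missing, never
#' zero.
#'
#' @param config A [run_config()].
#' @return A list: `report` ([build_report()] output), `cells`, `cell_stats`,
#'   `aggregates`, `coloc` (or `NULL`), `labels` (cell and aggregate
#'   [label_volume()]s), `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "read"
  res <- tryCatch({
    pipeline_log(stage, paste("reading", config$ri_path))
    tomo <- read_volume(config$ri_path, config$spacing, "ri")
    spacing <- tomo$spacing
    fluor <- NULL
    if (!is.null(config$fluor_path)) {
      fluor <- read_volume(config$fluor_path, spacing, "fluorescence")
      if (!identical(dim(fluor$values), dim(tomo$values)))
        stop("fluorescence volume shape differs from tomogram", call. = FALSE)
    }

    stage <- "segment_cells"
    if (!is.null(config$cells_path)) {
      cell_labels <- read_volume(config$cells_path, spacing, "labels")
      seg <- list(labels = cell_labels,
                  cells = cells_from_labels(cell_labels, tomo))
    } else {
      fg <- foreground_mask(tomo, config$segmentation)
      seg <- segment_cells(fg, config$segmentation, spacing, tomogram = tomo)
    }
    pipeline_log(stage, sprintf("%d cell(s)", nrow(seg$cells)))

    stage <- "detect_aggregates"
    det <- detect_aggregates(tomo, seg$labels, config$aggregates, spacing)
    pipeline_log(stage, sprintf("%d aggregate(s)", nrow(det$aggregates)))

    stage <- "cell_stats"
    cstats <- compute_cell_stats(seg$cells, det$aggregates, spacing)

    stage <- "colocalize"
    coloc_tab <- NULL
    if (!is.null(fluor)) {
      fmask <- binarize_fluorescence(fluor, config$coloc, seg$labels)
      hmask <- high_ri_mask(tomo, config$aggregates)
      coloc_tab <- coloc_per_cell(fmask, hmask, seg$labels,
                                  tomogram = tomo, fluor = fluor)
      pipeline_log(stage, sprintf("pooled fraction %.1f%%",
                                  coloc_tab$summary$pooled_fraction))
    } else {
      pipeline_log(stage, "no fluorescence input: colocalization missing")
    }

    stage <- "report"
    report <- build_report(cstats, det$aggregates,
                           if (!is.null(coloc_tab)) coloc_tab$per_cell else NULL,
                           alpha = config$alpha)

    prov <- list(
      tool = "holoquant",
      version = as.character(packageVersion("holoquant")),
      inputs = Filter(Negate(is.null), list(
        ri = list(path = config$ri_path,
                  sha256 = digest::digest(file = config$ri_path,
                                          algo = "sha256")),
        fluor = if (!is.null(config$fluor_path))
          list(path = config$fluor_path,
               sha256 = digest::digest(file = config$fluor_path,
                                       algo = "sha256")),
        cells = if (!is.null(config$cells_path))
          list(path = config$cells_path,
               sha256 = digest::digest(file = config$cells_path,
                                       algo = "sha256")))),
      params = list(segmentation = unclass(config$segmentation),
                    aggregates = unclass(config$aggregates),
                    coloc = unclass(config$coloc),
                    alpha = config$alpha, seed = config$seed),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

    out <- list(report = report, cells = seg$cells, cell_stats = cstats,
                aggregates = det$aggregates, coloc = coloc_tab,
                labels = list(cells = seg$labels, aggregates = det$labels),
                provenance = prov)

    if (!is.null(config$out_dir)) {
      stage <- "write"
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      op <- function(f) file.path(config$out_dir, f)
      write_volume(seg$labels, op("cells.tif"))
      write_volume(det$labels, op("aggregates.tif"))
      write_table(seg$cells, op("cells.csv"))
      write_table(det$aggregates, op("aggregates.csv"))
      write_table(cstats, op("cellstats.csv"))
      if (!is.null(coloc_tab)) {
        write_table(coloc_tab$per_cell, op("coloc.csv"))
        write_table(coloc_tab$summary, op("coloc_summary.csv"))
      }
      jsonlite::write_json(report_to_list(report), op("report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null")
      jsonlite::write_json(prov, op("provenance.json"), auto_unbox = TRUE,
                           pretty = TRUE)
      pipeline_log(stage, paste("artifacts in", config$out_dir))
    }
    out
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  res
}

# build a cell table from a precomputed label volume
cells_from_labels <- function(cell_labels, tomogram) {
  labs <- cell_labels$labels
  vv <- voxel_volume(cell_labels$spacing)
  k <- max(labs)
  if (k == 0L)
    return(data.frame(id = integer(0), voxel_count = integer(0),
                      volume_um3 = numeric(0), mean_ri = numeric(0),
                      centroid_z = numeric(0), centroid_y = numeric(0),
                      centroid_x = numeric(0)))
  idx <- which(labs > 0L)
  lab_at <- labs[idx]
  co <- arrayInd(idx, dim(labs)) - 1L
  sizes <- tabulate(lab_at, k)
  data.frame(id = seq_len(k), voxel_count = sizes, volume_um3 = sizes * vv,
             mean_ri = as.numeric(tapply(tomogram$values[idx], lab_at, mean)),
             centroid_z = as.numeric(tapply(co[, 1], lab_at, mean)),
             centroid_y = as.numeric(tapply(co[, 2], lab_at, mean)),
             centroid_x = as.numeric(tapply(co[, 3], lab_at, mean)))
}

#' Simulate scenes and validate recovery end-to-end
#'
#' For each seed: generate a scene, run the analysis stages in memory, match
#' detected aggregates to ground truth by maximal voxel overlap, and emit
#' per-seed recovery metrics. This is the package's own closed-loop check
#' that the thresholding rules recover the generator's stated world.
#'
#' @param config A [scene_config()]; its `seed` field is replaced by each
#'   element of `seeds`.
#' @param seeds Integer vector of scene seeds.
#' @param segmentation,aggregates,coloc Stage parameter objects.
#' @return A data frame with one row per seed: true/detected cell and
#'   aggregate counts, mean detected aggregate volume, per-cell count mean,
#'   matched-aggregate fraction, pooled colocalization fraction, and the
#'   pooled cell-volume vs NP-volume correlation across all seeds is
#'   attached as attribute `pooled_uptake_r` (with `pooled_cells`).
#' @export
simulate_and_validate <- function(config = scene_config(),
                                  seeds = 1:5,
                                  segmentation = segmentation_params(),
                                  aggregates = aggregate_params(),
                                  coloc = coloc_params()) {
  rows <- vector("list", length(seeds))
  all_cells <- list()
  for (k in seq_along(seeds)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[k])
    sc <- generate_scene(cfg)
    fg <- foreground_mask(sc$ri, segmentation)
    seg <- segment_cells(fg, segmentation, sc$ri$spacing, tomogram = sc$ri)
    det <- detect_aggregates(sc$ri, seg$labels, aggregates, sc$ri$spacing)
    cstats <- compute_cell_stats(seg$cells, det$aggregates, sc$ri$spacing)

    # match detected aggregates to truth by maximal voxel overlap
    both <- det$labels$labels > 0L & sc$truth$aggregate_labels$labels > 0L
    matched <- 0L
    if (any(both)) {
      pairs <- table(det = det$labels$labels[both],
                     tru = sc$truth$aggregate_labels$labels[both])
      # a true aggregate is recovered if some detected component overlaps it
      matched <- sum(colSums(pairs > 0) > 0)
    }

    pooled <- NA_real_
    if (!is.null(sc$fluor) && any(sc$fluor$values > 0)) {
      fmask <- binarize_fluorescence(sc$fluor, coloc, seg$labels)
      hmask <- high_ri_mask(sc$ri, aggregates)
      cp <- coloc_per_cell(fmask, hmask, seg$labels)
      pooled <- cp$summary$pooled_fraction
    }

    rows[[k]] <- data.frame(
      seed = seeds[k],
      true_cells = nrow(sc$truth$per_cell),
      detected_cells = nrow(seg$cells),
      true_aggregates = nrow(sc$truth$per_aggregate),
      detected_aggregates = sum(det$aggregates$cell_id > 0),
      matched_aggregate_fraction = if (nrow(sc$truth$per_aggregate) > 0)
        matched / nrow(sc$truth$per_aggregate) else NA_real_,
      mean_detected_volume_um3 =
        mean(det$aggregates$volume_um3[det$aggregates$cell_id > 0]),
      mean_count_per_cell = mean(cstats$aggregate_count),
      mean_np_fraction_pct = mean(cstats$np_volume_fraction),
      pooled_coloc_pct = pooled)
    all_cells[[k]] <- cstats
  }
  out <- do.call(rbind, rows)
  pooled_cells <- do.call(rbind, all_cells)
  r <- NA_real_
  if (nrow(pooled_cells) >= 3 && sd(pooled_cells$cell_volume_um3) > 0 &&
      sd(pooled_cells$total_np_volume_um3) > 0)
    r <- cor(pooled_cells$cell_volume_um3, pooled_cells$total_np_volume_um3)
  attr(out, "pooled_uptake_r") <- r
  attr(out, "pooled_cells") <- pooled_cells
  out
}
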