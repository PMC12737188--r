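# Synthetic holotomography scenes with exact ground truth.
#
# The generator renders the world the downstream analysis assumes: ellipsoidal
# cells with cytoplasmic RI just above the 1.34 background cut, spherical
# high-RI nanoparticle aggregates (lognormal volumes) carrying fluorescence,
# fluorescence-free lipid-droplet confounders in the same RI band, a tunable
# positive association between cell volume and nanoparticle load, and additive
# Gaussian RI noise applied last. With noise off, the 1.34/1.36 thresholds
# recover the ground truth exactly (up to one voxel boundary shell per
# object), which is what makes every downstream stage testable without real
# acquisitions.

#' Synthetic scene configuration
#'
#' Defaults encode the measurement context the analysis targets: background
#' medium RI 1.330 (< 1.34), cytoplasm 1.340-1.358 (below the 1.36 aggregate
#' cut), aggregates 1.370-1.420 (> 1.36), lipid droplets 1.370-1.490,
#' aggregate counts ~ rounded N(50, 45) floored at 0, aggregate volumes
#' lognormal with natural-log parameters (-0.90, 0.78) (arithmetic mean 0.55,
#' SD 0.50 µm³), 12 cells per field (230 cells over 20 fields of view
#' corresponds to ~11.5 per field), and a cell-volume/NP-load association of
#' 0.35.
#'
#' @param shape Grid dim `(nz, ny, nx)`; default `c(64, 192, 192)` — a
#'   32 µm x 38.4 µm x 38.4 µm field at the default spacing, comfortably
#'   holding 12 adherent cells.
#' @param spacing A [voxel_spacing()]; default 0.5 µm axial, 0.2 µm lateral.
#' @param n_cells Number of cells (>= 0); default 12.
#' @param cell_radius_mean_um,cell_radius_sd_um Per-axis (z, y, x) mean and SD
#'   of ellipsoid semi-axes in µm; defaults `c(2.5, 6, 6)` and
#'   `c(0.3, 0.8, 0.8)` give ~380 µm³ adherent-cell-shaped cells.
#' @param ri_background Background/medium RI (default 1.330, must be < 1.34).
#' @param ri_cytoplasm Cytoplasm RI interval (default `c(1.340, 1.358)`).
#' @param ri_aggregate Aggregate RI interval (default `c(1.370, 1.420)`,
#'   lower bound must exceed 1.36).
#' @param ri_droplet Lipid-droplet RI interval (default `c(1.370, 1.490)`).
#' @param aggregates_per_cell `c(mean, sd)` of the Gaussian count draw,
#'   rounded and floored at 0 (default `c(50, 45)`).
#' @param aggregate_volume_lognormal `c(mu_ln, sigma_ln)` natural-log
#'   parameters of aggregate volume in µm³ (default `c(-0.90, 0.78)`).
#' @param droplets_per_cell Poisson mean of droplets per cell (default 2).
#' @param uptake_association Target correlation in (-1, 1) between cell
#'   volume and total NP volume (default 0.35).
#' @param fluorophore_fraction Probability that an aggregate carries
#'   fluorescence (default 1).
#' @param sub_threshold_fluor_fraction Fraction of total fluorescent NP
#'   volume placed as dispersed sub-threshold-RI voxels (default 0; 0.08
#'   emulates the ~92% fluorescence-in-high-RI overlap of real scenes).
#' @param noise_sd_ri SD of additive Gaussian RI noise (default 0.002).
#' @param seed Integer RNG seed (default 1).
#' @return A `scene_config` object.
#' @export
scene_config <- function(shape = c(64L, 192L, 192L),
                         spacing = voxel_spacing(0.5, 0.2, 0.2),
                         n_cells = 12L,
                         cell_radius_mean_um = c(2.5, 6, 6),
                         cell_radius_sd_um = c(0.3, 0.8, 0.8),
                         ri_background = 1.330,
                         ri_cytoplasm = c(1.340, 1.358),
                         ri_aggregate = c(1.370, 1.420),
                         ri_droplet = c(1.370, 1.490),
                         aggregates_per_cell = c(50, 45),
                         aggregate_volume_lognormal = c(-0.90, 0.78),
                         droplets_per_cell = 2,
                         uptake_association = 0.35,
                         fluorophore_fraction = 1.0,
                         sub_threshold_fluor_fraction = 0.0,
                         noise_sd_ri = 0.002,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L),
            inherits(spacing, "voxel_spacing"),
            n_cells >= 0,
            length(cell_radius_mean_um) == 3L, all(cell_radius_mean_um > 0),
            length(cell_radius_sd_um) == 3L, all(cell_radius_sd_um >= 0),
            length(ri_cytoplasm) == 2L, length(ri_aggregate) == 2L,
            length(ri_droplet) == 2L,
            length(aggregates_per_cell) == 2L, aggregates_per_cell[2] >= 0,
            length(aggregate_volume_lognormal) == 2L,
            aggregate_volume_lognormal[2] > 0,
            droplets_per_cell >= 0,
            abs(uptake_association) < 1,
            fluorophore_fraction >= 0, fluorophore_fraction <= 1,
            sub_threshold_fluor_fraction >= 0, sub_threshold_fluor_fraction < 1,
            noise_sd_ri >= 0)
  if (!(ri_background < 1.34 && 1.34 <= ri_cytoplasm[1]))
    stop("require ri_background < 1.34 <= ri_cytoplasm low", call. = FALSE)
  if (ri_cytoplasm[1] > ri_cytoplasm[2] || ri_cytoplasm[2] >= 1.36)
    stop("cytoplasm interval must be ordered and stay below 1.36",
         call. = FALSE)
  if (ri_aggregate[1] <= 1.36 || ri_aggregate[1] > ri_aggregate[2])
    stop("aggregate RI interval must be ordered with low bound > 1.36",
         call. = FALSE)
  if (ri_droplet[1] <= 1.36 || ri_droplet[1] > ri_droplet[2])
    stop("droplet RI interval must be ordered with low bound > 1.36",
         call. = FALSE)

  cfg <- list(shape = shape, spacing = spacing, n_cells = as.integer(n_cells),
              cell_radius_mean_um = cell_radius_mean_um,
              cell_radius_sd_um = cell_radius_sd_um,
              ri_background = ri_background, ri_cytoplasm = ri_cytoplasm,
              ri_aggregate = ri_aggregate, ri_droplet = ri_droplet,
              aggregates_per_cell = aggregates_per_cell,
              aggregate_volume_lognormal = aggregate_volume_lognormal,
              droplets_per_cell = droplets_per_cell,
              uptake_association = uptake_association,
              fluorophore_fraction = fluorophore_fraction,
              sub_threshold_fluor_fraction = sub_threshold_fluor_fraction,
              noise_sd_ri = noise_sd_ri, seed = as.integer(seed))

  grid_um3 <- prod(shape) * voxel_volume(spacing)
  exp_cell <- 4 / 3 * pi * prod(cell_radius_mean_um)
  if (n_cells * exp_cell > 0.6 * grid_um3)
    stop(sprintf(
      "infeasible config: expected cell volume %.0f um^3 exceeds 60%% of the %.0f um^3 grid",
      n_cells * exp_cell, grid_um3), call. = FALSE)
  structure(cfg, class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("<scene_config> %d x %d x %d, %d cell(s), seed %d\n",
              x$shape[1], x$shape[2], x$shape[3], x$n_cells, x$seed))
  invisible(x)
}

# ---- geometry helpers (voxel centers at (i - 0.5) * d) ---------------------

ellipsoid_indices <- function(dims, steps, center, radii) {
  lo <- pmax(1L, as.integer(ceiling((center - radii) / steps + 0.5 - 1e-9)))
  hi <- pmin(dims, as.integer(floor((center + radii) / steps + 0.5 + 1e-9)))
  if (any(lo > hi)) return(integer(0))
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  uz <- ((zi - 0.5) * steps[1] - center[1]) / radii[1]
  uy <- ((yi - 0.5) * steps[2] - center[2]) / radii[2]
  ux <- ((xi - 0.5) * steps[3] - center[3]) / radii[3]
  keep <- which(outer(outer(uz^2, uy^2, "+"), ux^2, "+") <= 1)
  if (length(keep) == 0L) return(integer(0))
  a <- arrayInd(keep, c(length(zi), length(yi), length(xi)))
  zi[a[, 1]] + dims[1] * ((yi[a[, 2]] - 1L) + dims[2] * (xi[a[, 3]] - 1L))
}

voxel_of <- function(dims, steps, point) {
  i <- pmin(pmax(as.integer(floor(point / steps)) + 1L, 1L), dims)
  i[1] + dims[1] * ((i[2] - 1L) + dims[2] * (i[3] - 1L))
}

# 26-neighborhood dilation of a set of linear indices (within bounds)
dilate26 <- function(idx, dims) {
  if (length(idx) == 0L) return(idx)
  co <- arrayInd(idx, dims)
  out <- vector("list", 27L)
  k <- 0L
  for (a in -1:1) for (b in -1:1) for (cc in -1:1) {
    k <- k + 1L
    z <- co[, 1] + a; y <- co[, 2] + b; x <- co[, 3] + cc
    ok <- z >= 1L & z <= dims[1] & y >= 1L & y <= dims[2] &
      x >= 1L & x <= dims[3]
    out[[k]] <- z[ok] + dims[1] * ((y[ok] - 1L) + dims[2] * (x[ok] - 1L))
  }
  unique(unlist(out))
}

runif_in_unit_ball <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2)) * runif(1)^(1 / 3)
}

#' Per-cell nanoparticle load multipliers with a target volume association
#'
#' Gaussian-copula mixture: the latent load score of cell *i* is
#' `target_r * z_i + sqrt(1 - target_r^2) * e_i`, where `z_i` is the normal
#' score of the cell-volume rank and `e_i` is independent noise. The latent
#' score is mapped onto the count marginal `N(mean_count, sd_count)` (floored
#' at 0), so the count dispersion itself plays the role of the independent
#' component; in expectation over scenes the realized correlation between
#' cell volume and total NP volume approaches `target_r` (attenuated a few
#' percent by count discreteness, the floor at 0, and per-aggregate volume
#' noise).
#'
#' @param cell_volumes Numeric vector of cell volumes (>= 3 cells).
#' @param target_r Target correlation, `|target_r| < 1`.
#' @param mean_count,sd_count Count marginal parameters (defaults 50, 45).
#' @param seed Optional seed; `NULL` (default) draws from the current RNG
#'   stream.
#' @return Numeric vector of nonnegative multipliers `m` with
#'   `round(mean_count * m)` the per-cell aggregate count.
#' @export
induce_uptake_association <- function(cell_volumes, target_r,
                                      mean_count = 50, sd_count = 45,
                                      seed = NULL) {
  n <- length(cell_volumes)
  if (n < 3) stop("need at least 3 cells", call. = FALSE)
  if (abs(target_r) >= 1) stop("|target_r| must be < 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eps <- rnorm(n)
  if (sd(cell_volumes) == 0) {
    warning("degenerate cell volumes (all equal): independent loads",
            call. = FALSE)
    latent <- eps
  } else {
    z <- qnorm(rank(cell_volumes, ties.method = "average") / (n + 1))
    z <- z / sd(z)
    latent <- target_r * z + sqrt(1 - target_r^2) * eps
  }
  pmax(0, 1 + (sd_count / mean_count) * latent)
}

# place one sphere of radius r inside cell `cell_id`; returns voxel indices or
# NULL. Tier 1 honors the one-voxel separation margin (`blocked`), tier 2 only
# exact non-overlap (`occupied`).
place_sphere <- function(dims, steps, cell_center, cell_radii, r,
                         cell_lab, cell_id, occupied, blocked,
                         attempts, use_margin) {
  margin_ok <- pmax(cell_radii - r, 0.1)
  for (k in seq_len(attempts)) {
    u <- runif_in_unit_ball()
    center <- cell_center + u * margin_ok
    idx <- ellipsoid_indices(dims, steps, center, rep(r, 3))
    if (length(idx) == 0L) idx <- voxel_of(dims, steps, center)
    idx <- idx[cell_lab[idx] == cell_id]
    if (length(idx) == 0L) next
    if (use_margin) {
      if (any(blocked[idx])) next
    } else {
      if (any(occupied[idx])) next
    }
    return(idx)
  }
  NULL
}

#' Generate a synthetic scene
#'
#' Renders the configured world and returns the RI tomogram, the
#' co-registered fluorescence volume and the exact ground truth. Identical
#' seeds give bit-identical outputs. Cells that cannot be placed after
#' bounded retries raise an error (cells are never dropped silently);
#' aggregate placement degrades gracefully in over-crowded cells (separation
#' margin, then plain non-overlap, then stop) and the ground-truth tables
#' always describe exactly what was rendered.
#'
#' @param config A [scene_config()].
#' @return A list: `ri` ([ri_tomogram()]), `fluor`
#'   ([fluorescence_volume()]), `truth` (list with `cell_labels`,
#'   `aggregate_labels`, `droplet_labels` — [label_volume()]s — and data
#'   frames `per_cell` (`id`, `true_volume_um3`, `true_total_np_volume_um3`,
#'   `true_aggregate_count`, `target_aggregate_count`) and `per_aggregate`
#'   (`id`, `cell_id`, `true_volume_um3`, `fluorescent`), `per_droplet`),
#'   and `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  dims <- config$shape
  sp <- config$spacing
  steps <- c(sp$dz, sp$dy, sp$dx)
  vv <- voxel_volume(sp)
  n_vox <- prod(dims)
  size_um <- dims * steps

  set.seed(config$seed)
  ri <- array(config$ri_background, dims)
  cell_lab <- array(0L, dims)
  agg_lab <- array(0L, dims)
  drop_lab <- array(0L, dims)
  fluor <- array(0, dims)

  n_cells <- config$n_cells
  centers <- matrix(0, n_cells, 3)
  radii_m <- matrix(0, n_cells, 3)
  cell_base_ri <- numeric(n_cells)
  blocked_cells <- array(FALSE, dims)  # placed cells dilated by one voxel

  for (i in seq_len(n_cells)) {
    radii <- pmax(config$cell_radius_mean_um +
                    config$cell_radius_sd_um * rnorm(3),
                  config$cell_radius_mean_um * 0.4)
    if (any(2 * radii >= size_um))
      stop("cell larger than the grid: enlarge shape or shrink radii",
           call. = FALSE)
    placed <- FALSE
    for (attempt in seq_len(1000L)) {
      center <- radii + runif(3) * (size_um - 2 * radii)
      idx <- ellipsoid_indices(dims, steps, center, radii)
      if (length(idx) == 0L) next
      if (any(blocked_cells[idx])) next
      cell_lab[idx] <- i
      blocked_cells[dilate26(idx, dims)] <- TRUE
      centers[i, ] <- center
      radii_m[i, ] <- radii
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("could not place cell %d after 1000 attempts; reduce n_cells or cell size", i),
           call. = FALSE)
    base <- runif(1, config$ri_cytoplasm[1] + 1e-4, config$ri_cytoplasm[2])
    cell_base_ri[i] <- base
    ri[idx] <- base
    # nucleus: slightly lower-RI inclusion, still >= 1.34 (excluded from truth)
    nuc <- ellipsoid_indices(dims, steps, center, radii * 0.45)
    nuc <- nuc[cell_lab[nuc] == i]
    if (length(nuc) > 0) ri[nuc] <- max(1.3402, base - 0.004)
  }
  rm(blocked_cells)

  cell_vox <- if (n_cells > 0) tabulate(cell_lab[cell_lab > 0L], n_cells)
              else integer(0)

  # per-cell aggregate counts via the uptake-association copula
  mean_c <- config$aggregates_per_cell[1]
  sd_c <- config$aggregates_per_cell[2]
  counts <- integer(n_cells)
  if (n_cells >= 3 && mean_c > 0) {
    mult <- induce_uptake_association(cell_vox * vv, config$uptake_association,
                                      mean_c, sd_c)
    counts <- as.integer(round(mean_c * mult))
  } else if (n_cells > 0 && mean_c > 0) {
    counts <- as.integer(pmax(0, round(rnorm(n_cells, mean_c, sd_c))))
  }

  mu_ln <- config$aggregate_volume_lognormal[1]
  sig_ln <- config$aggregate_volume_lognormal[2]
  occupied <- array(FALSE, dims)   # aggregate or droplet voxels
  blocked <- array(FALSE, dims)    # the same, dilated by one voxel

  agg_rows <- list(); drop_rows <- list()
  agg_next <- 0L; drop_next <- 0L
  placed_counts <- integer(n_cells)

  for (i in seq_len(n_cells)) {
    set.seed((config$seed %% 100000L) * 7919L + i)  # per-cell sub-stream
    k_agg <- counts[i]
    vols <- sort(rlnorm(k_agg, mu_ln, sig_ln), decreasing = TRUE)
    fl <- runif(k_agg) < config$fluorophore_fraction
    n_drop <- rpois(1, config$droplets_per_cell)
    dvols <- sort(rlnorm(n_drop, mu_ln, sig_ln), decreasing = TRUE)

    place_all <- function(vols, is_droplet, fl_flags) {
      for (j in seq_along(vols)) {
        r <- (3 * vols[j] / (4 * pi))^(1 / 3)
        idx <- place_sphere(dims, steps, centers[i, ], radii_m[i, ], r,
                            cell_lab, i, occupied, blocked, 400L, TRUE)
        if (is.null(idx))
          idx <- place_sphere(dims, steps, centers[i, ], radii_m[i, ], r,
                              cell_lab, i, occupied, blocked, 400L, FALSE)
        if (is.null(idx)) return(invisible(NULL))  # cell jammed: stop placing
        if (is_droplet) {
          drop_next <<- drop_next + 1L
          drop_lab[idx] <<- drop_next
          ri[idx] <<- runif(1, config$ri_droplet[1], config$ri_droplet[2])
          drop_rows[[drop_next]] <<- data.frame(
            id = drop_next, cell_id = i,
            true_volume_um3 = length(idx) * vv)
        } else {
          agg_next <<- agg_next + 1L
          agg_lab[idx] <<- agg_next
          ri[idx] <<- runif(1, config$ri_aggregate[1], config$ri_aggregate[2])
          if (fl_flags[j]) fluor[idx] <<- runif(length(idx), 500, 1000)
          agg_rows[[agg_next]] <<- data.frame(
            id = agg_next, cell_id = i,
            true_volume_um3 = length(idx) * vv,
            fluorescent = fl_flags[j])
          placed_counts[i] <<- placed_counts[i] + 1L
        }
        occupied[idx] <<- TRUE
        blocked[dilate26(idx, dims)] <<- TRUE
      }
      invisible(NULL)
    }
    place_all(vols, FALSE, fl)
    place_all(dvols, TRUE, logical(length(dvols)))
  }
  rm(occupied, blocked)

  per_aggregate <- if (agg_next > 0) do.call(rbind, agg_rows) else
    data.frame(id = integer(0), cell_id = integer(0),
               true_volume_um3 = numeric(0), fluorescent = logical(0))
  per_droplet <- if (drop_next > 0) do.call(rbind, drop_rows) else
    data.frame(id = integer(0), cell_id = integer(0),
               true_volume_um3 = numeric(0))

  # dispersed sub-threshold fluorescence (fluorescent NP volume outside the
  # high-RI mask, emulating membrane-bound / sub-resolution particles)
  set.seed((config$seed %% 100000L) * 7919L + n_cells + 1L)
  f <- config$sub_threshold_fluor_fraction
  if (f > 0 && agg_next > 0) {
    fl_vox_cell <- vapply(seq_len(n_cells), function(i) {
      rows <- per_aggregate$cell_id == i & per_aggregate$fluorescent
      as.integer(round(sum(per_aggregate$true_volume_um3[rows]) / vv))
    }, integer(1))
    d_cell <- as.integer(round(f / (1 - f) * fl_vox_cell))
    for (i in seq_len(n_cells)) {
      if (d_cell[i] == 0L) next
      eligible <- which(cell_lab == i & agg_lab == 0L & drop_lab == 0L &
                          fluor == 0)
      take <- min(d_cell[i], length(eligible))
      pick <- if (take > 0) sample(eligible, take) else integer(0)
      fluor[pick] <- runif(length(pick), 500, 1000)
    }
  }

  if (config$noise_sd_ri > 0)
    ri <- ri + rnorm(n_vox, 0, config$noise_sd_ri)
  ri[ri < 1] <- 1; ri[ri > 2] <- 2

  per_cell <- data.frame(
    id = seq_len(n_cells),
    true_volume_um3 = cell_vox * vv,
    true_total_np_volume_um3 = vapply(seq_len(n_cells), function(i)
      sum(per_aggregate$true_volume_um3[per_aggregate$cell_id == i]),
      numeric(1)),
    true_aggregate_count = placed_counts,
    target_aggregate_count = counts)
  if (n_cells == 0L)
    per_cell <- per_cell[integer(0), , drop = FALSE]

  list(ri = ri_tomogram(ri, sp),
       fluor = fluorescence_volume(fluor, sp),
       truth = list(cell_labels = label_volume(cell_lab, sp),
                    aggregate_labels = label_volume(agg_lab, sp),
                    droplet_labels = label_volume(drop_lab, sp),
                    per_cell = per_cell,
                    per_aggregate = per_aggregate,
                    per_droplet = per_droplet),
       config = config)
}
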