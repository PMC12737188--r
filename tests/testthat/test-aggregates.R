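sp_half <- voxel_spacing(0.5, 0.5, 0.5)

cube_scene <- function() {
  # a "cell" slab at RI 1.35 containing an 8-voxel aggregate cube at 1.40
  vals <- array(1.33, c(12, 12, 12))
  vals[3:10, 3:10, 3:10] <- 1.35
  vals[5:6, 5:6, 5:6] <- 1.40
  tomo <- ri_tomogram(vals, sp_half)
  cells <- array(0L, c(12, 12, 12))
  cells[3:10, 3:10, 3:10] <- 1L
  list(tomo = tomo, cells = label_volume(cells, sp_half))
}

test_that("high-RI threshold is strict at 1.36", {
  mk <- function(val) ri_tomogram(array(val, c(4, 4, 4)), sp_half)
  expect_false(any(high_ri_mask(mk(1.35))))
  expect_false(any(high_ri_mask(mk(1.36))))  # "exceeding 1.36" => 1.36 out
  expect_true(all(high_ri_mask(mk(1.3600001))))
})

test_that("an 8-voxel cube at 0.5 um spacing is one 1.0 um^3 aggregate", {
  s <- cube_scene()
  det <- detect_aggregates(s$tomo, s$cells,
                           aggregate_params(min_aggregate_voxels = 1), sp_half)
  expect_identical(nrow(det$aggregates), 1L)
  expect_equal(det$aggregates$volume_um3, 1.0)
  expect_identical(det$aggregates$cell_id, 1L)
  expect_equal(det$aggregates$mean_ri, 1.40)
  expect_gte(det$aggregates$max_ri, det$aggregates$mean_ri)
})

test_that("a one-voxel gap separates components at 26-connectivity", {
  vals <- array(1.33, c(10, 10, 10))
  vals[2:9, 2:9, 2:9] <- 1.35
  vals[4:5, 4:5, 3] <- 1.40
  vals[4:5, 4:5, 5] <- 1.40   # gap at x = 4
  tomo <- ri_tomogram(vals, sp_half)
  det <- detect_aggregates(tomo, NULL,
                           aggregate_params(min_aggregate_voxels = 1), sp_half)
  expect_identical(nrow(det$aggregates), 2L)
})

test_that("component extraction matches the igraph oracle", {
  for (seed in 7:10) {
    dims <- c(16L, 16L, 16L)
    set.seed(seed)
    vals <- array(1.33 + 0.06 * (runif(prod(dims)) < 0.2), dims)
    tomo <- ri_tomogram(vals, sp_half)
    det <- detect_aggregates(tomo, NULL,
                             aggregate_params(min_aggregate_voxels = 1),
                             sp_half)
    mask <- vals > 1.36
    oracle <- oracle_label_components(mask, 26)
    expect_same_partition(det$labels$labels, oracle, mask)
  }
})

test_that("raising the threshold never grows the mask; accounting closes", {
  sc <- generate_scene(test_scene_config(seed = 12, noise_sd_ri = 0.002))
  m136 <- high_ri_mask(sc$ri, aggregate_params(high_ri_threshold = 1.36))
  m138 <- high_ri_mask(sc$ri, aggregate_params(high_ri_threshold = 1.38))
  expect_true(all(m138 <= m136))

  det <- detect_aggregates(sc$ri, sc$truth$cell_labels,
                           aggregate_params(min_aggregate_voxels = 2),
                           sc$ri$spacing)
  lab <- det$labels$labels
  dropped <- sum(m136) - sum(lab > 0L)
  expect_gte(dropped, 0)
  expect_identical(sum(det$aggregates$voxel_count) + dropped,
                   as.integer(sum(m136)))
})

test_that("cell stats join counts, volumes and fractions", {
  cells <- data.frame(id = 1:2, voxel_count = c(800L, 400L),
                      volume_um3 = c(100, 50), mean_ri = c(1.35, 1.351),
                      centroid_z = 0, centroid_y = 0, centroid_x = 0)
  aggs <- data.frame(id = 1:3, cell_id = c(1L, 1L, 0L),
                     voxel_count = c(4L, 4L, 2L),
                     volume_um3 = c(0.5, 0.5, 0.25),
                     mean_ri = 1.4, max_ri = 1.41,
                     centroid_z = 0, centroid_y = 0, centroid_x = 0)
  cs <- compute_cell_stats(cells, aggs)
  expect_identical(cs$aggregate_count, c(2L, 0L))
  expect_equal(cs$np_volume_fraction, c(1.0, 0))
  expect_equal(cs$total_np_volume_um3, c(1.0, 0))
  expect_equal(cs$mean_aggregate_volume_um3, c(0.5, NA_real_))

  bad <- aggs; bad$cell_id[1] <- 9L
  expect_error(compute_cell_stats(cells, bad), "unknown cell id")
})

test_that("size distribution fractions, cumulative curve and lognormal tail", {
  d <- aggregate_size_distribution(c(0.2, 0.4, 1.5), cutoff_um3 = 1)
  expect_equal(d$fraction_below_cutoff, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(aggregate_size_distribution(c(0.2, 0.4))$fraction_below_cutoff,
               100)
  expect_true(all(diff(d$cumulative$cum_percent) >= 0))
  expect_equal(d$cumulative$cum_percent[nrow(d$cumulative)], 100)
  expect_identical(sum(d$histogram$count), 3L)

  # Phi(0.90 / 0.78) ~ 0.8757 of lognormal(-0.90, 0.78) mass lies below 1 um^3
  set.seed(21)
  frac <- aggregate_size_distribution(rlnorm(10000, -0.90, 0.78),
                                      1)$fraction_below_cutoff
  expect_lt(abs(frac - 87.57), 1.5)
  expect_error(aggregate_size_distribution(numeric(0)), "no aggregates")
})

test_that("noise-free scenes: counts and volumes recovered within a shell", {
  sc <- generate_scene(test_scene_config(seed = 13))
  fg <- foreground_mask(sc$ri)
  seg <- segment_cells(fg, test_seg_params(), sc$ri$spacing)
  det <- detect_aggregates(sc$ri, seg$labels,
                           aggregate_params(min_aggregate_voxels = 1),
                           sc$ri$spacing)
  expect_identical(nrow(det$aggregates), nrow(sc$truth$per_aggregate))
  expect_equal(sort(det$aggregates$volume_um3),
               sort(sc$truth$per_aggregate$true_volume_um3), tolerance = 1e-9)
})

test_that("droplets are detected as extra components, exactly", {
  cfg <- test_scene_config(seed = 14, droplets_per_cell = 2,
                           aggregates_per_cell = c(10, 3))
  sc <- generate_scene(cfg)
  seg <- segment_cells(foreground_mask(sc$ri), test_seg_params(),
                       sc$ri$spacing)
  det <- detect_aggregates(sc$ri, seg$labels,
                           aggregate_params(min_aggregate_voxels = 1),
                           sc$ri$spacing)
  expect_identical(nrow(det$aggregates),
                   nrow(sc$truth$per_aggregate) + nrow(sc$truth$per_droplet))
})
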