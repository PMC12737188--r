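test_that("empty scene is uniform background with empty truth tables", {
  cfg <- test_scene_config(n_cells = 0L, noise_sd_ri = 0)
  sc <- generate_scene(cfg)
  expect_true(all(sc$ri$values == cfg$ri_background))
  expect_true(all(sc$fluor$values == 0))
  expect_identical(nrow(sc$truth$per_cell), 0L)
  expect_identical(nrow(sc$truth$per_aggregate), 0L)
  expect_identical(max(sc$truth$cell_labels$labels), 0L)
})

test_that("identical seeds give bit-identical scenes", {
  a <- generate_scene(test_scene_config(seed = 5, noise_sd_ri = 0.002))
  b <- generate_scene(test_scene_config(seed = 5, noise_sd_ri = 0.002))
  expect_identical(a$ri$values, b$ri$values)
  expect_identical(a$fluor$values, b$fluor$values)
  expect_identical(a$truth$per_aggregate, b$truth$per_aggregate)
  c <- generate_scene(test_scene_config(seed = 6, noise_sd_ri = 0.002))
  expect_false(identical(a$ri$values, c$ri$values))
})

test_that("default lognormal aggregate volumes match the stated moments", {
  # closed form: mean = exp(mu + s^2/2) ~ 0.551, sd = mean*sqrt(exp(s^2)-1) ~ 0.504
  set.seed(123)
  v <- rlnorm(10000, -0.90, 0.78)
  expect_lt(abs(mean(v) - 0.5511), 0.03)
  expect_lt(abs(sd(v) - 0.5044), 0.05)
})

test_that("pre-noise RI bands separate background, cytoplasm and aggregates", {
  cfg <- test_scene_config(seed = 2, droplets_per_cell = 1)
  sc <- generate_scene(cfg)
  cells <- sc$truth$cell_labels$labels > 0L
  aggs <- sc$truth$aggregate_labels$labels > 0L
  drops <- sc$truth$droplet_labels$labels > 0L
  expect_true(all(sc$ri$values[!cells] < 1.34))
  expect_true(all(sc$ri$values[cells & !aggs & !drops] < 1.36))
  expect_true(all(sc$ri$values[cells & !aggs & !drops] >= 1.34))
  expect_true(all(sc$ri$values[aggs | drops] > 1.36))
})

test_that("conservation and containment invariants hold", {
  sc <- generate_scene(test_scene_config(seed = 3, droplets_per_cell = 1))
  vv <- voxel_volume(sc$ri$spacing)
  # cell voxel accounting
  expect_equal(sum(sc$truth$cell_labels$labels > 0L) * vv,
               sum(sc$truth$per_cell$true_volume_um3))
  # per-aggregate volumes are exactly voxel counts x voxel volume
  counts <- tabulate(sc$truth$aggregate_labels$labels[
    sc$truth$aggregate_labels$labels > 0L])
  expect_equal(counts * vv, sc$truth$per_aggregate$true_volume_um3)
  # every aggregate lies inside exactly one cell
  agg_lab <- sc$truth$aggregate_labels$labels
  cell_lab <- sc$truth$cell_labels$labels
  for (id in sc$truth$per_aggregate$id) {
    owner <- unique(cell_lab[agg_lab == id])
    expect_length(owner, 1L)
    expect_identical(owner, sc$truth$per_aggregate$cell_id[id])
  }
  # per-cell totals equal the sum of member aggregates
  for (i in sc$truth$per_cell$id) {
    expect_equal(sc$truth$per_cell$true_total_np_volume_um3[i],
                 sum(sc$truth$per_aggregate$true_volume_um3[
                   sc$truth$per_aggregate$cell_id == i]))
  }
})

test_that("fluorescence sits exactly on fluorophore-bearing NP voxels", {
  sc <- generate_scene(test_scene_config(seed = 4, droplets_per_cell = 2))
  agg_lab <- sc$truth$aggregate_labels$labels
  fl_ids <- sc$truth$per_aggregate$id[sc$truth$per_aggregate$fluorescent]
  on_fl <- array(agg_lab %in% fl_ids, dim(agg_lab))
  expect_true(all(sc$fluor$values[on_fl] > 0))
  expect_true(all(sc$fluor$values[!on_fl] == 0))  # no dispersed voxels here
  # droplets never fluoresce
  expect_true(all(sc$fluor$values[sc$truth$droplet_labels$labels > 0L] == 0))
})

test_that("dispersed sub-threshold fluorescence has the configured share", {
  sc <- generate_scene(test_scene_config(seed = 8,
                                         sub_threshold_fluor_fraction = 0.08))
  fl <- sc$fluor$values > 0
  on_agg <- sc$truth$aggregate_labels$labels > 0L
  n_disp <- sum(fl & !on_agg)
  share <- n_disp / sum(fl)
  expect_lt(abs(share - 0.08), 0.01)
  # dispersed voxels stay below the 1.36 aggregate threshold
  expect_true(all(sc$ri$values[fl & !on_agg] < 1.36))
})

test_that("infeasible configurations are rejected, not silently degraded", {
  expect_error(scene_config(shape = c(8L, 16L, 16L), n_cells = 50L),
               "infeasible")
  expect_error(scene_config(ri_background = 1.35), "1.34")
  expect_error(scene_config(ri_aggregate = c(1.35, 1.40)), "1.36")
  expect_error(scene_config(uptake_association = 1), "invalid|abs",
               class = "simpleError")
})

test_that("uptake association copula hits its target across the range", {
  set.seed(77)
  vols <- rlnorm(1000, 6, 0.35)

  # target 0: loads independent of volume
  m0 <- induce_uptake_association(vols, 0)
  expect_lt(abs(cor(vols, m0)), 3 / sqrt(1000))

  # target 0.99: near-deterministic ranking survives count discretisation
  m99 <- induce_uptake_association(vols, 0.99)
  t99 <- round(50 * m99) * 0.551
  expect_gt(cor(vols, t99), 0.9)

  # target 0.35: mean realized r over 20 replicates of 500 cells within 0.05,
  # with total NP volume simulated as a sum of lognormal aggregate volumes
  rs <- vapply(1:20, function(k) {
    set.seed(1000 + k)
    v <- rlnorm(500, 6, 0.35)
    mm <- induce_uptake_association(v, 0.35)
    kk <- round(50 * mm)
    tt <- vapply(kk, function(n) sum(rlnorm(n, -0.90, 0.78)), numeric(1))
    cor(v, tt)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.35), 0.05)
})

test_that("degenerate equal volumes warn and fall back to independent loads", {
  expect_warning(m <- induce_uptake_association(rep(10, 50), 0.5, seed = 1),
                 "degenerate")
  expect_length(m, 50)
  expect_true(all(m >= 0))
})
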