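sp1 <- voxel_spacing(1, 1, 1)

test_that("binarization: two-level, fixed threshold, and degenerate inputs", {
  v <- array(0, c(4, 8, 8)); v[2, , ] <- 100
  fl <- fluorescence_volume(v, sp1)
  expect_identical(binarize_fluorescence(fl, coloc_params()), v == 100)
  expect_identical(
    binarize_fluorescence(fl, coloc_params("fixed", 50)), v == 100)

  w <- array(rep(c(40, 60), each = 32), c(4, 4, 4))
  flw <- fluorescence_volume(w, sp1)
  expect_identical(binarize_fluorescence(flw, coloc_params("fixed", 50)),
                   w == 60)

  expect_warning(
    m <- binarize_fluorescence(fluorescence_volume(array(0, c(2, 2, 2)), sp1)),
    "all-zero")
  expect_false(any(m))
})

test_that("otsu separates well-split modes with < 1% misclassification", {
  set.seed(31)
  lowv <- rnorm(20000, 100, 10)
  highv <- rnorm(20000, 400, 10)  # 30 sigma apart >> 6 sigma requirement
  thr <- otsu_threshold(c(lowv, highv))
  mis <- (sum(lowv > thr) + sum(highv <= thr)) / 40000
  expect_lt(mis, 0.01)
})

test_that("containment gives 100%, disjointness 0%, emptiness missing", {
  f <- array(FALSE, c(4, 6, 6)); f[2, 2:3, 2:3] <- TRUE
  h <- array(FALSE, c(4, 6, 6)); h[2, 1:4, 1:4] <- TRUE
  r <- colocalize(f, h, params = coloc_params(scope = "whole_volume"))
  expect_equal(r$fluor_in_high_ri_fraction, 100)

  h2 <- array(FALSE, c(4, 6, 6)); h2[4, , ] <- TRUE
  r2 <- colocalize(f, h2, params = coloc_params(scope = "whole_volume"))
  expect_equal(r2$fluor_in_high_ri_fraction, 0)

  r3 <- colocalize(array(FALSE, c(4, 6, 6)), h,
                   params = coloc_params(scope = "whole_volume"))
  expect_true(is.na(r3$fluor_in_high_ri_fraction))
})

test_that("swapping masks swaps the fractions, overlap unchanged", {
  set.seed(41)
  f <- array(runif(216) < 0.3, c(6, 6, 6))
  h <- array(runif(216) < 0.4, c(6, 6, 6))
  a <- colocalize(f, h, params = coloc_params(scope = "whole_volume"))
  b <- colocalize(h, f, params = coloc_params(scope = "whole_volume"))
  expect_identical(a$overlap_voxels, b$overlap_voxels)
  expect_equal(a$fluor_in_high_ri_fraction, b$high_ri_in_fluor_fraction)
  expect_equal(a$high_ri_in_fluor_fraction, b$fluor_in_high_ri_fraction)
})

test_that("dilating the high-RI mask never decreases the M1 fraction", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- c(8L, 8L, 8L)
    f <- array(runif(512) < 0.3, d)
    h <- array(runif(512) < 0.2, d)
    hd <- array(FALSE, d)
    hd[holoquant:::dilate26(which(h), d)] <- TRUE
    a <- colocalize(f, h, params = coloc_params(scope = "whole_volume"))
    b <- colocalize(f, hd, params = coloc_params(scope = "whole_volume"))
    if (!is.na(a$fluor_in_high_ri_fraction))
      expect_gte(b$fluor_in_high_ri_fraction, a$fluor_in_high_ri_fraction)
  }
})

test_that("voxel Pearson r is invariant under positive affine rescaling", {
  sc <- generate_scene(test_scene_config(seed = 15))
  hm <- high_ri_mask(sc$ri)
  fm <- binarize_fluorescence(sc$fluor, coloc_params(), sc$truth$cell_labels)
  r1 <- colocalize(fm, hm, sc$truth$cell_labels, coloc_params(),
                   tomogram = sc$ri, fluor = sc$fluor)$voxel_pearson_r
  scaled <- sc$fluor
  scaled$values <- 3.7 * scaled$values + 11
  r2 <- colocalize(fm, hm, sc$truth$cell_labels, coloc_params(),
                   tomogram = sc$ri, fluor = scaled)$voxel_pearson_r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("per-cell colocalization: identical masks and missing cells", {
  labs <- array(0L, c(4, 8, 8))
  labs[, 1:4, ] <- 1L; labs[, 5:8, ] <- 2L
  cl <- label_volume(labs, sp1)
  m <- array(runif(256) < 0.3, c(4, 8, 8))
  cc <- coloc_per_cell(m, m, cl)
  expect_equal(cc$per_cell$fluor_in_high_ri_fraction, c(100, 100))
  expect_equal(cc$summary$sd_fraction, 0)
  expect_equal(cc$summary$mean_fraction, 100)

  m2 <- m; m2[, 5:8, ] <- FALSE  # cell 2 has no fluorescence
  h <- array(TRUE, c(4, 8, 8))
  cc2 <- coloc_per_cell(m2, h, cl)
  expect_true(is.na(cc2$per_cell$fluor_in_high_ri_fraction[2]))
  expect_identical(cc2$summary$n_cells, 1L)
})

test_that("the ~92% overlap world is recovered with spread across cells", {
  cfg <- test_scene_config(seed = 16, n_cells = 6,
                           shape = c(40L, 128L, 128L),
                           aggregates_per_cell = c(30, 10),
                           sub_threshold_fluor_fraction = 0.08)
  sc <- generate_scene(cfg)
  seg <- segment_cells(foreground_mask(sc$ri), test_seg_params(),
                       sc$ri$spacing)
  hm <- high_ri_mask(sc$ri)
  fm <- binarize_fluorescence(sc$fluor, coloc_params(), seg$labels)
  cc <- coloc_per_cell(fm, hm, seg$labels)
  expect_lt(abs(cc$summary$mean_fraction - 92), 2)
  expect_gt(cc$summary$sd_fraction, 0)
})
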