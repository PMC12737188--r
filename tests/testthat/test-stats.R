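test_that("p_from_r reproduces the published correlation p-values", {
  expect_equal(p_from_r(0, 10), 1)
  expect_equal(p_from_r(1, 50), 0)
  # frozen from a numerical integration of the t density (df = 228):
  expect_equal(p_from_r(0.0942, 230), 0.1544469301, tolerance = 1e-8)
  expect_lt(p_from_r(0.3534, 230), 1e-4)
  # monotone decreasing in |r| at fixed n
  ps <- p_from_r(seq(0.05, 0.95, by = 0.05), 30)
  expect_true(all(diff(ps) < 0))
})

test_that("p_from_r agrees with a t-density integration oracle to 1e-6", {
  tdens <- function(x, df)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  for (n in c(10, 50, 230)) {
    for (r in seq(0.05, 0.95, by = 0.15)) {
      t0 <- r * sqrt(n - 2) / sqrt(1 - r^2)
      oracle <- 2 * integrate(tdens, t0, Inf, df = n - 2,
                              rel.tol = 1e-10)$value
      expect_equal(p_from_r(r, n), oracle, tolerance = 1e-6)
    }
  }
})

test_that("pearson_cor matches cor.test and flags significance", {
  x <- 1:10
  res <- pearson_cor(x, 2 * x)
  expect_equal(res$r, 1)
  expect_equal(res$p_two_tailed, 0)
  expect_true(res$significant)

  set.seed(51)
  a <- rnorm(40); b <- 0.4 * a + rnorm(40)
  res2 <- pearson_cor(a, b)
  ct <- cor.test(a, b)
  expect_equal(res2$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res2$p_two_tailed, ct$p.value, tolerance = 1e-12)
  expect_equal(res2$t_stat, unname(ct$statistic), tolerance = 1e-12)
  expect_identical(res2$significant, ct$p.value < 0.05)

  expect_error(pearson_cor(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("group comparisons match t.test/aov oracles and t^2 = F", {
  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  same <- compare_groups(g, "t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_two_tailed, 1)

  set.seed(52)
  x <- rnorm(30, 0); y <- rnorm(25, 0.8)
  ours <- compare_groups(list(x, y), "t")
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_two_tailed, ref$p.value, tolerance = 1e-12)

  ours_w <- compare_groups(list(x, y), "t", var_equal = FALSE)
  ref_w <- t.test(x, y)
  expect_equal(ours_w$p_two_tailed, ref_w$p.value, tolerance = 1e-12)

  z <- rnorm(28, 0.4)
  aov_ref <- summary(aov(v ~ g, data.frame(
    v = c(x, y, z),
    g = factor(rep(1:3, c(30, 25, 28))))))[[1]]
  ours_a <- compare_groups(list(x, y, z), "anova")
  expect_equal(ours_a$statistic, aov_ref$`F value`[1], tolerance = 1e-10)
  expect_equal(ours_a$p_two_tailed, aov_ref$`Pr(>F)`[1], tolerance = 1e-10)

  two <- compare_groups(list(x, y), "anova")
  expect_equal(two$statistic, ours$statistic^2, tolerance = 1e-12)

  big <- compare_groups(list(rnorm(50, 0), rnorm(50, 5)), "t")
  expect_lt(big$p_two_tailed, 1e-4)
  expect_error(compare_groups(list(x), "t"), ">= 2")
  expect_error(compare_groups(list(x, 1), "t"), "at least 2 values")
})

test_that("gaussian fits: trivial cases and the truncated-normal oracle", {
  f <- fit_gaussian(c(1, 3))
  expect_equal(f$mean, 2)
  expect_equal(fit_gaussian(rep(4, 10))$sd_ml, 0)
  # N(50, 45) truncated at 0 has mean mu + sigma*phi(a)/(1-Phi(a)) = 61.1725
  set.seed(53)
  draws <- rnorm(2e5, 50, 45)
  draws <- draws[draws > 0][1:1e5]
  expect_lt(abs(fit_gaussian(draws)$mean - 61.1725) / 61.1725, 0.02)
  expect_error(fit_gaussian(1), "at least 2")
})

test_that("type-I error of the correlation test is calibrated at 5%", {
  set.seed(54)
  n <- 50; reps <- 10000
  X <- matrix(rnorm(n * reps), n)
  Y <- matrix(rnorm(n * reps), n)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  r <- colSums(Xc * Yc) / sqrt(colSums(Xc^2) * colSums(Yc^2))
  rate <- mean(p_from_r(r, n) < 0.05)
  expect_lt(abs(rate - 0.05), 0.006)
})

test_that("build_report computes the descriptive block and correlations", {
  cells <- data.frame(cell_id = 1L, cell_volume_um3 = 100, mean_cell_ri = 1.35,
                      aggregate_count = 2L, total_np_volume_um3 = 1.0,
                      np_volume_fraction = 1.0, mean_aggregate_volume_um3 = 0.5)
  aggs <- data.frame(id = 1:2, cell_id = 1L, voxel_count = 25L,
                     volume_um3 = 0.5, mean_ri = 1.4, max_ri = 1.42,
                     centroid_z = 0, centroid_y = 0, centroid_x = 0)
  rep1 <- build_report(cells, aggs)
  expect_equal(rep1$descriptives$aggregate_size_um3$mean, 0.5)
  expect_equal(rep1$descriptives$aggregate_size_um3$sd, 0)
  expect_null(rep1$correlations$cell_volume_vs_np_volume)  # n < 3

  empty <- build_report(cells[integer(0), ], aggs[integer(0), ])
  expect_true(is.na(empty$descriptives$np_volume_fraction_pct$mean))
  expect_null(empty$distributions$aggregate_sizes)

  # purity: identical inputs -> identical report
  sc <- generate_scene(test_scene_config(seed = 17))
  seg <- segment_cells(foreground_mask(sc$ri), test_seg_params(),
                       sc$ri$spacing, tomogram = sc$ri)
  det <- detect_aggregates(sc$ri, seg$labels, aggregate_params(),
                           sc$ri$spacing)
  cs <- compute_cell_stats(seg$cells, det$aggregates)
  expect_identical(build_report(cs, det$aggregates),
                   build_report(cs, det$aggregates))
  r8 <- build_report(cs, det$aggregates)$correlations$cell_volume_vs_np_volume
  expect_true(!is.null(r8))
  expect_true(abs(r8$r) <= 1)
})

test_that("zero-aggregate cells are excluded from the size-vs-RI pairs", {
  cells <- data.frame(cell_id = 1:5, cell_volume_um3 = c(100, 120, 90, 110, 95),
                      mean_cell_ri = c(1.35, 1.352, 1.348, 1.351, 1.349),
                      aggregate_count = c(3L, 0L, 2L, 1L, 4L),
                      total_np_volume_um3 = c(1.5, 0, 1.0, 0.4, 2.0),
                      np_volume_fraction = c(1.5, 0, 1.1, 0.36, 2.1),
                      mean_aggregate_volume_um3 = c(0.5, NA, 0.5, 0.4, 0.5))
  aggs <- data.frame(id = 1:3, cell_id = c(1L, 3L, 5L), voxel_count = 25L,
                     volume_um3 = 0.5, mean_ri = 1.4, max_ri = 1.42,
                     centroid_z = 0, centroid_y = 0, centroid_x = 0)
  rep1 <- build_report(cells, aggs)
  expect_identical(rep1$correlations$mean_aggregate_size_vs_mean_ri$n, 4L)
})
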