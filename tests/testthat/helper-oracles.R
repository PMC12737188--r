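# Independent oracles used across the suite. The connected-component oracle
# builds an explicit adjacency graph with array shifts and asks igraph for
# its components — a different algorithm and code path from the package's
# C++ labeling.

oracle_label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  co <- arrayInd(idx, d)
  key <- function(z, y, x) z + d[1] * ((y - 1L) + d[2] * (x - 1L))
  lookup <- integer(prod(d))
  lookup[idx] <- seq_along(idx)

  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  ord <- rowSums(abs(offs))
  offs <- offs[ord > 0 & ord <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ]
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    z <- co[, 1] + offs$dz[r]; y <- co[, 2] + offs$dy[r]; x <- co[, 3] + offs$dx[r]
    ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    nb <- lookup[key(z[ok], y[ok], x[ok])]
    hit <- nb > 0L
    edges[[r]] <- cbind(which(ok)[hit], nb[hit])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(em) && nrow(em) > 0) g <- igraph::add_edges(g, t(em))
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

# two labelings describe the same partition iff their contingency table is a
# (partial) permutation matrix over the foreground
expect_same_partition <- function(lab_a, lab_b, mask) {
  tab <- table(lab_a[mask], lab_b[mask])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
}

# a small, quick default scene for tests
test_scene_config <- function(seed = 1, ...) {
  args <- list(shape = c(32L, 128L, 128L),
               n_cells = 4L,
               cell_radius_mean_um = c(2.2, 4.5, 4.5),
               cell_radius_sd_um = c(0.2, 0.5, 0.5),
               aggregates_per_cell = c(20, 8),
               droplets_per_cell = 0,
               noise_sd_ri = 0,
               seed = seed)
  do.call(scene_config, modifyList(args, list(...)))
}

test_seg_params <- function(...) {
  segmentation_params(min_cell_volume_um3 = 50, ...)
}

# random blobby masks: union of a few random boxes plus salt voxels
random_mask <- function(dims, seed) {
  set.seed(seed)
  m <- array(runif(prod(dims)) < 0.25, dims)
  for (k in 1:3) {
    lo <- pmax(1L, sapply(dims, function(n) sample.int(n, 1)) - 3L)
    hi <- pmin(dims, lo + sample(2:5, 3, replace = TRUE))
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  m
}
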