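test_that("a 3x3 block is one cluster with the right area", {
  m <- matrix(FALSE, 8, 8); m[2:4, 3:5] <- TRUE
  lab <- label_clusters(m, pixel_size = 0.1)
  expect_equal(nrow(lab$table), 1)
  expect_equal(lab$table$pixel_count, 9L)
  expect_equal(lab$table$area_mm2, 0.09)
})

test_that("diagonal touching depends on connectivity", {
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(nrow(label_clusters(m, connectivity = 4)$table), 2)
  expect_equal(nrow(label_clusters(m, connectivity = 8)$table), 1)
})

test_that("labeling matches the flood-fill oracle on random masks", {
  set.seed(101)
  for (i in 1:100) {
    m <- matrix(runif(32 * 32) < 0.35, 32, 32)
    conn <- if (i %% 2 == 0) 4 else 8
    got <- label_clusters(m, connectivity = conn)$labels
    want <- flood_fill_labels(m, connectivity = conn)
    expect_identical(canonical_labels(got), canonical_labels(want))
  }
})

test_that("labels are deterministically ordered by topmost-leftmost pixel", {
  m <- matrix(FALSE, 6, 6)
  m[5, 1] <- TRUE; m[1, 5] <- TRUE; m[3, 3] <- TRUE
  tab <- label_clusters(m)$table
  expect_equal(tab$centroid_row, c(1, 3, 5))
})

test_that("min_pixels drops small components", {
  m <- matrix(FALSE, 8, 8); m[1, 1] <- TRUE; m[5:6, 5:6] <- TRUE
  tab <- label_clusters(m, min_pixels = 2)$table
  expect_equal(nrow(tab), 1)
  expect_equal(tab$pixel_count, 4L)
})

test_that("translation preserves counts and areas, shifts centroids", {
  set.seed(8)
  m <- matrix(runif(20 * 20) < 0.3, 20, 20)
  m[c(1, 20), ] <- FALSE; m[, c(1, 20)] <- FALSE
  shifted <- matrix(FALSE, 20, 20)
  shifted[2:20, 2:20] <- m[1:19, 1:19]
  a <- label_clusters(m)$table
  b <- label_clusters(shifted)$table
  expect_equal(nrow(a), nrow(b))
  expect_equal(sort(a$pixel_count), sort(b$pixel_count))
  expect_equal(b$centroid_row, a$centroid_row + 1)
  expect_equal(b$centroid_col, a$centroid_col + 1)
})

make_femap <- function(iron, mask = NULL, pixel_size = 0.1) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(iron), ncol(iron))
  stratify(fe_map(iron, mask, pixel_size))
}

test_that("per-bin cluster areas conserve the supra-threshold pixel area", {
  set.seed(17)
  iron <- matrix(runif(40 * 40, 0, 0.3), 40, 40)
  fe <- make_femap(iron)
  d <- cluster_distribution(fe, n_bins = 15)
  edges <- d$bin_edges
  for (i in seq_len(15)) {
    sel <- if (i < 15) iron >= edges[i] & iron < edges[i + 1]
           else iron >= edges[i] & iron <= edges[i + 1]
    expect_equal(d$total_cluster_area_per_bin[i], sum(sel) * 0.1^2,
                 tolerance = 1e-12)
  }
  expect_equal(sum(d$clusters_per_bin), nrow(d$cluster_table))
})

test_that("a map confined to one bin puts all clusters in that bin", {
  iron <- matrix(0.21, 10, 10)           # bin (0.20, 0.22]
  d <- cluster_distribution(make_femap(iron), n_bins = 15)
  expect_equal(sum(d$clusters_per_bin > 0), 1)
  expect_equal(d$clusters_per_bin[11], 1)
})

test_that("a planted deposit lands in the bin containing its concentration", {
  iron <- matrix(0.03, 30, 30)
  iron[10:11, 10:11] <- 0.2
  d <- cluster_distribution(make_femap(iron), n_bins = 15)
  expect_equal(d$clusters_per_bin[11], 1)  # 0.2 in [0.20, 0.22)
  expect_equal(d$mean_cluster_area_per_bin[11], 4 * 0.01)
})

test_that("phantom distribution maxima fall in the low-iron range", {
  ph <- generate_mri_phantom(mri_phantom_config(grid_rows = 128,
    grid_cols = 128, tumor_radius = 50, n_deposits = 30, seed = 19))
  res <- analyze_mge_phantom(ph)
  d <- res$distribution
  thr <- 0.15
  peak_bin <- which.max(d$clusters_per_bin)
  expect_lt(d$bin_centers[peak_bin], thr)
  expect_lt(res$median_iron_freq, thr)
})

test_that("high-iron cluster count recovers the planted deposit count", {
  ph <- generate_mri_phantom(mri_phantom_config(grid_rows = 128,
    grid_cols = 128, tumor_radius = 50, n_deposits = 30, noise_sd = 0,
    seed = 23))
  res <- analyze_mge_phantom(ph)
  expect_equal(res$n_high_clusters, 30)
})

test_that("no deposits means no high-iron clusters", {
  ph <- generate_mri_phantom(mri_phantom_config(grid_rows = 64, grid_cols = 64,
    tumor_radius = 28, n_deposits = 0, noise_sd = 0, seed = 1))
  res <- analyze_mge_phantom(ph)
  expect_equal(res$n_high_clusters, 0)
  expect_length(res$high$high_cluster_areas, 0)
})

test_that("planted 2x2 high-iron deposits each measure 0.04 mm2", {
  iron <- matrix(0.03, 40, 40)
  for (p in list(c(5, 5), c(15, 25), c(30, 10))) {
    iron[p[1]:(p[1] + 1), p[2]:(p[2] + 1)] <- 0.25
  }
  hm <- high_iron_metrics(make_femap(iron))
  expect_equal(hm$n_high_clusters, 3)
  expect_equal(hm$high_cluster_areas, rep(0.04, 3))
})

test_that("high-iron metrics demand a stratified map", {
  fe <- fe_map(matrix(0.1, 4, 4), matrix(TRUE, 4, 4), 0.1)
  expect_error(high_iron_metrics(fe), "stratified")
})
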