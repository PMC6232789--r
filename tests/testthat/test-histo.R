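test_that("color rule detects blue, rejects white background", {
  px <- array(0, c(1, 3, 3))
  px[1, 1, ] <- c(0, 0, 1)        # pure blue
  px[1, 2, ] <- c(1, 1, 1)        # white background
  px[1, 3, ] <- c(0.9, 0.7, 0.75) # pinkish tissue
  got <- detect_iron_pixels(histo_raster(px, 2))
  expect_equal(as.vector(got), c(TRUE, FALSE, FALSE))
})

test_that("RGB rendering of a phantom detects exactly the iron class", {
  hp <- generate_histo_phantom(histo_phantom_config(section_rows = 900,
    section_cols = 900, n_deposits = 3, n_background_macrophages = 50,
    min_separation_um = 250, seed = 3))
  rgb <- render_histo_rgb(hp$raster)
  expect_identical(detect_iron_pixels(rgb),
                   detect_iron_pixels(hp$raster))
  expect_gt(sum(detect_iron_pixels(rgb)), 0)
})

test_that("aligned block mean produces exact area fractions", {
  m <- matrix(0, 1000, 1000)
  m[101:200, 201:300] <- 1                       # one full tile
  den <- downsample_to_mri(m, 100)
  expect_equal(dim(den), c(10, 10))
  expect_equal(den[2, 3], 1)
  expect_equal(sum(den), 1)

  m2 <- matrix(0, 200, 200)
  m2[1:50, 1:50] <- 1                            # quarter of a 100x100 tile
  expect_equal(downsample_to_mri(m2, 100)[1, 1], 0.25)

  expect_true(all(downsample_to_mri(matrix(0, 300, 300), 100) == 0))
})

test_that("block-mean downsampling conserves mass on exact multiples", {
  set.seed(55)
  m <- matrix(runif(600 * 400) < 0.1, 600, 400)
  den <- downsample_to_mri(m, 50)
  expect_lt(abs(sum(den) * 50^2 - sum(m)), 1e-9)
})

test_that("downsampling rejects oversized factors", {
  expect_error(downsample_to_mri(matrix(0, 10, 10), 20), "exceeds")
})

test_that("watershed separates distinct blobs and splits necked pairs", {
  den <- matrix(0, 20, 20)
  den[4:6, 4:6] <- 0.5
  den[14:16, 14:16] <- 0.5
  expect_equal(max(watershed_deposits(den)), 2)

  # two blobs bridged by a 1-px low-density neck
  den2 <- matrix(0, 11, 21)
  den2[4:8, 4:8] <- 0.6
  den2[4:8, 14:18] <- 0.6
  den2[6, 9:13] <- 0.05
  lab2 <- watershed_deposits(den2)
  expect_equal(max(lab2), 2)

  expect_equal(max(watershed_deposits(matrix(0, 10, 10))), 0)
})

test_that("cells are counted per deposit with conservation", {
  lab <- matrix(0L, 10, 10)
  lab[2:3, 2:3] <- 1L
  lab[7:8, 7:8] <- 2L
  # factor 10, 1 um/px: deposit 1 spans 10-30 um, deposit 2 spans 60-80 um
  cells <- data.frame(
    x_um = c(15, 25, 22, 18, 12, 75, 75, 50),
    y_um = c(15, 25, 22, 18, 12, 75, 65, 50),
    iron = c(rep(TRUE, 7), TRUE))
  res <- count_cells_per_deposit(lab, cells, factor = 10,
                                 microns_per_pixel = 1)
  expect_equal(res$deposit_table$iron_cell_count, c(5L, 2L))
  expect_equal(res$n_assigned + res$n_unassigned, sum(cells$iron))
  expect_equal(res$n_unassigned, 1)
  expect_equal(res$deposit_table$area_lowres_pixels, c(4L, 4L))
})

test_that("cells on background only give an empty deposit table", {
  lab <- matrix(0L, 5, 5)
  cells <- data.frame(x_um = c(10, 20), y_um = c(10, 20),
                      iron = c(TRUE, TRUE))
  res <- count_cells_per_deposit(lab, cells, factor = 10,
                                 microns_per_pixel = 1)
  expect_equal(nrow(res$deposit_table), 0)
  expect_equal(res$n_unassigned, 2)
})

test_that("out-of-raster cells are skipped with a warning count", {
  lab <- matrix(1L, 5, 5)
  cells <- data.frame(x_um = c(10, 999), y_um = c(10, 999),
                      iron = c(TRUE, TRUE))
  expect_warning(
    res <- count_cells_per_deposit(lab, cells, factor = 10,
                                   microns_per_pixel = 1),
    "skipped")
  expect_equal(res$n_skipped, 1)
  expect_equal(res$deposit_table$iron_cell_count, 1L)
})

test_that("phantom deposits are recovered with faithful cell counts", {
  for (s in c(2, 9, 27)) {
    hp <- generate_histo_phantom(histo_phantom_config(seed = s))
    res <- map_histology_deposits(hp$raster, hp$truth$cell_table)
    expect_equal(nrow(res$deposit_table), 20)
    expect_lt(abs(mean(res$deposit_table$iron_cell_count) -
                  mean(hp$truth$deposits$n_cells)), 1)
  }
})

test_that("raster container validates its inputs", {
  expect_error(histo_raster(matrix(0, 2, 2), -1), "microns_per_pixel")
  expect_error(histo_raster(array(0, c(2, 2, 4)), 1, mode = "rgb"),
               "rows x cols x 3")
})
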