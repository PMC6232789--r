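test_that("MRI phantom plants exactly the configured number of deposits", {
  ph <- generate_mri_phantom(mri_phantom_config(grid_rows = 128,
    grid_cols = 128, tumor_radius = 50, n_deposits = 30, seed = 1))
  expect_equal(nrow(ph$truth$deposits), 30)
  expect_equal(length(unique(ph$truth$deposit_pixels$deposit_id)), 30)
})

test_that("noiseless uniform-iron phantom decays with the closed-form T2*", {
  # C = 0.1 mg/g, R2* = 400*0.1 + 20 = 60 s^-1, T2* = 16.67 ms
  cfg <- mri_phantom_config(grid_rows = 48, grid_cols = 48, tumor_radius = 20,
    baseline_iron_mean = 0.1, baseline_iron_sd = 0, n_deposits = 0,
    calibration_slope = 400, calibration_intercept = 20,
    noise_sd = 0, seed = 3)
  ph <- generate_mri_phantom(cfg)
  inside <- ph$truth$tumor_mask
  te_s <- cfg$echo_times / 1000
  for (e in seq_along(te_s)) {
    expected <- cfg$s0 * exp(-60 * te_s[e])
    expect_true(all(abs(ph$series$stack[, , e][inside] - expected) < 1e-9))
  }
  expect_equal(1000 / 60, 16.6667, tolerance = 1e-4)
})

test_that("phantom seed contract: same seed identical, new seed new layout", {
  cfg1 <- mri_phantom_config(grid_rows = 96, grid_cols = 96,
    tumor_radius = 40, n_deposits = 12, seed = 1)
  ph_a <- generate_mri_phantom(cfg1)
  ph_b <- generate_mri_phantom(cfg1)
  expect_identical(ph_a$series$stack, ph_b$series$stack)
  expect_identical(ph_a$truth$deposits, ph_b$truth$deposits)

  cfg2 <- mri_phantom_config(grid_rows = 96, grid_cols = 96,
    tumor_radius = 40, n_deposits = 12, seed = 2)
  ph_c <- generate_mri_phantom(cfg2)
  expect_equal(nrow(ph_c$truth$deposits), nrow(ph_a$truth$deposits))
  expect_false(identical(ph_a$truth$deposits$centroid_row,
                         ph_c$truth$deposits$centroid_row))
})

test_that("deposits sit inside the tumor margin band, disjoint", {
  cfg <- mri_phantom_config(grid_rows = 128, grid_cols = 128,
    tumor_radius = 50, n_deposits = 25, margin_band = 0.5, seed = 5)
  ph <- generate_mri_phantom(cfg)
  dp <- ph$truth$deposit_pixels
  expect_true(all(ph$truth$tumor_mask[cbind(dp$row, dp$col)]))
  # pixel sets disjoint
  expect_equal(anyDuplicated(dp[, c("row", "col")]), 0)
  # deposit centers confined to the peripheral band
  ctr <- (128 + 1) / 2
  d <- sqrt((ph$truth$deposits$centroid_row - ctr)^2 +
            (ph$truth$deposits$centroid_col - ctr)^2)
  expect_true(all(d >= (1 - cfg$margin_band) * cfg$tumor_radius -
                    max(sqrt(ph$truth$deposits$pixel_count)) - 1))
})

test_that("noiseless signal is exactly log-linear in TE", {
  ph <- generate_mri_phantom(mri_phantom_config(grid_rows = 64, grid_cols = 64,
    tumor_radius = 28, n_deposits = 6, noise_sd = 0, seed = 11))
  te <- ph$series$echo_times
  idx <- which(ph$truth$tumor_mask)[seq(1, 400, by = 7)]
  y <- matrix(ph$series$stack, 64 * 64, length(te))[idx, ]
  ly <- log(y)
  # residuals of an exact line through the first two echoes
  slope <- (ly[, 2] - ly[, 1]) / (te[2] - te[1])
  pred <- ly[, 1] + outer(slope, te - te[1])
  expect_lt(max(abs(pred - ly) / abs(ly)), 1e-10)
})

test_that("invalid MRI phantom configurations are rejected", {
  expect_error(mri_phantom_config(echo_times = numeric(0)), "echo_times")
  expect_error(mri_phantom_config(echo_times = c(3, 2, 1)), "echo_times")
  expect_error(mri_phantom_config(tumor_radius = 5, n_deposits = 100,
                                  deposit_area_mean = 10), "deposit area")
  expect_error(mri_phantom_config(baseline_iron_mean = 0.2), "baseline")
  expect_error(mri_phantom_config(noise_sd = -1), "noise_sd")
})

test_that("histology phantom reproduces ~14 iron+ macrophages per deposit", {
  hp <- generate_histo_phantom(histo_phantom_config(n_deposits = 20,
    cells_per_deposit_mean = 14, seed = 7))
  expect_equal(nrow(hp$truth$deposits), 20)
  # Poisson SEM at n = 20 deposits: sqrt(14/20) ~ 0.84; 14 +/- 3 is generous
  expect_lt(abs(mean(hp$truth$deposits$n_cells) - 14), 3)
  # all deposit cells iron-positive
  dep_cells <- hp$truth$cell_table[!is.na(hp$truth$cell_table$deposit_id), ]
  expect_true(all(dep_cells$iron))
})

test_that("marker frequencies follow the configured polarization split", {
  hp <- generate_histo_phantom(histo_phantom_config(n_deposits = 0,
    n_background_macrophages = 10000, p_m1 = 0.42, p_m2 = 0.58,
    p_double = 0, p_iron_background = 0, seed = 21))
  ct <- hp$truth$cell_table
  expect_equal(nrow(ct), 10000)
  expect_lt(abs(mean(ct$aif1) - 0.42), 0.015)
  expect_true(all(ct$aif1 | ct$cd206))   # p_m1 + p_m2 = 1, none double
  expect_false(any(ct$aif1 & ct$cd206))
})

test_that("no deposits and zero background iron gives an iron-free raster", {
  hp <- generate_histo_phantom(histo_phantom_config(n_deposits = 0,
    n_background_macrophages = 200, p_iron_background = 0, seed = 2))
  expect_equal(sum(hp$raster$pixels == 2L), 0)
  expect_false(any(hp$truth$cell_table$iron))
})

test_that("histology phantom rejects sections too small for the deposits", {
  expect_error(histo_phantom_config(section_rows = 300, section_cols = 300,
                                    n_deposits = 50), "too small")
  expect_error(histo_phantom_config(p_m1 = 1.2), "probabilities")
  expect_error(histo_phantom_config(p_m1 = 0.2, p_m2 = 0.2, p_double = 0.3),
               "marker probabilities")
})

test_that("histology phantom is reproducible under a fixed seed", {
  a <- generate_histo_phantom(histo_phantom_config(seed = 4))
  b <- generate_histo_phantom(histo_phantom_config(seed = 4))
  expect_identical(a$raster$pixels, b$raster$pixels)
  expect_identical(a$truth$cell_table, b$truth$cell_table)
})
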