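test_that("exact standards recover the calibration line", {
  std <- data.frame(conc_mg_g = c(0, 0.1, 0.2, 0.3),
                    r2star_s = c(20, 60, 100, 140))
  cal <- fit_calibration(std)
  expect_equal(cal$slope, 400, tolerance = 1e-12)
  expect_equal(cal$intercept, 20, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
})

test_that("two exact points recover an arbitrary line", {
  for (mb in list(c(250, 10), c(617.3, 33.8))) {
    std <- data.frame(conc_mg_g = c(0, 0.3),
                      r2star_s = c(mb[2], mb[2] + 0.3 * mb[1]))
    cal <- fit_calibration(std)
    expect_equal(cal$slope, mb[1], tolerance = 1e-10)
    expect_equal(cal$intercept, mb[2], tolerance = 1e-10)
  }
})

test_that("noisy standards recover the slope within 5%, matching the
           closed-form normal equations", {
  set.seed(31)
  conc <- rep(c(0, 0.1, 0.2, 0.3), each = 20)
  r2 <- 400 * conc + 20 + rnorm(length(conc), 0, 2)
  cal <- fit_calibration(data.frame(conc_mg_g = conc, r2star_s = r2))
  expect_lt(abs(cal$slope - 400) / 400, 0.05)
  # independent closed-form least-squares solution
  m_hat <- sum((conc - mean(conc)) * (r2 - mean(r2))) /
           sum((conc - mean(conc))^2)
  b_hat <- mean(r2) - m_hat * mean(conc)
  expect_equal(cal$slope, m_hat, tolerance = 1e-10)
  expect_equal(cal$intercept, b_hat, tolerance = 1e-10)
})

test_that("degenerate calibration designs are rejected", {
  expect_error(fit_calibration(data.frame(conc_mg_g = c(0.1, 0.1),
                                          r2star_s = c(40, 60))),
               "degenerate")
  expect_error(fit_calibration(data.frame(conc_mg_g = c(0, 0.3),
                                          r2star_s = c(140, 20))),
               "calibration-failure")
})

make_r2map <- function(r2_values) {
  m <- matrix(r2_values, 2, 2)
  structure(list(r2star = m, s0 = m * 0 + 100, rss = m * 0,
                 fit_ok = matrix(TRUE, 2, 2), pixel_size = 0.1),
            class = "r2star_map")
}

test_that("calibration inversion and clamping follow the line", {
  cal <- list(slope = 400, intercept = 20, conc_range = c(0, 0.3))
  fe <- apply_calibration(make_r2map(c(80, 10, 20, 500)), cal)
  expect_equal(fe$iron[1, 1], 0.15, tolerance = 1e-12)  # (80-20)/400
  expect_equal(fe$iron[2, 1], 0)                        # below intercept
  expect_equal(fe$iron[1, 2], 0)                        # exactly intercept
  expect_equal(fe$iron[2, 2], 0.3)                      # clamped high
})

test_that("calibration round trip is the identity on the calibrated range", {
  cal <- list(slope = 321.5, intercept = 17.2, conc_range = c(0, 0.3))
  conc <- seq(0, 0.3, length.out = 4)
  fe <- apply_calibration(make_r2map(cal$slope * conc + cal$intercept), cal)
  expect_equal(as.vector(fe$iron), conc, tolerance = 1e-12)
})

test_that("noiseless phantom maps back to the planted iron map", {
  ph <- generate_mri_phantom(mri_phantom_config(grid_rows = 96,
    grid_cols = 96, tumor_radius = 40, n_deposits = 8, noise_sd = 0,
    seed = 13))
  fit <- fit_monoexponential(ph$series, mask = ph$truth$tumor_mask)
  fe <- apply_calibration(fit, c(ph$truth$calibration,
                                 list(conc_range = c(0, 0.3))),
                          mask = ph$truth$tumor_mask)
  inside <- ph$truth$tumor_mask
  expect_lt(max(abs(fe$iron[inside] - ph$truth$iron_map[inside])), 1e-6)
})

test_that("stratification threshold is the range midpoint, boundary high", {
  fe <- fe_map(matrix(c(0.05, 0.15, 0.2, 0.149), 2, 2),
               matrix(TRUE, 2, 2), pixel_size = 0.1)
  fe <- stratify(fe)
  expect_equal(fe$high_threshold, 0.15)
  expect_equal(fe$strata[1, 1], "low")
  expect_equal(fe$strata[2, 1], "high")    # exactly at threshold -> high
  expect_equal(fe$strata[1, 2], "high")
  expect_equal(fe$strata[2, 2], "low")
})

test_that("strata partition the raster", {
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  fe <- stratify(fe_map(matrix(c(0, 0.2, 0.1, 0.3), 2, 2), mask, 0.1))
  expect_true(all(fe$strata %in% c("low", "high", "undefined")))
  expect_equal(sum(fe$strata == "undefined"), 1)
  expect_equal(sum(fe$strata != "undefined"), sum(mask))
})

test_that("an all-zero map has no high-iron pixels", {
  fe <- stratify(fe_map(matrix(0, 4, 4), matrix(TRUE, 4, 4), 0.1))
  expect_equal(sum(fe$strata == "high"), 0)
})
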