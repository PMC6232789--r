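#' Configuration for the synthetic MGE tumor phantom
#'
#' Builds a validated configuration for [generate_mri_phantom()]. The phantom
#' emulates a single axial tumor cross section imaged with a 2D
#' multi-gradient-echo (MGE) sequence: a low-iron tumor bulk plus a number of
#' rare, compact, high-iron deposits (macrophage iron colonies) confined to a
#' peripheral margin band of the tumor disc.
#'
#' @param grid_rows,grid_cols Raster dimensions in pixels.
#' @param pixel_size In-plane pixel size in mm (default 0.1).
#' @param echo_times Echo times in ms, strictly increasing. Default sixteen
#'   evenly spaced 3 ms echoes, TE = 3, 6, ..., 48 ms.
#' @param tumor_radius Tumor disc radius in pixels.
#' @param baseline_iron_mean,baseline_iron_sd Mean and SD (mg iron/g) of the
#'   Gaussian baseline iron field inside the tumor. The baseline is clamped to
#'   stay non-negative and well below `deposit_iron_lo` so that deposits are
#'   the only high-iron structures.
#' @param n_deposits Number of high-iron deposits to plant.
#' @param deposit_area_mean Mean deposit area in pixels; per-deposit target
#'   areas are Poisson-distributed (minimum 1 pixel).
#' @param deposit_iron_lo,deposit_iron_hi Range (mg/g) from which each
#'   deposit's iron concentration is drawn uniformly.
#' @param calibration_slope,calibration_intercept Linear R2*-iron relation
#'   R2* = m C + b used to synthesize the signal (m in s^-1 per mg/g, b in
#'   s^-1).
#' @param s0 Signal amplitude at TE = 0 (arbitrary units).
#' @param noise_sd Additive Gaussian noise SD as a fraction of `s0`.
#' @param rician If `TRUE`, magnitude (Rician) noise is simulated instead of
#'   the high-SNR additive-Gaussian approximation.
#' @param margin_band Fraction of the tumor radius forming the peripheral
#'   annulus in which deposits are placed (deposits sit at radial distance
#'   >= (1 - margin_band) * tumor_radius).
#' @param min_separation Minimum distance (pixels) between deposit centers.
#'   The default (`NULL`) chooses a separation that guarantees deposits can
#'   never touch, so connected-component counts recover the planted count.
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce bit-identical phantoms.
#'
#' @return An object of class `mri_phantom_config` (a named list).
#' @seealso [generate_mri_phantom()]
#' @export
mri_phantom_config <- function(grid_rows = 256L, grid_cols = 256L,
                               pixel_size = 0.1,
                               echo_times = seq(3, 48, by = 3),
                               tumor_radius = 50,
                               baseline_iron_mean = 0.03,
                               baseline_iron_sd = 0.01,
                               n_deposits = 30L,
                               deposit_area_mean = 4,
                               deposit_iron_lo = 0.15,
                               deposit_iron_hi = 0.30,
                               calibration_slope = 400,
                               calibration_intercept = 20,
                               s0 = 100,
                               noise_sd = 0.02,
                               rician = FALSE,
                               margin_band = 0.5,
                               min_separation = NULL,
                               seed = 1L) {
  cfg <- list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
              pixel_size = pixel_size, echo_times = as.numeric(echo_times),
              tumor_radius = tumor_radius,
              baseline_iron_mean = baseline_iron_mean,
              baseline_iron_sd = baseline_iron_sd,
              n_deposits = as.integer(n_deposits),
              deposit_area_mean = deposit_area_mean,
              deposit_iron_lo = deposit_iron_lo,
              deposit_iron_hi = deposit_iron_hi,
              calibration_slope = calibration_slope,
              calibration_intercept = calibration_intercept,
              s0 = s0, noise_sd = noise_sd, rician = isTRUE(rician),
              margin_band = margin_band, min_separation = min_separation,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_mri_phantom_config(cfg)
  class(cfg) <- "mri_phantom_config"
  cfg
}

validate_mri_phantom_config <- function(cfg) {
  if (length(cfg$echo_times) == 0)
    stop("configuration error: 'echo_times' must not be empty", call. = FALSE)
  if (any(cfg$echo_times <= 0) || any(diff(cfg$echo_times) <= 0))
    stop("configuration error: 'echo_times' must be positive and strictly increasing",
         call. = FALSE)
  if (cfg$baseline_iron_mean < 0 || cfg$baseline_iron_mean >= cfg$deposit_iron_lo)
    stop("configuration error: need 0 <= baseline_iron_mean < deposit_iron_lo",
         call. = FALSE)
  if (!(cfg$deposit_iron_lo <= cfg$deposit_iron_hi && cfg$deposit_iron_hi <= 0.3))
    stop("configuration error: need deposit_iron_lo <= deposit_iron_hi <= 0.3",
         call. = FALSE)
  if (cfg$n_deposits < 0)
    stop("configuration error: 'n_deposits' must be >= 0", call. = FALSE)
  if (cfg$noise_sd < 0)
    stop("configuration error: 'noise_sd' must be >= 0", call. = FALSE)
  if (cfg$margin_band <= 0 || cfg$margin_band > 1)
    stop("configuration error: 'margin_band' must be in (0, 1]", call. = FALSE)
  tumor_area <- pi * cfg$tumor_radius^2
  if (cfg$n_deposits * cfg$deposit_area_mean > tumor_area)
    stop("configuration error: requested total deposit area exceeds tumor area",
         call. = FALSE)
  invisible(cfg)
}

# Grow a compact blob of `target` pixels by a seeded random walk from
# (cr, cc), constrained to a disc of radius r_max around the seed and to the
# grid. Returns a two-column matrix of (row, col).
grow_blob <- function(cr, cc, target, r_max, nrow, ncol) {
  pix <- matrix(c(cr, cc), 1, 2)
  pos <- c(cr, cc)
  steps <- matrix(c(-1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L), 4, 2, byrow = TRUE)
  guard <- 0L
  while (nrow(pix) < target) {
    guard <- guard + 1L
    if (guard > 10000L) break
    cand <- pos + steps[sample.int(4L, 1L), ]
    if (cand[1] < 1 || cand[1] > nrow || cand[2] < 1 || cand[2] > ncol) next
    if ((cand[1] - cr)^2 + (cand[2] - cc)^2 > r_max^2) next
    pos <- cand
    if (!any(pix[, 1] == pos[1] & pix[, 2] == pos[2]))
      pix <- rbind(pix, pos)
  }
  pix
}

# Rejection-sample n centers in the annulus [r_lo, r_hi[i]] around (cr, cc).
# The required center-to-center distance between deposits i and j is
# sep[i] + sep[j] (per-pair, so small deposits pack densely while still
# never touching); scalar `sep` recycles, and a scalar r_hi does too.
sample_deposit_centers <- function(n, cr, cc, r_lo, r_hi, sep) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  sep <- rep_len(sep, n)
  r_hi <- rep_len(r_hi, n)
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  max_tries <- 5000L * n
  while (placed < n) {
    i <- placed + 1L
    tries <- tries + 1L
    if (tries > max_tries)
      stop("configuration error: could not place deposits with the requested ",
           "separation inside the margin band; reduce n_deposits or ",
           "min_separation", call. = FALSE)
    r <- sqrt(stats::runif(1, r_lo^2, r_hi[i]^2))
    th <- stats::runif(1, 0, 2 * pi)
    p <- round(c(cr + r * sin(th), cc + r * cos(th)))
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - p[1])^2 +
            (centers[seq_len(placed), 2] - p[2])^2
      if (any(d2 < (sep[seq_len(placed)] + sep[i])^2)) next
    }
    placed <- i
    centers[placed, ] <- p
  }
  centers
}

#' Generate a synthetic multi-gradient-echo tumor phantom
#'
#' Simulates an MGE magnitude image stack from a known per-pixel iron map.
#' The iron map is a Gaussian baseline field inside a central tumor disc plus
#' `n_deposits` compact high-iron blobs (grown by seeded random walk to a
#' Poisson target area) confined to the peripheral margin band. Per pixel,
#' the relaxation rate follows the linear calibration R2* = m C + b and the
#' signal decays as S(TE) = S0 exp(-TE R2*) (TE converted from ms to s),
#' with additive zero-mean Gaussian noise of SD `noise_sd * s0` (or Rician
#' magnitude noise when `rician = TRUE`). Pixels outside the tumor contain
#' noise only. Magnitudes are clamped at zero.
#'
#' @param config An [mri_phantom_config()].
#' @return A list with components:
#'   \describe{
#'     \item{series}{An [mge_series()] with the noisy echo stack.}
#'     \item{truth}{Ground truth: `iron_map` (mg/g matrix), `tumor_mask`
#'       (logical matrix), `deposits` (per-deposit summary data frame),
#'       `deposit_pixels` (data frame of deposit_id, row, col, iron_mg_g),
#'       `r2star` (s^-1 matrix), and the calibration used.}
#'   }
#' @examples
#' ph <- generate_mri_phantom(mri_phantom_config(grid_rows = 64, grid_cols = 64,
#'   tumor_radius = 24, n_deposits = 5, seed = 1))
#' nrow(ph$truth$deposits)
#' @export
generate_mri_phantom <- function(config) {
  stopifnot(inherits(config, "mri_phantom_config"))
  validate_mri_phantom_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)

  nr <- config$grid_rows; nc <- config$grid_cols
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  tumor <- disc_mask(nr, nc, cr, cc, config$tumor_radius)

  # Baseline field: clamped so no baseline pixel approaches the deposit range.
  baseline_cap <- 0.8 * config$deposit_iron_lo
  iron <- matrix(0, nr, nc)
  n_t <- sum(tumor)
  iron[tumor] <- pmin(pmax(stats::rnorm(n_t, config$baseline_iron_mean,
                                        config$baseline_iron_sd), 0),
                      baseline_cap)

  n_dep <- config$n_deposits
  targets <- if (n_dep > 0) pmax(1L, stats::rpois(n_dep, config$deposit_area_mean))
             else integer(0)
  r_max <- pmax(1L, ceiling(sqrt(targets)))
  # place large deposits first; per-pair separation r_i + r_j + 2 guarantees
  # blobs are disjoint and non-adjacent under 8-connectivity
  ord <- order(r_max, decreasing = TRUE)
  targets <- targets[ord]; r_max <- r_max[ord]
  sep <- if (!is.null(config$min_separation)) config$min_separation / 2
         else r_max + 1

  r_hi <- config$tumor_radius - r_max - 1
  r_lo <- max(0, (1 - config$margin_band) * config$tumor_radius)
  if (n_dep > 0 && any(r_hi <= r_lo))
    stop("configuration error: margin band too narrow for the deposit size",
         call. = FALSE)
  centers <- sample_deposit_centers(n_dep, cr, cc, r_lo, r_hi, sep)

  dep_pix <- vector("list", n_dep)
  dep_iron <- if (n_dep > 0) stats::runif(n_dep, config$deposit_iron_lo,
                                          config$deposit_iron_hi) else numeric(0)
  for (d in seq_len(n_dep)) {
    pix <- grow_blob(centers[d, 1], centers[d, 2], targets[d], r_max[d], nr, nc)
    iron[cbind(pix[, 1], pix[, 2])] <- dep_iron[d]
    dep_pix[[d]] <- data.frame(deposit_id = d, row = pix[, 1], col = pix[, 2],
                               iron_mg_g = dep_iron[d])
  }
  deposit_pixels <- if (n_dep > 0) do.call(rbind, dep_pix)
                    else data.frame(deposit_id = integer(0), row = integer(0),
                                    col = integer(0), iron_mg_g = numeric(0))
  deposits <- if (n_dep > 0) {
    data.frame(deposit_id = seq_len(n_dep),
               centroid_row = vapply(dep_pix, function(p) mean(p$row), 0),
               centroid_col = vapply(dep_pix, function(p) mean(p$col), 0),
               pixel_count = vapply(dep_pix, nrow, 0L),
               iron_mg_g = dep_iron)
  } else {
    data.frame(deposit_id = integer(0), centroid_row = numeric(0),
               centroid_col = numeric(0), pixel_count = integer(0),
               iron_mg_g = numeric(0))
  }

  r2s <- matrix(0, nr, nc)
  r2s[tumor] <- config$calibration_slope * iron[tumor] + config$calibration_intercept

  te_s <- config$echo_times / 1000
  n_echo <- length(te_s)
  stack <- array(0, dim = c(nr, nc, n_echo))
  decay <- exp(-outer(as.vector(r2s[tumor]), te_s))
  sig_sd <- config$noise_sd * config$s0
  for (e in seq_len(n_echo)) {
    plane <- matrix(0, nr, nc)
    plane[tumor] <- config$s0 * decay[, e]
    if (sig_sd > 0) {
      if (config$rician) {
        plane <- sqrt((plane + stats::rnorm(nr * nc, 0, sig_sd))^2 +
                      stats::rnorm(nr * nc, 0, sig_sd)^2)
      } else {
        plane <- pmax(plane + stats::rnorm(nr * nc, 0, sig_sd), 0)
      }
    }
    stack[, , e] <- plane
  }

  series <- mge_series(stack, config$echo_times, config$pixel_size)
  truth <- list(iron_map = iron, tumor_mask = tumor,
                deposits = deposits, deposit_pixels = deposit_pixels,
                r2star = r2s,
                calibration = list(slope = config$calibration_slope,
                                   intercept = config$calibration_intercept))
  list(series = series, truth = truth)
}
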