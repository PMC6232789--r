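#' Configuration for the synthetic histology section phantom
#'
#' Builds a validated configuration for [generate_histo_phantom()]. The
#' phantom emulates a Prussian-blue-stained tumor cross section: colonies of
#' iron-positive macrophages (deposits) clustered near the peripheral tumor
#' margin, plus a diffuse background population of macrophages carrying
#' polarization marker labels (pan-macrophage CD68/F4-80, M1-like AIF1,
#' M2-like CD206) at configurable frequencies.
#'
#' @param section_rows,section_cols Raster dimensions in pixels.
#' @param microns_per_pixel Full-resolution pixel pitch in micrometers.
#' @param n_deposits Number of iron-positive macrophage colonies.
#' @param cells_per_deposit_mean Mean iron-positive cells per deposit
#'   (Poisson, minimum 1; default 14).
#' @param n_background_macrophages Number of diffuse macrophages outside
#'   deposits.
#' @param p_m1 Probability a macrophage is AIF1-positive (M1-like).
#' @param p_m2 Probability a macrophage is CD206-positive (M2-like).
#' @param p_double Probability a macrophage carries both markers; must not
#'   exceed `p_m1` or `p_m2`, and `p_m1 + p_m2 - p_double` must be <= 1.
#' @param p_iron_background Probability a background (non-deposit)
#'   macrophage is iron-positive.
#' @param deposit_margin_band Fraction of the tumor radius forming the
#'   peripheral band where deposits are placed.
#' @param deposit_spread_um SD (micrometers) of the Gaussian scatter of cell
#'   centers around their deposit center.
#' @param cell_radius_um Radius (micrometers) of the stained disc painted
#'   per iron-positive cell in the label raster.
#' @param min_separation_um Minimum distance between deposit centers
#'   (micrometers); keeps colonies resolvable after downsampling.
#' @param seed Integer seed.
#' @return An object of class `histo_phantom_config`.
#' @export
histo_phantom_config <- function(section_rows = 2200L, section_cols = 2200L,
                                 microns_per_pixel = 2,
                                 n_deposits = 20L,
                                 cells_per_deposit_mean = 14,
                                 n_background_macrophages = 500L,
                                 p_m1 = 0.42, p_m2 = 0.58, p_double = 0,
                                 p_iron_background = 0.004,
                                 deposit_margin_band = 0.35,
                                 deposit_spread_um = 30,
                                 cell_radius_um = 8,
                                 min_separation_um = 500,
                                 seed = 1L) {
  cfg <- list(section_rows = as.integer(section_rows),
              section_cols = as.integer(section_cols),
              microns_per_pixel = microns_per_pixel,
              n_deposits = as.integer(n_deposits),
              cells_per_deposit_mean = cells_per_deposit_mean,
              n_background_macrophages = as.integer(n_background_macrophages),
              p_m1 = p_m1, p_m2 = p_m2, p_double = p_double,
              p_iron_background = p_iron_background,
              deposit_margin_band = deposit_margin_band,
              deposit_spread_um = deposit_spread_um,
              cell_radius_um = cell_radius_um,
              min_separation_um = min_separation_um,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_histo_phantom_config(cfg)
  class(cfg) <- "histo_phantom_config"
  cfg
}

validate_histo_phantom_config <- function(cfg) {
  probs <- c(cfg$p_m1, cfg$p_m2, cfg$p_double, cfg$p_iron_background)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$p_double > min(cfg$p_m1, cfg$p_m2) ||
      cfg$p_m1 + cfg$p_m2 - cfg$p_double > 1 + 1e-12)
    stop("configuration error: inconsistent marker probabilities", call. = FALSE)
  if (cfg$cells_per_deposit_mean <= 0)
    stop("configuration error: 'cells_per_deposit_mean' must be > 0",
         call. = FALSE)
  if (cfg$n_deposits < 0)
    stop("configuration error: 'n_deposits' must be >= 0", call. = FALSE)
  if (cfg$deposit_margin_band <= 0 || cfg$deposit_margin_band > 1)
    stop("configuration error: 'deposit_margin_band' must be in (0, 1]",
         call. = FALSE)
  tumor_r_px <- 0.45 * min(cfg$section_rows, cfg$section_cols)
  band_area_um2 <- pi * (tumor_r_px^2 -
                         ((1 - cfg$deposit_margin_band) * tumor_r_px)^2) *
                   cfg$microns_per_pixel^2
  # hexagonal-packing bound on how many separated centers fit the band
  if (cfg$n_deposits > 0 &&
      cfg$n_deposits > 2 * band_area_um2 / (sqrt(3) * cfg$min_separation_um^2))
    stop("configuration error: section too small for the requested number ",
         "of separated deposits", call. = FALSE)
  invisible(cfg)
}

# Sample marker flags for n macrophages: categories double-positive,
# M1-only, M2-only, double-negative with the configured probabilities.
sample_marker_flags <- function(n, p_m1, p_m2, p_double) {
  p <- c(double = p_double, m1 = p_m1 - p_double, m2 = p_m2 - p_double)
  p <- c(p, none = max(0, 1 - sum(p)))
  cat_idx <- sample.int(4L, n, replace = TRUE, prob = p)
  data.frame(aif1 = cat_idx %in% c(1L, 2L), cd206 = cat_idx %in% c(1L, 3L))
}

# Paint discs of radius r_px around centers (row, col) into raster with
# value `value`; returns the raster.
paint_discs <- function(raster, centers, r_px, value) {
  if (nrow(centers) == 0) return(raster)
  nr <- nrow(raster); nc <- ncol(raster)
  off <- expand.grid(dr = -ceiling(r_px):ceiling(r_px),
                     dc = -ceiling(r_px):ceiling(r_px))
  off <- off[off$dr^2 + off$dc^2 <= r_px^2, , drop = FALSE]
  for (i in seq_len(nrow(centers))) {
    rr <- round(centers[i, 1]) + off$dr
    cc <- round(centers[i, 2]) + off$dc
    keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    raster[cbind(rr[keep], cc[keep])] <- value
  }
  raster
}

#' Generate a synthetic histology section with known ground truth
#'
#' Produces (i) a label raster at full resolution encoding background (0),
#' tumor tissue (1), and iron-positive pixels (2, standing in for Prussian
#' blue) and (ii) a ground-truth cell table. Deposit cells are all
#' iron-positive and clustered (Gaussian scatter) around deposit centers
#' placed with a minimum separation in the peripheral margin band of the
#' tumor disc; background macrophages are spread over the whole tumor and
#' are iron-positive with probability `p_iron_background`. Every macrophage
#' is CD68/F4-80-positive; AIF1/CD206 flags follow the configured
#' probabilities.
#'
#' @param config A [histo_phantom_config()].
#' @return A list with `raster` (a `histo_raster` label raster) and `truth`
#'   containing `cell_table` (cell_id, x_um, y_um, cd68, f480, aif1, cd206,
#'   iron, deposit_id), `deposits` (per-deposit id, center, cell count) and
#'   `tumor_mask`.
#' @export
generate_histo_phantom <- function(config) {
  stopifnot(inherits(config, "histo_phantom_config"))
  validate_histo_phantom_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)

  nr <- config$section_rows; nc <- config$section_cols
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  tumor_r <- 0.45 * min(nr, nc)
  tumor <- disc_mask(nr, nc, cr, cc, tumor_r)
  raster <- matrix(0L, nr, nc)
  raster[tumor] <- 1L

  mpp <- config$microns_per_pixel
  min_sep_px <- config$min_separation_um / mpp
  pad_px <- (3 * config$deposit_spread_um + config$cell_radius_um) / mpp
  r_hi <- tumor_r - pad_px
  r_lo <- (1 - config$deposit_margin_band) * tumor_r
  n_dep <- config$n_deposits
  centers <- sample_deposit_centers(n_dep, cr, cc, max(r_lo, 0),
                                    max(r_hi, r_lo + 1), min_sep_px / 2)

  cells <- list()
  dep_counts <- integer(n_dep)
  for (d in seq_len(n_dep)) {
    k <- max(1L, stats::rpois(1, config$cells_per_deposit_mean))
    dep_counts[d] <- k
    sd_px <- config$deposit_spread_um / mpp
    rr <- stats::rnorm(k, centers[d, 1], sd_px)
    cc_ <- stats::rnorm(k, centers[d, 2], sd_px)
    cells[[d]] <- data.frame(row = rr, col = cc_, iron = TRUE, deposit_id = d)
  }
  n_bg <- config$n_background_macrophages
  if (n_bg > 0) {
    r <- sqrt(stats::runif(n_bg, 0, (tumor_r - pad_px)^2))
    th <- stats::runif(n_bg, 0, 2 * pi)
    cells[[n_dep + 1]] <- data.frame(
      row = cr + r * sin(th), col = cc + r * cos(th),
      iron = stats::runif(n_bg) < config$p_iron_background,
      deposit_id = NA_integer_)
  }
  cells <- if (length(cells)) do.call(rbind, cells)
           else data.frame(row = numeric(0), col = numeric(0),
                           iron = logical(0), deposit_id = integer(0))
  n_cells <- nrow(cells)
  flags <- sample_marker_flags(n_cells, config$p_m1, config$p_m2,
                               config$p_double)
  cell_table <- data.frame(cell_id = seq_len(n_cells),
                           x_um = cells$col * mpp, y_um = cells$row * mpp,
                           cd68 = rep(TRUE, n_cells),
                           f480 = rep(TRUE, n_cells),
                           aif1 = flags$aif1, cd206 = flags$cd206,
                           iron = cells$iron,
                           deposit_id = cells$deposit_id)

  iron_centers <- as.matrix(cells[cells$iron, c("row", "col"), drop = FALSE])
  raster <- paint_discs(raster, iron_centers, config$cell_radius_um / mpp, 2L)

  deposits <- if (n_dep > 0) {
    data.frame(deposit_id = seq_len(n_dep),
               center_row = centers[, 1], center_col = centers[, 2],
               n_cells = dep_counts)
  } else {
    data.frame(deposit_id = integer(0), center_row = numeric(0),
               center_col = numeric(0), n_cells = integer(0))
  }
  list(raster = histo_raster(raster, mpp, mode = "label",
                             provenance = "phantom"),
       truth = list(cell_table = cell_table, deposits = deposits,
                    tumor_mask = tumor))
}

#' Render a label histology raster to RGB
#'
#' Maps the phantom's label classes to stain-like colors: background white,
#' tissue nuclear-fast-red-like pink, iron-positive pixels Prussian-blue-like
#' blue. Intended for testing the color-based iron detector and for
#' visualization.
#'
#' @param histo A label-mode `histo_raster`.
#' @return An RGB-mode `histo_raster` (rows x cols x 3 array in \[0, 1\]).
#' @export
render_histo_rgb <- function(histo) {
  stopifnot(inherits(histo, "histo_raster"), histo$mode == "label")
  lab <- histo$pixels
  cols <- rbind(background = c(1, 1, 1),
                tissue = c(0.93, 0.70, 0.75),
                iron = c(0.10, 0.15, 0.75))
  rgb <- array(0, dim = c(nrow(lab), ncol(lab), 3))
  for (ch in 1:3) {
    plane <- matrix(cols["background", ch], nrow(lab), ncol(lab))
    plane[lab == 1L] <- cols["tissue", ch]
    plane[lab == 2L] <- cols["iron", ch]
    rgb[, , ch] <- plane
  }
  histo_raster(rgb, histo$microns_per_pixel, mode = "rgb",
               provenance = histo$provenance)
}
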