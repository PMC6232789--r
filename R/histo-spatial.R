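#' Histology raster container
#'
#' @param pixels Either a rows x cols x 3 RGB array (values in \[0, 1\] or
#'   \[0, 255\]) or an integer label matrix (0 background, 1 tissue, 2
#'   iron-positive).
#' @param microns_per_pixel Pixel pitch in micrometers (> 0).
#' @param mode `"rgb"` or `"label"`; inferred from `pixels` when missing.
#' @param provenance `"phantom"` or `"file"`.
#' @return An object of class `histo_raster`.
#' @export
histo_raster <- function(pixels, microns_per_pixel,
                         mode = c("auto", "rgb", "label"),
                         provenance = "file") {
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- if (is.array(pixels) && length(dim(pixels)) == 3) "rgb" else "label"
  if (mode == "rgb" && (!is.array(pixels) || length(dim(pixels)) != 3 ||
                        dim(pixels)[3] != 3))
    stop("input error: rgb mode requires a rows x cols x 3 array",
         call. = FALSE)
  if (mode == "label" && !is.matrix(pixels))
    stop("input error: label mode requires a matrix", call. = FALSE)
  if (microns_per_pixel <= 0)
    stop("input error: 'microns_per_pixel' must be > 0", call. = FALSE)
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel,
                 mode = mode, provenance = provenance),
            class = "histo_raster")
}

#' Detect iron-positive (Prussian-blue-like) pixels
#'
#' For RGB rasters a pixel is called iron-positive when its blue chromatic
#' fraction B / (R + G + B) is at least `blue_ratio_threshold` and its
#' luminance falls below the white-background cutoff (unstained slide
#' background is bright and near-achromatic, so it fails both tests). Label
#' rasters bypass the color logic and return the iron class directly.
#'
#' @param histo A `histo_raster`.
#' @param blue_ratio_threshold Chromatic threshold in (0, 1\], default 0.5.
#' @param white_cutoff Luminance (Rec. 709, normalized to \[0, 1\]) above
#'   which a pixel is treated as background, default 0.9.
#' @param iron_class Label value encoding iron in label mode (default 2).
#' @return Logical matrix of iron-positive pixels.
#' @export
detect_iron_pixels <- function(histo, blue_ratio_threshold = 0.5,
                               white_cutoff = 0.9, iron_class = 2L) {
  stopifnot(inherits(histo, "histo_raster"))
  if (histo$mode == "label") return(histo$pixels == iron_class)
  if (histo$mode != "rgb")
    stop("input error: unknown raster mode", call. = FALSE)
  px <- histo$pixels
  if (max(px) > 1) px <- px / 255
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  total <- r + g + b
  ratio <- ifelse(total > 0, b / total, 0)
  lum <- 0.2126 * r + 0.7152 * g + 0.0722 * b
  ratio >= blue_ratio_threshold & lum < white_cutoff
}

#' Downsample a full-resolution binary mask to MRI resolution
#'
#' Pixel averaging over factor x factor tiles produces a density raster
#' whose values are the iron-positive area fraction per MRI-scale pixel;
#' when the raster dimensions are not exact multiples of the factor, the
#' block mean over the largest exact-multiple subgrid is followed by
#' bilinear resampling to the ceiling dimensions.
#'
#' @param mask Logical or 0/1 matrix at full histology resolution.
#' @param factor Per-axis downsampling factor (>= 1); 100 maps a ~1 um/px
#'   scan onto the 0.1 mm MRI grid.
#' @return Numeric matrix with values in \[0, 1\].
#' @examples
#' m <- matrix(0, 40, 40); m[1:10, 1:10] <- 1
#' downsample_to_mri(m, 10)[1, 1]   # 1.0, the fully covered tile
#' @export
downsample_to_mri <- function(mask, factor) {
  assert_matrix_like(mask, "mask")
  factor <- as.integer(factor)
  if (factor < 1) stop("input error: 'factor' must be >= 1", call. = FALSE)
  if (factor > nrow(mask) || factor > ncol(mask))
    stop("input error: 'factor' exceeds the raster dimensions", call. = FALSE)
  m <- (mask != 0) * 1
  nr <- nrow(m); nc <- ncol(m)
  br <- nr %/% factor; bc <- nc %/% factor
  core <- m[seq_len(br * factor), seq_len(bc * factor), drop = FALSE]
  # block mean via row-group then column-group sums
  g_r <- rep(seq_len(br), each = factor)
  g_c <- rep(seq_len(bc), each = factor)
  bm <- rowsum(core, g_r)
  bm <- t(rowsum(t(bm), g_c)) / factor^2
  if (nr %% factor == 0 && nc %% factor == 0) return(bm)
  out_r <- ceiling(nr / factor); out_c <- ceiling(nc / factor)
  out <- EBImage::resize(EBImage::Image(bm), w = out_r, h = out_c)
  pmin(pmax(EBImage::imageData(out), 0), 1)
}

#' Discretize an iron density raster into deposit regions by watershed
#'
#' The density raster (iron-positive area fraction at MRI resolution) is
#' Gaussian-smoothed, thresholded at `min_density` to form the foreground
#' mask of regions containing iron-positive macrophages, and split into
#' discrete deposits by watershed on the smoothed density (touching colonies
#' separate at density valleys). Regions smaller than `min_area` are
#' dropped; surviving regions are relabeled deterministically by their
#' topmost-then-leftmost pixel.
#'
#' @param density Numeric matrix in \[0, 1\] (see [downsample_to_mri()]).
#' @param smoothing_sigma Gaussian smoothing SD in low-resolution pixels
#'   (default 0.5, matched to deposits spanning about one MRI-scale pixel;
#'   0 disables smoothing).
#' @param min_density Foreground threshold on the smoothed density
#'   (default 0.02).
#' @param min_area Minimum region size in low-resolution pixels (default 1).
#' @param tolerance Watershed merge tolerance on the smoothed density
#'   (minimum peak-to-saddle height separating two deposits; default 0.01).
#' @return Integer label matrix (0 = background).
#' @export
watershed_deposits <- function(density, smoothing_sigma = 0.5,
                               min_density = 0.02, min_area = 1,
                               tolerance = 0.01) {
  assert_matrix_like(density, "density")
  if (any(density < 0 | density > 1))
    stop("input error: density values must lie in [0, 1]", call. = FALSE)
  sm <- if (smoothing_sigma > 0)
          EBImage::imageData(EBImage::gblur(EBImage::Image(density),
                                            sigma = smoothing_sigma))
        else density
  fg <- sm >= min_density
  if (!any(fg)) return(matrix(0L, nrow(density), ncol(density)))
  surf <- sm * fg
  lab <- EBImage::imageData(EBImage::watershed(EBImage::Image(surf),
                                               tolerance = tolerance, ext = 2))
  lab[!fg] <- 0
  relabeled <- finalize_labeling(matrix(as.integer(lab), nrow(lab), ncol(lab)),
                                 min_pixels = min_area, pixel_size = 1,
                                 connectivity = 8)
  relabeled$labels
}

#' Count iron-positive cells per watershed deposit region
#'
#' Maps full-resolution cell centroids (micrometers) into the low-resolution
#' deposit frame and assigns each iron-positive cell to the deposit label
#' under its centroid. Cells falling on background are counted as
#' unassigned; cells outside the raster are skipped and counted as warnings.
#'
#' @param deposits Integer label matrix from [watershed_deposits()].
#' @param cells Data frame with `x_um`, `y_um` and logical `iron` (a phantom
#'   `cell_table` works directly); only iron-positive rows are assigned.
#' @param factor Per-axis downsampling factor used to build the deposit
#'   frame.
#' @param microns_per_pixel Full-resolution pixel pitch (um).
#' @param mri_pixel_mm Edge length (mm) of one low-resolution pixel, used
#'   for deposit areas; default `factor * microns_per_pixel / 1000`.
#' @return A list with `deposit_table` (deposit_id, area_lowres_pixels,
#'   area_mm2, iron_cell_count, centroid_row, centroid_col), `n_assigned`,
#'   `n_unassigned` (iron-positive cells over background) and `n_skipped`
#'   (out-of-raster coordinates).
#' @export
count_cells_per_deposit <- function(deposits, cells, factor,
                                    microns_per_pixel,
                                    mri_pixel_mm = factor * microns_per_pixel / 1000) {
  assert_matrix_like(deposits, "deposits")
  stopifnot(all(c("x_um", "y_um", "iron") %in% names(cells)))
  iron_cells <- cells[cells$iron, , drop = FALSE]
  n_iron <- nrow(iron_cells)

  # low-res pixel indices under each centroid (1-based; a tile covers
  # full-resolution positions ((i-1)*factor, i*factor])
  r_lo <- ceiling(iron_cells$y_um / microns_per_pixel / factor)
  c_lo <- ceiling(iron_cells$x_um / microns_per_pixel / factor)
  inside <- r_lo >= 1 & r_lo <= nrow(deposits) &
            c_lo >= 1 & c_lo <= ncol(deposits)
  n_skipped <- sum(!inside)
  if (n_skipped > 0)
    warning(sprintf("%d cell(s) outside the deposit raster were skipped",
                    n_skipped), call. = FALSE)
  lab_under <- rep(0L, n_iron)
  lab_under[inside] <- deposits[cbind(r_lo[inside], c_lo[inside])]

  ids <- sort(unique(deposits[deposits > 0]))
  if (length(ids) == 0) {
    tab <- data.frame(deposit_id = integer(0), area_lowres_pixels = integer(0),
                      area_mm2 = numeric(0), iron_cell_count = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
    return(list(deposit_table = tab, n_assigned = 0L,
                n_unassigned = sum(inside), n_skipped = n_skipped))
  }
  nr <- nrow(deposits)
  nz <- which(deposits > 0)
  lab <- deposits[nz]
  area <- as.integer(tapply(lab, lab, length)[as.character(ids)])
  cr <- tapply(((nz - 1L) %% nr) + 1L, lab, mean)[as.character(ids)]
  cc <- tapply(((nz - 1L) %/% nr) + 1L, lab, mean)[as.character(ids)]
  counts <- vapply(ids, function(id) sum(lab_under == id), 0L)
  tab <- data.frame(deposit_id = ids,
                    area_lowres_pixels = area,
                    area_mm2 = area * mri_pixel_mm^2,
                    iron_cell_count = counts,
                    centroid_row = as.numeric(cr),
                    centroid_col = as.numeric(cc))
  list(deposit_table = tab,
       n_assigned = sum(counts),
       n_unassigned = sum(inside & lab_under == 0L),
       n_skipped = n_skipped)
}

#' Full histology deposit-mapping pipeline for one section
#'
#' Chains iron-pixel detection, downsampling to MRI resolution, watershed
#' discretization and per-deposit cell counting.
#'
#' @param histo A `histo_raster`.
#' @param cells Cell table with `x_um`, `y_um`, `iron` (e.g. from the
#'   phantom ground truth or an external cell caller).
#' @param factor Per-axis downsampling factor; default chosen so one
#'   low-resolution pixel spans `mri_pixel_mm`.
#' @param mri_pixel_mm Target MRI pixel size in mm (default 0.1).
#' @param ... Passed to [watershed_deposits()].
#' @inheritParams detect_iron_pixels
#' @return The [count_cells_per_deposit()] result plus `density`, `labels`
#'   and `iron_mask`.
#' @export
map_histology_deposits <- function(histo, cells,
                                   factor = round(1000 * mri_pixel_mm /
                                                  histo$microns_per_pixel),
                                   mri_pixel_mm = 0.1,
                                   blue_ratio_threshold = 0.5, ...) {
  iron_mask <- detect_iron_pixels(histo,
                                  blue_ratio_threshold = blue_ratio_threshold)
  density <- downsample_to_mri(iron_mask, factor)
  labels <- watershed_deposits(density, ...)
  res <- count_cells_per_deposit(labels, cells, factor,
                                 histo$microns_per_pixel,
                                 mri_pixel_mm = mri_pixel_mm)
  c(res, list(density = density, labels = labels, iron_mask = iron_mask))
}
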