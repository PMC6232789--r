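#' Read and write rasters
#'
#' Dispatches on file extension: `.nii`/`.nii.gz` volumes (double precision,
#' lossless round trip, used for echo stacks and parametric maps),
#' `.tif`/`.tiff` (single- or multi-page, values in \[0, 1\]), `.png`
#' (histology). NIfTI support requires the RNifti package.
#'
#' @param path File path; the extension selects the container.
#' @return For `read_raster`: a matrix (single plane), a 3D array
#'   (multi-page / volume), with pixel size (mm) in attribute `pixel_size`
#'   when the container carries it.
#' @export
read_raster <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: file not found: %s", path), call. = FALSE)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("I/O error: RNifti is required for NIfTI files", call. = FALSE)
    img <- RNifti::readNifti(path)
    out <- array(as.numeric(img), dim = dim(img))
    pd <- RNifti::pixdim(img)
    attr(out, "pixel_size") <- pd[1]
    out
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) == 1) pages[[1]]
    else array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop(sprintf("I/O error: unsupported raster container '.%s' (%s)",
                 ext, path), call. = FALSE)
  }
}

#' @rdname read_raster
#' @param x Matrix or 3D array to write.
#' @param pixel_size Optional pixel size in mm recorded in NIfTI headers.
#' @export
write_raster <- function(x, path, pixel_size = NULL) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("I/O error: RNifti is required for NIfTI files", call. = FALSE)
    if (!is.null(pixel_size))
      attr(x, "pixdim") <- rep(pixel_size, length(dim(x)))
    RNifti::writeNifti(RNifti::asNifti(x, datatype = "double"), path)
  } else if (ext %in% c("tif", "tiff")) {
    if (min(x) < 0 || max(x) > 1)
      stop("I/O error: TIFF output requires values in [0, 1]; use NIfTI for ",
           "unbounded maps", call. = FALSE)
    planes <- if (length(dim(x)) == 3)
                lapply(seq_len(dim(x)[3]), function(i) x[, , i])
              else x
    tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  } else if (ext == "png") {
    png::writePNG(x, path)
  } else {
    stop(sprintf("I/O error: unsupported raster container '.%s' (%s)",
                 ext, path), call. = FALSE)
  }
  invisible(path)
}

#' Write and read an MGE series (volume + sidecar metadata)
#'
#' The echo stack goes to `<prefix>.nii` in double precision and the
#' acquisition metadata (echo times in ms, pixel size in mm, optional TR and
#' flip angle) to `<prefix>.json`, giving a lossless round trip.
#'
#' @param series An [mge_series()].
#' @param prefix Output path prefix (no extension).
#' @export
write_mge_series <- function(series, prefix) {
  stopifnot(inherits(series, "mge_series"))
  write_raster(series$stack, paste0(prefix, ".nii"),
               pixel_size = series$pixel_size)
  meta <- list(echo_times_ms = series$echo_times,
               pixel_size_mm = series$pixel_size,
               tr_s = series$tr, flip_angle_deg = series$flip_angle)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_mge_series
#' @export
read_mge_series <- function(prefix) {
  nii <- paste0(prefix, ".nii")
  meta_path <- paste0(prefix, ".json")
  if (!file.exists(meta_path))
    stop(sprintf("I/O error: missing sidecar metadata: %s", meta_path),
         call. = FALSE)
  stack <- read_raster(nii)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  mge_series(array(stack, dim = dim(stack)),
             echo_times = meta$echo_times_ms,
             pixel_size = meta$pixel_size_mm,
             tr = meta$tr_s, flip_angle = meta$flip_angle_deg)
}

#' Flat key=value run configuration
#'
#' Every stage parameter of the two pipelines lives in one flat, namespaced
#' key=value file so all defaults are auditable in one place. Unknown keys
#' are rejected; values are coerced to the type of the corresponding
#' default. Every pipeline run writes the fully resolved configuration next
#' to its outputs.
#'
#' @return `default_run_config()` returns the named list of defaults.
#' @export
default_run_config <- function() {
  list(mode = "both", seed = 1L, out_dir = "femri-out",
       mri.grid_rows = 128L, mri.grid_cols = 128L, mri.tumor_radius = 52,
       mri.pixel_size = 0.1, mri.n_deposits = 30L, mri.deposit_area_mean = 4,
       mri.noise_sd = 0.02, mri.series_prefix = "",
       cal.standards_csv = "", cal.slope = 400, cal.intercept = 20,
       cal.range_lo = 0, cal.range_hi = 0.3,
       fit.min_signal_fraction = 0.05,
       clusters.connectivity = 8L, clusters.min_pixels = 1L,
       clusters.n_bins = 15L,
       histo.section_rows = 2200L, histo.section_cols = 2200L,
       histo.microns_per_pixel = 2, histo.n_deposits = 20L,
       histo.cells_per_deposit_mean = 14, histo.n_background = 500L,
       histo.p_m1 = 0.42, histo.p_m2 = 0.58, histo.p_double = 0,
       histo.p_iron_background = 0.004, histo.cells_csv = "",
       histo.mri_pixel_mm = 0.1,
       ws.smoothing_sigma = 0.5, ws.min_density = 0.02, ws.min_area = 1L,
       ws.tolerance = 0.01)
}

#' @rdname default_run_config
#' @param path Path to a key=value text file (`#` comments and blank lines
#'   allowed).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: config file not found: %s", path), call. = FALSE)
  defaults <- default_run_config()
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- defaults
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0)
      stop(sprintf("config error: malformed line '%s'", ln), call. = FALSE)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (!key %in% names(defaults))
      stop(sprintf("config error: unknown key '%s'", key), call. = FALSE)
    proto <- defaults[[key]]
    cfg[[key]] <- if (is.integer(proto)) as.integer(val)
                  else if (is.numeric(proto)) as.numeric(val)
                  else val
  }
  cfg
}

#' @rdname default_run_config
#' @param config A run-configuration list.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, format(v, scientific = FALSE, trim = TRUE))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

pipeline_log <- function(fmt, ...) {
  message(sprintf(paste0("[femri] ", fmt), ...))
}

#' Run the end-to-end MRI and/or histology pipelines
#'
#' MRI path: simulate (or load) an MGE series, fit pixel-wise R2*, calibrate
#' to iron concentration, stratify, and quantify by both the whole-ROI
#' distribution and the localized high-iron clusters. Histology path:
#' simulate a section, detect iron-positive pixels, downsample to MRI
#' resolution, discretize deposits by watershed, count cells per deposit,
#' and compute polarization frequencies. All intermediate rasters and
#' tables are written under `out_dir` together with the resolved
#' configuration and a JSON run report; reruns with the same configuration
#' are bit-identical.
#'
#' @param config A run configuration (see [default_run_config()] /
#'   [read_run_config()]).
#' @return Invisibly, the run report (also written as `report.json`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(is.list(config))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(out, "resolved-config.txt"))
  report <- list(seed = config$seed, mode = config$mode)

  if (config$mode %in% c("mri", "both")) {
    pipeline_log("MRI pipeline: simulating phantom (seed %d)", config$seed)
    ph <- generate_mri_phantom(mri_phantom_config(
      grid_rows = config$mri.grid_rows, grid_cols = config$mri.grid_cols,
      tumor_radius = config$mri.tumor_radius,
      pixel_size = config$mri.pixel_size,
      n_deposits = config$mri.n_deposits,
      deposit_area_mean = config$mri.deposit_area_mean,
      noise_sd = config$mri.noise_sd, seed = config$seed))
    series <- ph$series
    mask <- ph$truth$tumor_mask
    utils::write.csv(ph$truth$deposits,
                     file.path(out, "true_deposits.csv"), row.names = FALSE)

    cal <- if (nzchar(config$cal.standards_csv)) {
      pipeline_log("calibrating from standards: %s", config$cal.standards_csv)
      fit_calibration(utils::read.csv(config$cal.standards_csv),
                      conc_range = c(config$cal.range_lo, config$cal.range_hi))
    } else {
      list(slope = config$cal.slope, intercept = config$cal.intercept,
           conc_range = c(config$cal.range_lo, config$cal.range_hi))
    }
    pipeline_log("fitting %d-echo relaxometry over %d ROI pixels",
                 length(series$echo_times), sum(mask))
    fit <- fit_monoexponential(series, mask = mask,
                               min_signal_fraction = config$fit.min_signal_fraction)
    femap <- stratify(apply_calibration(fit, cal, mask = mask))
    dist <- cluster_distribution(femap, n_bins = config$clusters.n_bins,
                                 connectivity = config$clusters.connectivity,
                                 min_pixels = config$clusters.min_pixels)
    high <- high_iron_metrics(femap,
                              connectivity = config$clusters.connectivity,
                              min_pixels = config$clusters.min_pixels)
    if (requireNamespace("RNifti", quietly = TRUE)) {
      write_mge_series(series, file.path(out, "mge_series"))
      iron_out <- femap$iron; iron_out[is.na(iron_out)] <- -1
      write_raster(iron_out, file.path(out, "femap.nii"),
                   pixel_size = femap$pixel_size)
    }
    utils::write.csv(high$clusters$table,
                     file.path(out, "high_clusters.csv"), row.names = FALSE)
    utils::write.csv(data.frame(bin_center = dist$bin_centers,
                                clusters = dist$clusters_per_bin,
                                mean_area_mm2 = dist$mean_cluster_area_per_bin),
                     file.path(out, "roi_distribution.csv"), row.names = FALSE)
    report$mri <- list(n_fitted = sum(fit$fit_ok),
                       median_r2star_s = stats::median(fit$r2star[fit$fit_ok]),
                       median_iron_freq = dist$median_iron_freq,
                       median_iron_size = dist$median_iron_size,
                       n_high_clusters = high$n_high_clusters,
                       mean_high_area_mm2 = if (high$n_high_clusters > 0)
                         mean(high$high_cluster_areas) else NA)
    pipeline_log("MRI pipeline: %d high-iron clusters", high$n_high_clusters)
  }

  if (config$mode %in% c("histo", "both")) {
    pipeline_log("histology pipeline: simulating section (seed %d)",
                 config$seed)
    hp <- generate_histo_phantom(histo_phantom_config(
      section_rows = config$histo.section_rows,
      section_cols = config$histo.section_cols,
      microns_per_pixel = config$histo.microns_per_pixel,
      n_deposits = config$histo.n_deposits,
      cells_per_deposit_mean = config$histo.cells_per_deposit_mean,
      n_background_macrophages = config$histo.n_background,
      p_m1 = config$histo.p_m1, p_m2 = config$histo.p_m2,
      p_double = config$histo.p_double,
      p_iron_background = config$histo.p_iron_background,
      seed = config$seed))
    cells <- if (nzchar(config$histo.cells_csv))
               utils::read.csv(config$histo.cells_csv)
             else hp$truth$cell_table
    res <- map_histology_deposits(hp$raster, cells,
                                  mri_pixel_mm = config$histo.mri_pixel_mm,
                                  smoothing_sigma = config$ws.smoothing_sigma,
                                  min_density = config$ws.min_density,
                                  min_area = config$ws.min_area,
                                  tolerance = config$ws.tolerance)
    utils::write.csv(res$deposit_table,
                     file.path(out, "histo_deposits.csv"), row.names = FALSE)
    utils::write.csv(cells, file.path(out, "cells.csv"), row.names = FALSE)
    pol <- polarization_frequencies(cells)
    iron_freq <- iron_subset_frequencies(cells)
    report$histo <- list(n_deposits = nrow(res$deposit_table),
                         mean_cells_per_deposit =
                           if (nrow(res$deposit_table) > 0)
                             mean(res$deposit_table$iron_cell_count) else NA,
                         f_m1_pct = pol$f_m1_pct, f_m2_pct = pol$f_m2_pct,
                         iron_subsets_pct = iron_freq)
    pipeline_log("histology pipeline: %d deposits recovered",
                 nrow(res$deposit_table))
  }

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(report)
}
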