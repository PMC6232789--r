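#' Fit the linear R2*-iron calibration from reference standards
#'
#' Aqueous iron standards of known concentration establish a linear relation
#' R2* = m C + b between the effective transverse relaxation rate and iron
#' concentration; the fitted line converts R2* maps into parametric iron
#' (FeMRI) maps.
#'
#' @param standards Data frame with columns `conc_mg_g` (mg iron/g) and
#'   `r2star_s` (s^-1); at least two distinct concentrations.
#' @param conc_range Two-element numeric, the calibrated concentration range
#'   in mg/g (default `c(0, 0.3)`).
#' @return An object of class `iron_calibration` with `slope` (s^-1 per
#'   mg/g), `intercept` (s^-1), `conc_range`, `r_squared` and `n`.
#' @examples
#' std <- data.frame(conc_mg_g = c(0, 0.1, 0.2, 0.3),
#'                   r2star_s = c(20, 60, 100, 140))
#' fit_calibration(std)    # slope 400, intercept 20, r^2 = 1
#' @export
fit_calibration <- function(standards, conc_range = c(0, 0.3)) {
  stopifnot(is.data.frame(standards),
            all(c("conc_mg_g", "r2star_s") %in% names(standards)))
  if (length(conc_range) != 2 || conc_range[1] >= conc_range[2])
    stop("input error: 'conc_range' must be increasing [lo, hi]", call. = FALSE)
  conc <- standards$conc_mg_g
  r2 <- standards$r2star_s
  if (length(unique(conc)) < 2)
    stop("degenerate-design error: at least two distinct concentrations required",
         call. = FALSE)
  fit <- stats::lm(r2 ~ conc)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (m <= 0)
    stop("calibration-failure error: fitted slope is not positive", call. = FALSE)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((r2 - mean(r2))^2)
  r_squared <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = m, intercept = b,
                 conc_range = as.numeric(conc_range),
                 r_squared = r_squared, n = length(conc)),
            class = "iron_calibration")
}

#' @export
print.iron_calibration <- function(x, ...) {
  cat(sprintf("<iron_calibration> R2* = %.4g C + %.4g s^-1 (r^2 = %.4f, n = %d), range %.2f-%.2f mg/g\n",
              x$slope, x$intercept, x$r_squared, x$n,
              x$conc_range[1], x$conc_range[2]))
  invisible(x)
}

#' Convert an R2* map to a parametric iron (FeMRI) map
#'
#' Inverts the calibration line per pixel, C = (R2* - b) / m, on the masked
#' fitted pixels. Concentrations are clamped to the calibrated range (maps
#' saturate rather than discard out-of-range values; rates below the
#' intercept map to 0, preserving physical non-negativity). Pixels outside
#' the mask or with failed fits are undefined (`NA`).
#'
#' @param r2map An `r2star_map` from [fit_monoexponential()].
#' @param cal An [fit_calibration()] result, or a list with `slope`,
#'   `intercept` and optionally `conc_range`.
#' @param mask Logical tumor ROI matrix; defaults to all fitted pixels.
#' @return An object of class `fe_map` with `iron` (mg/g matrix),
#'   `tumor_mask`, `pixel_size`, `conc_range` and an empty `strata` slot to
#'   be filled by [stratify()].
#' @export
apply_calibration <- function(r2map, cal, mask = NULL) {
  stopifnot(inherits(r2map, "r2star_map"))
  if (is.null(cal$slope) || is.null(cal$intercept))
    stop("input error: 'cal' must carry slope and intercept", call. = FALSE)
  conc_range <- if (!is.null(cal$conc_range)) cal$conc_range else c(0, 0.3)
  if (is.null(mask)) mask <- r2map$fit_ok
  assert_same_dim(r2map$r2star, mask, "r2star", "mask")

  iron <- matrix(NA_real_, nrow(r2map$r2star), ncol(r2map$r2star))
  ok <- mask & r2map$fit_ok
  iron[ok] <- pmin(pmax((r2map$r2star[ok] - cal$intercept) / cal$slope,
                        conc_range[1]), conc_range[2])
  structure(list(iron = iron, tumor_mask = mask,
                 pixel_size = r2map$pixel_size,
                 conc_range = conc_range, strata = NULL),
            class = "fe_map")
}

#' Construct an fe_map directly from a known iron raster
#'
#' Useful for analyzing ground-truth maps or externally produced
#' concentration rasters with the cluster tools.
#'
#' @param iron Numeric matrix of concentrations (mg/g).
#' @param tumor_mask Logical ROI matrix.
#' @param pixel_size Pixel size in mm.
#' @param conc_range Calibrated range, mg/g.
#' @return An `fe_map`.
#' @export
fe_map <- function(iron, tumor_mask, pixel_size, conc_range = c(0, 0.3)) {
  assert_matrix_like(iron, "iron")
  assert_same_dim(iron, tumor_mask, "iron", "tumor_mask")
  out <- matrix(NA_real_, nrow(iron), ncol(iron))
  out[tumor_mask] <- pmin(pmax(iron[tumor_mask], conc_range[1]), conc_range[2])
  structure(list(iron = out, tumor_mask = tumor_mask, pixel_size = pixel_size,
                 conc_range = as.numeric(conc_range), strata = NULL),
            class = "fe_map")
}

#' Stratify a FeMRI map into low- and high-iron pixels
#'
#' The high-iron stratum is defined with respect to the median of the
#' calibrated distribution range: threshold = midpoint of `conc_range`
#' (0.15 mg/g for the default 0.0-0.3 mg/g range). Pixels at or above the
#' threshold are `"high"` (the boundary is inclusive so ties resolve
#' deterministically toward deposit sensitivity), pixels below are `"low"`,
#' and unfitted / out-of-ROI pixels are `"undefined"`. The three strata
#' partition the raster.
#'
#' @param femap An `fe_map`.
#' @return The `fe_map` with `strata` filled (character matrix with values
#'   `"low"`, `"high"`, `"undefined"`) and the threshold stored as
#'   `high_threshold`.
#' @examples
#' m <- fe_map(matrix(c(0.05, 0.15, 0.2, 0.1), 2, 2),
#'             matrix(TRUE, 2, 2), pixel_size = 0.1)
#' stratify(m)$strata
#' @export
stratify <- function(femap) {
  stopifnot(inherits(femap, "fe_map"))
  thr <- mean(femap$conc_range)
  strata <- matrix("undefined", nrow(femap$iron), ncol(femap$iron))
  defined <- femap$tumor_mask & !is.na(femap$iron)
  strata[defined & femap$iron >= thr] <- "high"
  strata[defined & femap$iron < thr] <- "low"
  femap$strata <- strata
  femap$high_threshold <- thr
  femap
}

#' @export
print.fe_map <- function(x, ...) {
  cat(sprintf("<fe_map> %d x %d px (%.3g mm/px), range %.2f-%.2f mg/g, %d ROI px%s\n",
              nrow(x$iron), ncol(x$iron), x$pixel_size,
              x$conc_range[1], x$conc_range[2], sum(x$tumor_mask),
              if (is.null(x$strata)) "" else
                sprintf(", %d high-iron px", sum(x$strata == "high"))))
  invisible(x)
}
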