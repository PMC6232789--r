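#' Multi-gradient-echo image series
#'
#' Container for a stack of magnitude images acquired at increasing echo
#' times, the raw observable of T2* relaxometry.
#'
#' @param stack Numeric array of dimension rows x cols x echoes; magnitudes
#'   must be non-negative.
#' @param echo_times Echo times in ms, strictly increasing, one per echo.
#' @param pixel_size In-plane pixel size in mm.
#' @param tr Optional repetition time (s), carried as metadata.
#' @param flip_angle Optional flip angle (degrees), carried as metadata.
#' @return An object of class `mge_series`.
#' @export
mge_series <- function(stack, echo_times, pixel_size, tr = NULL,
                       flip_angle = NULL) {
  if (!is.array(stack) || length(dim(stack)) != 3)
    stop("input error: 'stack' must be a rows x cols x echoes array",
         call. = FALSE)
  if (dim(stack)[3] != length(echo_times))
    stop("input error: stack depth must equal length(echo_times)",
         call. = FALSE)
  if (any(diff(echo_times) <= 0))
    stop("input error: 'echo_times' must be strictly increasing",
         call. = FALSE)
  if (any(stack < 0))
    stop("input error: magnitudes must be non-negative", call. = FALSE)
  structure(list(stack = stack, echo_times = as.numeric(echo_times),
                 pixel_size = pixel_size, tr = tr, flip_angle = flip_angle),
            class = "mge_series")
}

#' @export
print.mge_series <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<mge_series> %d x %d pixels, %d echoes (TE %.1f-%.1f ms), %.3g mm/px\n",
              d[1], d[2], d[3], min(x$echo_times), max(x$echo_times),
              x$pixel_size))
  invisible(x)
}

# Vectorized Gauss-Newton refinement (with Levenberg damping) of the
# two-parameter monoexponential S = s0 exp(-r2 te) across all pixels at once.
# y: n_px x n_echo matrix; te: echo times in seconds.
refine_monoexp <- function(y, te, s0, r2, max_iter = 20, tol = 1e-12) {
  n <- nrow(y)
  lambda <- rep(1e-3, n)
  rss <- rowSums((y - s0 * exp(outer(-r2, te)))^2)
  for (it in seq_len(max_iter)) {
    E <- exp(outer(-r2, te))                # n x k
    m <- s0 * E
    res <- y - m
    # Jacobian columns: dS/ds0 = E, dS/dr2 = -te * m
    a11 <- rowSums(E * E)
    a12 <- rowSums(E * sweep(-m, 2, te, `*`))
    a22 <- rowSums(sweep(m, 2, te, `*`)^2)
    g1 <- rowSums(E * res)
    g2 <- rowSums(sweep(-m, 2, te, `*`) * res)
    d11 <- a11 * (1 + lambda)
    d22 <- a22 * (1 + lambda)
    det <- d11 * d22 - a12^2
    det[abs(det) < 1e-300] <- NA
    ds0 <- (d22 * g1 - a12 * g2) / det
    dr2 <- (d11 * g2 - a12 * g1) / det
    ds0[is.na(ds0)] <- 0; dr2[is.na(dr2)] <- 0
    s0_new <- s0 + ds0
    r2_new <- r2 + dr2
    rss_new <- rowSums((y - s0_new * exp(outer(-r2_new, te)))^2)
    better <- rss_new <= rss
    s0[better] <- s0_new[better]
    r2[better] <- r2_new[better]
    lambda[better] <- pmax(lambda[better] / 4, 1e-9)
    lambda[!better] <- pmin(lambda[!better] * 8, 1e8)
    improved <- rss[better] - rss_new[better]
    rss[better] <- rss_new[better]
    if (all(!better) || (length(improved) && max(improved) < tol * (1 + max(rss))))
      break
  }
  list(s0 = s0, r2 = r2, rss = rss)
}

# Closed-form per-pixel log-linear regression of ln S on TE, weighted by
# S^2 (the delta-method variance weighting for log-transformed exponentials)
# so that noise-dominated late echoes do not destabilize the line.
loglinear_init <- function(y, te) {
  eps <- max(y) * 1e-12 + .Machine$double.xmin
  ly <- log(pmax(y, eps))
  w <- y^2
  sw <- rowSums(w)
  zero_w <- sw <= 0
  w[zero_w, ] <- 1
  sw[zero_w] <- ncol(y)
  te_m <- matrix(te, nrow(y), length(te), byrow = TRUE)
  te_bar <- rowSums(w * te_m) / sw
  ly_bar <- rowSums(w * ly) / sw
  te_c <- te_m - te_bar
  slope <- rowSums(w * te_c * ly) / rowSums(w * te_c^2)
  intercept <- ly_bar - slope * te_bar
  list(s0 = exp(intercept), r2 = -slope)
}

#' Pixel-wise monoexponential T2*/R2* fitting of an MGE series
#'
#' Fits S(TE) = S0 exp(-R2* TE) independently at every masked pixel by
#' nonlinear least squares, initialized from the ordinary log-linear
#' regression of ln S on TE. Pixels whose first-echo signal falls below
#' `min_signal_fraction` times the masked 99th-percentile first-echo signal
#' are excluded (`fit_ok = FALSE`): they are background or signal voids where
#' the decay model is not identifiable. Negative fitted rates are clamped to
#' zero with `fit_ok` retained.
#'
#' @param series An [mge_series()]; at least 3 echoes are required.
#' @param mask Logical matrix selecting pixels to fit; defaults to all pixels.
#' @param min_signal_fraction Low-signal exclusion threshold in \[0, 1)
#'   (default 0.05).
#' @param method `"nls"` (default; log-linear initialization refined by
#'   damped Gauss-Newton) or `"loglinear"` (the initialization alone).
#' @return An object of class `r2star_map` with matrices `r2star` (s^-1),
#'   `s0`, `rss`, logical `fit_ok`, and the `pixel_size`.
#' @examples
#' te <- seq(3, 48, by = 3)
#' stack <- array(100 * exp(-outer(rep(1, 4), te / 1000 * 50)), c(2, 2, 16))
#' fit <- fit_monoexponential(mge_series(stack, te, 0.1))
#' fit$r2star[1, 1]   # 50 s^-1
#' @export
fit_monoexponential <- function(series, mask = NULL, min_signal_fraction = 0.05,
                                method = c("nls", "loglinear")) {
  stopifnot(inherits(series, "mge_series"))
  method <- match.arg(method)
  d <- dim(series$stack)
  if (d[3] < 3)
    stop("input error: at least 3 echoes are required", call. = FALSE)
  if (min_signal_fraction < 0 || min_signal_fraction >= 1)
    stop("input error: 'min_signal_fraction' must be in [0, 1)", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  assert_same_dim(series$stack, mask, "stack", "mask")

  te_s <- series$echo_times / 1000       # rates carried in s^-1
  first <- series$stack[, , 1]
  ref <- stats::quantile(first[mask], 0.99, names = FALSE)
  fit_sel <- mask & (first >= min_signal_fraction * ref)

  r2star <- matrix(NA_real_, d[1], d[2])
  s0 <- matrix(NA_real_, d[1], d[2])
  rss <- matrix(NA_real_, d[1], d[2])
  fit_ok <- matrix(FALSE, d[1], d[2])

  idx <- which(fit_sel)
  if (length(idx)) {
    y <- matrix(series$stack, d[1] * d[2], d[3])[idx, , drop = FALSE]
    init <- loglinear_init(y, te_s)
    if (method == "nls") {
      ref_fit <- refine_monoexp(y, te_s, init$s0, pmax(init$r2, 0))
    } else {
      ref_fit <- list(s0 = init$s0, r2 = init$r2,
                      rss = rowSums((y - init$s0 * exp(outer(-init$r2, te_s)))^2))
    }
    r2star[idx] <- pmax(ref_fit$r2, 0)
    s0[idx] <- ref_fit$s0
    rss[idx] <- ref_fit$rss
    fit_ok[idx] <- TRUE
  }
  structure(list(r2star = r2star, s0 = s0, rss = rss, fit_ok = fit_ok,
                 pixel_size = series$pixel_size),
            class = "r2star_map")
}

#' Convert an R2* map to a T2* map
#'
#' T2* = 1000 / R2* (ms per s^-1) at every fitted pixel. Pixels with
#' R2* = 0 or failed fits are returned as `NA` (undefined).
#'
#' @param r2map An `r2star_map` from [fit_monoexponential()].
#' @return Matrix of T2* values in ms.
#' @export
t2star_map <- function(r2map) {
  stopifnot(inherits(r2map, "r2star_map"))
  t2 <- matrix(NA_real_, nrow(r2map$r2star), ncol(r2map$r2star))
  ok <- r2map$fit_ok & !is.na(r2map$r2star) & r2map$r2star > 0
  t2[ok] <- 1000 / r2map$r2star[ok]
  t2
}
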