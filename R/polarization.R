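#' Whole-section macrophage polarization frequencies
#'
#' Computes the M1/M2 polarization split from a cell table: f_M1 =
#' N(AIF1+) / (N(AIF1+) + N(CD206+)) and f_M2 = 1 - f_M1, expressed as
#' percentages. Double-positive AIF1+CD206+ cells count toward both
#' numerators and both terms of the denominator (set
#' `double_positive = "exclude"` to drop them instead). Optionally also
#' reports the CD68+ macrophage density per mm2 when the counted section
#' area is supplied.
#'
#' @param cells Data frame with logical columns `aif1`, `cd206` and
#'   optionally `cd68`.
#' @param section_area_mm2 Optional counted area for the CD68 density.
#' @param double_positive `"include"` (default) or `"exclude"`.
#' @return A list with `n_m1`, `n_m2`, `f_m1_pct`, `f_m2_pct`, `n_cd68`,
#'   and `cd68_per_mm2` (NA when no area is given).
#' @examples
#' cells <- data.frame(aif1 = rep(c(TRUE, FALSE), c(420, 580)),
#'                     cd206 = rep(c(FALSE, TRUE), c(420, 580)))
#' polarization_frequencies(cells)$f_m1_pct   # 42
#' @export
polarization_frequencies <- function(cells, section_area_mm2 = NULL,
                                     double_positive = c("include", "exclude")) {
  double_positive <- match.arg(double_positive)
  stopifnot(all(c("aif1", "cd206") %in% names(cells)))
  sel <- if (double_positive == "exclude") !(cells$aif1 & cells$cd206)
         else rep(TRUE, nrow(cells))
  n_m1 <- sum(cells$aif1[sel])
  n_m2 <- sum(cells$cd206[sel])
  if (n_m1 + n_m2 == 0)
    stop("undefined frequency error: no AIF1+ or CD206+ macrophages",
         call. = FALSE)
  n_cd68 <- if ("cd68" %in% names(cells)) sum(cells$cd68) else NA_integer_
  f_m1 <- 100 * n_m1 / (n_m1 + n_m2)
  list(n_m1 = n_m1, n_m2 = n_m2,
       f_m1_pct = f_m1,
       f_m2_pct = 100 - f_m1,   # exact complement by construction
       n_cd68 = n_cd68,
       cd68_per_mm2 = if (!is.null(section_area_mm2) && !is.na(n_cd68))
                        n_cd68 / section_area_mm2 else NA_real_)
}

#' Iron-positive subset frequencies per macrophage population
#'
#' For each marker population X in CD68, AIF1, CD206 and the AIF1+CD206+
#' double-positive population, the percentage of X+ cells that are also
#' iron-positive: iron+X+ / X+. These localized frequencies quantify how
#' much of each polarization subset carries (nanoparticle) iron.
#'
#' @param cells Data frame with logical columns `cd68`, `aif1`, `cd206`,
#'   `iron`.
#' @return Named list of percentages (`iron_cd68_pct`, `iron_aif1_pct`,
#'   `iron_cd206_pct`, `iron_double_pct`); a ratio with an empty denominator
#'   population is `NA`.
#' @examples
#' cells <- data.frame(cd68 = TRUE, aif1 = FALSE, cd206 = TRUE,
#'                     iron = rep(c(TRUE, FALSE), c(49, 951)))
#' iron_subset_frequencies(cells)$iron_cd68_pct   # 4.9
#' @export
iron_subset_frequencies <- function(cells) {
  stopifnot(all(c("cd68", "aif1", "cd206", "iron") %in% names(cells)))
  ratio <- function(pop) {
    n <- sum(pop)
    if (n == 0) NA_real_ else 100 * sum(pop & cells$iron) / n
  }
  list(iron_cd68_pct = ratio(cells$cd68),
       iron_aif1_pct = ratio(cells$aif1),
       iron_cd206_pct = ratio(cells$cd206),
       iron_double_pct = ratio(cells$aif1 & cells$cd206))
}

#' Two-tailed pooled-variance Student's t-test
#'
#' Classical unpaired two-sample Student's t-test with pooled variance (not
#' Welch), two-tailed p-value on n1 + n2 - 2 degrees of freedom. Degenerate
#' inputs with zero pooled variance return p = 1 when the means are equal
#' and p = 0 otherwise (with an infinite t-statistic).
#'
#' @param a,b Numeric vectors, at least 2 observations each.
#' @return A list of class `pooled_t_result` with `t_statistic`, `p_value`,
#'   `df`, `mean_a`, `mean_b`, `sem_a`, `sem_b`, `n_a`, `n_b`.
#' @examples
#' two_tailed_t_test(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
two_tailed_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("input error: at least 2 observations per group", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  dm <- mean(a) - mean(b)
  if (sp2 == 0) {
    t_stat <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 1 else 0
  } else {
    t_stat <- dm / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(t_statistic = t_stat, p_value = p, df = df,
                 mean_a = mean(a), mean_b = mean(b),
                 sem_a = stats::sd(a) / sqrt(n1),
                 sem_b = stats::sd(b) / sqrt(n2),
                 n_a = n1, n_b = n2),
            class = "pooled_t_result")
}

#' @export
print.pooled_t_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.4g, two-tailed p = %.4g\n", x$df, x$t_statistic,
              x$p_value))
  cat(sprintf("  group a: %.4g +/- %.4g SEM (n = %d)\n", x$mean_a, x$sem_a,
              x$n_a))
  cat(sprintf("  group b: %.4g +/- %.4g SEM (n = %d)\n", x$mean_b, x$sem_b,
              x$n_b))
  invisible(x)
}
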