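#' @keywords internal
"_PACKAGE"

# Binary disc mask centred at (cr, cc) with radius r (pixels), on an
# nrow x ncol grid. Pixel centres are at integer coordinates.
disc_mask <- function(nrow, ncol, cr, cc, r) {
  rows <- matrix(seq_len(nrow), nrow, ncol)
  cols <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (rows - cr)^2 + (cols - cc)^2 <= r^2
}

# Weighted median over values x with non-negative weights w: smallest x
# at which the cumulative weight reaches half the total.
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  if (sum(w) == 0) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}

assert_matrix_like <- function(x, name) {
  if (!is.matrix(x)) stop(sprintf("'%s' must be a matrix", name), call. = FALSE)
}

assert_same_dim <- function(a, b, name_a, name_b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop(sprintf("'%s' and '%s' have incompatible dimensions (%s vs %s)",
                 name_a, name_b,
                 paste(dim(a)[1:2], collapse = "x"),
                 paste(dim(b)[1:2], collapse = "x")), call. = FALSE)
  }
}
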