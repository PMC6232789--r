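# Independent oracles used across the suite. These deliberately use naive
# algorithms (queue-based flood fill, exhaustive grid search) so they share
# no code path with the package implementations they check.

# Brute-force connected-component labeling by queue flood fill.
flood_fill_labels <- function(mask, connectivity = 8) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  labels <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
          cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
        else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  lab <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!m[r0, c0] || labels[r0, c0] > 0L) next
    lab <- lab + 1L
    queue <- matrix(c(r0, c0), 1, 2)
    labels[r0, c0] <- lab
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = TRUE]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            m[rr, cc] && labels[rr, cc] == 0L) {
          labels[rr, cc] <- lab
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  labels
}

# Canonicalize a label matrix: relabel components by first occurrence in
# column-major order so two labelings can be compared for identical
# membership regardless of numbering.
canonical_labels <- function(labels) {
  out <- labels
  seen <- integer(0)
  nz <- which(labels > 0)
  for (i in nz) {
    l <- labels[i]
    if (!l %in% seen) seen <- c(seen, l)
    out[i] <- match(l, seen)
  }
  out
}

# Exhaustive grid-search monoexponential fit for one pixel: minimizes RSS of
# S0 exp(-r2 te) over a dense (s0, r2) grid, refined once around the best
# cell. Rates in s^-1, te in seconds.
grid_search_monoexp <- function(y, te_s, s0_range, r2_range, n_grid = 80) {
  best <- c(NA, NA, Inf)
  for (pass in 1:2) {
    s0s <- seq(s0_range[1], s0_range[2], length.out = n_grid)
    r2s <- seq(r2_range[1], r2_range[2], length.out = n_grid)
    for (s0 in s0s) for (r2 in r2s) {
      rss <- sum((y - s0 * exp(-r2 * te_s))^2)
      if (rss < best[3]) best <- c(s0, r2, rss)
    }
    ds <- diff(s0_range) / (n_grid - 1)
    dr <- diff(r2_range) / (n_grid - 1)
    s0_range <- c(best[1] - ds, best[1] + ds)
    r2_range <- c(max(0, best[2] - dr), best[2] + dr)
  }
  list(s0 = best[1], r2 = best[2], rss = best[3])
}

# Small noiseless MGE stack: every pixel decays with the given R2* (s^-1).
make_uniform_stack <- function(nr, nc, s0, r2_s, te_ms) {
  te_s <- te_ms / 1000
  stack <- array(0, c(nr, nc, length(te_ms)))
  for (e in seq_along(te_ms)) stack[, , e] <- s0 * exp(-r2_s * te_s[e])
  stack
}
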