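# Independent brute-force oracles used to pin the optimized implementations.

# G(r) by explicit per-point loops: count targets per annulus per reference,
# with the same border-exclusion rule, no grid acceleration.
oracle_gr <- function(ref, tgt, bins, roi) {
  A <- polygon_area(roi)
  lambda <- nrow(tgt) / A
  nb <- length(bins) - 1
  dbound <- vapply(seq_len(nrow(ref)), function(i) {
    dist_to_polygon_boundary(ref$x[i], ref$y[i], roi)
  }, numeric(1))
  g <- rep(NA_real_, nb)
  for (j in seq_len(nb)) {
    area_j <- pi * (bins[j + 1]^2 - bins[j]^2)
    counts <- c()
    for (i in seq_len(nrow(ref))) {
      if (dbound[i] < bins[j + 1]) next
      d <- sqrt((tgt$x - ref$x[i])^2 + (tgt$y - ref$y[i])^2)
      counts <- c(counts, sum(d >= bins[j] & d < bins[j + 1]))
    }
    if (length(counts) > 0) g[j] <- mean(counts) / (area_j * lambda)
  }
  g
}

# MSD by explicit double loop over frame pairs.
oracle_msd <- function(x, y, max_lag) {
  vapply(seq_len(max_lag), function(L) {
    s <- 0; n <- 0
    for (i in seq_len(length(x) - L)) {
      s <- s + (x[i + L] - x[i])^2 + (y[i + L] - y[i])^2
      n <- n + 1
    }
    s / n
  }, numeric(1))
}

# Feret by brute force over all vertex pairs (no hull shortcut).
oracle_feret <- function(poly) {
  n <- nrow(poly)
  best <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    best <- max(best, sqrt(sum((poly[i, ] - poly[j, ])^2)))
  }
  best
}

# Connected components of the <= threshold distance graph
# (single-linkage cut), as membership vector.
oracle_single_linkage <- function(x, y, threshold) {
  d <- stats::dist(cbind(x, y))
  stats::cutree(stats::hclust(d, method = "single"), h = threshold)
}

# Dense square grid of points, used to build clusters with exact hulls.
grid_points <- function(x0, x1, y0, y1, by = 10) {
  g <- expand.grid(x = seq(x0, x1, by = by), y = seq(y0, y1, by = by))
  data.frame(x = g$x, y = g$y, species = "A", frame = 0L, precision = 5)
}

# access to internal helpers used by oracles
polygon_area <- efferoquant:::polygon_area
dist_to_polygon_boundary <- efferoquant:::dist_to_polygon_boundary
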