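# Planar geometry helpers shared by the SMLM, FRET and morphometry modules.
# Conventions (documented once, used everywhere): continuous coordinates in nm,
# origin at the bottom-left, y up. Polygons are n x 2 matrices of vertices in
# order (open ring: the closing edge last->first is implicit). Images are
# matrices with dim 1 = x and dim 2 = y; the centre of pixel (i, j) sits at
# ((i - 0.5) * px_nm, (j - 0.5) * px_nm).

#' Rectangular region of interest
#'
#' Convenience constructor for an axis-aligned rectangular ROI polygon.
#'
#' @param width,height Side lengths in nm.
#' @param origin Numeric length-2, bottom-left corner in nm.
#' @return A 4 x 2 vertex matrix usable wherever an ROI polygon is expected.
#' @export
rect_roi <- function(width, height = width, origin = c(0, 0)) {
  stopifnot(width > 0, height > 0)
  cbind(
    x = origin[1] + c(0, width, width, 0),
    y = origin[2] + c(0, 0, height, height)
  )
}

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2 || nrow(poly) < 3) {
    stop("a polygon must be an n x 2 matrix with n >= 3 vertices")
  }
  storage.mode(poly) <- "double"
  poly
}

#' Polygon area (shoelace formula)
#' @param poly Vertex matrix.
#' @return Area in nm^2 (always positive).
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:nrow(poly), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Vectorized point-in-polygon (boundary counts as inside within `eps`).
points_in_polygon <- function(x, y, poly, eps = 1e-9) {
  poly <- as_polygon(poly)
  if (length(x) == 0) return(logical(0))
  inside <- mgcv::in.out(rbind(poly, poly[1, ]), cbind(x, y))
  # in.out excludes some boundary points; rescue those within eps of an edge
  border <- !inside
  if (any(border)) {
    d <- dist_to_polygon_boundary(x[border], y[border], poly)
    inside[border] <- d <= eps
  }
  inside
}

# Distance from points to the closest point on any polygon edge.
dist_to_polygon_boundary <- function(x, y, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- poly[c(2:n, 1), 1]; by <- poly[c(2:n, 1), 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  best <- rep(Inf, length(x))
  for (e in seq_len(n)) {
    if (len2[e] == 0) {
      d2 <- (x - ax[e])^2 + (y - ay[e])^2
    } else {
      t <- ((x - ax[e]) * dx[e] + (y - ay[e]) * dy[e]) / len2[e]
      t <- pmin(1, pmax(0, t))
      d2 <- (x - (ax[e] + t * dx[e]))^2 + (y - (ay[e] + t * dy[e]))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Minimum distance between two polygon boundaries; 0 when they overlap.
polygon_min_distance <- function(a, b) {
  a <- as_polygon(a); b <- as_polygon(b)
  if (any(points_in_polygon(a[, 1], a[, 2], b)) ||
      any(points_in_polygon(b[, 1], b[, 2], a))) {
    return(0)
  }
  # neither contains the other's vertices and convex inputs are assumed:
  # the minimum is attained vertex-to-edge
  min(
    min(dist_to_polygon_boundary(a[, 1], a[, 2], b)),
    min(dist_to_polygon_boundary(b[, 1], b[, 2], a))
  )
}

# Uniform draws inside a polygon by rejection from its bounding box.
runif_in_polygon <- function(n, poly, rng_max_iter = 10000L) {
  poly <- as_polygon(poly)
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out_x <- numeric(0); out_y <- numeric(0)
  it <- 0L
  while (length(out_x) < n && it < rng_max_iter) {
    m <- max(2L * (n - length(out_x)), 16L)
    px <- stats::runif(m, xr[1], xr[2])
    py <- stats::runif(m, yr[1], yr[2])
    keep <- points_in_polygon(px, py, poly)
    out_x <- c(out_x, px[keep]); out_y <- c(out_y, py[keep])
    it <- it + 1L
  }
  if (length(out_x) < n) stop("rejection sampling failed; degenerate polygon?")
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

# Convex hull of points as a vertex matrix (counter-clockwise).
convex_hull <- function(x, y) {
  idx <- grDevices::chull(x, y)
  cbind(x = x[idx], y = y[idx])
}
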