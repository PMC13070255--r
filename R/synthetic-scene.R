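# Synthetic uptake-assay scenes: cells with internalized and surface-bound
# targets, an "outside" label channel marking only the non-internalized
# targets (as surface labelling with streptavidin / anti-IgG does), and an
# optional dye channel carried by every target.

paint_disk <- function(img, cx, cy, r_px, value) {
  d <- dim(img)
  xi <- pmax(1L, floor(cx - r_px)):pmin(d[1], ceiling(cx + r_px))
  yi <- pmax(1L, floor(cy - r_px)):pmin(d[2], ceiling(cy + r_px))
  for (j in yi) {
    dx2 <- (xi - cx)^2 + (j - cy)^2
    hit <- xi[dx2 <= r_px^2]
    img[hit, j] <- img[hit, j] + value
  }
  img
}

circle_polygon <- function(cx, cy, r, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# non-overlapping uniform positions in an annulus/disk (rejection)
place_points <- function(n, cx, cy, rmin, rmax, min_sep) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n && tries < 20000L) {
    r <- sqrt(stats::runif(1, rmin^2, rmax^2))
    th <- stats::runif(1, 0, 2 * pi)
    p <- c(cx + r * cos(th), cy + r * sin(th))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_sep) {
      pts <- rbind(pts, p)
    }
    tries <- tries + 1L
  }
  if (nrow(pts) < n) stop("could not place targets without overlap")
  pts
}

#' Generate a synthetic uptake-assay scene
#'
#' Builds a multi-channel raster scene of \code{n_cells} circular cells,
#' each with a known number of internalized and surface-bound targets
#' (beads or apoptotic-cell mimics). Three channels are produced: the
#' target channel (all targets), the outside-label channel (surface-bound
#' targets only) and a dye channel in which every target carries a known
#' integrated intensity. Targets are placed without mutual overlap so
#' connected-component counting is exact.
#'
#' @param n_cells Number of cells.
#' @param beads_internal_per_cell,beads_external_per_cell Targets per cell.
#' @param seed Integer seed.
#' @param dye_per_target Integrated dye intensity per target (a.u.).
#' @param px_nm Pixel size, nm.
#' @param cell_radius_nm,bead_radius_nm Geometry, nm.
#' @return An \code{uptake_scene}: list with \code{channels}
#'   (\code{targets}, \code{outside}, \code{dye} matrices), \code{cells}
#'   (list of ROI polygons, nm), \code{targets} (data.frame with nm centre,
#'   owning cell, \code{internal} flag), \code{px_nm} and \code{truth}
#'   (\code{index}, \code{bound}, \code{dye_internal_per_cell}).
#' @export
gen_uptake_scene <- function(n_cells, beads_internal_per_cell,
                             beads_external_per_cell, seed = NULL,
                             dye_per_target = 1000, px_nm = 200,
                             cell_radius_nm = 8000, bead_radius_nm = 1500) {
  stopifnot(n_cells >= 1, beads_internal_per_cell >= 0,
            beads_external_per_cell >= 0)
  with_local_seed(seed, {
    tile_nm <- 2.5 * cell_radius_nm
    W <- ceiling(n_cells * tile_nm / px_nm)
    H <- ceiling(tile_nm / px_nm)
    targets_img <- matrix(0, W, H)
    outside_img <- matrix(0, W, H)
    dye_img <- matrix(0, W, H)
    bead_r_px <- bead_radius_nm / px_nm
    cells <- vector("list", n_cells)
    targ <- list()
    for (i in seq_len(n_cells)) {
      cx <- (i - 0.5) * tile_nm
      cy <- tile_nm / 2
      cells[[i]] <- circle_polygon(cx, cy, cell_radius_nm)
      sep <- 2 * bead_radius_nm + 3 * px_nm
      n_int <- beads_internal_per_cell
      n_ext <- beads_external_per_cell
      pts <- place_points(n_int + n_ext, cx, cy,
                          rmin = 0,
                          rmax = cell_radius_nm - bead_radius_nm - px_nm,
                          min_sep = sep)
      internal <- rep(c(TRUE, FALSE), c(n_int, n_ext))
      for (k in seq_len(nrow(pts))) {
        px_x <- pts[k, 1] / px_nm + 0.5
        px_y <- pts[k, 2] / px_nm + 0.5
        targets_img <- paint_disk(targets_img, px_x, px_y, bead_r_px, 1)
        if (!internal[k]) {
          outside_img <- paint_disk(outside_img, px_x, px_y, bead_r_px, 1)
        }
        # spread dye_per_target uniformly over the target footprint
        tmp <- paint_disk(matrix(0, W, H), px_x, px_y, bead_r_px, 1)
        npx <- sum(tmp > 0)
        dye_img <- dye_img + tmp * (dye_per_target / npx)
      }
      targ[[i]] <- data.frame(x = pts[, 1], y = pts[, 2],
                              cell = i, internal = internal)
    }
    targets_df <- do.call(rbind, targ)
    truth <- list(
      index = beads_internal_per_cell,
      bound = beads_external_per_cell,
      dye_internal_per_cell = beads_internal_per_cell * dye_per_target
    )
    structure(list(
      channels = list(targets = targets_img, outside = outside_img,
                      dye = dye_img),
      cells = cells, targets = targets_df, px_nm = px_nm, truth = truth
    ), class = "uptake_scene")
  })
}
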