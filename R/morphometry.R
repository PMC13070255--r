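# Synapse and uptake morphometrics: Feret's diameter and synapse
# expansion, Pearson colocalization, radial intensity profiles,
# base-to-leading-edge cup profiles, and the phagocytic/efferocytic index.

#' Feret's diameter of a polygon
#'
#' Maximum caliper distance: the largest pairwise distance between
#' vertices, attained on the convex hull.
#'
#' @param polygon n x 2 vertex matrix, nm.
#' @return Diameter in nm.
#' @export
feret_diameter <- function(polygon) {
  poly <- as_polygon(polygon)
  h <- convex_hull(poly[, 1], poly[, 2])
  if (nrow(h) < 2) stop("degenerate polygon")
  max(stats::dist(h))
}

#' Synapse expansion series
#'
#' Feret's diameter of the synapse outline at each time point, normalized
#' to the first time point at which a synapse is visible (outline area
#' above \code{min_area_nm2}; visibility in the source assay is a focal
#' criterion, which 2-D outlines cannot recover, hence the area proxy).
#'
#' @param outlines List of outline polygons (nm), one per time point;
#'   \code{NULL} entries are allowed for time points without a synapse.
#' @param times Numeric time stamps (min); default 0, 1, 2, ...
#' @param min_area_nm2 Minimum outline area for a synapse to count as
#'   visible.
#' @return Data.frame with \code{time}, \code{feret} (nm, NA when not
#'   visible) and \code{fold_change} (feret / feret at first visible time).
#' @export
expansion_series <- function(outlines, times = NULL, min_area_nm2 = 0) {
  if (length(outlines) == 0) stop("need at least one time point")
  times <- times %||% (seq_along(outlines) - 1)
  feret <- vapply(seq_along(outlines), function(i) {
    p <- outlines[[i]]
    if (is.null(p) || polygon_area(p) <= min_area_nm2) return(NA_real_)
    feret_diameter(p)
  }, numeric(1))
  first <- which(!is.na(feret))[1]
  if (is.na(first)) stop("no visible synapse at any time point")
  data.frame(time = times, feret = feret,
             fold_change = feret / feret[first])
}

#' Pearson colocalization coefficient
#'
#' Pearson correlation between two channels over the masked pixels.
#'
#' @param img_a,img_b Numeric matrices of identical dimension.
#' @param mask Optional logical matrix; default all pixels.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_colocalization <- function(img_a, img_b, mask = NULL) {
  if (!all(dim(img_a) == dim(img_b))) stop("images must share dimensions")
  mask <- mask %||% (array(TRUE, dim = dim(img_a)))
  a <- img_a[mask]; b <- img_b[mask]
  if (length(a) < 2) stop("need at least 2 masked pixels")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("constant channel: correlation undefined")
  }
  stats::cor(a, b)
}

#' Radial intensity profile about a centre
#'
#' Mean pixel intensity per concentric annulus about \code{center}.
#' Annuli are clipped to the image bounds implicitly: each annulus mean is
#' taken over the pixels (area elements) actually present, so total
#' intensity is conserved: sum(mean * n_pixels) equals the image sum over
#' the covered radius range.
#'
#' @param image Numeric matrix (dim 1 = x).
#' @param center Length-2 centre in nm.
#' @param bin_width_nm Annulus width, nm.
#' @param px_nm Pixel size, nm.
#' @param max_radius_nm Outermost radius; default covers the whole image.
#' @return Data.frame with \code{r_lo}, \code{r_hi}, \code{r_mid} (nm),
#'   \code{mean_intensity}, \code{n_pixels}.
#' @export
radial_profile <- function(image, center, bin_width_nm, px_nm = 100,
                           max_radius_nm = NULL) {
  if (bin_width_nm < px_nm) stop("bin width below pixel size")
  d <- dim(image)
  if (center[1] < 0 || center[1] > d[1] * px_nm ||
      center[2] < 0 || center[2] > d[2] * px_nm) {
    stop("center must lie inside the image")
  }
  cx <- (seq_len(d[1]) - 0.5) * px_nm
  cy <- (seq_len(d[2]) - 0.5) * px_nm
  r <- sqrt(outer(cx - center[1], rep(1, d[2]))^2 +
            outer(rep(1, d[1]), cy - center[2])^2)
  rmax <- max_radius_nm %||% max(r)
  edges <- seq(0, rmax + bin_width_nm, by = bin_width_nm)
  idx <- findInterval(r, edges, left.open = FALSE)
  idx[r >= edges[length(edges)]] <- 0L
  nb <- length(edges) - 1
  n_px <- tabulate(idx[idx > 0], nbins = nb)
  sums <- vapply(seq_len(nb), function(j) sum(image[idx == j]), numeric(1))
  keep <- n_px > 0
  data.frame(r_lo = edges[-(nb + 1)][keep], r_hi = edges[-1][keep],
             r_mid = ((edges[-1] + edges[-(nb + 1)]) / 2)[keep],
             mean_intensity = (sums / pmax(n_px, 1))[keep],
             n_pixels = n_px[keep])
}

# nearest-pixel line sample of an image between two nm points
sample_line <- function(image, from, to, px_nm, n = 100) {
  t <- seq(0, 1, length.out = n)
  x <- from[1] + t * (to[1] - from[1])
  y <- from[2] + t * (to[2] - from[2])
  i <- pmin(pmax(ceiling(x / px_nm), 1), dim(image)[1])
  j <- pmin(pmax(ceiling(y / px_nm), 1), dim(image)[2])
  image[cbind(i, j)]
}

#' Base-to-leading-edge cup profile
#'
#' Samples a channel and a membrane-reference channel along the cup axis
#' from base (fractional position 0) to leading edge (position 1), divides
#' channel by membrane (normalizing for membrane density), and min-max
#' scales the result to [0, 1]. Cups outside the engulfment window
#' (default 50--75% of the target circumference engulfed) are rejected, so
#' profiles are only compared between cups at the same engulfment stage.
#'
#' @param channel,membrane Numeric matrices of identical dimension.
#' @param cup_axis List with \code{base} and \code{tip}, each a length-2
#'   nm point.
#' @param engulfment Fraction of the target engulfed by this cup.
#' @param engulfment_window Acceptance window for \code{engulfment}.
#' @param px_nm Pixel size, nm.
#' @param n_samples Profile sampling points.
#' @return Data.frame with \code{position} (0 base to 1 leading edge) and
#'   \code{intensity} (normalized, min-max scaled). Attribute
#'   \code{degenerate_flat} flags a constant ratio profile.
#' @export
cup_profile <- function(channel, membrane, cup_axis, engulfment,
                        engulfment_window = c(0.5, 0.75), px_nm = 100,
                        n_samples = 100) {
  if (!all(dim(channel) == dim(membrane))) stop("channels must share dimensions")
  if (engulfment < engulfment_window[1] || engulfment > engulfment_window[2]) {
    stop(sprintf("cup with %.0f%% engulfment outside the %.0f-%.0f%% window",
                 100 * engulfment, 100 * engulfment_window[1],
                 100 * engulfment_window[2]))
  }
  ch <- sample_line(channel, cup_axis$base, cup_axis$tip, px_nm, n_samples)
  mb <- sample_line(membrane, cup_axis$base, cup_axis$tip, px_nm, n_samples)
  if (any(mb <= 0)) stop("membrane reference is zero along the profile")
  ratio <- ch / mb
  rng <- range(ratio)
  flat <- diff(rng) <= .Machine$double.eps * max(abs(rng), 1) * 100
  scaled <- if (flat) rep(0, length(ratio)) else (ratio - rng[1]) / diff(rng)
  out <- data.frame(position = seq(0, 1, length.out = n_samples),
                    intensity = scaled)
  attr(out, "degenerate_flat") <- flat
  out
}

# Otsu mask of a channel; a constant channel yields an empty mask when it
# is flat at (or below) zero signal, otherwise an error.
otsu_mask_or_empty <- function(img) {
  rg <- range(img, finite = TRUE)
  if (diff(rg) <= 0) {
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  scaled <- (img - rg[1]) / diff(rg)
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  scaled > th
}

#' Phagocytic / efferocytic uptake index
#'
#' \strong{beads mode}: targets are segmented from the target channel by
#' connected components; a target counts as bound (non-internalized) when
#' at least \code{outside_overlap_frac} of its footprint carries
#' outside-label signal, internalized otherwise; each target is assigned
#' to the cell ROI containing its centroid. The index is the mean number
#' of internalized targets per cell.
#'
#' \strong{apoptotic_cells mode}: an Otsu threshold is applied to the
#' outside-label (streptavidin) channel, the mask inverted and applied to
#' the dye channel, the dye integrated per cell ROI, and (when
#' \code{control_mean} is supplied) normalized to the control-group mean.
#'
#' @param scene An \code{uptake_scene} (or compatible list with
#'   \code{channels}, \code{cells}, \code{px_nm}).
#' @param mode \code{"beads"} or \code{"apoptotic_cells"}.
#' @param outside_overlap_frac Footprint overlap required to call a bead
#'   bound (default 0.5).
#' @param control_mean Mean integrated dye of the control group
#'   (apoptotic_cells mode); when given, normalized values are returned.
#' @return An \code{uptake_result} list. Beads mode: per-cell
#'   \code{internalized} and \code{bound} counts, \code{index} (mean
#'   internalized per cell) and \code{bound_per_cell}. Apoptotic mode:
#'   per-cell \code{integrated_dye}, and \code{normalized} when
#'   \code{control_mean} is given.
#' @export
uptake_index <- function(scene, mode = c("beads", "apoptotic_cells"),
                         outside_overlap_frac = 0.5, control_mean = NULL) {
  mode <- match.arg(mode)
  if (length(scene$cells) == 0) stop("no cell ROIs in scene")
  px <- scene$px_nm
  cells <- scene$cells
  if (mode == "beads") {
    tgt <- scene$channels$targets
    lab <- EBImage::bwlabel(EBImage::Image(1 * (tgt > 0.5)))
    lab <- as.matrix(EBImage::imageData(lab))
    outside <- scene$channels$outside > 0.5
    n_obj <- max(lab)
    internal <- integer(length(cells)); bound <- integer(length(cells))
    for (o in seq_len(n_obj)) {
      pix <- which(lab == o, arr.ind = TRUE)
      cx <- mean(pix[, 1] - 0.5) * px
      cy <- mean(pix[, 2] - 0.5) * px
      cell <- which(vapply(cells, function(p)
        points_in_polygon(cx, cy, p), logical(1)))[1]
      if (is.na(cell)) next
      frac_out <- mean(outside[pix])
      if (frac_out >= outside_overlap_frac) {
        bound[cell] <- bound[cell] + 1L
      } else {
        internal[cell] <- internal[cell] + 1L
      }
    }
    structure(list(mode = mode, internalized = internal, bound = bound,
                   index = mean(internal), bound_per_cell = mean(bound)),
              class = "uptake_result")
  } else {
    keep <- !otsu_mask_or_empty(scene$channels$outside)
    dye <- scene$channels$dye * keep
    d <- dim(dye)
    cxs <- (seq_len(d[1]) - 0.5) * px
    cys <- (seq_len(d[2]) - 0.5) * px
    pxx <- rep(cxs, times = d[2]); pyy <- rep(cys, each = d[1])
    integrated <- vapply(cells, function(p) {
      sum(dye[points_in_polygon(pxx, pyy, p)])
    }, numeric(1))
    out <- list(mode = mode, integrated_dye = integrated,
                index = mean(integrated))
    if (!is.null(control_mean)) {
      out$normalized <- integrated / control_mean
      out$index <- mean(out$normalized)
    }
    structure(out, class = "uptake_result")
  }
}

#' @export
print.uptake_result <- function(x, ...) {
  if (x$mode == "beads") {
    cat(sprintf("uptake index (beads): %.3f internalized/cell, %.3f bound/cell (n=%d cells)\n",
                x$index, x$bound_per_cell, length(x$internalized)))
  } else {
    cat(sprintf("uptake (apoptotic cells): mean %s dye/cell (n=%d cells)\n",
                signif(x$index, 4), length(x$integrated_dye)))
  }
  invisible(x)
}
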