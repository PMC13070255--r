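# Co-clustering statistics on two-species localization data.
#
# G(r): the density of a target species in annuli around each reference
# molecule, normalized to the target's mean density over the ROI. G(r) = 1
# for independent species; short-range enrichment indicates co-clustering,
# enrichment just beyond the cluster scale indicates contacting clusters.
# Because raw G(r) scales with protein density, a min-max scaled curve is
# carried alongside. Edge effects are handled by border exclusion: a
# reference point contributes to an annulus only if that annulus fits
# inside the ROI around it.

as_loc_table <- function(table) {
  if (is.list(table) && !is.null(table$table)) table <- table$table
  stopifnot(is.data.frame(table), all(c("x", "y") %in% names(table)))
  table
}

# Per-reference annulus counts. Exact: targets are bucketed on a grid of
# cell size r_max, and only the 3x3 cell neighbourhood of each reference
# (a superset of the r_max disk) is examined, so counts are identical to
# the all-pairs computation.
annulus_counts <- function(rx, ry, tx, ty, edges) {
  nb <- length(edges) - 1
  nr <- length(rx)
  r_max <- edges[nb + 1]
  counts <- matrix(0L, nr, nb)
  key <- function(cx, cy) paste(cx, cy)
  tcx <- floor(tx / r_max); tcy <- floor(ty / r_max)
  cell_of <- split(seq_along(tx), key(tcx, tcy))
  rcx <- floor(rx / r_max); rcy <- floor(ry / r_max)
  ref_cells <- split(seq_len(nr), key(rcx, rcy))
  for (rc in names(ref_cells)) {
    refs <- ref_cells[[rc]]
    cx <- rcx[refs[1]]; cy <- rcy[refs[1]]
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      cand <- c(cand, cell_of[[key(cx + dx, cy + dy)]])
    }
    if (length(cand) == 0) next
    d <- sqrt(outer(rx[refs], tx[cand], "-")^2 +
              outer(ry[refs], ty[cand], "-")^2)
    idx <- findInterval(d, edges, left.open = FALSE)
    idx[d >= r_max] <- 0L
    rows <- length(refs)
    flat <- idx + nb * (row(d) - 1L)
    flat <- flat[idx > 0L]
    tab <- tabulate(flat, nbins = nb * rows)
    counts[refs, ] <- matrix(tab, rows, nb, byrow = TRUE)
  }
  counts
}

#' Cross-species radial distribution function G(r)
#'
#' @param reference,target Localization tables (data.frames with \code{x},
#'   \code{y} in nm, or generator output lists).
#' @param bins Annulus edges in nm, strictly increasing; default 0--500 nm
#'   in 10 nm bins, matching the 100--300 nm cluster length scales of
#'   receptor nanodomains.
#' @param roi ROI polygon (nm). Target density is taken as
#'   \code{nrow(target) / area(roi)}.
#' @return A \code{radial_distribution}: data.frame with \code{r_lo},
#'   \code{r_hi}, \code{r_mid}, \code{g}, \code{g_scaled},
#'   \code{n_reference} (references contributing per bin), plus attributes.
#'   Bins whose annuli fit around no reference point are NA.
#' @export
radial_distribution <- function(reference, target, bins = seq(0, 500, by = 10),
                                roi) {
  reference <- as_loc_table(reference)
  target <- as_loc_table(target)
  if (nrow(reference) == 0 || nrow(target) == 0) {
    stop("reference and target must be non-empty")
  }
  if (any(diff(bins) <= 0) || length(bins) < 2) {
    stop("bins must be strictly increasing edges")
  }
  A <- polygon_area(roi)
  if (A <= 0) stop("roi area must be positive")
  nb <- length(bins) - 1
  lambda <- nrow(target) / A

  dbound <- dist_to_polygon_boundary(reference$x, reference$y, roi)
  counts <- annulus_counts(reference$x, reference$y, target$x, target$y, bins)
  area_bin <- pi * (bins[-1]^2 - bins[-(nb + 1)]^2)

  g <- rep(NA_real_, nb)
  n_ref <- integer(nb)
  for (j in seq_len(nb)) {
    keep <- dbound >= bins[j + 1]
    n_ref[j] <- sum(keep)
    if (n_ref[j] > 0) {
      g[j] <- mean(counts[keep, j]) / (area_bin[j] * lambda)
    }
  }
  if (all(n_ref == 0)) stop("all reference points are edge-excluded")
  rng <- range(g, na.rm = TRUE)
  g_scaled <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  out <- data.frame(r_lo = bins[-(nb + 1)], r_hi = bins[-1],
                    r_mid = (bins[-1] + bins[-(nb + 1)]) / 2,
                    g = g, g_scaled = g_scaled, n_reference = n_ref)
  attr(out, "lambda_target") <- lambda
  attr(out, "roi_area") <- A
  class(out) <- c("radial_distribution", "data.frame")
  out
}

#' Randomize localization positions over an ROI
#'
#' Monte-Carlo null for non-interacting proteins: the same number of
#' molecules placed i.i.d. uniformly over the ROI; species, frame and
#' precision labels are preserved.
#'
#' @param table Localization table.
#' @param roi ROI polygon (nm).
#' @param seed Integer seed.
#' @return A table of the same shape with new \code{x}, \code{y}.
#' @export
randomize_positions <- function(table, roi, seed = NULL) {
  table <- as_loc_table(table)
  if (polygon_area(roi) <= 0) stop("roi area must be positive")
  if (nrow(table) == 0) return(table)
  with_local_seed(seed, {
    p <- runif_in_polygon(nrow(table), roi)
    table$x <- p[, 1]
    table$y <- p[, 2]
    table
  })
}

#' Monte-Carlo randomization envelope for G(r)
#'
#' Pointwise 2.5th/97.5th percentile envelope of G(r) over \code{n_reps}
#' position randomizations of the reference species (the reference is the
#' species whose positions the null hypothesis scrambles).
#'
#' @inheritParams radial_distribution
#' @param n_reps Number of randomizations (>= 20).
#' @param seed Integer seed.
#' @return List with \code{low}, \code{high} (per-bin), \code{n_reps}.
#' @export
mc_envelope <- function(reference, target, bins = seq(0, 500, by = 10), roi,
                        n_reps = 100, seed = NULL) {
  if (n_reps < 20) stop("n_reps must be >= 20 for a 95% envelope")
  reference <- as_loc_table(reference)
  with_local_seed(seed, {
    gs <- vapply(seq_len(n_reps), function(i) {
      rr <- randomize_positions(reference, roi, seed = NULL)
      radial_distribution(rr, target, bins, roi)$g
    }, numeric(length(bins) - 1))
    list(low = apply(gs, 1, stats::quantile, probs = 0.025, na.rm = TRUE),
         high = apply(gs, 1, stats::quantile, probs = 0.975, na.rm = TRUE),
         n_reps = n_reps)
  })
}

## ---- OPTICS cluster extraction -------------------------------------------

# Neighbor lists within eps via cell binning (exact).
eps_neighbors <- function(x, y, eps) {
  n <- length(x)
  cx <- floor(x / eps); cy <- floor(y / eps)
  key <- paste(cx, cy)
  cell_of <- split(seq_len(n), key)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cx[i] + dx, cy[i] + dy)
      cand <- c(cand, cell_of[[k]])
    }
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    keep <- d2 <= eps^2
    out[[i]] <- list(idx = cand[keep], d = sqrt(d2[keep]))
  }
  out
}

# OPTICS ordering with generating distance eps and minPts (point itself
# included in the minPts count, as in the common implementations).
optics_order <- function(x, y, eps, min_points) {
  n <- length(x)
  nb <- eps_neighbors(x, y, eps)
  core <- vapply(seq_len(n), function(i) {
    d <- sort(nb[[i]]$d)
    if (length(d) >= min_points) d[min_points] else Inf
  }, numeric(1))
  reach <- rep(Inf, n)
  processed <- rep(FALSE, n)
  order_out <- integer(0)
  seeds <- rep(Inf, n)       # tentative reachability of unprocessed seeds
  for (start in seq_len(n)) {
    if (processed[start]) next
    queue <- start
    seeds[start] <- Inf
    while (length(queue) > 0) {
      # pop unprocessed point with smallest tentative reachability
      qs <- seeds[queue]
      k <- which.min(qs)
      p <- queue[k]
      queue <- queue[-k]
      if (processed[p]) next
      processed[p] <- TRUE
      reach[p] <- seeds[p]
      order_out <- c(order_out, p)
      if (is.finite(core[p])) {
        ns <- nb[[p]]
        upd <- !processed[ns$idx]
        if (any(upd)) {
          ids <- ns$idx[upd]
          newr <- pmax(core[p], ns$d[upd])
          better <- newr < seeds[ids]
          if (any(better)) {
            seeds[ids[better]] <- newr[better]
            queue <- unique(c(queue, ids[better]))
          }
        }
      }
    }
  }
  list(order = order_out, reachability = reach[order_out],
       core_dist = core[order_out])
}

hull_polygon <- function(x, y) {
  h <- convex_hull(x, y)
  if (nrow(h) >= 3) return(h)
  # degenerate (collinear) cluster: thin rectangle around the segment
  eps <- 1e-6
  if (nrow(h) == 1) h <- rbind(h, h)
  v <- h[2, ] - h[1, ]
  nv <- sqrt(sum(v^2))
  u <- if (nv > 0) v / nv else c(1, 0)
  perp <- c(-u[2], u[1]) * eps
  rbind(h[1, ] + perp, h[2, ] + perp, h[2, ] - perp, h[1, ] - perp)
}

#' Extract clusters from a localization table (OPTICS)
#'
#' Orders points by OPTICS density reachability (generating distance
#' \code{max_reach_nm}, \code{min_points} neighbours including the point
#' itself) and extracts clusters by reachability threshold at
#' \code{max_reach_nm}; points whose reachability and core distance both
#' exceed the threshold are noise, as are clusters with fewer than
#' \code{min_points} members. Per-cluster centroid, convex-hull boundary
#' and diameter (maximum pairwise member distance) are computed.
#'
#' @param table Localization table.
#' @param min_points Minimum cluster membership (>= 2).
#' @param max_reach_nm Reachability threshold / generating distance, nm.
#' @return A \code{cluster_set}: list with \code{clusters} (list of
#'   \code{members}, \code{centroid}, \code{hull}, \code{diameter}),
#'   \code{noise} (point indices), \code{table}, \code{params}.
#' @export
extract_clusters <- function(table, min_points = 5, max_reach_nm = 50) {
  table <- as_loc_table(table)
  if (nrow(table) == 0) stop("table must be non-empty")
  if (min_points < 2) stop("min_points must be >= 2")
  ord <- optics_order(table$x, table$y, eps = max_reach_nm,
                      min_points = min_points)
  labels <- rep(0L, nrow(table))
  cur <- 0L
  for (i in seq_along(ord$order)) {
    p <- ord$order[i]
    if (ord$reachability[i] > max_reach_nm) {
      if (ord$core_dist[i] <= max_reach_nm) {
        cur <- cur + 1L
        labels[p] <- cur
      } else {
        labels[p] <- 0L
      }
    } else {
      labels[p] <- cur
    }
  }
  clusters <- list()
  for (cl in seq_len(max(labels, 0L))) {
    members <- which(labels == cl)
    if (length(members) < min_points) {
      labels[members] <- 0L
      next
    }
    hx <- table$x[members]; hy <- table$y[members]
    hull <- hull_polygon(hx, hy)
    hv <- convex_hull(hx, hy)
    diam <- if (nrow(hv) > 1) max(stats::dist(hv)) else 0
    clusters[[length(clusters) + 1]] <- list(
      members = members,
      centroid = c(x = mean(hx), y = mean(hy)),
      hull = hull, diameter = diam
    )
  }
  structure(list(clusters = clusters, noise = which(labels == 0L),
                 table = table,
                 params = list(min_points = min_points,
                               max_reach_nm = max_reach_nm)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters, %d noise points (of %d)\n",
              length(x$clusters), length(x$noise), nrow(x$table)))
  invisible(x)
}

# relation of one cluster (from set A) to all clusters of set B
relate_one <- function(cl, clusters_b, contact_dist, intermix_frac, table_a) {
  px <- table_a$x[cl$members]; py <- table_a$y[cl$members]
  for (cb in clusters_b) {
    inside <- points_in_polygon(px, py, cb$hull)
    if (mean(inside) >= intermix_frac) return("colocalized")
  }
  for (cb in clusters_b) {
    if (polygon_min_distance(cl$hull, cb$hull) <= contact_dist) {
      return("contacting")
    }
  }
  "neither"
}

#' Classify cluster relations between two species
#'
#' For each cluster of species A: \emph{colocalized} (intermixed) if at
#' least \code{intermix_frac} of its members fall inside some B-cluster
#' boundary; otherwise \emph{contacting} if its boundary lies within
#' \code{contact_dist_nm} of some B-cluster boundary; otherwise
#' \emph{neither}. Colocalized is evaluated first, so the categories are
#' mutually exclusive. If \code{roi} is given, the classification is
#' repeated after randomizing the positions of the B species over the ROI
#' (re-extracting B clusters with the same parameters) to give the chance
#' baseline.
#'
#' @param clusters_a,clusters_b \code{cluster_set}s from
#'   \code{\link{extract_clusters}}.
#' @param contact_dist_nm Boundary-to-boundary contact threshold, nm
#'   (default 20 nm, of the order of the localization precision).
#' @param intermix_frac Member fraction required for colocalization
#'   (default 0.5).
#' @param roi,seed Optional: ROI polygon and seed for the randomized
#'   baseline.
#' @return A \code{relation_fractions} list: \code{colocalized_fraction},
#'   \code{contacting_fraction}, \code{neither_fraction} (summing to 1),
#'   per-cluster \code{relation}, parameters, and when \code{roi} is given
#'   \code{randomized_colocalized}, \code{randomized_contacting}.
#' @export
classify_cluster_relations <- function(clusters_a, clusters_b,
                                       contact_dist_nm = 20,
                                       intermix_frac = 0.5,
                                       roi = NULL, seed = NULL) {
  stopifnot(inherits(clusters_a, "cluster_set"),
            inherits(clusters_b, "cluster_set"))
  if (length(clusters_a$clusters) == 0 || length(clusters_b$clusters) == 0) {
    stop("both cluster sets must be non-empty")
  }
  rel <- vapply(clusters_a$clusters, relate_one, character(1),
                clusters_b = clusters_b$clusters,
                contact_dist = contact_dist_nm,
                intermix_frac = intermix_frac,
                table_a = clusters_a$table)
  nA <- length(rel)
  out <- list(
    colocalized_fraction = sum(rel == "colocalized") / nA,
    contacting_fraction = sum(rel == "contacting") / nA,
    neither_fraction = sum(rel == "neither") / nA,
    relation = rel,
    params = list(contact_dist_nm = contact_dist_nm,
                  intermix_frac = intermix_frac)
  )
  if (!is.null(roi)) {
    rnd_tab <- randomize_positions(clusters_b$table, roi, seed = seed)
    rnd_b <- extract_clusters(rnd_tab,
                              min_points = clusters_b$params$min_points,
                              max_reach_nm = clusters_b$params$max_reach_nm)
    if (length(rnd_b$clusters) == 0) {
      out$randomized_colocalized <- 0
      out$randomized_contacting <- 0
    } else {
      rrel <- vapply(clusters_a$clusters, relate_one, character(1),
                     clusters_b = rnd_b$clusters,
                     contact_dist = contact_dist_nm,
                     intermix_frac = intermix_frac,
                     table_a = clusters_a$table)
      out$randomized_colocalized <- sum(rrel == "colocalized") / nA
      out$randomized_contacting <- sum(rrel == "contacting") / nA
    }
  }
  class(out) <- "relation_fractions"
  out
}

#' @export
print.relation_fractions <- function(x, ...) {
  cat(sprintf(
    "cluster relations (n=%d A clusters): colocalized %.3f, contacting %.3f, neither %.3f\n",
    length(x$relation), x$colocalized_fraction, x$contacting_fraction,
    x$neither_fraction))
  if (!is.null(x$randomized_colocalized)) {
    cat(sprintf("  randomized baseline: colocalized %.3f, contacting %.3f\n",
                x$randomized_colocalized, x$randomized_contacting))
  }
  invisible(x)
}
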