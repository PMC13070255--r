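# Synthetic two-species localization patterns with known ground truth.
# These emulate the point-pattern regimes against which the co-clustering
# statistics are validated: complete spatial randomness, shared-disk
# co-clustering, and adjacent ("contacting") clusters.

#' Specification for a synthetic two-species point pattern
#'
#' Describes a square field populated by two molecular species in one of
#' three regimes: \code{"csr"} (each species an independent homogeneous
#' Poisson process), \code{"coclustered"} (both species occupy the same
#' circular nanoclusters), or \code{"contacting"} (each species occupies its
#' own cluster, placed edge-to-edge with a partner cluster of the other
#' species, separated by \code{contact_gap}).
#'
#' The default label density of 0.4 molecules per um^2 (one label per
#' 2.5 um^2) matches sparse single-fluorophore labelling of receptors on a
#' macrophage surface; the default 120 nm cluster diameter matches receptor
#' nanoclusters resolvable by localization microscopy.
#'
#' @param field_size Side length of the square field, nm.
#' @param mode One of \code{"csr"}, \code{"coclustered"}, \code{"contacting"}.
#' @param species_densities Length-2 numeric, molecules per um^2 per species
#'   (csr mode; also used to derive the default cluster count).
#' @param cluster_diameter Cluster diameter, nm.
#' @param cluster_occupancy Length-2 integer, molecules per cluster per species.
#' @param n_clusters Number of clusters (or cluster pairs in contacting mode).
#'   Default derives from \code{species_densities[1]} and the occupancy.
#' @param contact_gap Edge-to-edge gap between paired clusters, nm
#'   (contacting mode).
#' @param localization_precision_sd Gaussian localization jitter, nm.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A \code{pattern_spec} object.
#' @export
pattern_spec <- function(field_size = 10000,
                         mode = c("csr", "coclustered", "contacting"),
                         species_densities = c(0.4, 0.4),
                         cluster_diameter = 120,
                         cluster_occupancy = c(10, 10),
                         n_clusters = NULL,
                         contact_gap = 0,
                         localization_precision_sd = 10,
                         seed = NULL) {
  mode <- match.arg(mode)
  stop_if_not_scalar_pos(field_size, "field_size")
  if (length(species_densities) != 2 || any(!is.finite(species_densities)) ||
      any(species_densities <= 0)) {
    stop("`species_densities` must be two positive densities (per um^2)")
  }
  stop_if_not_scalar_pos(cluster_diameter, "cluster_diameter")
  stop_if_not_scalar_pos(contact_gap, "contact_gap", strict = FALSE)
  stop_if_not_scalar_pos(localization_precision_sd,
                         "localization_precision_sd", strict = FALSE)
  if (is.null(n_clusters)) {
    area_um2 <- (field_size / 1000)^2
    n_clusters <- max(1L, round(species_densities[1] * area_um2 /
                                  cluster_occupancy[1]))
  }
  structure(list(
    field_size = field_size, mode = mode,
    species_densities = species_densities,
    cluster_diameter = cluster_diameter,
    cluster_occupancy = as.integer(cluster_occupancy),
    n_clusters = as.integer(n_clusters),
    contact_gap = contact_gap,
    localization_precision_sd = localization_precision_sd,
    seed = seed
  ), class = "pattern_spec")
}

# uniform points in a disk of radius R about (cx, cy)
runif_in_disk <- function(n, cx, cy, R) {
  r <- R * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Generate a two-species localization pattern
#'
#' Draws a point pattern according to a \code{\link{pattern_spec}} and
#' returns it together with its ground truth (cluster assignment per point
#' and cluster centres), in the localization-table layout used by all SMLM
#' statistics: columns \code{x}, \code{y} (nm), \code{species},
#' \code{frame}, \code{precision} (nm), plus ground-truth \code{cluster}.
#'
#' Cluster centres are inset from the field edge by one cluster radius (plus
#' the gap and partner radius in contacting mode) so clusters lie wholly
#' inside the field. Localization jitter is applied after placement.
#'
#' @param spec A \code{\link{pattern_spec}}.
#' @return List with \code{table} (data.frame), \code{centers} (data.frame
#'   with cluster centres per species), \code{roi} (field polygon) and
#'   \code{spec}.
#' @export
gen_point_pattern <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  with_local_seed(spec$seed, {
    L <- spec$field_size
    roi <- rect_roi(L, L)
    sp_names <- c("A", "B")
    R <- spec$cluster_diameter / 2
    jit <- spec$localization_precision_sd

    if (spec$mode == "csr") {
      area_um2 <- (L / 1000)^2
      tabs <- lapply(1:2, function(s) {
        n <- stats::rpois(1, spec$species_densities[s] * area_um2)
        data.frame(
          x = stats::runif(n, 0, L), y = stats::runif(n, 0, L),
          species = rep(sp_names[s], n), cluster = rep(NA_integer_, n)
        )
      })
      centers <- data.frame(cluster = integer(0), species = character(0),
                            x = numeric(0), y = numeric(0))
      tab <- rbind(tabs[[1]], tabs[[2]])
    } else {
      k <- spec$n_clusters
      inset <- if (spec$mode == "contacting") 3 * R + spec$contact_gap else R
      inset <- min(inset, L / 2 - 1e-9)
      cx <- stats::runif(k, inset, L - inset)
      cy <- stats::runif(k, inset, L - inset)
      if (spec$mode == "coclustered") {
        centers <- data.frame(cluster = rep(seq_len(k), 2),
                              species = rep(sp_names, each = k),
                              x = rep(cx, 2), y = rep(cy, 2))
      } else {
        # partner cluster of species B placed edge-to-edge at a random angle
        th <- stats::runif(k, 0, 2 * pi)
        d <- 2 * R + spec$contact_gap  # centre-to-centre
        centers <- data.frame(cluster = rep(seq_len(k), 2),
                              species = rep(sp_names, each = k),
                              x = c(cx, cx + d * cos(th)),
                              y = c(cy, cy + d * sin(th)))
      }
      rows <- lapply(1:2, function(s) {
        cen <- centers[centers$species == sp_names[s], ]
        m <- spec$cluster_occupancy[s]
        do.call(rbind, lapply(seq_len(nrow(cen)), function(i) {
          p <- runif_in_disk(m, cen$x[i], cen$y[i], R)
          data.frame(x = p[, 1], y = p[, 2],
                     species = rep(sp_names[s], m),
                     cluster = rep(cen$cluster[i], m))
        }))
      })
      tab <- rbind(rows[[1]], rows[[2]])
    }

    if (jit > 0 && nrow(tab) > 0) {
      tab$x <- tab$x + stats::rnorm(nrow(tab), 0, jit)
      tab$y <- tab$y + stats::rnorm(nrow(tab), 0, jit)
    }
    tab$frame <- 0L
    tab$precision <- jit
    tab <- tab[, c("x", "y", "species", "frame", "precision", "cluster")]
    rownames(tab) <- NULL
    list(table = tab, centers = centers, roi = roi, spec = spec)
  })
}
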