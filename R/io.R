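# File I/O: localization and trajectory CSV, ROI GeoJSON, TIFF stacks.

loc_aliases <- c(
  "x [nm]" = "x", "y [nm]" = "y",
  "uncertainty [nm]" = "precision", "uncertainty_xy [nm]" = "precision",
  "precision [nm]" = "precision", "x_nm" = "x", "y_nm" = "y",
  "precision_nm" = "precision", "id" = "id", "frame" = "frame",
  "species" = "species", "x" = "x", "y" = "y", "precision" = "precision"
)

#' Read a localization table from CSV
#'
#' Accepts the package's native columns (\code{x}, \code{y},
#' \code{species}, \code{frame}, \code{precision}; nm) as well as
#' ThunderSTORM-style aliases (\code{x [nm]}, \code{y [nm]},
#' \code{uncertainty [nm]}).
#'
#' @param path CSV file path.
#' @return Localization data.frame.
#' @export
read_localizations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  hit <- nm %in% names(loc_aliases)
  names(df)[hit] <- unname(loc_aliases[nm[hit]])
  if (!all(c("x", "y") %in% names(df))) {
    stop("localization CSV must provide x and y coordinates (nm)")
  }
  if (!"species" %in% names(df)) df$species <- "A"
  if (!"frame" %in% names(df)) df$frame <- 0L
  if (!"precision" %in% names(df)) df$precision <- NA_real_
  df[, c("x", "y", "species", "frame", "precision",
         setdiff(names(df), c("x", "y", "species", "frame", "precision")))]
}

#' Write a localization table to CSV
#' @param table Localization data.frame.
#' @param path Output path.
#' @export
write_localizations <- function(table, path) {
  utils::write.csv(as_loc_table(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory table from CSV
#'
#' Expects columns \code{id}, \code{frame} and coordinates as \code{x_nm},
#' \code{y_nm} (or plain \code{x}, \code{y}); optional
#' \code{precision_nm} / \code{precision} and \code{frame_interval}.
#'
#' @param path CSV file path.
#' @return Trajectory data.frame in internal layout.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  ren <- c("x_nm" = "x", "y_nm" = "y", "precision_nm" = "precision")
  hit <- nm %in% names(ren)
  names(df)[hit] <- unname(ren[nm[hit]])
  if (!all(c("id", "frame", "x", "y") %in% names(df))) {
    stop("trajectory CSV must provide id, frame, x_nm, y_nm")
  }
  df
}

#' Write a trajectory table to CSV
#' @param tracks Trajectory data.frame or generator output.
#' @param path Output path.
#' @export
write_trajectories <- function(tracks, path) {
  df <- as_track_df(tracks)
  out <- data.frame(id = df$id, frame = df$frame,
                    x_nm = df$x, y_nm = df$y)
  if ("precision" %in% names(df)) out$precision_nm <- df$precision
  if ("frame_interval" %in% names(df)) out$frame_interval <- df$frame_interval
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read an ROI polygon from GeoJSON
#' @param path GeoJSON file with a Polygon geometry (nm coordinates).
#' @return Vertex matrix.
#' @export
read_roi_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (!is.null(gj$geometry)) gj$geometry else
    if (!is.null(gj$features)) gj$features$geometry else gj
  coords <- geom$coordinates
  if (is.list(coords)) coords <- coords[[1]]
  if (length(dim(coords)) == 3) coords <- coords[1, , ]
  poly <- as.matrix(coords)
  # drop a repeated closing vertex
  n <- nrow(poly)
  if (n > 1 && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  as_polygon(poly)
}

#' Write an ROI polygon to GeoJSON
#' @param poly Vertex matrix (nm).
#' @param path Output path.
#' @export
write_roi_geojson <- function(poly, path) {
  poly <- as_polygon(poly)
  ring <- rbind(poly, poly[1, , drop = FALSE])
  obj <- list(type = "Feature", properties = list(units = "nm"),
              geometry = list(type = "Polygon",
                              coordinates = list(unname(
                                lapply(seq_len(nrow(ring)),
                                       function(i) unname(ring[i, ]))))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Images travel as 32-bit TIFF normalized to [0,1] with a JSON sidecar
# carrying the scale, so arbitrary-range float images round-trip.
img_to_tiff_page <- function(m) t(m[, rev(seq_len(ncol(m))), drop = FALSE])
tiff_page_to_img <- function(p) {
  m <- t(p)
  m[, rev(seq_len(ncol(m))), drop = FALSE]
}

#' Write an image or image stack to TIFF
#'
#' Images use the package convention (dim 1 = x, dim 2 = y, origin
#' bottom-left); pages are stored in standard raster orientation. Values
#' are normalized by the global maximum, recorded in a \code{.json}
#' sidecar next to the file.
#'
#' @param images A matrix or list of matrices.
#' @param path Output TIFF path.
#' @export
write_image_stack <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  mx <- max(vapply(images, max, numeric(1)), 1e-12)
  pages <- lapply(images, function(m) img_to_tiff_page(m / mx))
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  jsonlite::write_json(list(scale = mx), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack from TIFF
#' @param path TIFF path (a \code{.json} scale sidecar is honoured when
#'   present).
#' @return List of matrices in package orientation.
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    scale <- jsonlite::read_json(sidecar)$scale
  }
  lapply(pages, function(p) tiff_page_to_img(p) * scale)
}
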