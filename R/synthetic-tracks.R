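# Synthetic 2-D single-particle trajectories: Brownian, confined (specular
# reflection at a circular corral) and directed (Brownian plus drift), with
# additive Gaussian localization error.

#' Specification for synthetic trajectories
#'
#' All tracks share one motion model. Brownian increments have variance
#' \code{2 * D * dt} per axis. Confined motion applies specular reflection
#' at a circular corral boundary of diameter \code{corral_diameter}
#' (reflection, not rejection, is used because it preserves the step-length
#' distribution; it slightly smooths the short-lag MSD near the boundary).
#' Directed motion adds a constant drift of \code{velocity} along a random
#' per-track heading. Localization error is added to the observed positions
#' only; ground-truth positions are returned unjittered.
#'
#' Defaults mirror a live-cell receptor-tracking acquisition: 100 ms frames
#' and 20 nm localization error.
#'
#' @param model One of \code{"brownian"}, \code{"confined"}, \code{"directed"}.
#' @param D Diffusion coefficient, um^2/s (>= 0).
#' @param corral_diameter Corral diameter, nm (confined only).
#' @param velocity Drift speed, um/s (directed only).
#' @param n_tracks,track_length Number of tracks and frames per track.
#' @param frame_interval Frame time, s.
#' @param localization_error_sd Localization error sd per axis, nm.
#' @param seed Integer seed.
#' @return A \code{motion_spec} object.
#' @export
motion_spec <- function(model = c("brownian", "confined", "directed"),
                        D = 0.1, corral_diameter = 200, velocity = 1,
                        n_tracks = 100, track_length = 100,
                        frame_interval = 0.1, localization_error_sd = 20,
                        seed = NULL) {
  model <- match.arg(model)
  stop_if_not_scalar_pos(D, "D", strict = FALSE)
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  stop_if_not_scalar_pos(localization_error_sd, "localization_error_sd",
                         strict = FALSE)
  if (model == "confined") {
    stop_if_not_scalar_pos(corral_diameter, "corral_diameter")
    if (corral_diameter < 2 * localization_error_sd) {
      stop("corral_diameter below 2 * localization_error_sd is degenerate")
    }
  }
  structure(list(model = model, D = D, corral_diameter = corral_diameter,
                 velocity = velocity, n_tracks = as.integer(n_tracks),
                 track_length = as.integer(track_length),
                 frame_interval = frame_interval,
                 localization_error_sd = localization_error_sd, seed = seed),
            class = "motion_spec")
}

# Specular reflection of proposed positions (bx, by) back into the circle of
# radius R centred at 0, given in-circle previous positions (ax, ay).
# Vectorized over tracks; iterates for the rare step that re-exits.
reflect_into_circle <- function(ax, ay, bx, by, R, max_iter = 64L) {
  for (it in seq_len(max_iter)) {
    out <- (bx^2 + by^2) > R^2
    if (!any(out)) break
    dx <- bx[out] - ax[out]; dy <- by[out] - ay[out]
    a2 <- dx^2 + dy^2
    ad <- ax[out] * dx + ay[out] * dy
    c0 <- ax[out]^2 + ay[out]^2 - R^2
    tt <- (-ad + sqrt(pmax(ad^2 - a2 * c0, 0))) / a2   # first boundary hit
    hx <- ax[out] + tt * dx; hy <- ay[out] + tt * dy
    nx <- hx / R; ny <- hy / R
    vx <- bx[out] - hx; vy <- by[out] - hy
    dot <- vx * nx + vy * ny
    bx[out] <- hx + (vx - 2 * dot * nx)
    by[out] <- hy + (vy - 2 * dot * ny)
    ax[out] <- hx; ay[out] <- hy
  }
  cbind(bx, by)
}

#' Generate a set of trajectories
#'
#' @param spec A \code{\link{motion_spec}}.
#' @return List with \code{tracks}: data.frame (\code{id}, \code{frame}
#'   0-based, \code{x}, \code{y} observed nm, \code{true_x}, \code{true_y},
#'   \code{precision} nm, \code{frame_interval} s), and \code{spec}. For
#'   confined motion tracks start at the corral centre (0, 0); otherwise at
#'   the origin.
#' @export
gen_trajectories <- function(spec) {
  stopifnot(inherits(spec, "motion_spec"))
  with_local_seed(spec$seed, {
    nt <- spec$n_tracks; L <- spec$track_length; dt <- spec$frame_interval
    step_sd <- sqrt(2 * spec$D * 1e6 * dt)      # nm per axis
    x <- matrix(0, nt, L); y <- matrix(0, nt, L)
    drift <- NULL
    if (spec$model == "directed") {
      th <- stats::runif(nt, 0, 2 * pi)
      v <- spec$velocity * 1000 * dt            # nm per frame
      drift <- cbind(v * cos(th), v * sin(th))
    }
    R <- spec$corral_diameter / 2
    for (f in 2:L) {
      px <- x[, f - 1] + stats::rnorm(nt, 0, step_sd)
      py <- y[, f - 1] + stats::rnorm(nt, 0, step_sd)
      if (!is.null(drift)) {
        px <- px + drift[, 1]; py <- py + drift[, 2]
      }
      if (spec$model == "confined") {
        p <- reflect_into_circle(x[, f - 1], y[, f - 1], px, py, R)
        px <- p[, 1]; py <- p[, 2]
      }
      x[, f] <- px; y[, f] <- py
    }
    err <- spec$localization_error_sd
    ox <- x + if (err > 0) stats::rnorm(nt * L, 0, err) else 0
    oy <- y + if (err > 0) stats::rnorm(nt * L, 0, err) else 0
    tracks <- data.frame(
      id = rep(seq_len(nt), each = L),
      frame = rep(seq_len(L) - 1L, nt),
      x = as.vector(t(ox)), y = as.vector(t(oy)),
      true_x = as.vector(t(x)), true_y = as.vector(t(y)),
      precision = err, frame_interval = dt
    )
    list(tracks = tracks, spec = spec)
  })
}
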