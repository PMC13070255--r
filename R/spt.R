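# Single-particle trajectory analysis: precision filtering, MSD-based
# diffusion coefficients, moment-scaling-spectrum (MSS) motion
# classification, and confinement-zone size.
#
# MSS: the ρ-th absolute moment of the displacement at lag τ is assumed to
# follow a power law μ_ρ(τ) ∝ τ^γ_ρ. The MSS slope is the slope of γ_ρ
# versus ρ through the origin: 0.5 for free (Brownian) diffusion, below
# 0.5 for confined (subdiffusive) motion, above 0.5 for directed
# (superdiffusive) motion.

as_track_df <- function(tracks) {
  if (is.list(tracks) && !is.null(tracks$tracks)) tracks <- tracks$tracks
  stopifnot(is.data.frame(tracks),
            all(c("id", "frame", "x", "y") %in% names(tracks)))
  tracks
}

#' Filter trajectories by localization precision and length
#'
#' Removes tracks whose mean localization precision exceeds
#' \code{max_precision_nm} (default 25 nm) or whose length is below
#' \code{min_length}.
#'
#' @param tracks Trajectory data.frame (\code{id}, \code{frame}, \code{x},
#'   \code{y}, \code{precision}) or generator output.
#' @param max_precision_nm Precision cutoff, nm.
#' @param min_length Minimum frames per track.
#' @return The filtered data.frame, with attribute \code{removed}
#'   (counts per criterion).
#' @export
filter_trajectories <- function(tracks, max_precision_nm = 25,
                                min_length = 20) {
  df <- as_track_df(tracks)
  if (!"precision" %in% names(df)) df$precision <- 0
  by_id <- split(seq_len(nrow(df)), df$id)
  mean_prec <- vapply(by_id, function(i) mean(df$precision[i]), numeric(1))
  len <- lengths(by_id)
  bad_prec <- mean_prec > max_precision_nm
  bad_len <- len < min_length
  keep_ids <- names(by_id)[!(bad_prec | bad_len)]
  out <- df[df$id %in% as.vector(keep_ids), , drop = FALSE]
  if (nrow(out) == 0) warning("no tracks survive filtering")
  attr(out, "removed") <- c(precision = sum(bad_prec),
                            length = sum(bad_len & !bad_prec))
  out
}

single_track <- function(tracks, id = NULL) {
  df <- as_track_df(tracks)
  if (!is.null(id)) df <- df[df$id == id, , drop = FALSE]
  df[order(df$frame), , drop = FALSE]
}

#' Time-averaged mean squared displacement of one track
#'
#' MSD(τ) averaged over all same-lag displacement pairs, for lags up to
#' \code{max_lag_fraction} of the track length.
#'
#' @param track Data.frame for one track (\code{frame}, \code{x}, \code{y},
#'   nm), frames contiguous.
#' @param max_lag_fraction Largest lag as a fraction of track length.
#' @param frame_interval Frame time in s; taken from the track if present.
#' @return Data.frame with \code{lag_frames}, \code{lag_s}, \code{msd}
#'   (nm^2), \code{n_pairs}.
#' @export
msd <- function(track, max_lag_fraction = 0.25, frame_interval = NULL) {
  tr <- single_track(track)
  n <- nrow(tr)
  max_lag <- max(1L, floor(n * max_lag_fraction))
  if (n < 2) stop("track too short for MSD")
  dt <- frame_interval %||%
    (if ("frame_interval" %in% names(tr)) tr$frame_interval[1] else 1)
  lags <- seq_len(max_lag)
  m <- vapply(lags, function(L) {
    dx <- tr$x[(1 + L):n] - tr$x[1:(n - L)]
    dy <- tr$y[(1 + L):n] - tr$y[1:(n - L)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  data.frame(lag_frames = lags, lag_s = lags * dt, msd = m,
             n_pairs = n - lags)
}

#' Diffusion coefficient from the initial MSD slope
#'
#' OLS fit of MSD versus lag over the first \code{fit_lags} lags with free
#' intercept (the intercept absorbs the constant localization-error offset
#' 4*sigma^2); D = slope / 4 for 2-D diffusion.
#'
#' @param msd_curve Output of \code{\link{msd}}.
#' @param fit_lags Number of initial lags (default 4).
#' @return D in um^2/s (clamped at 0).
#' @export
diffusion_coefficient <- function(msd_curve, fit_lags = 4) {
  k <- min(fit_lags, nrow(msd_curve))
  if (k < 2) stop("need at least 2 lags to fit a slope")
  fit <- stats::lm(msd ~ lag_s, data = msd_curve[seq_len(k), ])
  slope <- unname(stats::coef(fit)[2])       # nm^2 / s
  max(slope / 4, 0) * 1e-6                   # -> um^2/s
}

#' Moment scaling spectrum of one track
#'
#' Computes the time-averaged absolute displacement moments
#' \eqn{\mu_\rho(\tau)} for \eqn{\rho = 1..4}, the power-law indices
#' \eqn{\gamma_\rho} (log-log OLS over lags 1 to a quarter of the track
#' length), and the MSS slope (OLS of \eqn{\gamma_\rho} on \eqn{\rho}
#' constrained through the origin, since \eqn{\gamma_0 = 0}).
#'
#' @param track One track, >= \code{min_length} frames.
#' @param min_length Minimum track length (default 20).
#' @param through_origin Constrain the MSS fit through the origin
#'   (default TRUE).
#' @return List with \code{gamma_rho} (length 4), \code{mss_slope}.
#' @export
mss <- function(track, min_length = 20, through_origin = TRUE) {
  tr <- single_track(track)
  n <- nrow(tr)
  if (n < min_length) stop(sprintf("track shorter than %d frames", min_length))
  max_lag <- max(2L, floor(n / 4))
  lags <- seq_len(max_lag)
  rho <- 1:4
  mu <- sapply(lags, function(L) {
    dx <- tr$x[(1 + L):n] - tr$x[1:(n - L)]
    dy <- tr$y[(1 + L):n] - tr$y[1:(n - L)]
    dr <- sqrt(dx^2 + dy^2)
    vapply(rho, function(p) mean(dr^p), numeric(1))
  })                                          # 4 x n_lags
  if (any(mu <= 0)) stop("degenerate track: non-positive moments")
  lt <- log(lags)
  gamma_rho <- apply(log(mu), 1, function(lm_y) {
    unname(stats::coef(stats::lm(lm_y ~ lt))[2])
  })
  mss_slope <- if (through_origin) {
    sum(gamma_rho * rho) / sum(rho^2)
  } else {
    unname(stats::coef(stats::lm(gamma_rho ~ rho))[2])
  }
  list(gamma_rho = gamma_rho, mss_slope = mss_slope)
}

#' Classify motion from the MSS slope
#'
#' Confined below \code{low}, free within \code{[low, high]}, directed
#' above \code{high}. The defaults (0.30, 0.63) bracket the Brownian value
#' 0.5 with the width required by the sampling scatter of the MSS slope on
#' 100-frame tracks.
#'
#' @param mss_slope Scalar MSS slope.
#' @param low,high Class thresholds.
#' @return One of \code{"confined"}, \code{"free"}, \code{"directed"}.
#' @export
classify_motion <- function(mss_slope, low = 0.30, high = 0.63) {
  if (!is.finite(mss_slope)) stop("mss_slope must be finite")
  if (mss_slope < low) "confined"
  else if (mss_slope > high) "directed"
  else "free"
}

# 90th percentile of |projection difference| for i.i.d. points uniform in a
# disk of unit diameter, projected on a diameter. Used to convert the
# measured pairwise-projected extent into a corral diameter. Value obtained
# by numerical integration of the semicircle-density convolution (see the
# methods vignette); the oracle is re-derived in the test-suite.
UNIFORM_DISK_PROJ_Q90 <- 0.5888

#' Confinement-zone diameter of a confined track
#'
#' Operationalizes the corral size as the 90th percentile of pairwise
#' distances between positions projected on the major axis of the track's
#' positional variance-covariance matrix, rescaled by the same statistic
#' of a uniformly occupied circular corral of unit diameter, so that a
#' well-sampled circular corral of diameter d returns approximately d.
#'
#' When a \code{precision} column is present, the localization-error
#' contribution is deconvolved by shrinking the projected spread by
#' \code{sqrt(1 - sigma^2 / var_proj)}.
#'
#' @param track One track (nm).
#' @return Diameter estimate in nm (0 for a degenerate point-mass track,
#'   with a warning).
#' @export
confinement_diameter <- function(track) {
  tr <- single_track(track)
  P <- cbind(tr$x, tr$y)
  V <- stats::cov(P)
  if (!all(is.finite(V))) stop("degenerate covariance")
  if (max(abs(V)) == 0) {
    warning("point-mass track: confinement diameter 0")
    return(0)
  }
  ev <- eigen(V, symmetric = TRUE)
  axis <- ev$vectors[, 1]
  proj <- as.vector(P %*% axis)
  q90 <- stats::quantile(abs(outer(proj, proj, "-")[upper.tri(diag(length(proj)))]),
                         probs = 0.9, names = FALSE)
  if ("precision" %in% names(tr)) {
    s2 <- mean(tr$precision)^2
    vp <- stats::var(proj)
    if (vp > s2) q90 <- q90 * sqrt(1 - s2 / vp)
  }
  q90 / UNIFORM_DISK_PROJ_Q90
}

#' Per-track diffusion analysis
#'
#' Runs MSD, MSS and classification for every track in a set.
#'
#' @param tracks Trajectory data.frame or generator output.
#' @param fit_lags,low,high,min_length Passed through.
#' @return Data.frame with one row per track: \code{id}, \code{n_frames},
#'   \code{D}, \code{gamma_2}, \code{mss_slope}, \code{motion_class},
#'   \code{confinement_diameter} (NA unless confined).
#' @export
analyze_tracks <- function(tracks, fit_lags = 4, low = 0.30, high = 0.63,
                           min_length = 20) {
  df <- as_track_df(tracks)
  ids <- unique(df$id)
  rows <- lapply(ids, function(i) {
    tr <- single_track(df, i)
    if (nrow(tr) < min_length) return(NULL)
    mc <- msd(tr)
    D <- diffusion_coefficient(mc, fit_lags)
    ms <- mss(tr, min_length = min_length)
    cls <- classify_motion(ms$mss_slope, low, high)
    cd <- if (cls == "confined") confinement_diameter(tr) else NA_real_
    data.frame(id = i, n_frames = nrow(tr), D = D,
               gamma_2 = ms$gamma_rho[2], mss_slope = ms$mss_slope,
               motion_class = cls, confinement_diameter = cd)
  })
  do.call(rbind, rows)
}

#' Motion-class composition of a trajectory set
#'
#' Fractions of each motion class (optionally per group), mean D per
#' class, mean confinement diameter, with bootstrap confidence intervals
#' over tracks.
#'
#' @param results Data.frame from \code{\link{analyze_tracks}}.
#' @param grouping Optional factor of length \code{nrow(results)}.
#' @param n_boot Bootstrap replicates for the CIs.
#' @param seed Integer seed for the bootstrap.
#' @return Data.frame with one row per (group, class): \code{fraction},
#'   \code{ci_lo}, \code{ci_hi}, \code{mean_D},
#'   \code{mean_confinement_diameter}, \code{n_tracks}.
#' @export
fraction_confined <- function(results, grouping = NULL, n_boot = 500,
                              seed = NULL) {
  if (is.null(results) || nrow(results) == 0) stop("no results to summarize")
  grouping <- grouping %||% rep("all", nrow(results))
  with_local_seed(seed, {
    out <- list()
    for (g in unique(grouping)) {
      sub <- results[grouping == g, , drop = FALSE]
      n <- nrow(sub)
      for (cls in c("free", "confined", "directed")) {
        hit <- sub$motion_class == cls
        boot <- vapply(seq_len(n_boot), function(b) {
          mean(hit[sample.int(n, n, replace = TRUE)])
        }, numeric(1))
        out[[length(out) + 1]] <- data.frame(
          group = g, motion_class = cls,
          fraction = mean(hit),
          ci_lo = stats::quantile(boot, 0.025, names = FALSE),
          ci_hi = stats::quantile(boot, 0.975, names = FALSE),
          mean_D = if (any(hit)) mean(sub$D[hit]) else NA_real_,
          mean_confinement_diameter =
            if (cls == "confined" && any(hit)) {
              mean(sub$confinement_diameter[hit], na.rm = TRUE)
            } else NA_real_,
          n_tracks = n
        )
      }
    }
    do.call(rbind, out)
  })
}
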