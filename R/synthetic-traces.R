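# Synthetic stepwise-photobleaching traces with known step schedule.

#' Specification for a synthetic photobleaching trace
#'
#' Models a cluster of \code{n_steps} fluorophores under continuous maximal
#' excitation: each fluorophore survives each frame with probability
#' \code{1 - bleach_rate} (geometric lifetime) and bleaches exactly once, so
#' the noiseless trace is a monotone non-increasing staircase with unit drop
#' \code{unit_intensity}. Gaussian read noise and a constant baseline are
#' added on top.
#'
#' @param n_steps Number of fluorophores (true step count), >= 0.
#' @param unit_intensity Integrated intensity per fluorophore (a.u.).
#' @param frame_interval Frame time, s (metadata only).
#' @param bleach_rate Per-frame bleaching probability in (0, 1).
#' @param noise_sd Gaussian noise sd (a.u.).
#' @param baseline Constant offset (a.u.).
#' @param n_frames Trace length; default extends past the last bleach so the
#'   trace is fully bleached.
#' @param seed Integer seed.
#' @return A \code{trace_spec} object.
#' @export
trace_spec <- function(n_steps, unit_intensity = 100, frame_interval = 0.1,
                       bleach_rate = 0.005, noise_sd = 0, baseline = 0,
                       n_frames = NULL, seed = NULL) {
  stopifnot(is.numeric(n_steps), length(n_steps) == 1, n_steps >= 0)
  stop_if_not_scalar_pos(unit_intensity, "unit_intensity")
  stop_if_not_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  stopifnot(bleach_rate > 0, bleach_rate < 1)
  structure(list(
    n_steps = as.integer(n_steps), unit_intensity = unit_intensity,
    frame_interval = frame_interval, bleach_rate = bleach_rate,
    noise_sd = noise_sd, baseline = baseline,
    n_frames = n_frames, seed = seed
  ), class = "trace_spec")
}

#' Generate a photobleaching trace
#'
#' @param spec A \code{\link{trace_spec}}.
#' @return List with \code{trace} (data.frame \code{t} 0-based frame,
#'   \code{intensity}), \code{step_frames} (ground-truth frames at which the
#'   intensity first appears reduced, sorted, one entry per fluorophore) and
#'   \code{spec}.
#' @export
gen_bleach_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_steps
    # fluorophore i bleaches during frame b_i >= 1: frames 0..b_i-1 lit
    b <- if (n > 0) stats::rgeom(n, spec$bleach_rate) + 1L else integer(0)
    n_frames <- spec$n_frames %||%
      (max(c(b, 0L)) + max(50L, ceiling(1 / spec$bleach_rate / 4)))
    t <- seq_len(n_frames) - 1L
    survivors <- if (n > 0) {
      colSums(outer(b, t, FUN = ">"))
    } else rep(0L, n_frames)
    intensity <- spec$baseline + spec$unit_intensity * survivors
    if (spec$noise_sd > 0) {
      intensity <- intensity + stats::rnorm(n_frames, 0, spec$noise_sd)
    }
    list(
      trace = data.frame(t = t, intensity = intensity),
      step_frames = sort(b[b <= n_frames - 1L]),
      spec = spec
    )
  })
}
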