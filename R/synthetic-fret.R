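# Forward model for three-channel sensitized-emission FRET stacks.
#
# The forward model is, deliberately, the exact algebraic inverse of the
# estimator in compute_ea() (documented side by side with it): given a true
# apparent-efficiency map E, donor abundance Dm and acceptor abundance Am,
#   Iaa = Am                                   + bg_aa
#   Idd = Dm*(1 - E) + alpha*Am                + bg_dd
#   Ida = beta*Dm*(1 - E) + gamma*Am + E*Am    + bg_da
# so that F_c = Ida - beta*(Idd - alpha*Iaa) - gamma*Iaa = E*Iaa exactly at
# zero noise after background subtraction. Gaussian noise of sd `noise_sd`
# is added per channel. Zeroing one abundance map yields the single-label
# control stacks used for coefficient estimation.

#' Specification for a synthetic FRET stack
#'
#' @param true_E Matrix of true apparent FRET efficiency per pixel, each
#'   value in \code{[0, e_max]}.
#' @param donor_abundance,acceptor_abundance Matrices (a.u.), same dimension
#'   as \code{true_E}.
#' @param coefficients A \code{\link{fret_coefficients}} (its
#'   \code{background} is applied per channel).
#' @param noise_sd Gaussian channel noise sd (a.u.).
#' @param e_max Upper bound for valid \code{true_E}; default
#'   \code{FITC_ORB_EMAX}.
#' @param px_nm Pixel size, nm.
#' @param seed Integer seed.
#' @return A \code{fret_forward_spec} object.
#' @export
fret_forward_spec <- function(true_E, donor_abundance, acceptor_abundance,
                              coefficients, noise_sd = 0,
                              e_max = FITC_ORB_EMAX, px_nm = 100,
                              seed = NULL) {
  true_E <- as.matrix(true_E)
  donor_abundance <- as.matrix(donor_abundance)
  acceptor_abundance <- as.matrix(acceptor_abundance)
  if (!all(dim(true_E) == dim(donor_abundance)) ||
      !all(dim(true_E) == dim(acceptor_abundance))) {
    stop("true_E and the abundance maps must share dimensions")
  }
  if (any(true_E < 0) || any(true_E > e_max)) {
    stop(sprintf("true_E must lie in [0, %g] everywhere", e_max))
  }
  stopifnot(inherits(coefficients, "fret_coefficients"))
  stop_if_not_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  structure(list(true_E = true_E, donor_abundance = donor_abundance,
                 acceptor_abundance = acceptor_abundance,
                 coefficients = coefficients, noise_sd = noise_sd,
                 e_max = e_max, px_nm = px_nm, seed = seed),
            class = "fret_forward_spec")
}

#' Generate a three-channel FRET stack from the forward model
#'
#' @param spec A \code{\link{fret_forward_spec}}.
#' @return A \code{\link{fret_stack}}.
#' @export
gen_fret_stack <- function(spec) {
  stopifnot(inherits(spec, "fret_forward_spec"))
  with_local_seed(spec$seed, {
    co <- spec$coefficients
    E <- spec$true_E; Dm <- spec$donor_abundance; Am <- spec$acceptor_abundance
    bg <- co$background
    Iaa <- Am + bg[3]
    Idd <- Dm * (1 - E) + co$alpha * Am + bg[1]
    Ida <- co$beta * Dm * (1 - E) + co$gamma * Am + E * Am + bg[2]
    if (spec$noise_sd > 0) {
      n <- length(E)
      Idd <- Idd + stats::rnorm(n, 0, spec$noise_sd)
      Ida <- Ida + stats::rnorm(n, 0, spec$noise_sd)
      Iaa <- Iaa + stats::rnorm(n, 0, spec$noise_sd)
      dim(Idd) <- dim(Ida) <- dim(Iaa) <- dim(E)
    }
    fret_stack(Idd = Idd, Ida = Ida, Iaa = Iaa, px_nm = spec$px_nm)
  })
}
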