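# Corrected sensitized-emission FRET.
#
# Three channels are acquired: Idd (donor excitation / donor emission), Ida
# (donor excitation / acceptor emission, the raw "FRET" channel) and Iaa
# (acceptor excitation / acceptor emission). Four bleed-through coefficients
# are measured on single-label controls after background subtraction:
#   beta  = Ida / Idd on donor-only cells      (donor cross-talk)
#   alpha = Idd / Iaa on acceptor-only cells   (acceptor cross-excitation
#                                               into the donor channel)
#   gamma = Ida / Iaa on acceptor-only cells   (acceptor cross-excitation)
#   delta = Idd / Ida on acceptor-only cells   (FRET cross-talk; reported,
#                                               not used by the estimator)
# The corrected sensitized emission and apparent (acceptor-normalized) FRET
# efficiency are
#   F_c = Ida - beta * (Idd - alpha * Iaa) - gamma * Iaa,   E_A = F_c / Iaa,
# clamped to [0, E_max]. E_max = 0.3136 is the theoretical maximum of the
# FITC / octadecyl-rhodamine-B pair used for the integrin-conformation
# readout. Note the sign convention of that assay: the *bent* (inactive)
# integrin FRETs strongly to the membrane dye, so integrin activation is a
# DECREASE in E_A.

#' Maximum theoretical FRET efficiency of the FITC/ORB pair
#' @export
FITC_ORB_EMAX <- 0.3136

#' Bleed-through coefficient set
#'
#' @param alpha,beta,gamma,delta Non-negative bleed-through coefficients
#'   (see the definitions above).
#' @param background Length-3 numeric: background per channel in order
#'   (Idd, Ida, Iaa), a.u.
#' @param background_sd Length-3 numeric: background noise sd per channel
#'   (used for the Iaa floor and above-background masks).
#' @return A \code{fret_coefficients} object.
#' @export
fret_coefficients <- function(alpha, beta, gamma, delta = alpha / max(gamma, .Machine$double.eps),
                              background = c(0, 0, 0),
                              background_sd = c(0, 0, 0)) {
  vals <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("coefficients must be finite and >= 0")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 background = rep_len(background, 3),
                 background_sd = rep_len(background_sd, 3)),
            class = "fret_coefficients")
}

#' @export
print.fret_coefficients <- function(x, ...) {
  cat(sprintf(
    "FRET bleed-through coefficients\n  alpha=%.4g beta=%.4g gamma=%.4g delta=%.4g\n  background (Idd, Ida, Iaa): %s\n",
    x$alpha, x$beta, x$gamma, x$delta,
    paste(signif(x$background, 4), collapse = ", ")))
  invisible(x)
}

#' Three-channel FRET stack
#'
#' @param Idd,Ida,Iaa Numeric matrices of identical dimension (dim 1 = x).
#' @param px_nm Pixel size, nm (metadata).
#' @return A \code{fret_stack} object.
#' @export
fret_stack <- function(Idd, Ida, Iaa, px_nm = 100) {
  if (!all(dim(Idd) == dim(Ida)) || !all(dim(Idd) == dim(Iaa))) {
    stop("Idd, Ida and Iaa must share dimensions (registered channels)")
  }
  structure(list(Idd = Idd, Ida = Ida, Iaa = Iaa, px_nm = px_nm),
            class = "fret_stack")
}

# median over pixels above `k` background sds in the denominator channel
robust_ratio <- function(num, den, den_bg_sd, k = 3) {
  keep <- den > k * den_bg_sd & is.finite(num) & is.finite(den)
  if (!any(keep)) stop("control stack has no above-background pixels")
  stats::median(num[keep] / den[keep])
}

#' Estimate bleed-through coefficients from single-label controls
#'
#' Background per channel is the median over the unstained control; the four
#' coefficients are median-of-ratios estimates over above-background pixels
#' of the background-subtracted donor-only and acceptor-only controls. The
#' median makes both statistics robust to bright debris in the controls.
#'
#' @param donor_only,acceptor_only,unstained \code{\link{fret_stack}}s.
#' @return A \code{\link{fret_coefficients}} object.
#' @export
estimate_coefficients <- function(donor_only, acceptor_only, unstained) {
  stopifnot(inherits(donor_only, "fret_stack"),
            inherits(acceptor_only, "fret_stack"),
            inherits(unstained, "fret_stack"))
  bg <- c(stats::median(unstained$Idd),
          stats::median(unstained$Ida),
          stats::median(unstained$Iaa))
  bg_sd <- c(stats::mad(unstained$Idd),
             stats::mad(unstained$Ida),
             stats::mad(unstained$Iaa))
  d_dd <- donor_only$Idd - bg[1]
  d_da <- donor_only$Ida - bg[2]
  a_dd <- acceptor_only$Idd - bg[1]
  a_da <- acceptor_only$Ida - bg[2]
  a_aa <- acceptor_only$Iaa - bg[3]
  beta  <- robust_ratio(d_da, d_dd, bg_sd[1])
  alpha <- robust_ratio(a_dd, a_aa, bg_sd[3])
  gamma <- robust_ratio(a_da, a_aa, bg_sd[3])
  delta <- robust_ratio(a_dd, a_da, bg_sd[2])
  fret_coefficients(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                    background = bg, background_sd = bg_sd)
}

#' Pixelwise apparent FRET efficiency
#'
#' Subtracts channel backgrounds (clamping at 0), computes the corrected
#' sensitized emission \code{F_c = Ida - beta*(Idd - alpha*Iaa) - gamma*Iaa}
#' and \code{E_A = F_c / Iaa}, clamps to \code{[0, e_max]}, and marks pixels
#' with \code{Iaa} below \code{iaa_floor_k} background sds as undefined (NA)
#' to avoid division blow-up.
#'
#' @param stack A \code{\link{fret_stack}} (raw; backgrounds are taken from
#'   \code{coeffs}).
#' @param coeffs A \code{\link{fret_coefficients}}.
#' @param e_max Efficiency clamp; defaults to \code{FITC_ORB_EMAX}.
#' @param iaa_floor_k Multiplier on the Iaa background sd below which E_A is
#'   undefined.
#' @return A \code{fret_map}: list with \code{E_A} matrix (NA where
#'   undefined), \code{e_max}, \code{px_nm}.
#' @export
compute_ea <- function(stack, coeffs, e_max = FITC_ORB_EMAX, iaa_floor_k = 3) {
  stopifnot(inherits(stack, "fret_stack"), inherits(coeffs, "fret_coefficients"))
  bg <- coeffs$background
  Idd <- pmax(stack$Idd - bg[1], 0)
  Ida <- pmax(stack$Ida - bg[2], 0)
  Iaa <- pmax(stack$Iaa - bg[3], 0)
  Fc <- Ida - coeffs$beta * (Idd - coeffs$alpha * Iaa) - coeffs$gamma * Iaa
  EA_raw <- Fc / Iaa
  floor_val <- iaa_floor_k * coeffs$background_sd[3]
  EA_raw[Iaa <= floor_val] <- NA_real_
  EA <- pmin(pmax(EA_raw, 0), e_max)
  dim(EA) <- dim(EA_raw) <- dim(stack$Idd)
  # E_A_raw is kept unclamped: clamping censors the noise distribution at
  # E=0 / E=e_max and would bias ROI averages of low-FRET regions upward
  structure(list(E_A = EA, E_A_raw = EA_raw, e_max = e_max,
                 px_nm = stack$px_nm, mask = NULL), class = "fret_map")
}

#' Foreground mask from the Iaa and Idd channels
#'
#' Otsu-thresholds each channel, combines the two masks with a logical AND,
#' and dilates once with a 3x3 (8-connected) structuring element. The mask
#' restricts E_A to pixels carrying both membrane-dye and labelled-integrin
#' signal.
#'
#' @param Iaa,Idd Numeric matrices of identical dimension.
#' @return Logical matrix.
#' @export
build_mask <- function(Iaa, Idd) {
  if (!all(dim(Iaa) == dim(Idd))) stop("Iaa and Idd must share dimensions")
  otsu_mask <- function(img) {
    rg <- range(img, finite = TRUE)
    if (diff(rg) <= 0) stop("constant image: Otsu threshold undefined")
    scaled <- (img - rg[1]) / diff(rg)
    th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    scaled > th
  }
  core <- otsu_mask(Iaa) & otsu_mask(Idd)
  dil <- EBImage::dilate(EBImage::Image(core * 1),
                         EBImage::makeBrush(3, shape = "box"))
  as.matrix(dil) > 0
}

#' Apply a mask to a FRET map
#' @param map A \code{fret_map}.
#' @param mask Logical matrix from \code{\link{build_mask}}.
#' @return The map with E_A set NA outside the mask and \code{mask} stored.
#' @export
apply_mask <- function(map, mask) {
  stopifnot(inherits(map, "fret_map"), all(dim(mask) == dim(map$E_A)))
  map$E_A[!mask] <- NA_real_
  map$E_A_raw[!mask] <- NA_real_
  map$mask <- mask
  map
}

#' Summarize masked FRET efficiency within an ROI
#'
#' @param map A \code{fret_map} (typically after \code{\link{apply_mask}}).
#' @param roi_polygon ROI vertex matrix, nm coordinates.
#' @param clamped Use the clamped map (default). \code{FALSE} averages the
#'   unclamped efficiencies, which is unbiased near E = 0 where clamping
#'   censors the noise.
#' @return List with \code{mean_ea}, \code{n_pixels}, and the vector of
#'   contributing \code{values}.
#' @export
roi_fret <- function(map, roi_polygon, clamped = TRUE) {
  stopifnot(inherits(map, "fret_map"))
  d <- dim(map$E_A)
  cx <- (seq_len(d[1]) - 0.5) * map$px_nm
  cy <- (seq_len(d[2]) - 0.5) * map$px_nm
  px <- rep(cx, times = d[2])
  py <- rep(cy, each = d[1])
  inside <- points_in_polygon(px, py, roi_polygon)
  vals <- if (clamped) map$E_A[inside] else map$E_A_raw[inside]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("ROI does not intersect any defined masked pixel")
  list(mean_ea = mean(vals), n_pixels = length(vals), values = vals)
}

#' Display conversion: activation map
#'
#' Converts a FRET map into a 16-bit "activation" display image: because the
#' bent (inactive) integrin conformation gives high FRET, activation is
#' displayed as inverted E_A, monotone decreasing in E_A.
#'
#' @param map A \code{fret_map}.
#' @return Integer matrix in [0, 65535]; NA where E_A is undefined.
#' @export
activation_display <- function(map) {
  stopifnot(inherits(map, "fret_map"))
  out <- round((1 - map$E_A / map$e_max) * 65535)
  storage.mode(out) <- "integer"
  out
}
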