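# Axial angle convention used throughout: degrees in [0, 180), measured
# counterclockwise from the +column axis with the origin at the top-left
# (so the row gradient is sign-flipped before any atan2).

#' Estimate the local myofiber orientation field from the membrane stain
#'
#' Structure-tensor orientation: image gradients are computed on a
#' Gaussian-smoothed copy of the WGA channel, the outer-product tensor is
#' integrated with a Gaussian window of SD \code{windowSigmaUm}, and the
#' returned angle is the axial direction of the \emph{myofiber} axis - the
#' dominant membrane direction, i.e. the minor-eigenvector axis of the
#' gradient-energy tensor. Coherence is \code{(l1 - l2) / (l1 + l2)} of the
#' tensor eigenvalues: 0 for isotropic neighbourhoods, 1 for perfectly
#' oriented ones.
#'
#' In longitudinal sections the long lateral membranes dominate the gradient
#' energy at the default 8-um window, so the angle tracks the cell axis; a
#' small window (~1 um) instead tracks the nearest membrane ridge, which is
#' what [classifyParticles()] uses for near-circular particles.
#'
#' Within \code{borderSigmas} integration windows of the image edge the
#' tensor's support is truncated and the recovered axis can be confidently
#' wrong; those pixels are flagged indeterminate (coherence 0) instead.
#'
#' @param wgaChannel Numeric intensity matrix (must not be constant).
#' @param pixelSizeUm Pixel size in micrometres.
#' @param windowSigmaUm Tensor integration window SD in micrometres
#'   (default 8).
#' @param gradSigmaUm Pre-smoothing SD for gradient estimation (default 0.5).
#' @param borderSigmas Width of the indeterminate border band, in units of
#'   the integration window SD (default 2; 0 disables the band).
#'
#' @return An [OrientationField].
#' @export
estimateOrientationField <- function(wgaChannel, pixelSizeUm,
                                     windowSigmaUm = 8, gradSigmaUm = 0.5,
                                     borderSigmas = 2) {
  if (!is.matrix(wgaChannel)) stop("wgaChannel must be a matrix")
  rng <- range(wgaChannel)
  if (rng[1] == rng[2])
    stop("channel is constant; orientation undefined")
  sgrad <- gradSigmaUm / pixelSizeUm
  swin <- windowSigmaUm / pixelSizeUm

  # derivative-of-Gaussian gradient filters (separable); kernel sign and
  # scale cancel in the tensor, only the x/y consistency matters
  r <- max(3L, as.integer(ceiling(4 * sgrad)))
  xx <- -r:r
  g <- stats::dnorm(xx, sd = sgrad); g <- g / sum(g)
  dg <- xx / sgrad^2 * stats::dnorm(xx, sd = sgrad); dg <- dg - mean(dg)
  gx <- .Call_sep_conv(wgaChannel, g, dg)   # along columns (+x)
  gy <- .Call_sep_conv(wgaChannel, dg, g)   # along rows (down)
  gyf <- -gy                                # y up for CCW angles

  jxx <- .Call_gauss_blur(gx * gx, swin)
  jyy <- .Call_gauss_blur(gyf * gyf, swin)
  jxy <- .Call_gauss_blur(gx * gyf, swin)

  # dominant gradient axis, then +90 deg for the membrane/fiber axis
  thetaG <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
  angle <- (thetaG + 90) %% 180
  tr <- jxx + jyy
  coh <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / pmax(tr, .Machine$double.eps)
  coh <- pmin(pmax(coh, 0), 1)
  coh[tr <= .Machine$double.eps] <- 0

  # truncated window support near the edges: flag as indeterminate rather
  # than report a confidently wrong axis
  bw <- as.integer(ceiling(borderSigmas * swin))
  H <- nrow(coh); W <- ncol(coh)
  if (bw > 0 && 2 * bw < H && 2 * bw < W) {
    coh[c(seq_len(bw), (H - bw + 1):H), ] <- 0
    coh[, c(seq_len(bw), (W - bw + 1):W)] <- 0
  }

  methods::new("OrientationField", angleDeg = angle, coherence = coh,
               windowSigmaUm = windowSigmaUm)
}

#' Acute angle between two axial directions
#'
#' Axial angles identify theta with theta + 180; the acute difference is
#' therefore in \[0, 90\] (e.g. 179 vs 1 degrees differ by 2).
#'
#' @param a,b Angles in degrees (vectors recycle).
#' @return Acute axial difference in degrees.
#' @export
acuteAxialDiff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Coherence-weighted axial mean of angles (degrees) with weights w.
# Returns NA when all weights are zero.
.axialMean <- function(angles, w) {
  s <- sum(w)
  if (!is.finite(s) || s <= 0) return(NA_real_)
  a2 <- angles * pi / 90  # doubled angle
  (atan2(sum(w * sin(a2)), sum(w * cos(a2))) * 90 / pi) %% 180
}
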