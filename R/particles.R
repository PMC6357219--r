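#' Detect Cx43 particles as connected components
#'
#' Particles are 8-connected components of the binary mask (two pixels
#' touching only at a corner belong to one particle); components smaller than
#' \code{minAreaPx} are discarded as noise. For each particle the pixel area,
#' physical area, centroid and second-moment ellipse (principal-axis angle
#' and elongation) are computed. A variance of 1/12 px^2 per pixel is added
#' to the moment diagonal (the extent of a square pixel), which keeps axes
#' and elongations finite for one-pixel-wide objects.
#'
#' @param mask A [BinaryMask] or logical matrix.
#' @param pixelSizeUm Pixel size in micrometres.
#' @param minAreaPx Minimum component area in pixels (default 2).
#'
#' @return A [ParticleSet]; empty mask yields an empty set.
#' @export
detectParticles <- function(mask, pixelSizeUm, minAreaPx = 2L) {
  m <- if (methods::is(mask, "BinaryMask")) maskMatrix(mask) else mask
  if (!is.logical(m)) stop("mask must be logical")
  lab <- .Call_label8(m)
  empty <- function() methods::new("ParticleSet",
    table = data.frame(particle_id = integer(0), area_px = integer(0),
                       area_um2 = numeric(0), centroid_row = numeric(0),
                       centroid_col = numeric(0),
                       major_axis_angle_deg = numeric(0),
                       elongation = numeric(0), stringsAsFactors = FALSE),
    labels = matrix(0L, nrow(m), ncol(m)), pixelSizeUm = pixelSizeUm)
  nlab <- max(lab)
  if (nlab == 0L) return(empty())

  counts <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- which(counts >= minAreaPx)
  if (length(keep) == 0L) return(empty())
  remap <- integer(nlab); remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]

  idx <- which(lab > 0L)
  l <- lab[idx]
  r <- (idx - 1L) %% nrow(m) + 1L
  cc <- (idx - 1L) %/% nrow(m) + 1L
  n <- as.numeric(tabulate(l))
  sr <- rowsum(as.numeric(r), l)[, 1]; sc <- rowsum(as.numeric(cc), l)[, 1]
  srr <- rowsum(as.numeric(r)^2, l)[, 1]; scc <- rowsum(as.numeric(cc)^2, l)[, 1]
  src <- rowsum(as.numeric(r) * cc, l)[, 1]
  cr <- sr / n; ccol <- sc / n
  m02 <- srr / n - cr^2 + 1 / 12          # row (y) variance
  m20 <- scc / n - ccol^2 + 1 / 12        # column (x) variance
  m11 <- -(src / n - cr * ccol)           # y flipped for CCW convention
  angle <- (0.5 * atan2(2 * m11, m20 - m02) * 180 / pi) %% 180
  disc <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (m20 + m02 + disc) / 2; l2 <- (m20 + m02 - disc) / 2
  elong <- sqrt(l1 / pmax(l2, .Machine$double.eps))

  tab <- data.frame(particle_id = seq_along(n), area_px = as.integer(n),
                    area_um2 = n * pixelSizeUm^2, centroid_row = cr,
                    centroid_col = ccol, major_axis_angle_deg = angle,
                    elongation = elong, stringsAsFactors = FALSE)
  methods::new("ParticleSet", table = tab, labels = lab,
               pixelSizeUm = pixelSizeUm)
}

#' Classify particles as end-to-end or side-to-side junctions
#'
#' For each particle the local myofiber axis is the coherence-weighted axial
#' mean of the orientation field within \code{neighborhoodUm} of the
#' centroid (pixels below \code{coherenceFloor} are treated as
#' indeterminate). The particle's own axis is its second-moment major axis
#' when it is sufficiently elongated; near-circular particles
#' (elongation < \code{elongationMin}) carry unstable major axes, so their
#' axis is instead read from the fine-scale membrane orientation field at the
#' centroid (the ridge direction of the membrane the punctum sits on), when
#' such a field is supplied. The particle is \code{END_TO_END} when the acute
#' angle between its axis and the local fiber axis is greater than or equal
#' to \code{angleThresholdDeg} (intercalated-disc plaques lie transversal to
#' the fiber), otherwise \code{SIDE_TO_SIDE}; ties go to \code{END_TO_END}.
#'
#' Particles whose whole neighbourhood is indeterminate are flagged
#' unclassified (\code{NA} class) and later excluded from area totals.
#'
#' @param particles A [ParticleSet] from [detectParticles()].
#' @param field [OrientationField] at the fiber scale (default window 8 um).
#' @param fineField Optional [OrientationField] at the membrane-ridge scale
#'   (~1 um window) used for near-circular particles.
#' @param angleThresholdDeg Classification cutoff in degrees (default 45).
#' @param neighborhoodUm Radius of the local-fiber neighbourhood (default 5).
#' @param coherenceFloor Pixels with coherence below this are indeterminate
#'   (default 0.05).
#' @param elongationMin Elongation below which the membrane-ridge axis is
#'   used (default 1.2). The gate applied per particle is
#'   \code{elongationMin + 4.5 / area_px}: pixelization alone inflates the
#'   apparent elongation of a small circular particle by roughly that much,
#'   so small discs are not mistaken for genuinely elongated plaques.
#'
#' @return The [ParticleSet] with columns \code{local_fiber_angle_deg},
#'   \code{axis_used_deg}, \code{axis_source}, \code{delta_angle_deg} and
#'   \code{junction_class} added.
#' @export
classifyParticles <- function(particles, field, fineField = NULL,
                              angleThresholdDeg = 45, neighborhoodUm = 5,
                              coherenceFloor = 0.05, elongationMin = 1.2) {
  tab <- particles@table
  if (nrow(tab) == 0L) {
    tab$local_fiber_angle_deg <- numeric(0)
    tab$axis_used_deg <- numeric(0)
    tab$axis_source <- character(0)
    tab$delta_angle_deg <- numeric(0)
    tab$junction_class <- character(0)
    particles@table <- tab
    return(particles)
  }
  ang <- field@angleDeg; coh <- field@coherence
  H <- nrow(ang); W <- ncol(ang)
  psz <- particles@pixelSizeUm
  rad <- max(1L, as.integer(round(neighborhoodUm / psz)))
  off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  off <- off[off$dr^2 + off$dc^2 <= rad^2, ]

  nfa <- axis <- delta <- rep(NA_real_, nrow(tab))
  src <- rep(NA_character_, nrow(tab))
  cls <- rep(NA_character_, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    r0 <- round(tab$centroid_row[i]); c0 <- round(tab$centroid_col[i])
    rr <- r0 + off$dr; cc <- c0 + off$dc
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    ii <- cbind(rr[ok], cc[ok])
    w <- coh[ii]; w[w < coherenceFloor] <- 0
    nfa[i] <- .axialMean(ang[ii], w)
    if (is.na(nfa[i])) next  # indeterminate neighbourhood -> unclassified

    # discretization alone inflates a circle's apparent elongation by about
    # 4.5/area at the 95th percentile, so the roundness gate is size-aware
    gate <- elongationMin + 4.5 / tab$area_px[i]
    if (tab$elongation[i] >= gate || is.null(fineField)) {
      axis[i] <- tab$major_axis_angle_deg[i]
      src[i] <- "major_axis"
    } else {
      fr <- min(max(r0, 1L), H); fc <- min(max(c0, 1L), W)
      if (fineField@coherence[fr, fc] >= coherenceFloor) {
        axis[i] <- fineField@angleDeg[fr, fc]
        src[i] <- "membrane_ridge"
      } else {
        axis[i] <- tab$major_axis_angle_deg[i]
        src[i] <- "major_axis"
      }
    }
    delta[i] <- acuteAxialDiff(axis[i], nfa[i])
    cls[i] <- if (delta[i] >= angleThresholdDeg) "END_TO_END" else "SIDE_TO_SIDE"
  }
  tab$local_fiber_angle_deg <- nfa
  tab$axis_used_deg <- axis
  tab$axis_source <- src
  tab$delta_angle_deg <- delta
  tab$junction_class <- cls
  particles@table <- tab
  particles
}

#' End-to-end fraction of total junction area
#'
#' Sums classified particle areas per junction class and computes the
#' end-to-end percentage of total classified junction area. The side-to-side
#' percentage is the exact complement (100 - end-to-end), mirroring the
#' reciprocal relationship between the two compartments. Unclassified
#' particles are excluded from the totals and reported in the count.
#'
#' @param particles A classified [ParticleSet] (see [classifyParticles()]).
#' @param imageId Identifier stored in the result.
#' @param provenance Optional provenance list to attach.
#'
#' @return A [QuantResult]; with zero classified particles the percentage is
#'   \code{NA} and a message reports the counts.
#' @export
endToEndFraction <- function(particles, imageId = "image",
                             provenance = list()) {
  tab <- particles@table
  if (nrow(tab) > 0 && is.null(tab$junction_class))
    stop("particles must be classified first (see classifyParticles)")
  psz <- particles@pixelSizeUm
  classified <- !is.na(tab$junction_class)
  endPx <- sum(tab$area_px[classified & tab$junction_class == "END_TO_END"])
  sidePx <- sum(tab$area_px[classified & tab$junction_class == "SIDE_TO_SIDE"])
  endArea <- endPx * psz^2; sideArea <- sidePx * psz^2
  if (endPx + sidePx == 0) {
    message("endToEndFraction: no classified particles (",
            nrow(tab), " detected, ", sum(!classified),
            " unclassified); fraction undefined")
    pct <- NA_real_
  } else {
    pct <- 100 * endPx / (endPx + sidePx)
  }
  methods::new("QuantResult", imageId = imageId, particles = tab,
               nParticles = nrow(tab), nUnclassified = sum(!classified),
               totalAreaUm2 = endArea + sideArea, endToEndAreaUm2 = endArea,
               sideToSideAreaUm2 = sideArea, endToEndPct = pct,
               provenance = provenance)
}

#' Pipeline configuration for [quantifyImage()]
#'
#' @param threshold Segmentation threshold in DN, or \code{NULL} to use the
#'   Otsu suggestion of [suggestThreshold()] (recorded in the provenance).
#' @param radiusPx Rolling-ball radius in pixels (default 50).
#' @param windowSigmaUm Fiber-scale structure-tensor window (default 8 um).
#' @param fineSigmaUm Membrane-ridge-scale window used for near-circular
#'   particles (default 1 um).
#' @param gradSigmaUm Gradient pre-smoothing (default 0.5 um).
#' @param neighborhoodUm,angleThresholdDeg,coherenceFloor,elongationMin See
#'   [classifyParticles()].
#' @param minAreaPx Minimum particle area in pixels (default 2).
#' @param subtractWga Apply background subtraction to the WGA channel before
#'   orientation estimation (default \code{FALSE}; the segmented channel is
#'   always background-subtracted).
#'
#' @return Named list of class \code{"QuantConfig"}.
#' @export
quantConfig <- function(threshold = NULL, radiusPx = 50L, windowSigmaUm = 8,
                        fineSigmaUm = 1, gradSigmaUm = 0.5,
                        neighborhoodUm = 5, angleThresholdDeg = 45,
                        coherenceFloor = 0.05, elongationMin = 1.2,
                        minAreaPx = 2L, subtractWga = FALSE) {
  structure(list(threshold = threshold, radiusPx = as.integer(radiusPx),
                 windowSigmaUm = windowSigmaUm, fineSigmaUm = fineSigmaUm,
                 gradSigmaUm = gradSigmaUm, neighborhoodUm = neighborhoodUm,
                 angleThresholdDeg = angleThresholdDeg,
                 coherenceFloor = coherenceFloor,
                 elongationMin = elongationMin,
                 minAreaPx = as.integer(minAreaPx),
                 subtractWga = subtractWga),
            class = "QuantConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Quantify one image: the four-step junction census
#'
#' Runs the full pipeline on a [TissueImage]: (i) rolling-ball background
#' subtraction of the Cx43 channel, (ii) thresholding into a particle mask,
#' (iii) particle detection, myofiber orientation estimation from the WGA
#' channel and per-particle classification, (iv) the end-to-end percentage of
#' total junction area. Deterministic: the same image and configuration
#' always give the same result.
#'
#' @param image A [TissueImage] with channels \code{CX43} and \code{WGA}.
#' @param config A \code{"QuantConfig"} list from [quantConfig()].
#'
#' @return A [QuantResult] with full provenance attached.
#' @examples
#' ph <- generateTissuePhantom(phantomParams(imageHeightPx = 256,
#'   imageWidthPx = 320, nPuncta = 40, seed = 1))
#' qr <- quantifyImage(ph$image, quantConfig(radiusPx = 25))
#' endToEndPct(qr)
#' @export
quantifyImage <- function(image, config = quantConfig()) {
  stopifnot(methods::is(image, "TissueImage"))
  psz <- pixelSize(image)
  cx <- .stage("subtract_background",
               subtractBackground(getChannel(image, "CX43"), config$radiusPx))
  if (is.null(config$threshold)) {
    if (min(cx) == max(cx)) {
      # constant (e.g. empty) channel: no foreground at any finite threshold
      thr <- 65535; thrSource <- "degenerate"
      message("quantifyImage: constant Cx43 channel; no particles detectable")
    } else {
      thr <- .stage("suggest_threshold", suggestThreshold(cx))
      thrSource <- "otsu"
      message("quantifyImage: using Otsu threshold suggestion ",
              round(thr, 1), " DN")
    }
  } else {
    thr <- config$threshold; thrSource <- "config"
  }
  mask <- .stage("make_mask", makeMask(cx, thr))
  pset <- .stage("detect_particles",
                 detectParticles(mask, psz, config$minAreaPx))

  wga <- getChannel(image, "WGA")
  if (isTRUE(config$subtractWga))
    wga <- .stage("subtract_background_wga",
                  subtractBackground(wga, config$radiusPx))
  field <- .stage("estimate_orientation",
                  estimateOrientationField(wga, psz, config$windowSigmaUm,
                                           config$gradSigmaUm))
  fine <- .stage("estimate_orientation_fine",
                 estimateOrientationField(wga, psz, config$fineSigmaUm,
                                          config$gradSigmaUm))
  pset <- .stage("classify_particles",
                 classifyParticles(pset, field, fine,
                                   config$angleThresholdDeg,
                                   config$neighborhoodUm,
                                   config$coherenceFloor,
                                   config$elongationMin))
  prov <- list(threshold_used = thr, threshold_source = thrSource,
               radius_px = config$radiusPx, config = unclass(config),
               pixel_size_um = psz,
               package_version = as.character(utils::packageVersion("gjlat")))
  .stage("end_to_end_fraction",
         endToEndFraction(pset, imageId = image@sourceId, provenance = prov))
}
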