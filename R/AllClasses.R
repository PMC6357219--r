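#' Calibrated multi-channel tissue micrograph
#'
#' Container for a multi-channel 16-bit fluorescence micrograph of a cardiac
#' tissue section with its physical pixel calibration. Channels are stored as
#' numeric matrices (row-major, origin top-left) in digital numbers (DN,
#' 0--65535) and addressed by name; the canonical channel set is \code{CX43}
#' (gap-junction stain), \code{WGA} (membrane stain) and \code{DAPI} (nuclei).
#'
#' @slot channels Named list of numeric matrices, all with identical
#'   dimensions.
#' @slot pixelSizeUm Physical edge length of one pixel in micrometres
#'   (default acquisition calibration is 0.3225).
#' @slot sourceId Character identifier of the image origin (file path or
#'   phantom tag).
#'
#' @seealso [generateTissuePhantom()], [readTissueImage()], [quantifyImage()]
#' @export
setClass("TissueImage",
  representation(channels = "list", pixelSizeUm = "numeric", sourceId = "character"),
  prototype(channels = list(), pixelSizeUm = 0.3225, sourceId = NA_character_)
)

setValidity("TissueImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be named")
  if (!all(vapply(ch, is.matrix, TRUE)))
    return("all channels must be matrices")
  dims <- vapply(ch, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all channels must share identical dimensions")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  TRUE
})

#' Ground truth of a synthetic tissue phantom
#'
#' Records every rendered Cx43 punctum of a phantom (position, radius, pixel
#' area, junction class) before illumination and noise were applied, together
#' with the realized end-to-end area percentage and the analytic per-pixel
#' myofiber angle map.
#'
#' @slot puncta \code{data.frame} with columns \code{punctum_id}, \code{x_px},
#'   \code{y_px} (1-based pixel-centre coordinates; x = column, y = row),
#'   \code{radius_px}, \code{area_px} and \code{class} (\code{"END_TO_END"} or
#'   \code{"SIDE_TO_SIDE"}).
#' @slot trueFractionPct Realized end-to-end area as a percentage of total
#'   punctum area, in \[0, 100\] (\code{NA} when no puncta were placed).
#' @slot fiberAngleMap Numeric matrix of true axial fiber angles in degrees,
#'   \[0, 180).
#'
#' @seealso [generateTissuePhantom()]
#' @export
setClass("PhantomTruth",
  representation(puncta = "data.frame", trueFractionPct = "numeric",
                 fiberAngleMap = "matrix")
)

setValidity("PhantomTruth", function(object) {
  need <- c("punctum_id", "x_px", "y_px", "radius_px", "area_px", "class")
  if (!all(need %in% names(object@puncta)))
    return(paste("puncta must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@puncta) > 0 &&
      !all(object@puncta$class %in% c("END_TO_END", "SIDE_TO_SIDE")))
    return("punctum class must be END_TO_END or SIDE_TO_SIDE")
  if (!is.na(object@trueFractionPct) &&
      (object@trueFractionPct < 0 || object@trueFractionPct > 100))
    return("trueFractionPct must lie in [0, 100]")
  ang <- object@fiberAngleMap
  if (length(ang) && (min(ang) < 0 || max(ang) >= 180))
    return("fiberAngleMap values must lie in [0, 180)")
  TRUE
})

#' Binary segmentation mask
#'
#' Result of thresholding one image channel; the threshold is retained for
#' provenance. The comparison is inclusive (pixel >= threshold), so threshold
#' 0 selects every pixel.
#'
#' @slot mask Logical matrix with the source channel's dimensions.
#' @slot threshold Intensity threshold (DN) that produced the mask.
#' @slot channel Name of the source channel.
#'
#' @seealso [makeMask()], [detectParticles()]
#' @export
setClass("BinaryMask",
  representation(mask = "matrix", threshold = "numeric", channel = "character")
)

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (length(object@threshold) != 1L || is.na(object@threshold))
    return("threshold must be a single number")
  TRUE
})

#' Local myofiber orientation field
#'
#' Per-pixel axial orientation (degrees in \[0, 180), theta and theta + 180
#' identified) of the dominant local membrane direction, with the structure
#' tensor coherence in \[0, 1\] as a reliability weight.
#'
#' @slot angleDeg Numeric matrix of axial angles in degrees.
#' @slot coherence Numeric matrix in \[0, 1\]; 0 means isotropic
#'   (orientation indeterminate), 1 perfectly oriented.
#' @slot windowSigmaUm Standard deviation (micrometres) of the Gaussian
#'   tensor-integration window used.
#'
#' @seealso [estimateOrientationField()], [classifyParticles()]
#' @export
setClass("OrientationField",
  representation(angleDeg = "matrix", coherence = "matrix",
                 windowSigmaUm = "numeric")
)

setValidity("OrientationField", function(object) {
  if (!identical(dim(object@angleDeg), dim(object@coherence)))
    return("angleDeg and coherence must have identical dimensions")
  a <- object@angleDeg
  if (length(a) && (min(a) < 0 || max(a) >= 180))
    return("angles must lie in [0, 180)")
  co <- object@coherence
  if (length(co) && (min(co) < -1e-9 || max(co) > 1 + 1e-9))
    return("coherence must lie in [0, 1]")
  TRUE
})

#' Segmented Cx43 particles of one image
#'
#' Particles are 8-connected components of a binary mask. The per-particle
#' table carries geometry (pixel area, physical area, centroid, principal-axis
#' angle, elongation) and, after classification, the local fiber angle, the
#' acute axis-to-fiber angle and the junction class.
#'
#' @slot table \code{data.frame}, one row per particle.
#' @slot labels Integer matrix of the same shape as the mask; 0 background,
#'   k > 0 the pixels of particle k (row order of \code{table}).
#' @slot pixelSizeUm Pixel size in micrometres used for physical areas.
#'
#' @seealso [detectParticles()], [classifyParticles()], [endToEndFraction()]
#' @export
setClass("ParticleSet",
  representation(table = "data.frame", labels = "matrix", pixelSizeUm = "numeric")
)

setValidity("ParticleSet", function(object) {
  if (nrow(object@table) > 0 &&
      max(object@labels) != nrow(object@table))
    return("labels must index rows of the particle table")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  TRUE
})

#' Per-image junction census
#'
#' Totals of the end-to-end / side-to-side area partition of one image's
#' classified Cx43 particles, plus the full per-particle table and the
#' processing provenance. By construction the two class areas sum exactly to
#' the classified total and the two percentages sum exactly to 100.
#'
#' @slot imageId Image identifier.
#' @slot particles Per-particle \code{data.frame} (see [ParticleSet]).
#' @slot nParticles Number of detected particles.
#' @slot nUnclassified Particles excluded from the area totals because no
#'   reliable local orientation was available.
#' @slot totalAreaUm2,endToEndAreaUm2,sideToSideAreaUm2 Areas in square
#'   micrometres over classified particles.
#' @slot endToEndPct End-to-end percentage of total classified junction area
#'   (\code{NA} when nothing was classified).
#' @slot provenance Named list (threshold used and its source, rolling-ball
#'   radius, orientation and classification settings, package version).
#'
#' @seealso [quantifyImage()], [endToEndFraction()]
#' @export
setClass("QuantResult",
  representation(imageId = "character", particles = "data.frame",
                 nParticles = "integer", nUnclassified = "integer",
                 totalAreaUm2 = "numeric", endToEndAreaUm2 = "numeric",
                 sideToSideAreaUm2 = "numeric", endToEndPct = "numeric",
                 provenance = "list")
)

setValidity("QuantResult", function(object) {
  if (abs(object@endToEndAreaUm2 + object@sideToSideAreaUm2 -
          object@totalAreaUm2) > 0)
    return("class areas must sum exactly to the total")
  if (!is.na(object@endToEndPct) &&
      (object@endToEndPct < 0 || object@endToEndPct > 100))
    return("endToEndPct must lie in [0, 100]")
  TRUE
})

#' Annotated beat series
#'
#' Time-stamped heart beats labelled \code{NORMAL} or \code{PVC} (premature
#' ventricular complex), optional annotated fibrillation (VF) episode
#' intervals, and the analysis window (default the 10-min ischemic episode,
#' 0--600 s).
#'
#' @slot timesS Strictly increasing beat times in seconds.
#' @slot labels Character vector parallel to \code{timesS}.
#' @slot vfIntervals \code{data.frame} with columns \code{start_s},
#'   \code{end_s}; non-overlapping, inside the window.
#' @slot window Numeric length-2, analysis window in seconds.
#'
#' @seealso [beatSeries()], [readBeats()], [summarizeBeats()]
#' @export
setClass("BeatSeries",
  representation(timesS = "numeric", labels = "character",
                 vfIntervals = "data.frame", window = "numeric")
)

setValidity("BeatSeries", function(object) {
  if (length(object@timesS) != length(object@labels))
    return("times and labels must have equal length")
  if (length(object@timesS) > 1 && any(diff(object@timesS) <= 0))
    return("beat times must be strictly increasing")
  if (!all(object@labels %in% c("NORMAL", "PVC")))
    return("labels must be NORMAL or PVC")
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    return("window must be (start, end) with start < end")
  vf <- object@vfIntervals
  if (nrow(vf) > 0) {
    if (any(vf$start_s >= vf$end_s))
      return("VF intervals must have start < end")
    if (any(vf$start_s < object@window[1]) || any(vf$end_s > object@window[2]))
      return("VF intervals must lie inside the analysis window")
    o <- order(vf$start_s)
    if (nrow(vf) > 1 && any(vf$start_s[o][-1] < vf$end_s[o][-nrow(vf)]))
      return("VF intervals must not overlap")
  }
  TRUE
})

#' Arrhythmia summary of one recording
#'
#' Counts of PVC runs by category (single = 1, salvo = 2--3, tachycardia >= 4
#' consecutive PVCs), total PVC count, tachycardia and fibrillation durations,
#' and the tachyarrhythmia incidence flag (any tachycardia or VF episode in
#' the window).
#'
#' @slot nSingles,nSalvos,nTachEpisodes Episode counts per category.
#' @slot totalPvcs Total PVC count (= singles + salvo beats + tachycardia
#'   beats).
#' @slot tachDurationS,vfDurationS,tachyarrhythmiaDurationS Durations in
#'   seconds; the last is the exact sum of the first two.
#' @slot incidence \code{TRUE} when any tachycardia run or VF interval
#'   occurred.
#' @slot runs \code{data.frame} of the classified PVC runs.
#'
#' @seealso [summarizeBeats()]
#' @export
setClass("EcgSummary",
  representation(nSingles = "integer", nSalvos = "integer",
                 nTachEpisodes = "integer", totalPvcs = "integer",
                 tachDurationS = "numeric", vfDurationS = "numeric",
                 tachyarrhythmiaDurationS = "numeric", incidence = "logical",
                 runs = "data.frame")
)

setValidity("EcgSummary", function(object) {
  if (object@tachyarrhythmiaDurationS !=
      object@tachDurationS + object@vfDurationS)
    return("tachyarrhythmia duration must equal tachycardia + VF duration")
  TRUE
})

#' Result of one hypothesis test
#'
#' @slot test Test name.
#' @slot statistic Test statistic (U, F, odds ratio, ...).
#' @slot pValue p-value in \[0, 1\] (Bonferroni-adjusted where applicable).
#' @slot comparison Label of the comparison performed.
#' @slot alpha Significance level (0.05).
#' @slot significant \code{pValue < alpha}.
#' @slot method Extra detail (e.g., exact vs normal approximation).
#'
#' @export
setClass("TestResult",
  representation(test = "character", statistic = "numeric", pValue = "numeric",
                 comparison = "character", alpha = "numeric",
                 significant = "logical", method = "character"),
  prototype(alpha = 0.05, method = NA_character_)
)

setValidity("TestResult", function(object) {
  if (is.na(object@pValue) || object@pValue < 0 || object@pValue > 1)
    return("pValue must lie in [0, 1]")
  if (!identical(object@significant, object@pValue < object@alpha))
    return("significant must equal pValue < alpha")
  TRUE
})
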