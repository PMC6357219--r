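#' @name gjlat-accessors
#' @title Accessors for gjlat classes
#'
#' @description Slot accessors: \code{channelNames} and \code{getChannel}
#' for [TissueImage], \code{pixelSize} for calibrated objects,
#' \code{puncta} and \code{trueFraction} for [PhantomTruth],
#' \code{particleTable} for [ParticleSet] and [QuantResult],
#' \code{endToEndPct} for [QuantResult], \code{maskMatrix} for [BinaryMask],
#' \code{orientationAngles} and \code{orientationCoherence} for
#' [OrientationField].
#'
#' @param object The object to access.
#' @param name Channel name for \code{getChannel}.
#' @return The slot contents (see the class documentation).
NULL

#' @rdname gjlat-accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname gjlat-accessors
#' @export
setGeneric("getChannel", function(object, name) standardGeneric("getChannel"))
#' @rdname gjlat-accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname gjlat-accessors
#' @export
setGeneric("puncta", function(object) standardGeneric("puncta"))
#' @rdname gjlat-accessors
#' @export
setGeneric("trueFraction", function(object) standardGeneric("trueFraction"))
#' @rdname gjlat-accessors
#' @export
setGeneric("particleTable", function(object) standardGeneric("particleTable"))
#' @rdname gjlat-accessors
#' @export
setGeneric("endToEndPct", function(object) standardGeneric("endToEndPct"))
#' @rdname gjlat-accessors
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))
#' @rdname gjlat-accessors
#' @export
setGeneric("orientationAngles", function(object) standardGeneric("orientationAngles"))
#' @rdname gjlat-accessors
#' @export
setGeneric("orientationCoherence", function(object) standardGeneric("orientationCoherence"))

#' @rdname gjlat-accessors
#' @export
setMethod("channelNames", "TissueImage", function(object) names(object@channels))

#' @rdname gjlat-accessors
#' @export
setMethod("getChannel", "TissueImage", function(object, name) {
  if (!name %in% names(object@channels))
    stop("no channel '", name, "' in image '", object@sourceId, "'")
  object@channels[[name]]
})

#' @rdname gjlat-accessors
#' @export
setMethod("pixelSize", "TissueImage", function(object) object@pixelSizeUm)
#' @rdname gjlat-accessors
#' @export
setMethod("pixelSize", "ParticleSet", function(object) object@pixelSizeUm)
#' @rdname gjlat-accessors
#' @export
setMethod("puncta", "PhantomTruth", function(object) object@puncta)
#' @rdname gjlat-accessors
#' @export
setMethod("trueFraction", "PhantomTruth", function(object) object@trueFractionPct)
#' @rdname gjlat-accessors
#' @export
setMethod("particleTable", "ParticleSet", function(object) object@table)
#' @rdname gjlat-accessors
#' @export
setMethod("particleTable", "QuantResult", function(object) object@particles)
#' @rdname gjlat-accessors
#' @export
setMethod("endToEndPct", "QuantResult", function(object) object@endToEndPct)
#' @rdname gjlat-accessors
#' @export
setMethod("maskMatrix", "BinaryMask", function(object) object@mask)
#' @rdname gjlat-accessors
#' @export
setMethod("orientationAngles", "OrientationField", function(object) object@angleDeg)
#' @rdname gjlat-accessors
#' @export
setMethod("orientationCoherence", "OrientationField", function(object) object@coherence)

setMethod("show", "TissueImage", function(object) {
  d <- dim(object@channels[[1]])
  cat("TissueImage '", object@sourceId, "': ", d[1], " x ", d[2],
      " px (", round(d[2] * object@pixelSizeUm, 1), " x ",
      round(d[1] * object@pixelSizeUm, 1), " um), channels: ",
      paste(names(object@channels), collapse = ", "),
      ", pixel size ", object@pixelSizeUm, " um\n", sep = "")
})

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth: ", nrow(object@puncta), " puncta, end-to-end area ",
      if (is.na(object@trueFractionPct)) "NA" else
        sprintf("%.1f%%", object@trueFractionPct), "\n", sep = "")
})

setMethod("show", "BinaryMask", function(object) {
  cat("BinaryMask (", object@channel, "): ", sum(object@mask),
      " foreground px of ", length(object@mask),
      ", threshold ", object@threshold, " DN\n", sep = "")
})

setMethod("show", "OrientationField", function(object) {
  cat("OrientationField: ", nrow(object@angleDeg), " x ", ncol(object@angleDeg),
      " px, window sigma ", object@windowSigmaUm, " um, median coherence ",
      sprintf("%.2f", stats::median(object@coherence)), "\n", sep = "")
})

setMethod("show", "ParticleSet", function(object) {
  cat("ParticleSet: ", nrow(object@table), " particles, pixel size ",
      object@pixelSizeUm, " um\n", sep = "")
})

setMethod("show", "QuantResult", function(object) {
  cat("QuantResult '", object@imageId, "': ", object@nParticles, " particles",
      if (object@nUnclassified > 0)
        paste0(" (", object@nUnclassified, " unclassified)") else "",
      "\n  total junction area ", sprintf("%.2f", object@totalAreaUm2),
      " um^2, end-to-end ",
      if (is.na(object@endToEndPct)) "NA" else
        sprintf("%.1f%%", object@endToEndPct), "\n", sep = "")
})

setMethod("show", "EcgSummary", function(object) {
  cat("EcgSummary: ", object@totalPvcs, " PVCs (",
      object@nSingles, " singles, ", object@nSalvos, " salvos, ",
      object@nTachEpisodes, " tachycardia episodes)\n",
      "  tachyarrhythmia duration ",
      sprintf("%.1f", object@tachyarrhythmiaDurationS), " s, incidence ",
      object@incidence, "\n", sep = "")
})

setMethod("show", "TestResult", function(object) {
  cat(object@test, " [", object@comparison, "]: statistic = ",
      sprintf("%.4g", object@statistic), ", p = ",
      sprintf("%.4g", object@pValue),
      if (object@significant) " *" else "", "\n", sep = "")
})
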