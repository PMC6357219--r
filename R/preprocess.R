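#' Read a calibrated multi-channel TIFF
#'
#' Reads a (multi-page) TIFF into a [TissueImage], mapping pages to channel
#' names in the declared order. The pixel size is taken, in order of
#' precedence, from \code{pixelSizeOverride}, a \code{*_params.json} /
#' \code{params.json} sidecar in the same directory (as written by
#' [writePhantom()]), the TIFF resolution tags, and finally the default
#' acquisition calibration of 0.3225 um with a warning.
#'
#' @param path Path to the TIFF file.
#' @param pixelSizeOverride Optional pixel size in micrometres, overriding any
#'   recorded calibration.
#' @param channels Channel names, in page order.
#'
#' @return A [TissueImage]. Intensities are returned in 16-bit DN; non-16-bit
#'   input is accepted and rescaled, with a message.
#' @export
readTissueImage <- function(path, pixelSizeOverride = NULL,
                            channels = c("CX43", "WGA", "DAPI")) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(channels))
    stop("channel count mismatch: TIFF '", path, "' has ", length(pages),
         " page(s) but ", length(channels), " channel name(s) were declared")
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bits) && bits != 16L)
    message("readTissueImage: '", path, "' is ", bits,
            "-bit; rescaling to 16-bit DN")
  chans <- lapply(pages, function(pg) {
    if (length(dim(pg)) == 3L) pg <- pg[, , 1] # ignore extra samples
    m <- round(pg * 65535)
    attributes(m) <- list(dim = dim(m))  # drop TIFF tag attributes
    m
  })
  names(chans) <- channels

  psz <- NULL; src <- "tiff"
  if (!is.null(pixelSizeOverride)) {
    psz <- pixelSizeOverride; src <- "override"
  } else {
    sidecars <- c(sub("_image\\.tif{1,2}$", "_params.json", path),
                  file.path(dirname(path), "params.json"))
    sidecars <- sidecars[sidecars != path & file.exists(sidecars)]
    if (length(sidecars)) {
      meta <- jsonlite::read_json(sidecars[1])
      if (!is.null(meta$pixel_size_um)) {
        psz <- as.numeric(meta$pixel_size_um); src <- "sidecar"
      }
    }
    if (is.null(psz)) {
      xres <- attr(pages[[1]], "x.resolution")
      unit <- attr(pages[[1]], "resolution.unit")
      if (!is.null(xres) && is.numeric(xres) && xres > 0) {
        perUm <- switch(ifelse(is.null(unit), "inch", unit),
                        inch = xres / 25400, cm = xres / 10000, xres)
        psz <- 1 / perUm; src <- "tiff-tags"
      }
    }
    if (is.null(psz)) {
      psz <- 0.3225; src <- "default"
      warning("no pixel size recorded for '", path,
              "'; using default 0.3225 um", call. = FALSE)
    }
  }
  methods::new("TissueImage", channels = chans, pixelSizeUm = psz,
               sourceId = path)
}

#' Rolling-ball background subtraction
#'
#' Corrects uneven illumination by subtracting the morphological background:
#' the greyscale opening of the image with a non-flat spherical-cap ("rolling
#' ball") structuring element of the given radius, i.e. the envelope of a
#' ball rolled under the intensity surface. The output is
#' \code{pmin(pmax(input - background, 0), input)}, so it is non-negative and
#' never exceeds the input. This is the exact morphology; no downsampling
#' approximation is applied.
#'
#' @param channel Numeric intensity matrix.
#' @param radiusPx Ball radius in pixels (default 50).
#'
#' @return Background-subtracted matrix of the same shape (floating point;
#'   re-quantize only on write).
#' @examples
#' m <- matrix(100, 64, 64); m[30:34, 30:34] <- 5000
#' out <- subtractBackground(m, radiusPx = 10)
#' @export
subtractBackground <- function(channel, radiusPx = 50L) {
  if (!is.matrix(channel) || !is.numeric(channel))
    stop("channel must be a numeric matrix")
  radiusPx <- as.integer(radiusPx)
  if (radiusPx < 1L) stop("radiusPx must be >= 1")
  if (radiusPx > nrow(channel) && radiusPx > ncol(channel))
    stop("rolling-ball radius (", radiusPx,
         ") exceeds both image dimensions; background undefined")
  bg <- .Call_ball_opening(channel, radiusPx)
  pmin(pmax(channel - bg, 0), channel)
}

#' Threshold a channel into a binary mask
#'
#' The comparison is inclusive: a pixel is foreground when its intensity is
#' greater than or equal to the threshold, so threshold 0 selects everything
#' and threshold 65535 retains only saturated pixels.
#'
#' @param channel Numeric intensity matrix.
#' @param threshold Intensity threshold in DN, within \[0, 65535\].
#' @param channelName Name recorded in the mask for provenance.
#'
#' @return A [BinaryMask].
#' @export
makeMask <- function(channel, threshold, channelName = "CX43") {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 65535)
    stop("threshold must be a single value in [0, 65535]")
  methods::new("BinaryMask", mask = channel >= threshold,
               threshold = threshold, channel = channelName)
}

#' Suggest a segmentation threshold (Otsu)
#'
#' Deterministic automated stand-in for a manually chosen per-image
#' threshold: Otsu's between-class-variance maximizer computed on the
#' (background-subtracted) channel over the full 16-bit range. The manual
#' per-image threshold remains the primary path; when the suggestion is used
#' by [quantifyImage()] it is recorded in the provenance.
#'
#' @param channel Numeric intensity matrix; must not be constant.
#'
#' @return Threshold in DN.
#' @export
suggestThreshold <- function(channel) {
  rng <- range(channel)
  if (rng[1] == rng[2])
    stop("channel is constant; no threshold can be suggested - set one manually")
  th <- EBImage::otsu(EBImage::Image(channel / 65535), range = c(0, 1),
                      levels = 65536L)
  as.numeric(th) * 65535
}
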