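# Small phantom used throughout the unit tests (a few seconds end to end);
# acceptance tests use full-size frames.
smallPhantomParams <- function(...) {
  defaults <- list(imageHeightPx = 256L, imageWidthPx = 336L, nPuncta = 60L,
                   trueEndToEndFraction = 0.8, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(phantomParams, args)
}

smallQuantConfig <- function(...) {
  do.call(quantConfig, utils::modifyList(list(radiusPx = 30L), list(...)))
}

# 90-degree counterclockwise rotation of a matrix in screen convention.
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

rotateImage <- function(img) {
  methods::new("TissueImage",
               channels = lapply(img@channels, rot90),
               pixelSizeUm = pixelSize(img), sourceId = "rotated")
}
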