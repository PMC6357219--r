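#' Parameters of the synthetic cardiac-tissue phantom
#'
#' Builds a validated parameter set for [generateTissuePhantom()]. Defaults
#' emulate the acquisition the pipeline targets: 1344 x 1024 16-bit frames at
#' 0.3225 um/pixel, longitudinal sections of elongated cardiomyocytes
#' (~100 x 20 um) in a locally coherent fiber field, WGA-bright membranes,
#' Cx43 puncta concentrated at intercalated discs, smooth uneven illumination
#' and a Poisson (shot) + Gaussian (read) CCD noise model.
#'
#' @param imageHeightPx,imageWidthPx Image dimensions in pixels.
#' @param pixelSizeUm Pixel edge in micrometres.
#' @param nCellRows Number of cell rows spanning the image height; only used
#'   to derive the cell width when \code{cellWidthUm} is \code{NA}.
#' @param cellLengthUm,cellWidthUm Cell size along / across the fiber axis
#'   (um). \code{cellWidthUm = NA} derives the width from \code{nCellRows}.
#' @param fiberMeanAngleDeg Mean myofiber axis, degrees in \[0, 180)
#'   (axial; measured counterclockwise from the +column axis, origin
#'   top-left).
#' @param fiberWobbleDeg Standard deviation (degrees) of the smooth angular
#'   drift of the fiber field along the fiber direction; 0 gives a perfectly
#'   constant field.
#' @param nPuncta Number of Cx43 puncta to place.
#' @param trueEndToEndFraction Target fraction (0--1) of total punctum area
#'   placed at intercalated-disc (end-to-end) positions; the remainder goes to
#'   lateral membranes (side-to-side).
#' @param punctumRadiusMeanUm,punctumRadiusSdUm Mean and SD of the lognormal
#'   punctum radius (um).
#' @param membraneIntensity,punctumIntensity,nucleusIntensity Peak channel
#'   intensities in 16-bit DN.
#' @param illuminationGradientAmplitude Amplitude of the multiplicative
#'   low-order polynomial illumination surface, as a fraction of the mean
#'   (0 disables it).
#' @param gaussianNoiseSd Read-noise SD in DN (0 disables).
#' @param poissonScale Photons per DN for the shot-noise model (0 disables).
#' @param seed Default random seed used by [generateTissuePhantom()].
#'
#' @return A named list of class \code{"PhantomParams"}.
#' @examples
#' p <- phantomParams(nPuncta = 50, trueEndToEndFraction = 0.5)
#' @export
phantomParams <- function(imageHeightPx = 1024L, imageWidthPx = 1344L,
                          pixelSizeUm = 0.3225,
                          nCellRows = NA_integer_,
                          cellLengthUm = 100, cellWidthUm = 20,
                          fiberMeanAngleDeg = 0, fiberWobbleDeg = 8,
                          nPuncta = 300L, trueEndToEndFraction = 0.8,
                          punctumRadiusMeanUm = 0.8, punctumRadiusSdUm = 0.25,
                          membraneIntensity = 20000, punctumIntensity = 30000,
                          nucleusIntensity = 12000,
                          illuminationGradientAmplitude = 0.3,
                          gaussianNoiseSd = 150, poissonScale = 0.05,
                          seed = 0L) {
  p <- list(imageHeightPx = as.integer(imageHeightPx),
            imageWidthPx = as.integer(imageWidthPx),
            pixelSizeUm = pixelSizeUm, nCellRows = nCellRows,
            cellLengthUm = cellLengthUm, cellWidthUm = cellWidthUm,
            fiberMeanAngleDeg = fiberMeanAngleDeg %% 180,
            fiberWobbleDeg = fiberWobbleDeg,
            nPuncta = as.integer(nPuncta),
            trueEndToEndFraction = trueEndToEndFraction,
            punctumRadiusMeanUm = punctumRadiusMeanUm,
            punctumRadiusSdUm = punctumRadiusSdUm,
            membraneIntensity = membraneIntensity,
            punctumIntensity = punctumIntensity,
            nucleusIntensity = nucleusIntensity,
            illuminationGradientAmplitude = illuminationGradientAmplitude,
            gaussianNoiseSd = gaussianNoiseSd, poissonScale = poissonScale,
            seed = as.integer(seed))
  class(p) <- "PhantomParams"
  validatePhantomParams(p)
  p
}

#' Validate phantom parameters
#'
#' @param p A \code{"PhantomParams"} list (see [phantomParams()]).
#' @return \code{p}, invisibly, or an error describing the violated
#'   constraint.
#' @export
validatePhantomParams <- function(p) {
  if (p$imageHeightPx <= 0 || p$imageWidthPx <= 0)
    stop("image dimensions must be positive")
  if (!is.finite(p$pixelSizeUm) || p$pixelSizeUm <= 0)
    stop("pixelSizeUm must be positive")
  if (p$trueEndToEndFraction < 0 || p$trueEndToEndFraction > 1)
    stop("trueEndToEndFraction must lie in [0, 1]")
  for (f in c("cellLengthUm", "punctumRadiusMeanUm", "punctumRadiusSdUm")) {
    if (!is.finite(p[[f]]) || p[[f]] < 0 || (f != "punctumRadiusSdUm" && p[[f]] <= 0))
      stop(f, " must be positive")
  }
  cw <- .cellWidth(p)
  if (!is.finite(cw) || cw <= 0) stop("cell width must be positive")
  if (p$punctumRadiusMeanUm >= cw / 2)
    stop("punctum radius must be smaller than half the cell width (",
         cw / 2, " um)")
  for (f in c("membraneIntensity", "punctumIntensity", "nucleusIntensity")) {
    if (p[[f]] < 0 || p[[f]] > 65535)
      stop(f, " must lie in [0, 65535]")
  }
  if (p$nPuncta < 0) stop("nPuncta must be non-negative")
  if (p$gaussianNoiseSd < 0 || p$poissonScale < 0)
    stop("noise parameters must be non-negative")
  invisible(p)
}

.cellWidth <- function(p) {
  if (is.finite(p$cellWidthUm) && !is.na(p$cellWidthUm)) return(p$cellWidthUm)
  if (!is.na(p$nCellRows) && p$nCellRows > 0)
    return(p$imageHeightPx * p$pixelSizeUm / p$nCellRows)
  20
}

# Smooth angular drift of the fiber field: a sum of three long-period
# sinusoids in the along-fiber coordinate u, scaled so the RMS slope matches
# tan(fiberWobbleDeg). Returns the displacement g(u) and its derivative.
.wobble <- function(wobbleDeg) {
  periods <- c(180, 260, 410)
  if (wobbleDeg <= 0) {
    return(list(g = function(u) 0 * u, gp = function(u) 0 * u))
  }
  phases <- stats::runif(3, 0, 2 * pi)
  slopeRms <- tan(wobbleDeg * pi / 180)
  a <- rep(slopeRms * sqrt(2 / 3), 3)     # per-component slope amplitude
  A <- a * periods / (2 * pi)             # displacement amplitude (um)
  list(
    g = function(u) A[1] * sin(2 * pi * u / periods[1] + phases[1]) +
                    A[2] * sin(2 * pi * u / periods[2] + phases[2]) +
                    A[3] * sin(2 * pi * u / periods[3] + phases[3]),
    gp = function(u) a[1] * cos(2 * pi * u / periods[1] + phases[1]) +
                     a[2] * cos(2 * pi * u / periods[2] + phases[2]) +
                     a[3] * cos(2 * pi * u / periods[3] + phases[3])
  )
}

#' Generate a synthetic cardiac-tissue phantom with known ground truth
#'
#' Renders a three-channel (CX43, WGA, DAPI) 16-bit micrograph of a
#' longitudinal cardiac section: a brick-wall lattice of elongated cells whose
#' long axis follows a smooth orientation field, WGA-bright membranes, DAPI
#' nuclei in cell centres, and Cx43 puncta placed either on transversal cell
#' ends (intercalated discs, end-to-end) or on lateral membranes
#' (side-to-side) so that the end-to-end share of total punctum \emph{area}
#' approximates \code{trueEndToEndFraction} (area-weighted greedy
#' assignment). A multiplicative illumination gradient and Poisson + Gaussian
#' noise are applied last; the ground truth records every punctum before
#' noise.
#'
#' Puncta are rendered as discs with a logistic edge profile whose intensity
#' equals exactly half the peak at the nominal radius, so with noise and
#' illumination disabled each punctum's pixel set is exactly recoverable by
#' thresholding at \code{punctumIntensity / 2}. Placement enforces a minimum
#' separation so puncta never merge.
#'
#' The same \code{(params, seed)} pair always produces bit-identical output;
#' all randomness flows from one seeded generator.
#'
#' @param params A \code{"PhantomParams"} list from [phantomParams()].
#' @param seed Integer seed; defaults to \code{params$seed}.
#'
#' @return A list with elements \code{image} ([TissueImage]), \code{truth}
#'   ([PhantomTruth]) and \code{params} (the parameters with the seed used).
#' @examples
#' ph <- generateTissuePhantom(phantomParams(imageHeightPx = 256,
#'   imageWidthPx = 320, nPuncta = 40, seed = 1))
#' trueFraction(ph$truth)
#' @export
generateTissuePhantom <- function(params = phantomParams(), seed = params$seed) {
  validatePhantomParams(params)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  H <- params$imageHeightPx; W <- params$imageWidthPx
  psz <- params$pixelSizeUm
  L <- params$cellLengthUm; Wc <- .cellWidth(params)
  th0 <- params$fiberMeanAngleDeg * pi / 180
  c0 <- cos(th0); s0 <- sin(th0)

  wob <- .wobble(params$fiberWobbleDeg)

  # physical coordinates of pixel centres (x = column, y = row, origin
  # top-left); u runs along the mean fiber axis, v across it
  X <- matrix((seq_len(W) - 1) * psz, H, W, byrow = TRUE)
  Y <- matrix((seq_len(H) - 1) * psz, H, W)
  U <- X * c0 - Y * s0
  V <- X * s0 + Y * c0
  GP <- wob$gp(U)
  Wr <- V + wob$g(U)                      # warped cross-fiber coordinate

  angleMap <- (params$fiberMeanAngleDeg + atan(GP) * 180 / pi) %% 180

  # membranes: lateral at multiples of the cell width in Wr, transversal
  # (intercalated discs) at brick-offset multiples of the cell length in u
  sigmaM <- 0.45
  dLat <- abs(Wr - Wc * round(Wr / Wc)) / sqrt(1 + GP^2)
  rowIdx <- floor(Wr / Wc)
  phase <- (rowIdx %% 2) * (L / 2)
  Tt <- U - phase
  dTr <- abs(Tt - L * round(Tt / L))
  wga <- params$membraneIntensity *
    pmax(exp(-dLat^2 / (2 * sigmaM^2)), exp(-dTr^2 / (2 * sigmaM^2)))

  # nuclei: one ellipse per cell centre, axes 6 x 3 um
  frU <- Tt / L - floor(Tt / L)
  frW <- Wr / Wc - rowIdx
  q <- (abs(frU - 0.5) * L / 6)^2 + (abs(frW - 0.5) * Wc / 3)^2
  dapi <- params$nucleusIntensity * exp(-3 * q)

  # ---- puncta ------------------------------------------------------------
  n <- params$nPuncta
  truthDf <- data.frame(punctum_id = integer(0), x_px = numeric(0),
                        y_px = numeric(0), radius_px = numeric(0),
                        area_px = integer(0), class = character(0),
                        stringsAsFactors = FALSE)
  cx43 <- matrix(0, H, W)
  if (n > 0) {
    mlog <- log(1 + (params$punctumRadiusSdUm / params$punctumRadiusMeanUm)^2)
    radii <- stats::rlnorm(n, log(params$punctumRadiusMeanUm) - mlog / 2,
                           sqrt(mlog))
    radii <- pmin(pmax(radii, 0.3), Wc / 2 - 1.6)

    # coordinate ranges of the image in the fiber frame
    cx <- c(0, (W - 1) * psz); cy <- c(0, (H - 1) * psz)
    corners <- expand.grid(x = cx, y = cy)
    uRange <- range(corners$x * c0 - corners$y * s0)
    wRange <- range(corners$x * s0 + corners$y * c0) # v range; w differs by g
    rows <- floor((wRange[1] - 5) / Wc):floor((wRange[2] + 5) / Wc)
    margin <- 1.2

    # area-weighted class assignment: each punctum is steered to whichever
    # membrane keeps the cumulative end-to-end area share closest to the
    # target; if that class cannot be placed, the other is tried, so crowding
    # does not bias the realized fraction
    f <- params$trueEndToEndFraction
    acc <- list(); nDropped <- 0
    endArea <- 0; cumArea <- 0
    tryPlace <- function(r0, asEnd) {
      for (try in seq_len(300)) {
        j <- rows[sample.int(length(rows), 1)]
        ph <- (j %% 2) * (L / 2)
        if (asEnd) {
          ks <- floor((uRange[1] - L) / L):ceiling((uRange[2] + L) / L)
          u0 <- ks[sample.int(length(ks), 1)] * L + ph
          lo <- j * Wc + r0 + margin; hi <- (j + 1) * Wc - r0 - margin
          if (hi <= lo) next
          w0 <- stats::runif(1, lo, hi)
        } else {
          u0 <- stats::runif(1, uRange[1] - L, uRange[2] + L)
          w0 <- j * Wc
          # keep clear of disc lines of both adjacent rows
          ok <- TRUE
          for (jj in c(j - 1, j)) {
            pj <- (jj %% 2) * (L / 2)
            if (abs((u0 - pj) - L * round((u0 - pj) / L)) < r0 + 2.2) ok <- FALSE
          }
          if (!ok) next
        }
        v0 <- w0 - wob$g(u0)
        x0 <- u0 * c0 + v0 * s0; y0 <- -u0 * s0 + v0 * c0
        colC <- x0 / psz + 1; rowC <- y0 / psz + 1
        rpx <- r0 / psz
        if (colC < rpx + 4 || colC > W - rpx - 3 ||
            rowC < rpx + 4 || rowC > H - rpx - 3) next
        sep <- TRUE
        for (a in acc) {
          if ((colC - a$col)^2 + (rowC - a$row)^2 <
              ((r0 + a$r + 1.6) / psz)^2) { sep <- FALSE; break }
        }
        if (!sep) next
        return(list(col = colC, row = rowC, r = r0))
      }
      NULL
    }
    for (i in seq_len(n)) {
      r0 <- radii[i]
      a0 <- pi * r0^2
      wantEnd <- endArea < f * (cumArea + a0)
      cand <- tryPlace(r0, wantEnd)
      asEnd <- wantEnd
      if (is.null(cand) && f > 0 && f < 1) {
        # fall back to the other membrane class rather than dropping, so
        # crowding does not bias the realized fraction; at the exact bounds
        # 0 and 1 the class is mandatory and the punctum is dropped instead
        cand <- tryPlace(r0, !wantEnd)
        asEnd <- !wantEnd
      }
      if (is.null(cand)) { nDropped <- nDropped + 1; next }
      cand$cls <- if (asEnd) "END_TO_END" else "SIDE_TO_SIDE"
      acc[[length(acc) + 1]] <- cand
      cumArea <- cumArea + a0
      if (asEnd) endArea <- endArea + a0
    }
    if (nDropped > 0)
      message("phantom: dropped ", nDropped,
              " puncta that could not be placed without overlap")

    # render with a logistic edge (exactly half peak at the nominal radius,
    # truncated at radius + 0.6 um so separated puncta never interact)
    edgeW <- 0.15; tailUm <- 0.6
    out <- vector("list", length(acc))
    for (i in seq_along(acc)) {
      a <- acc[[i]]
      rw <- ceiling((a$r + tailUm) / psz) + 1
      rs <- max(1, floor(a$row - rw)):min(H, ceiling(a$row + rw))
      cs <- max(1, floor(a$col - rw)):min(W, ceiling(a$col + rw))
      d <- sqrt(outer((rs - a$row)^2, (cs - a$col)^2, "+")) * psz
      prof <- params$punctumIntensity * stats::plogis((a$r - d) / edgeW)
      prof[d > a$r + tailUm] <- 0
      cx43[rs, cs] <- cx43[rs, cs] + prof
      out[[i]] <- data.frame(punctum_id = i, x_px = a$col, y_px = a$row,
                             radius_px = a$r / psz, area_px = sum(d <= a$r),
                             class = a$cls, stringsAsFactors = FALSE)
    }
    if (length(out)) truthDf <- do.call(rbind, out)
  }

  trueFracPct <- if (nrow(truthDf) > 0) {
    100 * sum(truthDf$area_px[truthDf$class == "END_TO_END"]) /
      sum(truthDf$area_px)
  } else NA_real_

  # ---- illumination and noise -------------------------------------------
  chans <- list(CX43 = cx43, WGA = wga, DAPI = dapi)
  if (params$illuminationGradientAmplitude > 0) {
    xi <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
    eta <- matrix(seq(-1, 1, length.out = H), H, W)
    P <- 0.9 * xi + 0.45 * eta + 0.35 * xi * eta
    P <- P / max(abs(P))
    illum <- 1 + params$illuminationGradientAmplitude * P
    chans <- lapply(chans, function(m) m * illum)
  }
  ps <- params$poissonScale
  for (nm in names(chans)) {
    m <- chans[[nm]]
    if (ps > 0)
      m <- matrix(stats::rpois(length(m), pmax(m, 0) * ps) / ps,
                  nrow(m), ncol(m))
    if (params$gaussianNoiseSd > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, params$gaussianNoiseSd),
                      nrow(m), ncol(m))
    chans[[nm]] <- pmin(pmax(round(m), 0), 65535)
  }

  img <- methods::new("TissueImage", channels = chans, pixelSizeUm = psz,
                      sourceId = sprintf("phantom_seed%d", seed))
  truth <- methods::new("PhantomTruth", puncta = truthDf,
                        trueFractionPct = trueFracPct,
                        fiberAngleMap = angleMap)
  pOut <- params; pOut$seed <- as.integer(seed)
  list(image = img, truth = truth, params = pOut)
}

#' Write a phantom (or any tissue image) to disk
#'
#' Writes a multi-page 16-bit little-endian TIFF (one page per channel, in
#' stored channel order), a ground-truth CSV (one row per punctum) when a
#' truth object is given, and a params JSON sidecar recording the pixel size,
#' channel order and, when available, the generating parameters. The sidecar
#' is what [readTissueImage()] uses to recover the calibration, since the
#' TIFF writer used here does not emit resolution tags.
#'
#' @param image A [TissueImage].
#' @param truth A [PhantomTruth], or \code{NULL} to skip the CSV.
#' @param dir Output directory (created if missing).
#' @param params Optional \code{"PhantomParams"} list to embed in the JSON.
#' @param prefix File-name prefix (default \code{"phantom"}).
#'
#' @return Invisibly, the paths written (named character vector).
#' @export
writePhantom <- function(image, truth = NULL, dir, params = NULL,
                         prefix = "phantom") {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  tifPath <- file.path(dir, paste0(prefix, "_image.tif"))
  pages <- lapply(image@channels, function(m) m / 65535)
  ok <- tryCatch(
    tiff::writeTIFF(pages, tifPath, bits.per.sample = 16L,
                    compression = "none", reduce = FALSE),
    error = function(e) stop("cannot write TIFF at ", tifPath, ": ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("cannot write TIFF at ", tifPath, ": ",
                               conditionMessage(w), call. = FALSE))
  paths <- c(image = tifPath)
  if (!is.null(truth)) {
    csvPath <- file.path(dir, paste0(prefix, "_truth.csv"))
    utils::write.csv(puncta(truth), csvPath, row.names = FALSE, quote = FALSE)
    paths <- c(paths, truth = csvPath)
  }
  jsonPath <- file.path(dir, paste0(prefix, "_params.json"))
  meta <- list(pixel_size_um = image@pixelSizeUm,
               channels = names(image@channels),
               source_id = image@sourceId)
  if (!is.null(params)) meta$params <- unclass(params)
  jsonlite::write_json(meta, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, params = jsonPath))
}
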