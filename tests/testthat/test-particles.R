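barMask <- function(H, W, cells) {
  m <- matrix(FALSE, H, W)
  m[cells] <- TRUE
  m
}

constantField <- function(H, W, angle, coherence = 1) {
  methods::new("OrientationField", angleDeg = matrix(angle, H, W),
               coherence = matrix(coherence, H, W), windowSigmaUm = 8)
}

test_that("disjoint squares become separate particles with calibrated areas", {
  m <- matrix(FALSE, 20, 20)
  m[3:5, 3:5] <- TRUE
  m[12:14, 12:14] <- TRUE
  ps <- detectParticles(m, pixelSizeUm = 0.3225)
  tab <- particleTable(ps)
  expect_identical(nrow(tab), 2L)
  expect_equal(round(tab$area_um2, 3), c(0.936, 0.936))
  expect_equal(tab$elongation, c(1, 1), tolerance = 1e-9)
})

test_that("corner-touching squares are one particle under 8-connectivity", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE
  m[4:5, 4:5] <- TRUE  # touches only at the (3,3)-(4,4) corner
  ps <- detectParticles(m, 1)
  expect_identical(nrow(particleTable(ps)), 1L)
  expect_identical(particleTable(ps)$area_px, 8L)
})

test_that("a thin bar has the axis of its direction and high elongation", {
  hbar <- detectParticles(barMask(10, 20, cbind(5, 4:13)), 1)
  expect_equal(particleTable(hbar)$major_axis_angle_deg, 0)
  expect_gt(particleTable(hbar)$elongation, 5)
  vbar <- detectParticles(barMask(20, 10, cbind(4:13, 5)), 1)
  expect_equal(particleTable(vbar)$major_axis_angle_deg, 90)
})

test_that("small components are discarded and empty masks allowed", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- TRUE          # singleton: below the default 2-px floor
  m[5:6, 5] <- TRUE
  ps <- detectParticles(m, 1)
  expect_identical(nrow(particleTable(ps)), 1L)
  expect_identical(nrow(particleTable(detectParticles(matrix(FALSE, 5, 5), 1))), 0L)
})

test_that("particle pixel sets match the flood-fill oracle on random masks", {
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(runif(64 * 64) < 0.3, 64, 64)
    ps <- detectParticles(m, 1, minAreaPx = 1L)
    lab <- ps@labels
    mine <- lapply(seq_len(max(lab)), function(k) sort(which(lab == k)))
    mine <- mine[order(vapply(mine, min, 1L))]
    expect_identical(mine, oracleFloodFill8(m))
  }
})

test_that("classification follows the axis-to-fiber angle with ties to end-to-end", {
  field0 <- constantField(20, 20, 0)
  # vertical bar: axis 90, fiber 0 -> delta 90 -> END_TO_END
  v <- classifyParticles(detectParticles(barMask(20, 20, cbind(5:14, 10)), 1), field0)
  expect_identical(particleTable(v)$junction_class, "END_TO_END")
  expect_equal(particleTable(v)$delta_angle_deg, 90)
  # horizontal bar: delta 0 -> SIDE_TO_SIDE
  h <- classifyParticles(detectParticles(barMask(20, 20, cbind(10, 5:14)), 1), field0)
  expect_identical(particleTable(h)$junction_class, "SIDE_TO_SIDE")
  # 45-degree bar against fiber 0 with threshold 45: tie goes to END_TO_END
  d <- classifyParticles(detectParticles(
    barMask(20, 20, cbind(14:5, 5:14)), 1), field0)
  expect_equal(particleTable(d)$delta_angle_deg, 45)
  expect_identical(particleTable(d)$junction_class, "END_TO_END")
  # axial wrap: fiber at 179, horizontal bar (axis 0) -> delta 1 -> SIDE
  w <- classifyParticles(detectParticles(barMask(20, 20, cbind(10, 5:14)), 1),
                         constantField(20, 20, 179))
  expect_equal(particleTable(w)$delta_angle_deg, 1)
  expect_identical(particleTable(w)$junction_class, "SIDE_TO_SIDE")
})

test_that("an indeterminate neighbourhood leaves the particle unclassified", {
  ps <- detectParticles(barMask(20, 20, cbind(5:14, 10)), 1)
  cl <- classifyParticles(ps, constantField(20, 20, 0, coherence = 0))
  expect_true(is.na(particleTable(cl)$junction_class))
  qr <- suppressMessages(endToEndFraction(cl))
  expect_identical(qr@nUnclassified, 1L)
  expect_true(is.na(endToEndPct(qr)))
  expect_equal(qr@totalAreaUm2, 0)
})

test_that("the end-to-end fraction is the area-weighted share", {
  field <- constantField(30, 30, 0)
  m <- matrix(FALSE, 30, 30)
  m[5:16, 10] <- TRUE   # vertical, 12 px -> END
  m[25, 3:6] <- TRUE    # horizontal, 4 px -> SIDE
  qr <- endToEndFraction(classifyParticles(detectParticles(m, 1), field))
  expect_equal(endToEndPct(qr), 75)
  allEnd <- endToEndFraction(classifyParticles(
    detectParticles(barMask(20, 20, cbind(5:14, 10)), 1), field))
  expect_equal(endToEndPct(allEnd), 100)
})

test_that("class areas conserve the total and percentages are reciprocal", {
  ph <- generateTissuePhantom(smallPhantomParams(seed = 2))
  qr <- suppressMessages(quantifyImage(ph$image, smallQuantConfig()))
  expect_identical(qr@endToEndAreaUm2 + qr@sideToSideAreaUm2, qr@totalAreaUm2)
  side_pct <- 100 * qr@sideToSideAreaUm2 / qr@totalAreaUm2
  expect_identical(endToEndPct(qr) + (100 - endToEndPct(qr)), 100)
  expect_equal(side_pct, 100 - endToEndPct(qr), tolerance = 1e-12)
  tab <- particleTable(qr)
  pxTotal <- sum(tab$area_px[!is.na(tab$junction_class)])
  expect_equal(qr@totalAreaUm2, pxTotal * pixelSize(ph$image)^2)
})

test_that("flipping the angle criterion swaps the two class areas", {
  ph <- generateTissuePhantom(smallPhantomParams(seed = 4))
  qr <- suppressMessages(quantifyImage(ph$image, smallQuantConfig()))
  tab <- particleTable(qr)
  tab <- tab[!is.na(tab$junction_class) & abs(tab$delta_angle_deg - 45) > 1e-9, ]
  flipped <- ifelse(90 - tab$delta_angle_deg >= 45, "END_TO_END", "SIDE_TO_SIDE")
  expect_identical(
    sum(tab$area_px[flipped == "END_TO_END"]),
    sum(tab$area_px[tab$junction_class == "SIDE_TO_SIDE"]))
})

test_that("a noiseless phantom is recovered particle for particle", {
  ph <- generateTissuePhantom(smallPhantomParams(
    imageHeightPx = 512L, imageWidthPx = 512L, nPuncta = 70L,
    gaussianNoiseSd = 0, poissonScale = 0, illuminationGradientAmplitude = 0,
    seed = 5))
  cfg <- smallQuantConfig(threshold = ph$params$punctumIntensity / 2)
  qr <- suppressMessages(quantifyImage(ph$image, cfg))
  tr <- puncta(ph$truth)
  expect_identical(qr@nParticles, nrow(tr))
  tab <- particleTable(qr)
  nearest <- vapply(seq_len(nrow(tab)), function(i)
    which.min((tr$x_px - tab$centroid_col[i])^2 +
              (tr$y_px - tab$centroid_row[i])^2), 1L)
  agree <- mean(tab$junction_class == tr$class[nearest], na.rm = TRUE)
  expect_gte(agree, 0.95)
})

test_that("quantifyImage is deterministic and tolerates an empty channel", {
  ph <- generateTissuePhantom(smallPhantomParams(seed = 6))
  a <- suppressMessages(quantifyImage(ph$image, smallQuantConfig()))
  b <- suppressMessages(quantifyImage(ph$image, smallQuantConfig()))
  expect_identical(particleTable(a), particleTable(b))
  expect_identical(endToEndPct(a), endToEndPct(b))

  blank <- methods::new("TissueImage",
    channels = list(CX43 = matrix(0, 64, 64),
                    WGA = getChannel(ph$image, "WGA")[1:64, 1:64]),
    pixelSizeUm = 0.3225, sourceId = "blank")
  qr <- suppressMessages(quantifyImage(blank, smallQuantConfig()))
  expect_identical(qr@nParticles, 0L)
  expect_true(is.na(endToEndPct(qr)))
})

test_that("a 90-degree rotation leaves the end-to-end share nearly unchanged", {
  ph <- generateTissuePhantom(smallPhantomParams(
    imageHeightPx = 400L, imageWidthPx = 400L, nPuncta = 100L, seed = 9))
  q0 <- suppressMessages(quantifyImage(ph$image, smallQuantConfig()))
  q90 <- suppressMessages(quantifyImage(rotateImage(ph$image), smallQuantConfig()))
  expect_lt(abs(endToEndPct(q0) - endToEndPct(q90)), 2)
})

test_that("stage failures carry the stage name", {
  ph <- generateTissuePhantom(smallPhantomParams(nPuncta = 5L))
  expect_error(
    suppressMessages(quantifyImage(ph$image, smallQuantConfig(radiusPx = 5000L))),
    "subtract_background")
})
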