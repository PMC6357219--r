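test_that("background subtraction maps a constant image to zero", {
  m <- matrix(137, 80, 96)
  expect_true(all(subtractBackground(m, 20L) == 0))
})

test_that("a bright disc much smaller than the ball survives subtraction", {
  m <- matrix(0, 128, 128)
  ctr <- expand.grid(r = 1:128, c = 1:128)
  inside <- (ctr$r - 64)^2 + (ctr$c - 64)^2 <= 5^2
  m[cbind(ctr$r[inside], ctr$c[inside])] <- 20000
  out <- subtractBackground(m, 50L)
  expect_true(all(abs(out[m > 0] - 20000) <= 1))
  expect_true(all(out[m == 0] <= 1))
})

test_that("rolling ball equals the brute-force ball-element oracle", {
  set.seed(42)
  for (r in c(5L, 9L)) {
    img <- matrix(runif(64 * 72, 0, 5000), 64, 72)
    mine <- subtractBackground(img, r)
    oracle <- pmin(pmax(img - oracleBallOpening(img, r), 0), img)
    expect_equal(mine, oracle, tolerance = 1e-5)
  }
})

test_that("subtraction is bounded by the input and translation-equivariant", {
  set.seed(7)
  img <- matrix(runif(90 * 90, 0, 1000), 90, 90)
  out <- subtractBackground(img, 10L)
  expect_true(all(out >= 0) && all(out <= img))
  dy <- 3L; dx <- 5L
  shifted <- matrix(0, 90, 90)
  shifted[(1 + dy):90, (1 + dx):90] <- img[1:(90 - dy), 1:(90 - dx)]
  outS <- subtractBackground(shifted, 10L)
  core <- 25:60  # interior: the opening's reach is 2r, plus the shift margin
  expect_equal(outS[core + dy, core + dx], out[core, core], tolerance = 1e-5)
})

test_that("oversized ball radii and bad inputs are rejected", {
  expect_error(subtractBackground(matrix(0, 20, 20), 0L), ">= 1")
  expect_error(subtractBackground(matrix(0, 20, 20), 25L), "exceeds")
  # radius between the two dimensions is still defined
  expect_silent(subtractBackground(matrix(0, 20, 60), 30L))
})

test_that("mask thresholding is inclusive and monotone", {
  set.seed(1)
  ch <- matrix(sample(0:65535, 400), 20, 20)
  expect_true(all(maskMatrix(makeMask(ch, 0))))
  sat <- makeMask(ch, 65535)
  expect_identical(maskMatrix(sat), ch >= 65535)
  m1 <- maskMatrix(makeMask(ch, 10000))
  m2 <- maskMatrix(makeMask(ch, 30000))
  expect_true(all(m1[m2]))  # higher threshold is a subset
  expect_error(makeMask(ch, -1), "\\[0, 65535\\]")
})

test_that("noiseless phantom mask at half intensity recovers the truth area", {
  ph <- generateTissuePhantom(smallPhantomParams(
    gaussianNoiseSd = 0, poissonScale = 0, illuminationGradientAmplitude = 0))
  mask <- makeMask(getChannel(ph$image, "CX43"),
                   ph$params$punctumIntensity / 2)
  expect_identical(sum(maskMatrix(mask)),
                   as.integer(sum(puncta(ph$truth)$area_px)))
})

test_that("Otsu suggestion separates well-separated modes", {
  set.seed(3)
  ch <- matrix(sample(c(1000, 30000), 4096, replace = TRUE, prob = c(.7, .3)),
               64, 64)
  th <- suggestThreshold(ch)
  expect_gt(th, 1000)
  expect_lt(th, 30000)
  expect_error(suggestThreshold(matrix(5, 10, 10)), "constant")
})

test_that("Otsu on a noiseless phantom recovers nearly all punctum pixels", {
  ph <- generateTissuePhantom(smallPhantomParams(
    gaussianNoiseSd = 0, poissonScale = 0, illuminationGradientAmplitude = 0))
  cx <- getChannel(ph$image, "CX43")
  th <- suggestThreshold(cx)
  truthMask <- cx >= ph$params$punctumIntensity / 2
  sel <- cx >= th
  expect_gte(sum(sel & truthMask) / sum(truthMask), 0.99)
  expect_lte(sum(sel & !truthMask) / sum(!truthMask), 0.01)
})

test_that("the reader validates channel counts and falls back on calibration", {
  ph <- generateTissuePhantom(smallPhantomParams(nPuncta = 10L))
  dir <- withr::local_tempdir()
  writePhantom(ph$image, NULL, dir)
  tif <- file.path(dir, "phantom_image.tif")
  expect_error(readTissueImage(file.path(dir, "missing.tif")), "no such file")
  expect_error(readTissueImage(tif, channels = c("CX43", "WGA")),
               "channel count mismatch")
  # with the sidecar removed, the default calibration applies with a warning
  file.remove(file.path(dir, "phantom_params.json"))
  expect_warning(img <- readTissueImage(tif), "default 0.3225")
  expect_equal(pixelSize(img), 0.3225)
  expect_equal(pixelSize(readTissueImage(tif, pixelSizeOverride = 0.5)), 0.5)
})
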