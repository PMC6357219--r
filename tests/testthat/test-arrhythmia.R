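beatsFrom <- function(labels, dt = 0.25, ...) {
  beatSeries(seq_along(labels) * dt, labels, ...)
}

test_that("run categories follow the single/salvo/tachycardia bounds", {
  r1 <- classifyPvcRuns(beatsFrom(c("N", "V", "N")))
  expect_identical(r1$category, "SINGLE")
  # four consecutive PVCs are the shortest tachycardia
  r2 <- classifyPvcRuns(beatsFrom(c("N", "V", "V", "V", "V", "N")))
  expect_identical(r2$category, "TACHYCARDIA")
  expect_identical(r2$length, 4L)
  r3 <- classifyPvcRuns(beatsFrom(c("V", "V", "N", "V")))
  expect_identical(r3$category, c("SALVO", "SINGLE"))
  expect_identical(r3$length, c(2L, 1L))
  r4 <- classifyPvcRuns(beatsFrom(c("V", "V", "V", "N")))
  expect_identical(r4$category, "SALVO")
})

test_that("random sequences match the brute-force run scanner", {
  set.seed(77)
  for (i in 1:200) {
    labels <- ifelse(runif(sample(5:60, 1)) < 0.3, "V", "N")
    b <- beatsFrom(labels)
    expect_identical(classifyPvcRuns(b),
                     oracleRuns(b@labels),
                     info = paste("case", i))
  }
})

test_that("every PVC belongs to exactly one run", {
  set.seed(78)
  for (i in 1:50) {
    labels <- ifelse(runif(80) < 0.4, "V", "N")
    b <- beatsFrom(labels)
    s <- summarizeBeats(b)
    expect_identical(s@totalPvcs, sum(labels == "V"))
    runs <- classifyPvcRuns(b)
    expect_identical(sum(runs$length), sum(labels == "V"))
  }
})

test_that("adding a PVC is monotone and can promote a salvo", {
  labels <- c("N", "V", "V", "N", "V", "N", "N")
  s0 <- summarizeBeats(beatsFrom(labels))
  labels2 <- labels; labels2[6] <- "V"
  s1 <- summarizeBeats(beatsFrom(labels2))
  expect_gte(s1@totalPvcs, s0@totalPvcs)
  # converting the NORMAL inside V,V,N,V to PVC makes a run of 4
  labels3 <- c("N", "V", "V", "N", "V", "V", "N")
  labels4 <- labels3; labels4[4] <- "V"
  expect_identical(summarizeBeats(beatsFrom(labels3))@nTachEpisodes, 0L)
  s4 <- summarizeBeats(beatsFrom(labels4))
  expect_identical(s4@nTachEpisodes, 1L)
  expect_identical(s4@nSalvos, 0L)
})

test_that("durations combine beat spans, closure and VF intervals", {
  empty <- summarizeBeats(beatsFrom(rep("N", 10)))
  expect_identical(empty@totalPvcs, 0L)
  expect_false(empty@incidence)
  expect_identical(empty@tachyarrhythmiaDurationS, 0)

  vfOnly <- summarizeBeats(beatsFrom(rep("N", 10),
    vfIntervals = data.frame(start_s = 100, end_s = 130), dt = 30))
  expect_identical(vfOnly@vfDurationS, 30)
  expect_identical(vfOnly@tachyarrhythmiaDurationS, 30)
  expect_true(vfOnly@incidence)

  # 5 PVCs spanning 0.8 s in a 0.2-s rhythm: closure adds one median IBI
  times <- c(seq(8, 9.8, by = 0.2), seq(10, 10.8, by = 0.2),
             seq(11, 12, by = 0.2))
  labels <- c(rep("N", 10), rep("V", 5), rep("N", 6))
  s <- summarizeBeats(beatSeries(times, labels))
  expect_identical(s@nTachEpisodes, 1L)
  expect_equal(s@tachDurationS, 1.0)
  expect_equal(s@tachyarrhythmiaDurationS, 1.0)
  expect_true(s@incidence)
})

test_that("episodes reaching past the window end are truncated", {
  times <- c(1, 2, 3, 598.8, 599.2, 599.6, 600.0)
  labels <- c("N", "N", "N", "V", "V", "V", "V")
  expect_message(s <- summarizeBeats(beatSeries(times, labels)), "truncated")
  expect_equal(s@tachDurationS, 600 - 598.8)
})

test_that("series validation rejects malformed input", {
  expect_error(beatSeries(c(1, 2, 2), rep("N", 3)), "strictly increasing")
  expect_error(beatSeries(1:2, c("N", "Q")), "unknown beat label")
  expect_error(beatSeries(1:2, c("N", "V"),
    vfIntervals = data.frame(start_s = c(10, 20), end_s = c(25, 40))),
    "overlap")
  expect_error(beatSeries(1:2, c("N", "V"),
    vfIntervals = data.frame(start_s = 590, end_s = 650)),
    "inside the analysis window")
  expect_error(beatSeries(1:2, c("N", "V"),
    vfIntervals = data.frame(start_s = 30, end_s = 20)),
    "start < end")
})

test_that("beats CSVs round-trip with row-level error reporting", {
  dir <- withr::local_tempdir()
  beats <- file.path(dir, "beats.csv")
  writeLines(c("time_s,label", "0.5,N", "1.0,V", "1.5,N"), beats)
  b <- readBeats(beats)
  expect_length(b@timesS, 3)
  expect_identical(b@labels, c("NORMAL", "PVC", "NORMAL"))

  bad <- file.path(dir, "bad.csv")
  writeLines(c("time_s,label", "0.5,N", "0.4,V"), bad)
  expect_error(readBeats(bad), "row 3")

  vf <- file.path(dir, "vf.csv")
  writeLines(c("start_s,end_s", "10,5"), vf)
  expect_error(readBeats(beats, vf), "malformed VF interval at row 1")
})
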