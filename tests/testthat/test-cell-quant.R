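mkSpots <- function(x, y) {
  n <- length(x)
  data.frame(frame = rep(1L, n), t_s = rep(0, n), x_px = x, y_px = y,
             x_um = x * 0.16, y_um = y * 0.16, quality = rep(500, n),
             contrast = rep(0.3, n), total_intensity = rep(100, n),
             radius_um = rep(0.25, n), cell_id = rep(NA_integer_, n))
}

test_that("puncta are counted by centre-pixel membership", {
  mask <- matrix(FALSE, 32, 32); mask[10:20, 10:20] <- TRUE
  expect_equal(countPunctaInCell(mkSpots(numeric(0), numeric(0)), mask), 0L)
  # 3 inside, 2 outside
  sp <- mkSpots(c(10, 12, 15, 2, 30), c(10, 12, 15, 2, 30))
  expect_equal(countPunctaInCell(sp, mask), 3)
  # a spot exactly on the boundary pixel is counted
  expect_equal(countPunctaInCell(mkSpots(9, 9), mask), 1)
  expect_equal(countPunctaInCell(mkSpots(8, 9), mask), 0)
  # nucleus exclusion
  nuc <- matrix(FALSE, 32, 32); nuc[14:16, 14:16] <- TRUE
  expect_equal(countPunctaInCell(sp, mask, nuc), 2)
})

test_that("disjoint cell counts add up to the union count", {
  set.seed(31)
  cells <- matrix(0L, 48, 48)
  cells[5:20, 5:20] <- 1L; cells[25:45, 10:30] <- 2L; cells[5:15, 30:45] <- 3L
  sp <- mkSpots(sample(0:47, 60, TRUE), sample(0:47, 60, TRUE))
  perCell <- vapply(1:3, function(i) countPunctaInCell(sp, cells == i),
                    integer(1))
  expect_equal(sum(perCell), countPunctaInCell(sp, cells > 0))
})

test_that("cell series recover generator truth on quiet movies", {
  for (mode in c("vehicle", "instant")) {
    kin <- ReleaseKinetics(mode)
    sim <- simulateMovie(kin, quietAcq(), seed = 41)
    spots <- detectMovie(sim$movie, tinyDet())
    series <- buildCellSeries(sim$movie, sim$cells, spots, sim$nuclei)
    truth <- trueCounts(sim$truth)
    truth <- truth[order(truth$cell, truth$frame), ]
    expect_equal(series$count, truth$count)
    if (mode == "instant") {
      expect_true(all(series$count[series$t >= 60] == 0))
      expect_true(all(series$count[series$t < 60] == 6))
    }
  }
})

test_that("buildCellSeries validates inputs and handles one frame", {
  sim <- simulateMovie(ReleaseKinetics("vehicle"), tinyAcq(), seed = 42)
  one <- MovieStack(frames = frames(sim$movie)[1],
                    timestamps = timestamps(sim$movie)[1],
                    pixelSize = pixelSize(sim$movie))
  s <- buildCellSeries(one, sim$cells, mkSpots(10, 10))
  expect_equal(nrow(s), length(unique(sim$cells[sim$cells > 0])))

  bad <- mkSpots(10, 10); bad$frame <- 99L
  expect_error(buildCellSeries(one, sim$cells, bad), "frames outside")
  expect_error(buildCellSeries(one, matrix(0L, 96, 96), mkSpots(1, 1)),
               "no cells")
})

test_that("photobleaching QC follows the smoothed 10% rule", {
  expect_true(qcPhotobleach(rep(500, 50)))
  # monotone decline to 0.85 of baseline fails the 0.90 cutoff
  expect_false(qcPhotobleach(seq(1000, 850, length.out = 80)))
  # a single-frame dip to 0.7 in a flat 100-frame trace is absorbed by
  # the rolling mean (window mean >= 0.97)
  tr <- rep(1000, 100); tr[50] <- 700
  expect_true(qcPhotobleach(tr))
  expect_error(qcPhotobleach(rep(1, 9)), "at least 10 frames")
  # verdict is scale-invariant
  dec <- seq(1000, 800, length.out = 60)
  expect_identical(qcPhotobleach(dec), qcPhotobleach(dec * 17))
  expect_identical(qcPhotobleach(tr), qcPhotobleach(tr * 0.01))
})

test_that("still-image quantification measures per-cell means", {
  cells <- matrix(0L, 32, 32); cells[4:12, 4:12] <- 1L; cells[20:30, 20:30] <- 2L
  u <- matrix(9, 32, 32)
  rec <- quantifyStill(u, cells, condition = "a")
  expect_equal(rec$mean_intensity, c(9, 9))
  z <- matrix(0, 32, 32)
  expect_equal(quantifyStill(z, cells)$mean_intensity, c(0, 0))
  expect_error(quantifyStill(matrix(0, 8, 8), cells), "8x8")

  # synthetic still: recovered cell mean ~ truth within noise / sqrt(N)
  p <- StillImageParams(cellsPerCondition = 2, imageShape = c(128, 128),
                        conditions = data.frame(label = "flat",
                                                punctaPerCell = 0,
                                                cellIntensity = 800))
  st <- simulateStillExperiment(p, seed = 51)$flat
  rec <- quantifyStill(st$image, st$cells, condition = "flat")
  for (i in 1:2) {
    nPix <- sum(st$cells == i)
    nucFrac <- sum(st$nuclei == i) / nPix
    # nuclei are rendered at 0.6 of the cytoplasmic fill
    expected <- 200 + 800 * (1 - 0.4 * nucFrac)
    expect_lt(abs(rec$mean_intensity[i] - expected),
              5 * sqrt(expected) / sqrt(nPix) + 0.5)
  }
})

test_that("max-condition normalisation scales cells by the top condition", {
  rec <- rbind(
    data.frame(experiment = "e1", modality = "IF", condition = "A",
               cell = 1:2, mean_intensity = c(10, 20),
               puncta_count = NA_integer_, normalized_intensity = NA_real_),
    data.frame(experiment = "e1", modality = "IF", condition = "B",
               cell = 1:2, mean_intensity = c(30, 40),
               puncta_count = NA_integer_, normalized_intensity = NA_real_))
  out <- normalizeByMaxCondition(rec)
  expect_equal(out$normalized_intensity,
               c(10, 20, 30, 40) / 35, tolerance = 1e-12)
  # condition mean of the max condition is exactly 1
  expect_equal(mean(out$normalized_intensity[out$condition == "B"]), 1)

  # scale invariance within a group
  rec2 <- rec; rec2$mean_intensity <- rec2$mean_intensity * 3.7
  expect_equal(normalizeByMaxCondition(rec2)$normalized_intensity,
               out$normalized_intensity)

  # modalities normalise independently
  recPLA <- rec; recPLA$modality <- "PLA"
  recPLA$mean_intensity <- rec$mean_intensity * 100
  both <- normalizeByMaxCondition(rbind(rec, recPLA))
  expect_equal(both$normalized_intensity[both$modality == "PLA"],
               both$normalized_intensity[both$modality == "IF"])

  bad <- rec; bad$mean_intensity <- -bad$mean_intensity
  expect_error(normalizeByMaxCondition(bad), "not positive")
})
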