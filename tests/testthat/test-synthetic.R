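test_that("release-time sampling matches each kinetic regime", {
  expect_equal(sampleReleaseTimes(ReleaseKinetics("instant"), 5, seed = 1),
               rep(60, 5))
  expect_equal(sampleReleaseTimes(ReleaseKinetics("vehicle"), 3, seed = 1),
               rep(Inf, 3))
  expect_length(sampleReleaseTimes(ReleaseKinetics("instant"), 0, seed = 1),
                0)

  # Monte-Carlo mean of (tau - drugTime) vs the analytic mean 1/kRel
  k <- 0.02
  tau <- sampleReleaseTimes(ReleaseKinetics("exponential", kRel = k),
                            10000, seed = 7)
  se <- (1 / k) / sqrt(10000)
  expect_lt(abs(mean(tau - 60) - 1 / k), 3 * se)
  expect_true(all(tau >= 60))

  # two-stage mean = drugTime + 1/kBind + 1/kRel
  tau2 <- sampleReleaseTimes(
    ReleaseKinetics("two_stage", kBind = 0.01, kRel = 0.1), 10000, seed = 8)
  se2 <- sqrt(1 / 0.01^2 + 1 / 0.1^2) / sqrt(10000)
  expect_lt(abs(mean(tau2 - 60) - 110), 3 * se2)

  # reproducibility
  expect_identical(
    sampleReleaseTimes(ReleaseKinetics("exponential", kRel = k), 50,
                       seed = 11),
    sampleReleaseTimes(ReleaseKinetics("exponential", kRel = k), 50,
                       seed = 11))
})

test_that("increasing the release rate stochastically shortens survival", {
  means <- vapply(c(0.01, 0.02, 0.05), function(k)
    mean(sampleReleaseTimes(ReleaseKinetics("exponential", kRel = k),
                            2000, seed = 4)), numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("two-stage kinetics converge to exponential for fast binding", {
  k <- 0.02
  x <- sampleReleaseTimes(
    ReleaseKinetics("two_stage", kBind = 100 * k, kRel = k), 10000, seed = 5)
  y <- sampleReleaseTimes(ReleaseKinetics("exponential", kRel = k),
                          10000, seed = 6)
  d <- suppressWarnings(stats::ks.test(x, y)$statistic)
  expect_lt(as.numeric(d), 0.05)
})

test_that("timestamp sequences have the configured interval structure", {
  acq <- AcquisitionParams()
  ts <- simulateTimestamps(acq, seed = 2)
  expect_equal(ts[1], 0)
  expect_true(all(diff(ts) > 0))
  expect_true(all(diff(ts) >= acq@intervalMin - 1e-12))
  expect_true(all(diff(ts) <= acq@intervalMax + 1e-12))
  expect_lte(max(ts), acq@trialDuration)
  expect_gt(max(ts), acq@trialDuration - acq@intervalMax)
  expect_identical(ts, simulateTimestamps(acq, seed = 2))
})

test_that("vehicle movies keep true counts constant", {
  sim <- simulateMovie(ReleaseKinetics("vehicle"),
                       tinyAcq(bleachRate = 0), seed = 10)
  counts <- trueCounts(sim$truth)
  for (cid in unique(counts$cell))
    expect_true(all(counts$count[counts$cell == cid] == 6))
})

test_that("instant movies drop all true counts exactly at the drug time", {
  sim <- simulateMovie(ReleaseKinetics("instant"), tinyAcq(), seed = 10)
  counts <- trueCounts(sim$truth)
  expect_true(all(counts$count[counts$t < 60] == 6))
  expect_true(all(counts$count[counts$t >= 60] == 0))
})

test_that("exponential ground-truth survival matches the analytic law", {
  # e^{-0.021 * 33} ~ 0.5, so about half the puncta outlive drug + 33 s
  sim <- simulateMovie(ReleaseKinetics("exponential", kRel = 0.021),
                       AcquisitionParams(), seed = 12)
  tau <- truePuncta(sim$truth)$tDisappear
  n <- length(tau)
  expect_equal(n, 240)
  frac <- mean(tau > 60 + 33)
  p <- exp(-0.021 * 33)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("true counts never increase after the drug time", {
  for (kin in list(ReleaseKinetics("exponential", kRel = 0.05),
                   ReleaseKinetics("two_stage", kBind = 0.02, kRel = 0.1))) {
    counts <- trueCounts(simulateMovie(kin, tinyAcq(), seed = 13)$truth)
    for (cid in unique(counts$cell)) {
      cc <- counts[counts$cell == cid, ]
      post <- cc$count[cc$t >= 60]
      expect_true(all(diff(post) <= 0))
      expect_true(all(cc$count[cc$t < 60] == cc$count[1]))
    }
  }
})

test_that("simulation output is bit-identical for a fixed seed", {
  a <- simulateMovie(ReleaseKinetics("exponential", kRel = 0.03),
                     tinyAcq(), seed = 21)
  b <- simulateMovie(ReleaseKinetics("exponential", kRel = 0.03),
                     tinyAcq(), seed = 21)
  expect_identical(frames(a$movie), frames(b$movie))
  expect_identical(truePuncta(a$truth), truePuncta(b$truth))
  expect_identical(a$cells, b$cells)
})

test_that("multi-chain puncta fade gradually and vanish below the cutoff", {
  kin <- ReleaseKinetics("exponential", kRel = 0.05, chainsPerPunctum = 4,
                         detectFraction = 0.5)
  sim <- simulateMovie(kin, tinyAcq(), seed = 30)
  counts <- trueCounts(sim$truth)
  expect_true(all(counts$count[counts$t < 60] == 6))
  for (cid in unique(counts$cell)) {
    post <- counts$count[counts$cell == cid & counts$t >= 60]
    expect_true(all(diff(post) <= 0))
  }
})

test_that("still-image generator defaults give ~200 vs 4 puncta per cell", {
  p <- StillImageParams()
  expect_equal(p@conditions$punctaPerCell, c(200, 4))
  stills <- simulateStillExperiment(
    StillImageParams(cellsPerCondition = 3, imageShape = c(256, 256),
                     conditions = data.frame(
                       label = c("pos", "ctrl", "empty"),
                       punctaPerCell = c(40, 4, 0),
                       cellIntensity = c(1000, 150, 150))), seed = 14)
  expect_named(stills, c("pos", "ctrl", "empty"))
  expect_true(all(stills$empty$truth$count == 0))
  expect_gt(mean(stills$pos$truth$count), mean(stills$ctrl$truth$count))
  expect_equal(dim(stills$pos$image), c(256, 256))
})
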