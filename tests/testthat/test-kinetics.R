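test_that("boxcar smoothing uses truncated centred windows", {
  expect_equal(boxcarSmooth(c(0, 1, 2, 3, 4), 3), c(0.5, 1, 2, 3, 3.5))
  expect_equal(boxcarSmooth(rep(2.5, 20), 10), rep(2.5, 20))
  x <- rnorm(15)
  expect_equal(boxcarSmooth(x, 1), x)
  expect_error(boxcarSmooth(numeric(0), 3), "empty")
  expect_error(boxcarSmooth(c(1, NA), 3), "finite")
})

test_that("counts normalise to the strict pre-drug baseline", {
  p <- KineticsParams()
  out <- normalizeCounts(c(10, 30, 50, 70), c(10, 12, 14, 6), p)
  expect_equal(out$normalized, c(10, 12, 14, 6) / 12)

  const <- normalizeCounts(seq(0, 200, 10), rep(8, 21), p)
  expect_true(all(const$normalized == 1))
  expect_true(all(const$smoothed == 1))

  expect_error(normalizeCounts(c(10, 70), c(0, 5), p), "zero")
  expect_error(normalizeCounts(c(70, 80), c(5, 5), p), "baseline")
  # a frame stamped exactly at 60 s is post-drug, not baseline
  out2 <- normalizeCounts(c(30, 60, 90), c(10, 20, 30), p)
  expect_equal(out2$normalized[1], 1)
})

test_that("decay times follow the band rule with interpolation fallback", {
  p <- KineticsParams()
  # a single frame at exactly the fraction
  d <- decayTime(c(0, 50, 160, 300), c(1, 1, 0.5, 0.2), 0.5, p)
  expect_equal(d$time, 100)
  expect_equal(d$method, "band_average")
  expect_equal(d$nBand, 1L)

  # all frames inside the +/-0.01 band are averaged
  d2 <- decayTime(c(0, 150, 155, 165), c(1, 0.508, 0.501, 0.493), 0.5, p)
  expect_equal(d2$time, mean(c(150, 155, 165)) - 60, tolerance = 1e-12)
  expect_equal(d2$nBand, 3L)

  # steep decay skipping the band: linear interpolation
  d3 <- decayTime(c(0, 100, 110, 200), c(1, 0.6, 0.4, 0.1), 0.5, p)
  expect_equal(d3$method, "interpolated")
  expect_equal(d3$time, 105 - 60)

  # never reaches the fraction
  d4 <- decayTime(seq(0, 300, 10), rep(1, 31), 0.5, p)
  expect_equal(d4$method, "not_reached")
  expect_true(is.na(d4$time))

  # pre-drug frames near the fraction cannot enter the band
  d5 <- decayTime(c(10, 30, 100, 110, 200), c(0.5, 1, 0.6, 0.4, 0.1), 0.5, p)
  expect_equal(d5$time, 45)

  expect_error(decayTime(c(0, 30), c(1, 1), 0.5, p), "drugTime")
})

test_that("smoothed-exponential decay time matches the closed form", {
  # noiseless exponential, lambda = 0.02/s, 5-s sampling, boxcar k = 10;
  # the continuous boxcar over half-width w multiplies the curve by
  # sinh(lw)/(lw), shifting the half-crossing to (ln2 + ln bias)/l
  lam <- 0.02
  t <- seq(0, 480, 5)
  p <- KineticsParams(drugTime = 0)
  sm <- boxcarSmooth(exp(-lam * t), 10)
  est <- decayTime(t, sm, 0.5, p)$time
  w <- (10 - 1) / 2 * 5
  bias <- sinh(lam * w) / (lam * w)
  expected <- (log(2) + log(bias)) / lam
  expect_lt(abs(est - expected) / expected, 0.10)
})

test_that("replicate summaries aggregate cells onto a common grid", {
  p <- KineticsParams()
  t <- seq(0, 300, 5)
  decay <- pmin(1, exp(-0.02 * (t - 60)))
  cell <- data.frame(t = t, normalized = decay)

  one <- summarizeReplicate(list(cell), p)
  two <- summarizeReplicate(list(cell, cell), p)
  expect_equal(one$time, two$time)
  direct <- do.call(rbind, lapply(sort(p@fractions, decreasing = TRUE),
    function(f) decayTime(t, boxcarSmooth(decay, 10), f, p)))
  expect_equal(one$time, direct$time)

  # one constant cell + one stepping to zero: mean is 0.5 after the drug
  flat <- data.frame(t = t, normalized = rep(1, length(t)))
  step <- data.frame(t = t, normalized = as.numeric(t < 60))
  mix <- summarizeReplicate(list(flat, step), p)
  expect_false(is.na(mix$time[abs(mix$fraction - 2 / 3) < 1e-9]))
  expect_equal(mix$method[abs(mix$fraction - 1 / 3) < 1e-9], "not_reached")

  expect_error(summarizeReplicate(list(), p), "no QC-passing cells")
})

test_that("decay times are ordered for monotone trajectories", {
  p <- KineticsParams()
  for (lam in c(0.005, 0.02, 0.08)) {
    t <- seq(0, 480, 5)
    v <- pmin(1, exp(-lam * (t - 60)))
    s <- summarizeReplicate(list(data.frame(t = t, normalized = v)), p)
    times <- s$time[order(-s$fraction)]
    times <- times[!is.na(times)]
    expect_true(all(diff(times) >= 0))
  }
})

test_that("replicate t 1/2 recovers the simulated rate within 20%", {
  # ground-truth counts (no imaging noise) through the analysis chain
  lam <- 0.021
  sim <- simulateMovie(ReleaseKinetics("exponential", kRel = lam),
                       AcquisitionParams(), seed = 61)
  counts <- trueCounts(sim$truth)
  p <- KineticsParams()
  cells <- lapply(split(counts, counts$cell), function(cc)
    normalizeCounts(cc$t, cc$count, p))
  s <- summarizeReplicate(cells, p)
  t12 <- s$time[abs(s$fraction - 0.5) < 1e-9]
  w <- (p@boxcarK / 2) * 5.4
  bias <- sinh(lam * w) / (lam * w)
  expected <- (log(2) + log(bias)) / lam
  expect_lt(abs(t12 - expected) / expected, 0.20)
})

test_that("binned curves pool observations into half-open 5-s bins", {
  p <- KineticsParams()
  s1 <- data.frame(t = c(1, 3), normalized = c(0.4, 0.6))
  b <- binCurve(list(s1), p)
  expect_equal(b$mean, 0.5)
  expect_equal(b$sd, sd(c(0.4, 0.6)))
  expect_equal(b$n, 2L)
  expect_equal(b$bin_center, 2.5)

  # single observation: sd reported as 0; bin edges go right
  s2 <- data.frame(t = c(2, 5), normalized = c(1, 2))
  b2 <- binCurve(list(s2), p)
  expect_equal(b2$bin_center, c(2.5, 7.5))
  expect_equal(b2$sd, c(0, 0))
  expect_equal(sum(b2$n), 2L)

  # every observation lands in exactly one bin
  set.seed(71)
  s3 <- data.frame(t = runif(100, 0, 480), normalized = runif(100))
  expect_equal(sum(binCurve(list(s3), p)$n), 100L)
})
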