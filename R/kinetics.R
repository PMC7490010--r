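#' Centred boxcar (rolling mean) smoothing
#'
#' Rolling mean of width `k` observations. The window is centred; for
#' even `k` it extends `k/2` observations to the right and `k/2 - 1` to
#' the left of the centre. At the boundaries the window is truncated to
#' the available observations, so the output has the input's length.
#'
#' @param values numeric vector of finite values.
#' @param k window width in observations (`>= 1`).
#' @return Numeric vector of the same length.
#' @examples
#' boxcarSmooth(c(0, 1, 2, 3, 4), 3)  # c(0.5, 1, 2, 3, 3.5)
#' @export
boxcarSmooth <- function(values, k) {
  if (!length(values)) stop("empty input")
  if (!all(is.finite(values))) stop("values must be finite")
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  n <- length(values)
  left <- floor((k - 1) / 2)
  right <- floor(k / 2)
  cs <- cumsum(c(0, values))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Normalise a cell's puncta counts to its pre-drug baseline
#'
#' Divides every per-frame count by the mean count over baseline frames
#' (strictly `t < baselineWindow`, the pre-drug period). Fails when no
#' baseline frames exist or the baseline mean is zero.
#'
#' @param t numeric vector of frame timestamps (s).
#' @param counts numeric vector of per-frame puncta counts.
#' @param p a [KineticsParams] object.
#' @return A `data.frame` with columns `t`, `normalized`, `smoothed`
#'   (the boxcar-smoothed normalised counts, width `p@boxcarK`).
#' @export
normalizeCounts <- function(t, counts, p = KineticsParams()) {
  stopifnot(is(p, "KineticsParams"))
  if (length(t) != length(counts)) stop("t and counts lengths differ")
  base <- counts[t < p@baselineWindow]
  if (!length(base))
    stop("no frames before the ", p@baselineWindow, " s baseline window")
  bm <- mean(base)
  if (bm == 0) stop("baseline mean count is zero; cell cannot be normalized")
  norm <- counts / bm
  data.frame(t = t, normalized = norm,
             smoothed = boxcarSmooth(norm, p@boxcarK))
}

#' Decay time at a given remaining fraction
#'
#' Implements the band rule: all frames at `t >= drugTime` whose smoothed
#' normalised value lies within `+/- bandHalfwidth` of the target
#' fraction are collected and the mean of their timestamps, minus the
#' drug time, is returned (method `"band_average"`). When the band is
#' empty (a steep decay can skip it entirely at ~5-s sampling), the
#' linearly interpolated crossing time between the last frame above the
#' fraction and the first below it is returned (method `"interpolated"`).
#' A trajectory that never falls to the fraction (e.g. vehicle) gives
#' method `"not_reached"` with `time = NA`.
#'
#' @param t numeric vector of timestamps (s).
#' @param smoothed numeric vector of smoothed normalised counts.
#' @param fraction target remaining fraction in (0, 1).
#' @param p a [KineticsParams] object (uses `bandHalfwidth`, `drugTime`).
#' @return A one-row `data.frame` with columns `fraction`, `time` (s
#'   after drug addition), `nBand`, `method`.
#' @export
decayTime <- function(t, smoothed, fraction, p = KineticsParams()) {
  stopifnot(is(p, "KineticsParams"))
  if (length(t) != length(smoothed)) stop("t and smoothed lengths differ")
  if (max(t) < p@drugTime)
    stop("series ends before drugTime = ", p@drugTime, " s")
  res <- function(time, nBand, method)
    data.frame(fraction = fraction, time = time, nBand = nBand,
               method = method)
  inBand <- t >= p@drugTime & abs(smoothed - fraction) <= p@bandHalfwidth
  if (any(inBand))
    return(res(mean(t[inBand]) - p@drugTime, sum(inBand), "band_average"))
  post <- which(t >= p@drugTime)
  below <- post[smoothed[post] < fraction]
  if (!length(below)) return(res(NA_real_, 0L, "not_reached"))
  j <- below[1]
  if (j == 1L) return(res(0, 0L, "interpolated"))
  t0 <- t[j - 1]; v0 <- smoothed[j - 1]
  t1 <- t[j]; v1 <- smoothed[j]
  tc <- if (v0 == v1) t1 else t0 + (v0 - fraction) / (v0 - v1) * (t1 - t0)
  res(max(tc - p@drugTime, 0), 0L, "interpolated")
}

#' Replicate-level decay-time summary
#'
#' Builds the replicate-mean trajectory from the QC-passing cells of one
#' imaging trial and extracts decay times for every requested fraction.
#' Cells are aligned onto the union of all cells' timestamps by
#' nearest-frame lookup (fields are imaged asynchronously in general, so
#' frames need not coincide), the per-frame mean of the normalised counts
#' is taken, smoothed with the boxcar, and [decayTime()] applied.
#'
#' @param cellSeries list of per-cell `data.frame`s as returned by
#'   [normalizeCounts()] (columns `t`, `normalized`).
#' @param p a [KineticsParams] object.
#' @param replicate,condition labels copied into the summary.
#' @return A `data.frame` with one row per fraction: `replicate`,
#'   `condition`, `fraction`, `time`, `nBand`, `method`.
#' @export
summarizeReplicate <- function(cellSeries, p = KineticsParams(),
                               replicate = "r1", condition = "unknown") {
  stopifnot(is(p, "KineticsParams"))
  if (!length(cellSeries)) stop("no QC-passing cells in replicate")
  grid <- sort(unique(unlist(lapply(cellSeries, function(s) s$t))))
  vals <- vapply(cellSeries, function(s) {
    idx <- vapply(grid, function(tt) which.min(abs(s$t - tt)), integer(1))
    s$normalized[idx]
  }, numeric(length(grid)))
  meanTraj <- rowMeans(as.matrix(vals))
  smoothed <- boxcarSmooth(meanTraj, p@boxcarK)
  out <- do.call(rbind, lapply(sort(p@fractions, decreasing = TRUE),
    function(f) decayTime(grid, smoothed, f, p)))
  cbind(data.frame(replicate = replicate, condition = condition), out)
}

#' Binned mean/sd summary curve
#'
#' Pools the normalised counts of all cells into half-open time bins
#' `[i * binWidth, (i + 1) * binWidth)` on the trial clock and reports
#' per-bin mean, standard deviation (sample sd; 0 when n = 1) and n.
#'
#' @param cellSeries list of per-cell `data.frame`s (columns `t`,
#'   `normalized`).
#' @param p a [KineticsParams] object.
#' @param condition label copied into the output.
#' @return A `data.frame` with columns `bin_center`, `mean`, `sd`, `n`,
#'   `condition`.
#' @export
binCurve <- function(cellSeries, p = KineticsParams(),
                     condition = "unknown") {
  stopifnot(is(p, "KineticsParams"))
  if (!length(cellSeries)) stop("no series to bin")
  t <- unlist(lapply(cellSeries, function(s) s$t))
  v <- unlist(lapply(cellSeries, function(s) s$normalized))
  bin <- floor(t / p@binWidth)
  agg <- lapply(split(v, bin), function(x)
    c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
      n = length(x)))
  bins <- as.integer(names(agg))
  out <- data.frame(bin_center = (bins + 0.5) * p@binWidth,
                    mean = vapply(agg, `[[`, numeric(1), "mean"),
                    sd = vapply(agg, `[[`, numeric(1), "sd"),
                    n = as.integer(vapply(agg, `[[`, numeric(1), "n")),
                    condition = condition)
  rownames(out) <- NULL
  out[order(out$bin_center), , drop = FALSE]
}

#' Plot a binned summary curve
#'
#' Mean +/- sd per bin with a drug-addition marker; a minimal base-graphics
#' rendering of the condition-level summary.
#'
#' @param binned `data.frame` from [binCurve()] (one or more conditions).
#' @param drugTime drug-addition time (s) to mark.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plotBinnedCurve <- function(binned, drugTime = 60, ...) {
  conds <- unique(binned$condition)
  cols <- grDevices::hcl.colors(max(length(conds), 2), "Dark 3")
  graphics::plot(NA, xlim = range(binned$bin_center),
                 ylim = c(0, max(binned$mean + binned$sd, 1.1)),
                 xlab = "time (s)", ylab = "normalized puncta", ...)
  for (i in seq_along(conds)) {
    b <- binned[binned$condition == conds[i], ]
    graphics::lines(b$bin_center, b$mean, col = cols[i], lwd = 2)
    graphics::arrows(b$bin_center, b$mean - b$sd, b$bin_center,
                     b$mean + b$sd, angle = 90, code = 3, length = 0.02,
                     col = cols[i])
  }
  graphics::abline(v = drugTime, lty = 2)
  graphics::legend("bottomleft", legend = conds, col = cols[seq_along(conds)],
                   lwd = 2, bty = "n")
  invisible(NULL)
}
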