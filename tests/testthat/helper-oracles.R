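# Independent oracles used to validate the implementation paths.

# Brute-force scale-normalised LoG response: the kernel is sampled from
# the analytic formula and applied by direct per-pixel correlation.
# Only interior pixels (margin >= kernel radius) are computed; the rest
# are NA.
logOracle <- function(image, sigma) {
  r <- ceiling(4 * sigma)
  xs <- -r:r
  kern <- matrix(NA_real_, length(xs), length(xs))
  for (i in seq_along(xs)) {
    for (j in seq_along(xs)) {
      r2 <- xs[i]^2 + xs[j]^2
      kern[i, j] <- -sigma^2 * (r2 - 2 * sigma^2) / sigma^4 *
        exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)
    }
  }
  kern <- kern - mean(kern)
  out <- matrix(NA_real_, nrow(image), ncol(image))
  for (i in (r + 1):(nrow(image) - r)) {
    for (j in (r + 1):(ncol(image) - r)) {
      out[i, j] <- sum(kern * image[(i - r):(i + r), (j - r):(j + r)])
    }
  }
  out
}

# Exact two-sided Mann-Whitney p by explicit enumeration of every
# choose(n1 + n2, n1) assignment of the pooled values to group a.
mwEnumerate <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  uOf <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  uObs <- uOf(a, b)
  splits <- utils::combn(n, n1)
  us <- apply(splits, 2, function(idx) uOf(pooled[idx], pooled[-idx]))
  pLe <- mean(us <= uObs + 1e-9)
  pGe <- mean(us >= uObs - 1e-9)
  list(U = uObs, p = min(1, 2 * min(pLe, pGe)))
}

# Render a Gaussian spot onto an image (independent of the generator's
# internal renderer).
gaussSpot <- function(image, row, col, amp, sigma) {
  rows <- matrix(rep(seq_len(nrow(image)), ncol(image)), nrow(image))
  cols <- matrix(rep(seq_len(ncol(image)), each = nrow(image)), nrow(image))
  image + amp * exp(-((rows - row)^2 + (cols - col)^2) / (2 * sigma^2))
}
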