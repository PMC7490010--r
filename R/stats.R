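#' Welch's two-sample t-test
#'
#' Independent-samples t-test without the equal-variance assumption:
#' `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)` with real-valued
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from
#' the t distribution. The sign of `t` follows `mean(a) - mean(b)`.
#'
#' @param a,b numeric samples, each of size >= 2 with finite values.
#' @return A list with `t`, `df`, `p`, `meanA`, `meanB`, `nA`, `nB`.
#' @examples
#' welchT(c(1, 2, 3), c(2, 3, 4))
#' @export
welchT <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs size >= 2")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("samples must be finite")
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na
  vb <- stats::var(b) / nb
  se2 <- va + vb
  if (se2 == 0) {
    if (mean(a) == mean(b))
      stop("both samples have zero variance and equal means; t is undefined")
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = na + nb - 2, p = 0,
                meanA = mean(a), meanB = mean(b), nA = na, nB = nb))
  }
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df),
       meanA = mean(a), meanB = mean(b), nA = na, nB = nb)
}

## Null distribution of the Mann-Whitney U statistic: counts[u + 1] is the
## number of the choose(n + m, n) group assignments with U = u, by the
## standard recursion c(u; n, m) = c(u - m; n - 1, m) + c(u; n, m - 1).
#' @noRd
uCounts <- local({
  cache <- new.env(parent = emptyenv())
  function(n, m) {
    key <- paste(n, m)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- if (n == 0 || m == 0) 1 else {
      a <- uCounts(n - 1, m)  # last pooled value in sample a: adds U = m
      b <- uCounts(n, m - 1)
      out <- numeric(n * m + 1)
      out[seq_along(a) + m] <- a
      out[seq_along(b)] <- out[seq_along(b)] + b
      out
    }
    cache[[key]] <- val
    val
  }
})

#' Mann-Whitney U test
#'
#' Rank-sum test for two independent samples. `U` is the number of pairs
#' `(x in a, y in b)` with `x > y` (ties counting one half), computed via
#' midranks. When both samples are at most `exactMax` and no tied value
#' spans the two groups, the two-sided p-value is exact, from the full
#' null distribution of U over all group assignments (computed by the
#' standard counting recursion); otherwise the normal approximation with
#' tie correction and continuity correction is used. The exact two-sided
#' p is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param a,b non-empty numeric samples.
#' @param exactMax largest per-sample size for which the exact null
#'   distribution is used.
#' @return A list with `U`, `p`, `method` (`"exact"` or
#'   `"normal_approx_tie_corrected"`), `nA`, `nB`.
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mannWhitney <- function(a, b, exactMax = 20) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("samples must be finite")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  crossTies <- length(intersect(a, b)) > 0
  if (n1 <= exactMax && n2 <= exactMax && !crossTies) {
    f <- uCounts(n1, n2)
    total <- sum(f)
    u <- round(U)
    pLe <- sum(f[seq_len(u + 1)]) / total
    pGe <- sum(f[(u + 1):length(f)]) / total
    p <- min(1, 2 * min(pLe, pGe))
    method <- "exact"
  } else {
    N <- n1 + n2
    tie <- table(pooled)
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 / 12 *
                  ((N + 1) - sum(tie^3 - tie) / (N * (N - 1))))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- U - mu
      z <- (z - sign(z) * 0.5) / sigma  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx_tie_corrected"
  }
  list(U = U, p = p, method = method, nA = n1, nB = n2)
}

#' Welch comparisons of replicate decay times between two conditions
#'
#' For every decay fraction present in both summary tables, runs
#' [welchT()] on the replicate decay times of condition A versus
#' condition B. Fractions with "not reached" replicates are compared on
#' the reached replicates only and flagged.
#'
#' @param summaryA,summaryB `data.frame`s of replicate summaries (rows
#'   from [summarizeReplicate()], several replicates bound together).
#' @return A `data.frame` with one row per fraction: `fraction`,
#'   `meanA`, `meanB`, `nA`, `nB`, `t`, `df`, `p`, `nNotReached`.
#' @export
compareDecayTimes <- function(summaryA, summaryB) {
  fr <- intersect(unique(summaryA$fraction), unique(summaryB$fraction))
  if (!length(fr)) stop("no common fractions to compare")
  out <- lapply(sort(fr, decreasing = TRUE), function(f) {
    xa <- summaryA$time[summaryA$fraction == f]
    xb <- summaryB$time[summaryB$fraction == f]
    nNA <- sum(is.na(xa)) + sum(is.na(xb))
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2) {
      data.frame(fraction = f, meanA = mean(xa), meanB = mean(xb),
                 nA = length(xa), nB = length(xb), t = NA_real_,
                 df = NA_real_, p = NA_real_, nNotReached = nNA)
    } else {
      w <- welchT(xa, xb)
      data.frame(fraction = f, meanA = w$meanA, meanB = w$meanB,
                 nA = w$nA, nB = w$nB, t = w$t, df = w$df, p = w$p,
                 nNotReached = nNA)
    }
  })
  do.call(rbind, out)
}
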