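#' Sample per-punctum disappearance times
#'
#' Draws the times (seconds from trial start) at which individual puncta
#' disappear under the chosen kinetic regime. `vehicle` puncta never
#' disappear (`Inf`); `instant` puncta all disappear exactly at the drug
#' time; `exponential` puncta wait an i.i.d. Exp(`kRel`) time after drug
#' addition (no lag phase); `two_stage` puncta wait an Exp(`kBind`)
#' binding delay followed by an Exp(`kRel`) release time (hypoexponential,
#' producing an initial shoulder in the survival curve).
#'
#' @param kin a [ReleaseKinetics] object.
#' @param n number of puncta.
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used (so callers can manage reproducibility themselves).
#' @return Numeric vector of length `n` of disappearance times (s),
#'   possibly `Inf`.
#' @examples
#' sampleReleaseTimes(ReleaseKinetics("instant"), 3, seed = 1)
#' @export
sampleReleaseTimes <- function(kin, n, seed = NULL) {
  stopifnot(is(kin, "ReleaseKinetics"))
  validObject(kin)
  if (n < 0) stop("n must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  switch(kin@mode,
    vehicle = rep(Inf, n),
    instant = rep(kin@drugTime, n),
    exponential = kin@drugTime + stats::rexp(n, rate = kin@kRel),
    two_stage = kin@drugTime + stats::rexp(n, rate = kin@kBind) +
      stats::rexp(n, rate = kin@kRel),
    stop("unknown mode: ", kin@mode)
  )
}

#' Draw an irregular timestamp sequence
#'
#' Frame intervals are truncated-normal: drawn from
#' N(`intervalMean`, `intervalSd`) and re-drawn while outside
#' `[intervalMin, intervalMax]`. The sequence starts at 0 and covers
#' `[0, trialDuration]`.
#'
#' @param acq an [AcquisitionParams] object.
#' @param seed optional integer seed (`NULL` = current RNG stream).
#' @return Strictly increasing numeric vector of acquisition times (s).
#' @export
simulateTimestamps <- function(acq, seed = NULL) {
  stopifnot(is(acq, "AcquisitionParams"))
  validObject(acq)
  if (!is.null(seed)) set.seed(seed)
  rTrunc <- function(m) {
    out <- numeric(0)
    while (length(out) < m) {
      x <- stats::rnorm(m, acq@intervalMean, acq@intervalSd)
      out <- c(out, x[x >= acq@intervalMin & x <= acq@intervalMax])
    }
    out[seq_len(m)]
  }
  nGuess <- ceiling(acq@trialDuration / acq@intervalMin) + 8L
  ts <- cumsum(c(0, rTrunc(nGuess)))
  ts[ts <= acq@trialDuration]
}

## Elliptical cell layout: cells on a near-square grid with jittered
## centres; each cell holds a concentric punctum-free nucleus.
## Returns label matrices for cells and nuclei (0 = outside).
#' @noRd
layoutCells <- function(nCells, shape, jitter = 0.04) {
  nr <- max(1L, floor(sqrt(nCells)))
  nc <- ceiling(nCells / nr)
  bh <- shape[1] / nr
  bw <- shape[2] / nc
  rows <- matrix(rep(seq_len(shape[1]), shape[2]), shape[1])
  cols <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1])
  cells <- matrix(0L, shape[1], shape[2])
  nuclei <- matrix(0L, shape[1], shape[2])
  for (k in seq_len(nCells)) {
    gi <- (k - 1) %/% nc
    gj <- (k - 1) %% nc
    cy <- (gi + 0.5) * bh + stats::runif(1, -jitter, jitter) * bh
    cx <- (gj + 0.5) * bw + stats::runif(1, -jitter, jitter) * bw
    a <- 0.38 * bh * stats::runif(1, 0.9, 1.0)  # semi-axis, rows
    b <- 0.38 * bw * stats::runif(1, 0.9, 1.0)  # semi-axis, cols
    inCell <- ((rows - cy) / a)^2 + ((cols - cx) / b)^2 <= 1
    cells[inCell] <- k
    inNuc <- ((rows - cy) / (0.45 * a))^2 + ((cols - cx) / (0.45 * b))^2 <= 1
    nuclei[inNuc] <- k
  }
  list(cells = cells, nuclei = nuclei)
}

## Place n puncta uniformly in the allowed pixel set with a minimum
## pairwise separation (px); bounded retries, else error.
#' @noRd
placePuncta <- function(allowedIdx, shape, n, minSepPx, maxTries = 500L) {
  if (n == 0) return(cbind(row = numeric(0), col = numeric(0)))
  pr <- ((allowedIdx - 1L) %% shape[1]) + 1L
  pc <- ((allowedIdx - 1L) %/% shape[1]) + 1L
  ry <- rc <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (tryi in seq_len(maxTries)) {
      j <- sample.int(length(allowedIdx), 1L)
      y <- pr[j] + stats::runif(1, -0.5, 0.5)
      x <- pc[j] + stats::runif(1, -0.5, 0.5)
      if (i == 1L ||
          all((ry[seq_len(i - 1)] - y)^2 + (rc[seq_len(i - 1)] - x)^2 >=
              minSepPx^2)) {
        ry[i] <- y; rc[i] <- x
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place punctum ", i,
           " inside the cell mask after ", maxTries, " retries; ",
           "reduce punctaPerCell or spotMinSep")
  }
  cbind(row = ry, col = rc)
}

## Additively render a Gaussian spot (peak `amp`, sd `sigma` px) at a
## sub-pixel centre onto `img`, over a 4-sigma square patch.
#' @noRd
renderSpot <- function(img, row, col, amp, sigma) {
  r <- ceiling(4 * sigma)
  i0 <- max(1L, floor(row) - r); i1 <- min(nrow(img), floor(row) + r + 1L)
  j0 <- max(1L, floor(col) - r); j1 <- min(ncol(img), floor(col) + r + 1L)
  if (i0 > i1 || j0 > j1) return(img)
  gy <- exp(-((i0:i1) - row)^2 / (2 * sigma^2))
  gx <- exp(-((j0:j1) - col)^2 / (2 * sigma^2))
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amp * outer(gy, gx)
  img
}

## Poisson shot noise (with gain) plus Gaussian read noise, quantised to
## a non-negative 16-bit-like integer scale.
#' @noRd
cameraNoise <- function(signal, gain, readSd) {
  lam <- pmax(signal, 0) / gain
  x <- stats::rpois(length(lam), lam) * gain
  if (readSd > 0) x <- x + stats::rnorm(length(x), 0, readSd)
  matrix(pmin(pmax(round(x), 0), 65535), nrow(signal), ncol(signal))
}

#' Simulate a drug-addition time-lapse movie
#'
#' Renders a multi-frame field of elliptical cells (with punctum-free
#' nuclei) containing diffraction-limited reporter puncta that disappear
#' according to the release kinetics, then applies photobleaching and
#' Poisson-Gaussian camera noise. Frame times follow the irregular
#' acquisition clock of [simulateTimestamps()]. Puncta are placed in the
#' cytoplasm (cell minus nucleus) with a minimum pairwise separation so
#' that they are individually resolvable; a punctum is rendered in a frame
#' at time `t` while `t < ` its disappearance time (for multi-chain
#' puncta, while the surviving intensity fraction is at least
#' `detectFraction`, with amplitude proportional to surviving chains).
#'
#' @param kin a [ReleaseKinetics] object.
#' @param acq an [AcquisitionParams] object.
#' @param seed integer seed; the whole simulation is reproducible for a
#'   fixed seed.
#' @param condition,replicateId labels stored in the [MovieStack].
#' @return A list with elements `movie` ([MovieStack]), `cells` and
#'   `nuclei` (integer label matrices), and `truth` ([GroundTruth]).
#' @examples
#' sim <- simulateMovie(ReleaseKinetics("instant"),
#'   AcquisitionParams(imageShape = c(64, 64), cellsPerField = 2,
#'                     punctaPerCell = 4, trialDuration = 90),
#'   seed = 1)
#' sim$movie
#' @export
simulateMovie <- function(kin, acq, seed, condition = kin@mode,
                          replicateId = "r1") {
  stopifnot(is(kin, "ReleaseKinetics"), is(acq, "AcquisitionParams"))
  validObject(kin); validObject(acq)
  set.seed(as.integer(seed))
  shape <- as.integer(acq@imageShape)
  ts <- simulateTimestamps(acq)
  lay <- layoutCells(as.integer(acq@cellsPerField), shape)
  cyto <- lay$cells > 0 & lay$nuclei == 0
  psfPx <- acq@psfSigma / acq@pixelSize
  minSepPx <- acq@spotMinSep / acq@pixelSize

  nCells <- as.integer(acq@cellsPerField)
  nPer <- as.integer(acq@punctaPerCell)
  m <- as.integer(kin@chainsPerPunctum)

  punctaList <- vector("list", nCells)
  for (cid in seq_len(nCells)) {
    allowed <- which(lay$cells == cid & lay$nuclei == 0)
    if (!length(allowed)) stop("cell ", cid, " has an empty cytoplasm mask")
    pos <- placePuncta(allowed, shape, nPer, minSepPx)
    punctaList[[cid]] <- data.frame(cell = cid, row = pos[, "row"],
                                    col = pos[, "col"])
  }
  puncta <- do.call(rbind, punctaList)
  nP <- nrow(puncta)

  ## Per-chain release times; per-punctum amplitude fraction over time.
  chainTimes <- matrix(sampleReleaseTimes(kin, nP * m), nrow = nP)
  if (m == 1L) {
    puncta$tDisappear <- chainTimes[, 1]
  } else {
    ## punctum visible while surviving/m >= detectFraction, i.e. until the
    ## (m - ceiling(detectFraction*m) + 1)-th chain release
    need <- ceiling(kin@detectFraction * m - 1e-9)
    ord <- t(apply(chainTimes, 1, sort))
    puncta$tDisappear <- ord[, m - need + 1L]
  }

  frameMats <- vector("list", length(ts))
  nucFill <- 0.6  # nuclei rendered dimmer than cytoplasm, punctum-free
  base <- matrix(acq@backgroundLevel, shape[1], shape[2])
  base[lay$cells > 0] <- acq@backgroundLevel + nucFill * acq@cytoLevel
  base[cyto] <- acq@backgroundLevel + acq@cytoLevel

  ## reporter fluorescence is conserved: intensity of released puncta
  ## returns to the diffuse cytoplasmic pool of the cell
  cytoIdx <- lapply(seq_len(nCells), function(cid)
    which(lay$cells == cid & lay$nuclei == 0))
  cytoArea <- lengths(cytoIdx)
  punctumIntegral <- acq@spotAmplitude * 2 * pi * psfPx^2

  countRows <- vector("list", length(ts))
  for (f in seq_along(ts)) {
    t <- ts[f]
    img <- base
    if (m == 1L) {
      vis <- t < puncta$tDisappear
      ampFrac <- as.numeric(vis)
    } else {
      surv <- rowSums(chainTimes > t) / m
      vis <- surv >= kin@detectFraction
      ampFrac <- surv * vis
    }
    released <- punctumIntegral *
      tapply(1 - ampFrac, factor(puncta$cell, levels = seq_len(nCells)), sum)
    for (cid in seq_len(nCells))
      img[cytoIdx[[cid]]] <- img[cytoIdx[[cid]]] +
        released[cid] / cytoArea[cid]
    for (i in which(vis)) {
      img <- renderSpot(img, puncta$row[i], puncta$col[i],
                        acq@spotAmplitude * ampFrac[i], psfPx)
    }
    img <- img * exp(-acq@bleachRate * t)
    frameMats[[f]] <- cameraNoise(img, acq@poissonGain, acq@readNoiseSd)
    countRows[[f]] <- data.frame(cell = seq_len(nCells), frame = f, t = t,
      count = as.integer(tabulate(puncta$cell[vis], nbins = nCells)))
  }

  movie <- MovieStack(frames = frameMats, timestamps = ts,
                      pixelSize = acq@pixelSize, drugTime = kin@drugTime,
                      condition = condition, replicateId = replicateId)
  truth <- GroundTruth(
    puncta = data.frame(cell = puncta$cell, x = puncta$col - 1,
                        y = puncta$row - 1, tDisappear = puncta$tDisappear),
    counts = do.call(rbind, countRows),
    background = acq@backgroundLevel * exp(-acq@bleachRate * ts))
  list(movie = movie, cells = lay$cells, nuclei = lay$nuclei, truth = truth)
}

#' Simulate a multi-condition still-image experiment
#'
#' Renders one image per condition: elliptical cells filled at the
#' condition's mean diffuse intensity, each holding a Poisson-distributed
#' number of diffraction-limited puncta around the condition mean
#' (emulating IF / proximity-ligation puncta). Camera noise as in
#' [simulateMovie()].
#'
#' @param params a [StillImageParams] object.
#' @param seed integer seed.
#' @return A list with one element per condition, each a list of `image`
#'   (matrix), `cells` / `nuclei` (label matrices) and `truth`
#'   (`data.frame` with per-cell true puncta counts and fill intensities).
#' @export
simulateStillExperiment <- function(params, seed) {
  stopifnot(is(params, "StillImageParams"))
  validObject(params)
  set.seed(as.integer(seed))
  shape <- as.integer(params@imageShape)
  psfPx <- params@psfSigma / params@pixelSize
  minSepPx <- params@spotMinSep / params@pixelSize
  nCells <- as.integer(params@cellsPerCondition)

  out <- list()
  for (ci in seq_len(nrow(params@conditions))) {
    cond <- params@conditions[ci, ]
    lay <- layoutCells(nCells, shape)
    img <- matrix(params@backgroundLevel, shape[1], shape[2])
    img[lay$nuclei > 0] <- params@backgroundLevel + 0.6 * cond$cellIntensity
    img[lay$cells > 0 & lay$nuclei == 0] <-
      params@backgroundLevel + cond$cellIntensity
    truthRows <- vector("list", nCells)
    for (cid in seq_len(nCells)) {
      n <- stats::rpois(1, cond$punctaPerCell)
      allowed <- which(lay$cells == cid & lay$nuclei == 0)
      pos <- placePuncta(allowed, shape, n, minSepPx)
      if (n > 0) {
        for (i in seq_len(n))
          img <- renderSpot(img, pos[i, "row"], pos[i, "col"],
                            params@spotAmplitude, psfPx)
      }
      truthRows[[cid]] <- data.frame(condition = cond$label, cell = cid,
                                     count = n,
                                     cellIntensity = cond$cellIntensity)
    }
    out[[cond$label]] <- list(
      image = cameraNoise(img, params@poissonGain, params@readNoiseSd),
      cells = lay$cells, nuclei = lay$nuclei,
      truth = do.call(rbind, truthRows))
  }
  out
}
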