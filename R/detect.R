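## Reflective (half-sample symmetric) padding by r pixels on every side.
#' @noRd
padReflect <- function(img, r) {
  n <- nrow(img); m <- ncol(img)
  if (r >= n || r >= m)
    stop("padding radius ", r, " too large for a ", n, "x", m, " image")
  ri <- c(r:1, 1:n, n:(n - r + 1))
  ci <- c(r:1, 1:m, m:(m - r + 1))
  img[ri, ci]
}

## Sampled scale-normalised LoG kernel, sign-flipped so bright blobs give
## positive peaks: K = -sigma^2 * Laplacian(G_sigma), sampled on a
## (2r+1)^2 grid with r = ceiling(4 sigma), then made zero-sum so the
## response to a constant image is exactly zero.
#' @noRd
logKernel <- function(sigmaPx) {
  r <- ceiling(4 * sigmaPx)
  xs <- -r:r
  s2 <- sigmaPx^2
  k <- outer(xs, xs, function(x, y) {
    r2 <- x^2 + y^2
    -(r2 - 2 * s2) / (2 * pi * s2^2) * exp(-r2 / (2 * s2))
  })
  k - mean(k)
}

#' Scale-normalised Laplacian-of-Gaussian response
#'
#' Filters a 2-D image with the negated, scale-normalised Laplacian of a
#' Gaussian of standard deviation `sigmaPx` pixels, so that bright blobs
#' of matching scale produce positive peaks. The kernel is sampled
#' analytically out to 4 sigma, made zero-sum (zero response to constant
#' images) and applied with reflective boundary padding. The peak value of
#' this response is the spot "quality" used for thresholding.
#'
#' @param image numeric matrix with finite entries.
#' @param sigmaPx Gaussian scale in pixels (`> 0`).
#' @return A matrix of the same dimension as `image`.
#' @examples
#' img <- matrix(0, 21, 21); img[11, 11] <- 1
#' r <- logResponse(img, 1.2)
#' which(r == max(r), arr.ind = TRUE)
#' @export
logResponse <- function(image, sigmaPx) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  if (length(sigmaPx) != 1L || !is.finite(sigmaPx) || sigmaPx <= 0)
    stop("sigmaPx must be a single positive number")
  kern <- logKernel(sigmaPx)
  r <- (nrow(kern) - 1L) / 2L
  p <- padReflect(image, r)
  n <- nrow(image); m <- ncol(image)
  out <- matrix(0, n, m)
  for (i in seq_len(nrow(kern))) {
    for (j in seq_len(ncol(kern))) {
      k <- kern[i, j]
      out <- out + k * p[i:(i + n - 1L), j:(j + m - 1L)]
    }
  }
  out
}

## 8-neighbour local maxima (non-strict, plateaus resolved later by the
## lexicographic tie-break in proximity suppression); maxima within
## `border` pixels of the edge are discarded.
#' @noRd
localMaxima <- function(resp, border) {
  n <- nrow(resp); m <- ncol(resp)
  p <- matrix(-Inf, n + 2L, m + 2L)
  p[2:(n + 1), 2:(m + 1)] <- resp
  ok <- matrix(TRUE, n, m)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ok & (resp >= p[(2 + di):(n + 1 + di), (2 + dj):(m + 1 + dj)])
  }
  if (border >= 1) {
    b <- seq_len(min(border, n)); ok[b, ] <- FALSE; ok[n + 1 - b, ] <- FALSE
    b <- seq_len(min(border, m)); ok[, b] <- FALSE; ok[, m + 1 - b] <- FALSE
  }
  which(ok, arr.ind = TRUE)
}

#' Per-spot contrast and total intensity
#'
#' Contrast is `(mean(disc) - mean(annulus)) / (mean(disc) + mean(annulus))`
#' where the disc has radius `radiusPx` around `center` and the annulus
#' extends one disc-width further out; total intensity is the sum of raw
#' disc pixels. Regions falling outside the image are clipped (flagged in
#' the result).
#'
#' @param image numeric matrix (raw intensities).
#' @param center numeric `c(row, col)` in 1-based pixel coordinates.
#' @param radiusPx disc radius in pixels (`> 0`).
#' @return A list with `contrast`, `totalIntensity` and `clipped`.
#' @export
spotFeatures <- function(image, center, radiusPx) {
  if (radiusPx <= 0) stop("radiusPx must be > 0")
  n <- nrow(image); m <- ncol(image)
  r2out <- (2 * radiusPx)^2
  i0 <- floor(center[1] - 2 * radiusPx); i1 <- ceiling(center[1] + 2 * radiusPx)
  j0 <- floor(center[2] - 2 * radiusPx); j1 <- ceiling(center[2] + 2 * radiusPx)
  clipped <- i0 < 1 || j0 < 1 || i1 > n || j1 > m
  ii <- max(1L, i0):min(n, i1)
  jj <- max(1L, j0):min(m, j1)
  d2 <- outer((ii - center[1])^2, (jj - center[2])^2, "+")
  patch <- image[ii, jj, drop = FALSE]
  inDisc <- d2 <= radiusPx^2
  inAnn <- d2 > radiusPx^2 & d2 <= r2out
  if (!any(inDisc)) stop("zero-size disc at the given radius")
  mDisc <- mean(patch[inDisc])
  mAnn <- if (any(inAnn)) mean(patch[inAnn]) else 0
  denom <- mDisc + mAnn
  contrast <- if (denom == 0) 0 else (mDisc - mAnn) / denom
  list(contrast = contrast, totalIntensity = sum(patch[inDisc]),
       clipped = clipped)
}

#' Detect diffraction-limited spots in one frame
#'
#' Laplacian-of-Gaussian blob detection at the scale implied by the
#' estimated blob diameter (`sigma = (diameter/2) / sqrt(2)` converted to
#' pixels, the standard 2-D relation between blob radius and LoG scale).
#' Local maxima of the scale-normalised response are thresholded on
#' quality, maxima closer than one blob diameter keep only the
#' highest-quality one (ties broken toward the smaller (row, col) index),
#' per-spot contrast and total intensity are measured on the raw image,
#' and spots whose centre falls in the exclusion mask are dropped.
#' Maxima within `ceiling(sigma)` pixels of the border are discarded.
#'
#' @param image numeric matrix (one frame, raw intensities).
#' @param t frame timestamp (s), copied into the output.
#' @param params a [DetectionParams] object.
#' @param frame integer frame index, copied into the output.
#' @return A `data.frame` with columns `frame`, `t_s`, `x_px`, `y_px`
#'   (0-based pixel coordinates, x = column), `x_um`, `y_um`, `quality`,
#'   `contrast`, `total_intensity`, `radius_um`, `cell_id` (`NA` until
#'   assignment).
#' @export
detectSpots <- function(image, t = 0, params = DetectionParams(),
                        frame = 1L) {
  stopifnot(is(params, "DetectionParams"))
  validObject(params)
  radiusPx <- (params@blobDiameter / 2) / params@pixelSize
  if (radiusPx < 1)
    stop("blob radius is ", signif(radiusPx, 3), " px at pixelSize ",
         params@pixelSize, " um/px; scales below 1 px are undetectable")
  sigmaPx <- radiusPx / sqrt(2)
  resp <- logResponse(image, sigmaPx)
  cand <- localMaxima(resp, border = ceiling(sigmaPx))
  if (nrow(cand)) {
    q <- resp[cand]
    keepQ <- q >= params@qualityThreshold
    cand <- cand[keepQ, , drop = FALSE]
    q <- q[keepQ]
  } else q <- numeric(0)

  ## proximity suppression: greedy by quality (desc), lexicographic
  ## (row, col) tie-break; minimum centre distance = one blob diameter
  if (nrow(cand) > 1) {
    minD2 <- (params@blobDiameter / params@pixelSize)^2
    o <- order(-q, cand[, 1], cand[, 2])
    keep <- integer(0)
    for (i in o) {
      if (!length(keep) ||
          all((cand[keep, 1] - cand[i, 1])^2 +
              (cand[keep, 2] - cand[i, 2])^2 >= minD2))
        keep <- c(keep, i)
    }
    keep <- sort(keep)
    cand <- cand[keep, , drop = FALSE]
    q <- q[keep]
  }

  if (!is.null(params@exclusionMask) && nrow(cand)) {
    excl <- params@exclusionMask[cand] > 0
    cand <- cand[!excl, , drop = FALSE]
    q <- q[!excl]
  }

  n <- nrow(cand)
  feats <- lapply(seq_len(n), function(i)
    spotFeatures(image, c(cand[i, 1], cand[i, 2]), radiusPx))
  spots <- data.frame(
    frame = rep(as.integer(frame), n),
    t_s = rep(as.numeric(t), n),
    x_px = if (n) cand[, 2] - 1 else numeric(0),
    y_px = if (n) cand[, 1] - 1 else numeric(0),
    x_um = if (n) (cand[, 2] - 1) * params@pixelSize else numeric(0),
    y_um = if (n) (cand[, 1] - 1) * params@pixelSize else numeric(0),
    quality = q,
    contrast = vapply(feats, `[[`, numeric(1), "contrast"),
    total_intensity = vapply(feats, `[[`, numeric(1), "totalIntensity"),
    radius_um = rep(params@blobDiameter / 2, n),
    cell_id = rep(NA_integer_, n))
  filterSpots(spots, params)
}

#' Filter a spot table on configured minima and exclusion mask
#'
#' Removes spots failing any configured minimum (`qualityThreshold`,
#' `contrastMin`, `totalIntensityMin`) or whose centre pixel lies in the
#' exclusion mask. Order-preserving and idempotent.
#'
#' @param spots spot `data.frame` as returned by [detectSpots()].
#' @param params a [DetectionParams] object.
#' @return The filtered spot `data.frame`.
#' @export
filterSpots <- function(spots, params) {
  stopifnot(is(params, "DetectionParams"))
  if (!nrow(spots)) return(spots)
  keep <- spots$quality >= params@qualityThreshold
  if (!is.null(params@contrastMin))
    keep <- keep & spots$contrast >= params@contrastMin
  if (!is.null(params@totalIntensityMin))
    keep <- keep & spots$total_intensity >= params@totalIntensityMin
  if (!is.null(params@exclusionMask)) {
    idx <- cbind(round(spots$y_px) + 1L, round(spots$x_px) + 1L)
    keep <- keep & !(params@exclusionMask[idx] > 0)
  }
  out <- spots[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect spots in every frame of a movie
#'
#' Runs [detectSpots()] on each frame of a [MovieStack] and binds the
#' per-frame tables.
#'
#' @param movie a [MovieStack].
#' @param params a [DetectionParams]; its `pixelSize` is overridden by the
#'   movie's.
#' @return One spot `data.frame` (see [detectSpots()]) covering all frames.
#' @export
detectMovie <- function(movie, params = DetectionParams()) {
  stopifnot(is(movie, "MovieStack"))
  params@pixelSize <- pixelSize(movie)
  validObject(params)
  ts <- timestamps(movie)
  out <- lapply(seq_len(nFrames(movie)), function(f)
    detectSpots(frames(movie)[[f]], t = ts[f], params = params, frame = f))
  do.call(rbind, out)
}
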