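#' Assign detected spots to cells
#'
#' Sets each spot's `cell_id` from the label value at its centre pixel
#' (0 outside any cell becomes `NA`). Spots inside a nucleus are given
#' `NA` when a nucleus label matrix is supplied.
#'
#' @param spots spot `data.frame` (see [detectSpots()]).
#' @param cells integer label matrix (0 = outside).
#' @param nuclei optional nucleus label matrix.
#' @return The spot `data.frame` with `cell_id` filled in.
#' @export
assignSpotsToCells <- function(spots, cells, nuclei = NULL) {
  if (!nrow(spots)) return(spots)
  idx <- cbind(round(spots$y_px) + 1L, round(spots$x_px) + 1L)
  id <- cells[idx]
  if (!is.null(nuclei)) id[nuclei[idx] > 0] <- 0L
  spots$cell_id <- ifelse(id > 0, id, NA_integer_)
  spots
}

#' Count puncta inside one cell
#'
#' The number of spots whose centre pixel lies inside the cell mask and
#' outside the nucleus mask (when provided). Membership is decided by the
#' centre pixel, so a spot exactly on a boundary pixel is counted.
#'
#' @param spots spot `data.frame` (any set of rows with `x_px`, `y_px`).
#' @param cellMask logical (or 0/1) matrix for the cell.
#' @param nucleusMask optional logical matrix for the nucleus.
#' @return Integer count.
#' @export
countPunctaInCell <- function(spots, cellMask, nucleusMask = NULL) {
  if (!nrow(spots)) return(0L)
  idx <- cbind(round(spots$y_px) + 1L, round(spots$x_px) + 1L)
  inside <- cellMask[idx] > 0
  if (!is.null(nucleusMask)) inside <- inside & !(nucleusMask[idx] > 0)
  sum(inside)
}

#' Build per-cell count and cytoplasmic-intensity time series
#'
#' For every cell in the label matrix: per-frame puncta counts (spots
#' whose centre lies in the cell and outside its nucleus) and the mean
#' raw reporter intensity over the cytoplasm (cell mask minus nucleus
#' mask when available, else the whole cell mask), aligned to the movie's
#' timestamps.
#'
#' @param movie a [MovieStack].
#' @param cells integer label matrix.
#' @param spots spot `data.frame` covering all frames (`frame` column
#'   indexes the movie's frames).
#' @param nuclei optional nucleus label matrix.
#' @return A `data.frame` with columns `cell`, `frame`, `t`, `count`,
#'   `cytoMean`.
#' @export
buildCellSeries <- function(movie, cells, spots, nuclei = NULL) {
  stopifnot(is(movie, "MovieStack"))
  ts <- timestamps(movie)
  nF <- nFrames(movie)
  if (nrow(spots) && any(spots$frame < 1 | spots$frame > nF))
    stop("spot table references frames outside the movie (1..", nF, ")")
  ids <- sort(setdiff(unique(as.vector(cells)), 0))
  if (!length(ids)) stop("label matrix contains no cells")
  cytoIdx <- lapply(ids, function(cid) {
    idx <- which(cells == cid & (if (is.null(nuclei)) TRUE else nuclei == 0))
    if (!length(idx)) stop("cell ", cid, " has an empty mask")
    idx
  })
  spots <- assignSpotsToCells(spots, cells, nuclei)
  rows <- vector("list", length(ids) * nF)
  k <- 0L
  for (f in seq_len(nF)) {
    fr <- frames(movie)[[f]]
    sf <- spots[spots$frame == f & !is.na(spots$cell_id), , drop = FALSE]
    cnt <- tabulate(match(sf$cell_id, ids), nbins = length(ids))
    for (ci in seq_along(ids)) {
      k <- k + 1L
      rows[[k]] <- data.frame(cell = ids[ci], frame = f, t = ts[f],
                              count = cnt[ci],
                              cytoMean = mean(fr[cytoIdx[[ci]]]))
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$cell, out$frame), , drop = FALSE]
}

#' Photobleaching / focus quality control for one cell
#'
#' The cytoplasmic intensity trace is normalised to the mean of its first
#' 10 frames, smoothed with a centred rolling mean of window 10 (so
#' single-frame focus glitches do not discard cells), and the cell fails
#' when the smoothed trace drops below `1 - maxDecrease` (default: more
#' than a 10% decrease fails).
#'
#' @param cytoMean numeric vector of per-frame cytoplasmic intensities.
#' @param maxDecrease maximum tolerated fractional decrease.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
qcPhotobleach <- function(cytoMean, maxDecrease = 0.10) {
  if (length(cytoMean) < 10)
    stop("need at least 10 frames to form the QC baseline, got ",
         length(cytoMean))
  baseline <- mean(cytoMean[1:10])
  if (baseline <= 0) stop("non-positive QC baseline intensity")
  norm <- cytoMean / baseline
  smooth <- boxcarSmooth(norm, 10)
  min(smooth) >= 1 - maxDecrease
}

#' Per-cell mean intensities from a still image
#'
#' For each labelled cell: the mean raw intensity over its mask, and
#' optionally a puncta count from LoG detection restricted to the cell.
#'
#' @param image numeric matrix.
#' @param cells integer label matrix of the same dimension.
#' @param condition condition label attached to every record.
#' @param experiment experiment/replicate identifier.
#' @param modality modality label, e.g. `"IF"` or `"PLA"`.
#' @param detectParams optional [DetectionParams]; when supplied, puncta
#'   are detected once on the image and counted per cell.
#' @param nuclei optional nucleus label matrix (puncta inside are not
#'   counted).
#' @return A `data.frame` with columns `experiment`, `modality`,
#'   `condition`, `cell`, `mean_intensity`, `puncta_count` (`NA` without
#'   `detectParams`), `normalized_intensity` (`NA` until
#'   [normalizeByMaxCondition()]).
#' @export
quantifyStill <- function(image, cells, condition = "cond1",
                          experiment = "e1", modality = "IF",
                          detectParams = NULL, nuclei = NULL) {
  if (!identical(dim(image), dim(cells)))
    stop("image is ", paste(dim(image), collapse = "x"), " but labels are ",
         paste(dim(cells), collapse = "x"))
  ids <- sort(setdiff(unique(as.vector(cells)), 0))
  if (!length(ids)) stop("label matrix contains no cells")
  spots <- if (!is.null(detectParams))
    detectSpots(image, t = 0, params = detectParams) else NULL
  rows <- lapply(ids, function(cid) {
    mask <- cells == cid
    cnt <- if (is.null(spots)) NA_integer_ else
      countPunctaInCell(spots, mask,
                        if (is.null(nuclei)) NULL else nuclei == cid)
    data.frame(experiment = experiment, modality = modality,
               condition = condition, cell = cid,
               mean_intensity = mean(image[mask]),
               puncta_count = cnt,
               normalized_intensity = NA_real_)
  })
  do.call(rbind, rows)
}

#' Normalise per-cell intensities by the maximum condition mean
#'
#' Within each (experiment, modality) group, per-condition mean
#' intensities are computed and every cell's intensity is divided by the
#' largest condition mean. Normalisation is performed separately per
#' modality, so e.g. IF and PLA records sharing cells are each scaled
#' against their own modality's maximum. Individual cells may exceed 1
#' (only condition means are bounded by the maximum).
#'
#' @param records `data.frame` as produced by [quantifyStill()] (possibly
#'   several conditions / modalities bound together).
#' @return The records with `normalized_intensity` filled in.
#' @export
normalizeByMaxCondition <- function(records) {
  if (!nrow(records)) stop("no records to normalize")
  key <- interaction(records$experiment, records$modality, drop = TRUE)
  for (g in levels(key)) {
    sel <- key == g
    condMeans <- tapply(records$mean_intensity[sel], records$condition[sel],
                        mean)
    mx <- max(condMeans)
    if (!is.finite(mx) || mx <= 0)
      stop("maximum condition mean is not positive in group ", g)
    records$normalized_intensity[sel] <- records$mean_intensity[sel] / mx
  }
  records
}
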