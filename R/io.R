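#' Write a movie as multi-page TIFF plus JSON sidecar
#'
#' Frames are written as 16-bit grayscale TIFF pages; timestamps, pixel
#' size, drug time, condition and replicate id go to a JSON sidecar (a
#' portable alternative to writer-specific TIFF tag sets). Intensities
#' must lie in `[0, 65535]`; they are stored as integers, so a movie from
#' [simulateMovie()] round-trips bit-exactly.
#'
#' @param movie a [MovieStack].
#' @param tiffPath output TIFF path.
#' @param sidecarPath output JSON path; default replaces the TIFF
#'   extension with `.json`.
#' @return Invisibly, `tiffPath`.
#' @export
writeMovie <- function(movie, tiffPath,
                       sidecarPath = sub("\\.tiff?$", ".json", tiffPath)) {
  stopifnot(is(movie, "MovieStack"))
  pages <- lapply(frames(movie), function(f) {
    if (any(f < 0 | f > 65535)) stop("frame intensities outside [0, 65535]")
    round(f) / 65535
  })
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 16L)
  meta <- list(timestamps_s = timestamps(movie),
               pixel_size_um = pixelSize(movie),
               drug_time_s = drugTime(movie),
               condition = movie@condition,
               replicate_id = movie@replicateId)
  jsonlite::write_json(meta, sidecarPath, auto_unbox = TRUE, digits = NA)
  invisible(tiffPath)
}

#' Read a movie from TIFF plus JSON sidecar
#'
#' @param tiffPath multi-page TIFF path.
#' @param sidecarPath JSON sidecar path (see [writeMovie()]).
#' @return A [MovieStack].
#' @export
readMovie <- function(tiffPath,
                      sidecarPath = sub("\\.tiff?$", ".json", tiffPath)) {
  if (!file.exists(tiffPath)) stop("no such TIFF: ", tiffPath)
  if (!file.exists(sidecarPath)) stop("no such sidecar: ", sidecarPath)
  pages <- tiff::readTIFF(tiffPath, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) round(p * 65535))
  meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  ts <- meta$timestamps_s
  if (length(ts) != length(pages))
    stop("sidecar has ", length(ts), " timestamps but TIFF has ",
         length(pages), " frames")
  if (is.null(meta$pixel_size_um))
    stop("sidecar lacks pixel_size_um; detection needs it to convert ",
         "um to px")
  MovieStack(frames = pages, timestamps = as.numeric(ts),
             pixelSize = meta$pixel_size_um,
             drugTime = if (is.null(meta$drug_time_s)) 60 else
               meta$drug_time_s,
             condition = if (is.null(meta$condition)) "unknown" else
               meta$condition,
             replicateId = if (is.null(meta$replicate_id)) "r1" else
               meta$replicate_id)
}

#' Write / read an integer label image as TIFF
#'
#' Label values (0 = background) are stored in a 16-bit grayscale TIFF.
#'
#' @param labels integer matrix of labels in `[0, 65535]`.
#' @param path TIFF path.
#' @return `writeMask` invisibly returns `path`; `readMask` returns the
#'   integer label matrix.
#' @export
writeMask <- function(labels, path) {
  if (any(labels < 0 | labels > 65535)) stop("labels outside [0, 65535]")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("no such TIFF: ", path)
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read a TrackMate-style spot table
#'
#' Parses CSV spot exports with columns `POSITION_X`, `POSITION_Y`,
#' `FRAME`, `QUALITY` (required) and `POSITION_T`, `CONTRAST`,
#' `TOTAL_INTENSITY`, `RADIUS` (optional), in either the single-header
#' dialect or the dialect carrying three extra descriptive header rows
#' below the column names. Positions are interpreted as physical units
#' when `pixelSize` is given (TrackMate exports calibrated positions);
#' otherwise they are taken as pixels.
#'
#' @param path CSV path.
#' @param pixelSize optional pixel size (um/px) used to convert calibrated
#'   positions to pixels; `NULL` treats positions as pixels.
#' @return A spot `data.frame` in the layout of [detectSpots()].
#' @export
readTrackmateSpots <- function(path, pixelSize = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = TRUE)
  required <- c("POSITION_X", "POSITION_Y", "FRAME", "QUALITY")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required TrackMate columns: ",
         paste(missing, collapse = ", "))
  ## three-extra-header-row dialect: descriptive rows with non-numeric FRAME
  if (nrow(raw)) {
    bad <- suppressWarnings(is.na(as.numeric(raw$FRAME)))
    raw <- raw[!bad, , drop = FALSE]
  }
  num <- function(col, default = NA_real_) {
    if (col %in% names(raw)) suppressWarnings(as.numeric(raw[[col]]))
    else rep(default, nrow(raw))
  }
  x <- num("POSITION_X"); y <- num("POSITION_Y")
  calibrated <- !is.null(pixelSize)
  data.frame(
    frame = as.integer(num("FRAME")) + 1L,  # TrackMate frames are 0-based
    t_s = num("POSITION_T"),
    x_px = if (calibrated) x / pixelSize else x,
    y_px = if (calibrated) y / pixelSize else y,
    x_um = if (calibrated) x else rep(NA_real_, nrow(raw)),
    y_um = if (calibrated) y else rep(NA_real_, nrow(raw)),
    quality = num("QUALITY"),
    contrast = num("CONTRAST"),
    total_intensity = num("TOTAL_INTENSITY"),
    radius_um = num("RADIUS"),
    cell_id = rep(NA_integer_, nrow(raw)))
}

#' Write a spot table as CSV
#'
#' Stable column order: `frame`, `t_s`, `x_px`, `y_px`, `x_um`, `y_um`,
#' `quality`, `contrast`, `total_intensity`, `radius_um`, `cell_id`.
#'
#' @param spots spot `data.frame` (see [detectSpots()]).
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
writeSpots <- function(spots, path) {
  cols <- c("frame", "t_s", "x_px", "y_px", "x_um", "y_um", "quality",
            "contrast", "total_intensity", "radius_um", "cell_id")
  utils::write.csv(spots[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
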