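#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Release-kinetics parameters
#'
#' Parameterises how individual reporter puncta disappear after drug
#' addition. Four regimes are supported: `"vehicle"` (no disappearance),
#' `"instant"` (all puncta vanish at `drugTime`), `"exponential"`
#' (per-punctum exponential waiting time at rate `kRel` after `drugTime`;
#' the emetine-like regime with no lag phase) and `"two_stage"` (a
#' drug-binding step at rate `kBind` followed by a release step at rate
#' `kRel`, giving a hypoexponential waiting time with an initial shoulder;
#' the cycloheximide-like regime, where A-site crowding slows the binding
#' of puromycin but not the subsequent release).
#'
#' With `chainsPerPunctum > 1` each punctum carries several nascent chains
#' that release independently; punctum intensity is proportional to the
#' surviving chains and the punctum stops being rendered once the surviving
#' fraction drops below `detectFraction`.
#'
#' @param mode one of `"vehicle"`, `"instant"`, `"exponential"`,
#'   `"two_stage"`.
#' @param kRel release rate, per second (`exponential` and `two_stage`).
#' @param kBind binding rate, per second (`two_stage` only).
#' @param drugTime drug-addition time in seconds from trial start.
#' @param chainsPerPunctum number of independently releasing chains per
#'   punctum.
#' @param detectFraction fraction of initial punctum intensity below which
#'   the punctum is no longer rendered (used when `chainsPerPunctum > 1`).
#' @return A `ReleaseKinetics` object.
#' @examples
#' ReleaseKinetics("exponential", kRel = 0.021)
#' @export ReleaseKinetics
#' @exportClass ReleaseKinetics
ReleaseKinetics <- setClass("ReleaseKinetics",
  representation(
    mode = "character",
    kRel = "numericOrNULL",
    kBind = "numericOrNULL",
    drugTime = "numeric",
    chainsPerPunctum = "numeric",
    detectFraction = "numeric"
  )
)

setValidity("ReleaseKinetics", function(object) {
  msg <- character()
  modes <- c("vehicle", "instant", "exponential", "two_stage")
  if (length(object@mode) != 1L || !object@mode %in% modes)
    msg <- c(msg, sprintf("mode must be one of %s",
                          paste(sQuote(modes), collapse = ", ")))
  if (object@mode %in% c("exponential", "two_stage")) {
    if (is.null(object@kRel) || !is.finite(object@kRel) || object@kRel <= 0)
      msg <- c(msg, sprintf("kRel must be a positive rate for mode '%s'",
                            object@mode))
  }
  if (identical(object@mode, "two_stage")) {
    if (is.null(object@kBind) || !is.finite(object@kBind) || object@kBind <= 0)
      msg <- c(msg, "kBind must be a positive rate for mode 'two_stage'")
  }
  if (length(object@drugTime) != 1L || object@drugTime < 0)
    msg <- c(msg, "drugTime must be a single non-negative time (s)")
  if (object@chainsPerPunctum < 1 ||
      object@chainsPerPunctum != round(object@chainsPerPunctum))
    msg <- c(msg, "chainsPerPunctum must be a positive integer")
  if (object@detectFraction <= 0 || object@detectFraction > 1)
    msg <- c(msg, "detectFraction must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @noRd
setMethod("initialize", "ReleaseKinetics", function(.Object,
    mode = "vehicle", kRel = NULL, kBind = NULL, drugTime = 60,
    chainsPerPunctum = 1, detectFraction = 0.5, ...) {
  callNextMethod(.Object, mode = mode, kRel = kRel, kBind = kBind,
                 drugTime = drugTime, chainsPerPunctum = chainsPerPunctum,
                 detectFraction = detectFraction, ...)
})

setMethod("show", "ReleaseKinetics", function(object) {
  cat("ReleaseKinetics:", object@mode, "\n")
  if (!is.null(object@kRel)) cat("  kRel:", object@kRel, "/s\n")
  if (!is.null(object@kBind)) cat("  kBind:", object@kBind, "/s\n")
  cat("  drugTime:", object@drugTime, "s;",
      object@chainsPerPunctum, "chain(s)/punctum\n")
  invisible(NULL)
})

#' Acquisition / rendering parameters for synthetic movies
#'
#' Defaults emulate a spinning-disk live-imaging trial: ~8 min duration,
#' drug-independent irregular frame intervals (mean 5.4 s, sd 1.9 s,
#' truncated to 2.5-9.8 s), a 256x256 field at 0.16 um/px holding 8 cells
#' of ~30 puncta each, a diffraction-limited Gaussian PSF, mild
#' photobleaching (< 10% over the trial) and Poisson-plus-Gaussian camera
#' noise on a 16-bit-like intensity scale.
#'
#' @param trialDuration total trial length (s).
#' @param intervalMean,intervalSd mean and sd of frame intervals (s).
#' @param intervalMin,intervalMax truncation range for frame intervals (s).
#' @param imageShape integer vector `c(rows, cols)` in pixels.
#' @param pixelSize physical pixel size (um/px).
#' @param psfSigma Gaussian PSF standard deviation (um).
#' @param cellsPerField number of cells rendered per field.
#' @param punctaPerCell puncta per cell at trial start.
#' @param backgroundLevel extracellular background intensity (a.u.).
#' @param cytoLevel diffuse cytoplasmic reporter intensity added inside
#'   cells (a.u.).
#' @param spotAmplitude peak amplitude of one punctum above its local
#'   background (a.u.).
#' @param bleachRate photobleaching rate (per s), applied as
#'   `exp(-bleachRate * t)` to all signal.
#' @param poissonGain camera gain used for Poisson shot noise (a.u. per
#'   photon equivalent).
#' @param readNoiseSd Gaussian read-noise standard deviation (a.u.).
#' @param spotMinSep minimum pairwise separation between rendered puncta
#'   (um), so that simulated puncta are individually resolvable.
#' @return An `AcquisitionParams` object.
#' @export AcquisitionParams
#' @exportClass AcquisitionParams
AcquisitionParams <- setClass("AcquisitionParams",
  representation(
    trialDuration = "numeric",
    intervalMean = "numeric",
    intervalSd = "numeric",
    intervalMin = "numeric",
    intervalMax = "numeric",
    imageShape = "numeric",
    pixelSize = "numeric",
    psfSigma = "numeric",
    cellsPerField = "numeric",
    punctaPerCell = "numeric",
    backgroundLevel = "numeric",
    cytoLevel = "numeric",
    spotAmplitude = "numeric",
    bleachRate = "numeric",
    poissonGain = "numeric",
    readNoiseSd = "numeric",
    spotMinSep = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (!(object@intervalMin <= object@intervalMean &&
        object@intervalMean <= object@intervalMax))
    msg <- c(msg, "need intervalMin <= intervalMean <= intervalMax")
  pos <- c(trialDuration = object@trialDuration,
           intervalMean = object@intervalMean,
           intervalSd = object@intervalSd,
           intervalMin = object@intervalMin,
           pixelSize = object@pixelSize, psfSigma = object@psfSigma,
           cellsPerField = object@cellsPerField,
           backgroundLevel = object@backgroundLevel,
           cytoLevel = object@cytoLevel,
           spotAmplitude = object@spotAmplitude,
           poissonGain = object@poissonGain)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, paste("must be positive:", paste(bad, collapse = ", ")))
  if (length(object@imageShape) != 2L || any(object@imageShape < 16))
    msg <- c(msg, "imageShape must be c(rows, cols), each >= 16")
  if (object@punctaPerCell < 0)
    msg <- c(msg, "punctaPerCell must be >= 0")
  if (object@bleachRate < 0 || object@readNoiseSd < 0)
    msg <- c(msg, "bleachRate and readNoiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @noRd
setMethod("initialize", "AcquisitionParams", function(.Object,
    trialDuration = 480, intervalMean = 5.4, intervalSd = 1.9,
    intervalMin = 2.5, intervalMax = 9.8, imageShape = c(256, 256),
    pixelSize = 0.16, psfSigma = 0.17, cellsPerField = 8,
    punctaPerCell = 30, backgroundLevel = 200, cytoLevel = 300,
    spotAmplitude = 2000, bleachRate = 1e-4, poissonGain = 1,
    readNoiseSd = 3, spotMinSep = 0.64, ...) {
  callNextMethod(.Object, trialDuration = trialDuration,
                 intervalMean = intervalMean, intervalSd = intervalSd,
                 intervalMin = intervalMin, intervalMax = intervalMax,
                 imageShape = imageShape, pixelSize = pixelSize,
                 psfSigma = psfSigma, cellsPerField = cellsPerField,
                 punctaPerCell = punctaPerCell,
                 backgroundLevel = backgroundLevel, cytoLevel = cytoLevel,
                 spotAmplitude = spotAmplitude, bleachRate = bleachRate,
                 poissonGain = poissonGain, readNoiseSd = readNoiseSd,
                 spotMinSep = spotMinSep, ...)
})

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf(
    "AcquisitionParams: %gx%g px (%.2f um/px), %g s trial, %g cells x %g puncta\n",
    object@imageShape[1], object@imageShape[2], object@pixelSize,
    object@trialDuration, object@cellsPerField, object@punctaPerCell))
  cat(sprintf("  intervals %.1f +/- %.1f s in [%.1f, %.1f]\n",
              object@intervalMean, object@intervalSd,
              object@intervalMin, object@intervalMax))
  invisible(NULL)
})

#' Still-image experiment parameters
#'
#' Describes a multi-condition still-image (IF / PLA style) experiment:
#' per condition, a mean puncta-per-cell count and a mean diffuse cell
#' intensity. Defaults correspond to a strongly labelled positive
#' condition (~200 puncta per cell) and an antibody-omission control
#' (mean 4, i.e. < 8 puncta per cell).
#'
#' @param conditions `data.frame` with columns `label`, `punctaPerCell`
#'   (condition mean count) and `cellIntensity` (mean diffuse intensity
#'   over the cell, a.u.).
#' @param cellsPerCondition cells rendered per condition.
#' @param imageShape,pixelSize,psfSigma,backgroundLevel,spotAmplitude,poissonGain,readNoiseSd,spotMinSep
#'   raster and noise fields as in [AcquisitionParams()].
#' @return A `StillImageParams` object.
#' @export StillImageParams
#' @exportClass StillImageParams
StillImageParams <- setClass("StillImageParams",
  representation(
    conditions = "data.frame",
    cellsPerCondition = "numeric",
    imageShape = "numeric",
    pixelSize = "numeric",
    psfSigma = "numeric",
    backgroundLevel = "numeric",
    spotAmplitude = "numeric",
    poissonGain = "numeric",
    readNoiseSd = "numeric",
    spotMinSep = "numeric"
  )
)

setValidity("StillImageParams", function(object) {
  msg <- character()
  cond <- object@conditions
  need <- c("label", "punctaPerCell", "cellIntensity")
  if (nrow(cond) < 1L || !all(need %in% names(cond)))
    msg <- c(msg, sprintf("conditions needs >= 1 row and columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (any(cond$punctaPerCell < 0))
      msg <- c(msg, "punctaPerCell must be >= 0")
    if (any(cond$cellIntensity <= 0))
      msg <- c(msg, "cellIntensity must be > 0")
    if (anyDuplicated(cond$label))
      msg <- c(msg, "condition labels must be unique")
  }
  if (object@cellsPerCondition < 1)
    msg <- c(msg, "cellsPerCondition must be >= 1")
  if (length(object@imageShape) != 2L || any(object@imageShape < 16))
    msg <- c(msg, "imageShape must be c(rows, cols), each >= 16")
  if (length(msg)) msg else TRUE
})

#' @noRd
setMethod("initialize", "StillImageParams", function(.Object,
    conditions = data.frame(
      label = c("positive", "control"),
      punctaPerCell = c(200, 4),
      cellIntensity = c(1000, 150)),
    cellsPerCondition = 8, imageShape = c(512, 512), pixelSize = 0.16,
    psfSigma = 0.17, backgroundLevel = 200, spotAmplitude = 2000,
    poissonGain = 1, readNoiseSd = 3, spotMinSep = 0.32, ...) {
  callNextMethod(.Object, conditions = conditions,
                 cellsPerCondition = cellsPerCondition,
                 imageShape = imageShape, pixelSize = pixelSize,
                 psfSigma = psfSigma, backgroundLevel = backgroundLevel,
                 spotAmplitude = spotAmplitude, poissonGain = poissonGain,
                 readNoiseSd = readNoiseSd, spotMinSep = spotMinSep, ...)
})

#' Spot-detection parameters
#'
#' Configuration for Laplacian-of-Gaussian blob detection. Defaults mirror
#' a standard TrackMate-style configuration for diffraction-limited
#' reporter puncta: estimated blob diameter 0.5 um and quality threshold
#' 300 (calibrated for the 16-bit-like intensity scale of the synthetic
#' generator; the threshold is in scale-normalised LoG response units).
#' Optional minima on contrast and total intensity, and an exclusion mask
#' (e.g. nuclei), remove unwanted detections.
#'
#' @param blobDiameter estimated blob diameter (um).
#' @param qualityThreshold minimum scale-normalised LoG peak response.
#' @param contrastMin optional minimum spot contrast in `[-1, 1]`.
#' @param totalIntensityMin optional minimum summed disc intensity.
#' @param pixelSize pixel size (um/px) used to convert to pixels.
#' @param exclusionMask optional logical matrix; spots whose centre pixel
#'   is `TRUE` are suppressed.
#' @return A `DetectionParams` object.
#' @export DetectionParams
#' @exportClass DetectionParams
DetectionParams <- setClass("DetectionParams",
  representation(
    blobDiameter = "numeric",
    qualityThreshold = "numeric",
    contrastMin = "numericOrNULL",
    totalIntensityMin = "numericOrNULL",
    pixelSize = "numeric",
    exclusionMask = "matrixOrNULL"
  )
)

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (object@blobDiameter <= 0) msg <- c(msg, "blobDiameter must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@qualityThreshold < 0)
    msg <- c(msg, "qualityThreshold must be >= 0")
  if (!is.null(object@contrastMin) && object@contrastMin < -1)
    msg <- c(msg, "contrastMin must be >= -1")
  if (!is.null(object@totalIntensityMin) && object@totalIntensityMin < 0)
    msg <- c(msg, "totalIntensityMin must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @noRd
setMethod("initialize", "DetectionParams", function(.Object,
    blobDiameter = 0.5, qualityThreshold = 300, contrastMin = NULL,
    totalIntensityMin = NULL, pixelSize = 0.16, exclusionMask = NULL, ...) {
  callNextMethod(.Object, blobDiameter = blobDiameter,
                 qualityThreshold = qualityThreshold,
                 contrastMin = contrastMin,
                 totalIntensityMin = totalIntensityMin,
                 pixelSize = pixelSize, exclusionMask = exclusionMask, ...)
})

#' Decay-kinetics analysis parameters
#'
#' Parameters of the trajectory analysis: baseline window for per-cell
#' count normalisation (first 60 s, pre-drug), boxcar smoothing width
#' (k = 10 observations), the half-width of the band used for decay-time
#' extraction (+/- 0.01 in normalised units, i.e. 0.49-0.51 for t 1/2),
#' the decay fractions reported (2/3, 1/2, 1/3), the width of summary
#' bins (5 s) and the drug-addition time (60 s).
#'
#' @param baselineWindow baseline window length (s); frames with
#'   `t < baselineWindow` define the per-cell baseline.
#' @param boxcarK boxcar (rolling mean) window width, in observations.
#' @param bandHalfwidth half-width of the decay-time band, in normalised
#'   count units.
#' @param fractions decay fractions at which times are extracted.
#' @param binWidth summary bin width (s).
#' @param drugTime drug-addition time (s).
#' @return A `KineticsParams` object.
#' @export KineticsParams
#' @exportClass KineticsParams
KineticsParams <- setClass("KineticsParams",
  representation(
    baselineWindow = "numeric",
    boxcarK = "numeric",
    bandHalfwidth = "numeric",
    fractions = "numeric",
    binWidth = "numeric",
    drugTime = "numeric"
  )
)

setValidity("KineticsParams", function(object) {
  msg <- character()
  if (object@baselineWindow <= 0) msg <- c(msg, "baselineWindow must be > 0")
  if (object@boxcarK < 1 || object@boxcarK != round(object@boxcarK))
    msg <- c(msg, "boxcarK must be a positive integer")
  if (object@bandHalfwidth <= 0) msg <- c(msg, "bandHalfwidth must be > 0")
  if (any(object@fractions <= 0 | object@fractions >= 1))
    msg <- c(msg, "fractions must lie strictly in (0, 1)")
  if (length(object@fractions) > 1) {
    sp <- min(diff(sort(object@fractions)))
    if (object@bandHalfwidth >= sp)
      msg <- c(msg, "bandHalfwidth must be below the minimum fraction spacing")
  }
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  if (object@drugTime < 0) msg <- c(msg, "drugTime must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @noRd
setMethod("initialize", "KineticsParams", function(.Object,
    baselineWindow = 60, boxcarK = 10, bandHalfwidth = 0.01,
    fractions = c(2 / 3, 1 / 2, 1 / 3), binWidth = 5, drugTime = 60, ...) {
  callNextMethod(.Object, baselineWindow = baselineWindow,
                 boxcarK = boxcarK, bandHalfwidth = bandHalfwidth,
                 fractions = fractions, binWidth = binWidth,
                 drugTime = drugTime, ...)
})

#' Time-lapse movie container
#'
#' A time-ordered stack of 2-D intensity rasters with irregular per-frame
#' timestamps, a physical pixel size and trial metadata.
#'
#' @param frames list of numeric matrices, all of identical dimension.
#' @param timestamps numeric vector of per-frame acquisition times (s),
#'   strictly increasing, same length as `frames`.
#' @param pixelSize pixel size (um/px).
#' @param drugTime drug-addition time (s).
#' @param condition condition label.
#' @param replicateId replicate identifier.
#' @return A `MovieStack` object.
#' @seealso [frames()], [timestamps()], [pixelSize()], [nFrames()]
#' @export MovieStack
#' @exportClass MovieStack
MovieStack <- setClass("MovieStack",
  representation(
    frames = "list",
    timestamps = "numeric",
    pixelSize = "numeric",
    drugTime = "numeric",
    condition = "character",
    replicateId = "character"
  )
)

setValidity("MovieStack", function(object) {
  msg <- character()
  if (length(object@frames) != length(object@timestamps))
    msg <- c(msg, sprintf("%d frames but %d timestamps",
                          length(object@frames), length(object@timestamps)))
  if (length(object@frames)) {
    dims <- vapply(object@frames, dim, integer(2))
    if (!all(dims == dims[, 1]))
      msg <- c(msg, "all frames must share one dimension")
    if (is.unsorted(object@timestamps, strictly = TRUE))
      msg <- c(msg, "timestamps must be strictly increasing")
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number (um/px)")
  if (length(msg)) msg else TRUE
})

#' @noRd
setMethod("initialize", "MovieStack", function(.Object,
    frames = list(), timestamps = numeric(), pixelSize = 0.16,
    drugTime = 60, condition = "unknown", replicateId = "r1", ...) {
  callNextMethod(.Object, frames = frames, timestamps = timestamps,
                 pixelSize = pixelSize, drugTime = drugTime,
                 condition = condition, replicateId = replicateId, ...)
})

setMethod("show", "MovieStack", function(object) {
  d <- if (length(object@frames)) dim(object@frames[[1]]) else c(0, 0)
  cat(sprintf(
    "MovieStack '%s' (%s): %d frames of %dx%d px, %.2f um/px\n",
    object@condition, object@replicateId, length(object@frames), d[1], d[2],
    object@pixelSize))
  if (length(object@timestamps))
    cat(sprintf("  t in [%.1f, %.1f] s, drug at %.0f s\n",
                min(object@timestamps), max(object@timestamps),
                object@drugTime))
  invisible(NULL)
})

#' Generator-side ground truth
#'
#' Holds the generator's truth for a simulated experiment: per-punctum
#' records (cell, position, disappearance time; `Inf` for never), the true
#' per-cell visible-puncta count per frame, and the per-frame true
#' background level, for use as a recovery-test oracle.
#'
#' @param puncta `data.frame` with columns `cell`, `x`, `y` (px, 0-based),
#'   `tDisappear` (s, `Inf` if never).
#' @param counts `data.frame` with columns `cell`, `frame`, `t`, `count`.
#' @param background numeric vector of per-frame true background levels.
#' @return A `GroundTruth` object.
#' @export GroundTruth
#' @exportClass GroundTruth
GroundTruth <- setClass("GroundTruth",
  representation(
    puncta = "data.frame",
    counts = "data.frame",
    background = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!all(c("cell", "x", "y", "tDisappear") %in% names(object@puncta)))
    msg <- c(msg, "puncta needs columns cell, x, y, tDisappear")
  if (!all(c("cell", "frame", "t", "count") %in% names(object@counts)))
    msg <- c(msg, "counts needs columns cell, frame, t, count")
  if (nrow(object@counts) && any(object@counts$count < 0))
    msg <- c(msg, "true counts must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d puncta in %d cell(s), %d frame-count rows\n",
              nrow(object@puncta), length(unique(object@puncta$cell)),
              nrow(object@counts)))
  invisible(NULL)
})
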