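#' Accessors for MovieStack objects
#'
#' `frames()` returns the list of frame matrices, `timestamps()` the
#' per-frame acquisition times in seconds, `pixelSize()` the physical
#' pixel size in um/px, `drugTime()` the drug-addition time in seconds and
#' `nFrames()` the number of frames.
#'
#' @param x a [MovieStack] object.
#' @return See the individual descriptions.
#' @name MovieStack-accessors
#' @aliases frames timestamps pixelSize drugTime nFrames
NULL

#' @rdname MovieStack-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname MovieStack-accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname MovieStack-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname MovieStack-accessors
#' @export
setGeneric("drugTime", function(x) standardGeneric("drugTime"))

#' @rdname MovieStack-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname MovieStack-accessors
setMethod("frames", "MovieStack", function(x) x@frames)

#' @rdname MovieStack-accessors
setMethod("timestamps", "MovieStack", function(x) x@timestamps)

#' @rdname MovieStack-accessors
setMethod("pixelSize", "MovieStack", function(x) x@pixelSize)

#' @rdname MovieStack-accessors
setMethod("drugTime", "MovieStack", function(x) x@drugTime)

#' @rdname MovieStack-accessors
setMethod("nFrames", "MovieStack", function(x) length(x@frames))

#' Accessors for GroundTruth objects
#'
#' `truePuncta()` returns the per-punctum table (cell, position,
#' disappearance time), `trueCounts()` the per-cell per-frame true
#' visible-puncta counts and `trueBackground()` the per-frame true
#' background level.
#'
#' @param x a [GroundTruth] object.
#' @return A `data.frame` (or numeric vector for `trueBackground`).
#' @name GroundTruth-accessors
#' @aliases truePuncta trueCounts trueBackground
NULL

#' @rdname GroundTruth-accessors
#' @export
setGeneric("truePuncta", function(x) standardGeneric("truePuncta"))

#' @rdname GroundTruth-accessors
#' @export
setGeneric("trueCounts", function(x) standardGeneric("trueCounts"))

#' @rdname GroundTruth-accessors
#' @export
setGeneric("trueBackground", function(x) standardGeneric("trueBackground"))

#' @rdname GroundTruth-accessors
setMethod("truePuncta", "GroundTruth", function(x) x@puncta)

#' @rdname GroundTruth-accessors
setMethod("trueCounts", "GroundTruth", function(x) x@counts)

#' @rdname GroundTruth-accessors
setMethod("trueBackground", "GroundTruth", function(x) x@background)
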