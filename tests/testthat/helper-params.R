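# Small, fast configurations reused across test files.

# Two cells with a handful of puncta on a small raster; short trial.
tinyAcq <- function(...) {
  args <- utils::modifyList(
    list(imageShape = c(96, 96), cellsPerField = 2, punctaPerCell = 6,
         trialDuration = 120),
    list(...))
  do.call(AcquisitionParams, args)
}

# Near noise-free imaging: vanishing shot noise, no read noise, no bleach.
quietAcq <- function(...) {
  args <- utils::modifyList(
    list(poissonGain = 1e-3, readNoiseSd = 0, bleachRate = 0),
    list(...))
  do.call(tinyAcq, args)
}

tinyDet <- function(...) DetectionParams(pixelSize = 0.16, ...)
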