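## Generics and accessors. Slot access from user code should go through these.

#' @name fflmpi-accessors
#' @title Accessors for fflmpi objects
#' @description Small accessor generics: sample spacing and duty cycle of a
#'   geometry, voxel-by-frame matrices, timestamps, capnia state, masks,
#'   retained singular-vector counts and fitted coefficients.
#' @param object an fflmpi S4 object
#' @param x an fflmpi S4 object
#' @return the accessed component (see individual methods)
NULL

#' @rdname fflmpi-accessors
#' @export
setGeneric("sampleSpacing", function(object) standardGeneric("sampleSpacing"))

#' @rdname fflmpi-accessors
#' @export
setMethod("sampleSpacing", "ScannerGeometry", function(object)
  object@fovDiameter / object@nSamples)

#' @rdname fflmpi-accessors
#' @export
setGeneric("dutyCycle", function(object) standardGeneric("dutyCycle"))

#' @rdname fflmpi-accessors
#' @export
setMethod("dutyCycle", "ScannerGeometry", function(object) {
  live <- object@setSize * object@framePeriod
  live / (live + object@setGap)
})

#' @rdname fflmpi-accessors
#' @export
setGeneric("frameMatrix", function(object) standardGeneric("frameMatrix"))

#' @rdname fflmpi-accessors
#' @export
setMethod("frameMatrix", "ImageSeries", function(object)
  SummarizedExperiment::assay(object, "frames"))

#' @rdname fflmpi-accessors
#' @export
setGeneric("timestamps", function(object) standardGeneric("timestamps"))

#' @rdname fflmpi-accessors
#' @export
setMethod("timestamps", "ImageSeries", function(object)
  SummarizedExperiment::colData(object)$timestamp)

#' @rdname fflmpi-accessors
#' @export
setMethod("timestamps", "SinogramSeries", function(object) object@timestamps)

#' @rdname fflmpi-accessors
#' @export
setGeneric("capniaState", function(object) standardGeneric("capniaState"))

#' @rdname fflmpi-accessors
#' @export
setMethod("capniaState", "ImageSeries", function(object)
  SummarizedExperiment::colData(object)$state)

#' @rdname fflmpi-accessors
#' @export
setGeneric("frameIndex", function(object) standardGeneric("frameIndex"))

#' @rdname fflmpi-accessors
#' @export
setMethod("frameIndex", "ImageSeries", function(object)
  SummarizedExperiment::colData(object)$frameIndex)

#' @rdname fflmpi-accessors
#' @export
setGeneric("setIndex", function(object) standardGeneric("setIndex"))

#' @rdname fflmpi-accessors
#' @export
setMethod("setIndex", "ImageSeries", function(object)
  SummarizedExperiment::colData(object)$setIndex)

#' @rdname fflmpi-accessors
#' @export
setMethod("setIndex", "SinogramSeries", function(object) object@setIndex)

#' @rdname fflmpi-accessors
#' @export
setGeneric("imageDim", function(object) standardGeneric("imageDim"))

#' @rdname fflmpi-accessors
#' @export
setMethod("imageDim", "ImageSeries", function(object)
  S4Vectors::metadata(object)$dim)

#' @rdname fflmpi-accessors
#' @export
setMethod("imageDim", "GLMFit", function(object) object@dim)

#' @rdname fflmpi-accessors
#' @export
setGeneric("roiMask", function(object) standardGeneric("roiMask"))

#' @rdname fflmpi-accessors
#' @export
setMethod("roiMask", "ImageSeries", function(object)
  SummarizedExperiment::rowData(object)$inMask)

#' @rdname fflmpi-accessors
#' @export
setGeneric("roiMask<-", function(object, value) standardGeneric("roiMask<-"))

#' @rdname fflmpi-accessors
#' @export
setMethod("roiMask<-", "ImageSeries", function(object, value) {
  stopifnot(length(value) == nrow(object))
  SummarizedExperiment::rowData(object)$inMask <- as.logical(value)
  object
})

#' @rdname fflmpi-accessors
#' @export
setGeneric("retainedVectors", function(object)
  standardGeneric("retainedVectors"))

#' @rdname fflmpi-accessors
#' @export
setMethod("retainedVectors", "InverseOperator", function(object)
  object@retained)

#' @rdname fflmpi-accessors
#' @export
setMethod("coef", "GLMFit", function(object) object@coefficients)

#' @rdname fflmpi-accessors
#' @export
setGeneric("residualSd", function(object) standardGeneric("residualSd"))

#' @rdname fflmpi-accessors
#' @export
setMethod("residualSd", "GLMFit", function(object) object@residualSd)

#' @rdname fflmpi-accessors
#' @export
setGeneric("glmParams", function(object) standardGeneric("glmParams"))

#' @rdname fflmpi-accessors
#' @export
setMethod("glmParams", "GLMFit", function(object) object@params)

#' @rdname fflmpi-accessors
#' @export
setGeneric("tracerGrid", function(object) standardGeneric("tracerGrid"))

#' @rdname fflmpi-accessors
#' @export
setMethod("tracerGrid", "TracerMap", function(object) object@grid)

#' @rdname fflmpi-accessors
#' @export
setGeneric("harmonics", function(object) standardGeneric("harmonics"))

#' @rdname fflmpi-accessors
#' @export
setMethod("harmonics", "SinogramFrame", function(object) object@harmonics)

#' @rdname fflmpi-accessors
#' @export
setMethod("harmonics", "SinogramSeries", function(object) object@harmonics)

#' @rdname fflmpi-accessors
#' @export
setMethod("harmonics", "SystemMatrix", function(object) object@harmonics)

## --------------------------------------------------------------------------
## show methods
## --------------------------------------------------------------------------

setMethod("show", "ScannerGeometry", function(object) {
  cat("ScannerGeometry:",
      sprintf("%g kHz / %g mT drive, %g T/m gradient",
              object@driveFrequency / 1e3, object@driveAmplitude,
              object@gradient), "\n")
  cat(sprintf("  %d angles x %d samples over %g mm FOV (%.3f mm spacing)\n",
              as.integer(object@nAngles), as.integer(object@nSamples),
              object@fovDiameter, sampleSpacing(object)))
  cat(sprintf("  %g s frames in sets of %d, %g s gap (duty cycle %.1f%%)\n",
              object@framePeriod, as.integer(object@setSize), object@setGap,
              100 * dutyCycle(object)))
  cat(sprintf("  %d z-slices over %g mm\n",
              as.integer(object@zSlices), object@zExtent))
})

setMethod("show", "SpionModel", function(object) {
  cat(sprintf(
    "SpionModel: %g A.m^2/kg, core %g nm, field scale %g mT,\n",
    object@momentPerMass, object@coreDiameter, object@fieldScale))
  cat(sprintf("  signal gain %.4g A.U./ng, blood decay tau2 = %g s\n",
              object@signalGain, object@bloodDecayTau))
})

setMethod("show", "TracerMap", function(object) {
  d <- dim(object@grid)
  cat(sprintf(
    "TracerMap: %d x %d x %d grid, voxel %s mm, total Fe %.4g ng (%d nonzero voxels)\n",
    d[1], d[2], d[3], paste(signif(object@voxelSize, 3), collapse = " x "),
    sum(object@grid), sum(object@grid > 0)))
})

setMethod("show", "SinogramFrame", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "SinogramFrame @ t = %g s: %d angles x %d samples, harmonics [%s]\n",
    object@timestamp, d[1], d[2], paste(object@harmonics, collapse = ", ")))
})

setMethod("show", "SinogramSeries", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "SinogramSeries: %d frames (%d angles x %d samples, harmonics [%s]),\n",
    d[4], d[1], d[2], paste(object@harmonics, collapse = ", ")))
  cat(sprintf("  t = %g..%g s in %d sets\n", min(object@timestamps),
              max(object@timestamps), max(object@setIndex) + 1L))
})

setMethod("show", "ImageSeries", function(object) {
  d <- imageDim(object)
  cat(sprintf(
    "ImageSeries: %d x %d voxels x %d frames, t = %g..%g s, %d in mask\n",
    d[1], d[2], ncol(object), min(timestamps(object)),
    max(timestamps(object)), sum(roiMask(object))))
})

setMethod("show", "SystemMatrix", function(object) {
  cat(sprintf(
    "SystemMatrix: %d measurements x %d voxels (grid %s, harmonics [%s])\n",
    nrow(object@matrix), ncol(object@matrix),
    paste(object@gridDim, collapse = " x "),
    paste(object@harmonics, collapse = ", ")))
})

setMethod("show", "InverseOperator", function(object) {
  cat(sprintf(
    "InverseOperator: %d of %d singular vectors retained (energy >= %g in band <= %g Nyquist)\n",
    object@retained, length(object@singularValues),
    object@energyThreshold, object@lowresBand))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(
    "NoiseModel: sigma0 = %g A.U., lambda = %g, quadrant delta = %g\n",
    object@sigma0, object@lambdaGain, object@quadrantGainDelta))
  if (object@driftLinear != 0 || object@driftQuadratic != 0 ||
      object@transientAmplitude != 0)
    cat(sprintf("  drift %g/s + %g/s^2, transient %g * exp(-t/%g s)\n",
                object@driftLinear, object@driftQuadratic,
                object@transientAmplitude, object@transientTau))
})

setMethod("show", "CapniaProtocol", function(object) {
  cat(sprintf(
    "CapniaProtocol: %d cycles of %g s per state starting %s, delta CBV %g%%\n",
    as.integer(object@nCycles), object@stateDuration, object@startState,
    100 * object@deltaCbvFraction))
})

setMethod("show", "GLMParams", function(object) {
  cat(sprintf(
    "GLMParams (%s mode): tau1 = %g s, tau2 = %g s, tauD = %g s, deltaT = %g s\n",
    object@mode, object@tau1, object@tau2, object@tauD, object@deltaT))
})

setMethod("show", "GLMFit", function(object) {
  cat(sprintf("GLMFit (%s mode): %d voxels (%d in mask), %d regressors, df = %g\n",
              object@params@mode, nrow(object@coefficients),
              sum(object@mask), ncol(object@coefficients), object@df))
  ok <- object@mask & is.finite(object@cnr)
  if (any(ok))
    cat(sprintf("  peak |CNR| = %.3g, mean in-mask dS/S = %.3g%%\n",
                max(abs(object@cnr[ok])),
                mean(object@percentChange[ok], na.rm = TRUE)))
})

setMethod("show", "DilutionFit", function(object) {
  cat(sprintf(
    "DilutionFit: SNR = %.4g * ng %+.4g (R^2 = %.5g); detection limit %.2g ng at SNR = %g\n",
    object@slope, object@intercept, object@rSquared,
    object@detectionLimitMass, object@referenceSnr))
})

setMethod("show", "NoiseFit", function(object) {
  cat(sprintf("NoiseFit: sigma0 = %.4g A.U., lambda = %.4g (R^2 = %.4g)\n",
              object@sigma0, object@lambdaGain, object@rSquared))
})
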