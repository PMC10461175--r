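#' @import methods
#' @importFrom stats fft sd approx optim optimize convolve rnorm pt setNames coef
#' @importFrom utils modifyList read.csv write.csv
NULL

## ---------------------------------------------------------------------------
## Scanner geometry
## ---------------------------------------------------------------------------

#' Scanner geometry for a mechanically rotating field-free-line MPI imager
#'
#' Describes the acquisition geometry of a rotating-FFL scanner: a 25 kHz,
#' 8 mT-peak drive field along z, a 2.83 T/m selection gradient forming the
#' FFL, projections at 27 gantry angles with 66 shift samples across a 30 mm
#' field of view, 5 s frames acquired in sets of 5 with a 5 s (half rotation)
#' re-trigger gap, and a 5-slice through-plane model extent.
#'
#' @slot driveFrequency drive field frequency f0 (Hz)
#' @slot driveAmplitude drive field peak amplitude (mT)
#' @slot gradient selection gradient strength (T/m, equal to mT/mm)
#' @slot fovDiameter in-plane field of view diameter (mm)
#' @slot nAngles number of projection angles per frame
#' @slot nSamples number of FFL shift samples per projection
#' @slot shiftFrequency shift (FFL sweep) frequency (Hz), descriptive
#' @slot shiftCurrent shift coil peak current (A), descriptive
#' @slot rotationRate gantry rotation rate (Hz)
#' @slot framePeriod time per 2D frame (s)
#' @slot setSize frames acquired per continuous set
#' @slot setGap gap between sets (s)
#' @slot zSlices number of through-plane model slices
#' @slot zExtent through-plane model extent (mm)
#' @export
setClass("ScannerGeometry",
  representation(
    driveFrequency = "numeric", driveAmplitude = "numeric",
    gradient = "numeric", fovDiameter = "numeric",
    nAngles = "numeric", nSamples = "numeric",
    shiftFrequency = "numeric", shiftCurrent = "numeric",
    rotationRate = "numeric", framePeriod = "numeric",
    setSize = "numeric", setGap = "numeric",
    zSlices = "numeric", zExtent = "numeric"
  )
)

setValidity("ScannerGeometry", function(object) {
  msg <- character()
  if (object@nSamples < 2) msg <- c(msg, "nSamples must be >= 2")
  if (object@fovDiameter <= 0) msg <- c(msg, "fovDiameter must be > 0")
  if (object@nAngles < 1) msg <- c(msg, "nAngles must be >= 1")
  if (object@gradient <= 0) msg <- c(msg, "gradient must be > 0")
  if (object@framePeriod <= 0) msg <- c(msg, "framePeriod must be > 0")
  if (object@setSize < 1) msg <- c(msg, "setSize must be >= 1")
  if (object@setGap < 0) msg <- c(msg, "setGap must be >= 0")
  if (object@zSlices < 1 || object@zSlices %% 2 != 1)
    msg <- c(msg, "zSlices must be a positive odd count")
  if (length(msg)) msg else TRUE
})

#' Construct a ScannerGeometry
#'
#' Defaults reproduce the rodent FFL scanner: 25 kHz / 8 mT drive, 2.83 T/m
#' gradient, 27 angles x 66 samples over a 30 mm FOV (0.45 mm sample
#' spacing), 0.1 Hz rotation giving 5 s frames in sets of 5 with a 5 s gap
#' (83% duty cycle), and 5 z-slices over 7 mm.
#'
#' @param driveFrequency,driveAmplitude,gradient,fovDiameter,nAngles,nSamples
#'   see slot documentation in [ScannerGeometry-class]
#' @param shiftFrequency,shiftCurrent,rotationRate,framePeriod,setSize,setGap
#'   see slot documentation
#' @param zSlices,zExtent see slot documentation
#' @return a validated [ScannerGeometry-class] object
#' @examples
#' geom <- ScannerGeometry()
#' sampleSpacing(geom)  # 30/66 = 0.4545 mm
#' dutyCycle(geom)      # 25/30 = 0.833
#' @export
ScannerGeometry <- function(driveFrequency = 25e3, driveAmplitude = 8,
                            gradient = 2.83, fovDiameter = 30,
                            nAngles = 27, nSamples = 66,
                            shiftFrequency = 2.7, shiftCurrent = 42,
                            rotationRate = 0.1, framePeriod = 5,
                            setSize = 5, setGap = 5,
                            zSlices = 5, zExtent = 7) {
  new("ScannerGeometry",
    driveFrequency = driveFrequency, driveAmplitude = driveAmplitude,
    gradient = gradient, fovDiameter = fovDiameter,
    nAngles = as.numeric(nAngles), nSamples = as.numeric(nSamples),
    shiftFrequency = shiftFrequency, shiftCurrent = shiftCurrent,
    rotationRate = rotationRate, framePeriod = framePeriod,
    setSize = as.numeric(setSize), setGap = setGap,
    zSlices = as.numeric(zSlices), zExtent = zExtent)
}

## ---------------------------------------------------------------------------
## SPION magnetization model
## ---------------------------------------------------------------------------

#' Superparamagnetic nanoparticle (SPION) magnetization model
#'
#' Parameters of the tracer's Langevin magnetization response and its signal
#' calibration. `fieldScale` is the field (mT) at which the Langevin argument
#' equals one; it sets the sharpness of the magnetization curve and hence the
#' native point-spread-function width. `signalGain` converts ng of Fe at
#' saturation into arbitrary signal units and is normally set by
#' [calibrateSignalGain()]. `bloodDecayTau` is the tracer blood clearance
#' time constant tau2 (s).
#'
#' @slot momentPerMass magnetic moment per unit mass (A m^2 / kg)
#' @slot coreDiameter magnetic core diameter (nm)
#' @slot hydrodynamicDiameter hydrodynamic diameter (nm), descriptive
#' @slot fieldScale Langevin field scale (mT)
#' @slot signalGain arbitrary units per ng at saturation
#' @slot bloodDecayTau blood clearance time constant tau2 (s)
#' @export
setClass("SpionModel",
  representation(
    momentPerMass = "numeric", coreDiameter = "numeric",
    hydrodynamicDiameter = "numeric", fieldScale = "numeric",
    signalGain = "numeric", bloodDecayTau = "numeric"
  )
)

setValidity("SpionModel", function(object) {
  vals <- c(object@momentPerMass, object@coreDiameter,
            object@hydrodynamicDiameter, object@fieldScale,
            object@signalGain, object@bloodDecayTau)
  if (any(!is.finite(vals) & !is.infinite(vals)) || any(vals <= 0))
    "all SpionModel parameters must be positive" else TRUE
})

#' Construct a SpionModel
#'
#' Defaults describe a Synomag-D-like multicore tracer (110 A m^2/kg, 25 nm
#' core, 70 nm hydrodynamic diameter). The default `fieldScale` of 2.5 mT
#' puts the native in-plane PSF FWHM near 3 mm at a 2.83 T/m gradient.
#'
#' @param momentPerMass,coreDiameter,hydrodynamicDiameter,fieldScale
#'   see slot documentation in [SpionModel-class]
#' @param signalGain,bloodDecayTau see slot documentation
#' @return a validated [SpionModel-class] object
#' @export
SpionModel <- function(momentPerMass = 110, coreDiameter = 25,
                       hydrodynamicDiameter = 70, fieldScale = 2.5,
                       signalGain = 1, bloodDecayTau = 3100) {
  new("SpionModel",
    momentPerMass = momentPerMass, coreDiameter = coreDiameter,
    hydrodynamicDiameter = hydrodynamicDiameter, fieldScale = fieldScale,
    signalGain = signalGain, bloodDecayTau = bloodDecayTau)
}

## ---------------------------------------------------------------------------
## Tracer map (the imaged object)
## ---------------------------------------------------------------------------

#' Gridded tracer (iron) distribution
#'
#' The object being imaged: a 3D lattice of Fe mass per voxel (ng) on a
#' regular grid. `origin` is the offset (mm) of the grid center from the FFL
#' rotation axis.
#'
#' @slot grid 3D numeric array of Fe mass per voxel (ng), all >= 0
#' @slot voxelSize voxel edge lengths (mm), length 3
#' @slot origin offset of the grid center from the rotation axis (mm), length 3
#' @export
setClass("TracerMap",
  representation(grid = "array", voxelSize = "numeric", origin = "numeric")
)

setValidity("TracerMap", function(object) {
  msg <- character()
  if (length(dim(object@grid)) != 3L)
    msg <- c(msg, "grid must be a 3D array")
  if (any(object@grid < 0)) msg <- c(msg, "all voxel masses must be >= 0")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive lengths (mm)")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must be a length-3 offset (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct a TracerMap
#'
#' @param grid 3D array of Fe mass per voxel (ng); 2D matrices are promoted
#'   to a single-slice 3D array
#' @param voxelSize voxel size in mm (scalar or length 3)
#' @param origin grid-center offset from the rotation axis (mm, length 3)
#' @return a validated [TracerMap-class] object
#' @export
TracerMap <- function(grid, voxelSize = 3, origin = c(0, 0, 0)) {
  if (is.matrix(grid)) grid <- array(grid, dim = c(dim(grid), 1L))
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("TracerMap", grid = grid, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

## ---------------------------------------------------------------------------
## Sinograms
## ---------------------------------------------------------------------------

#' One harmonic-resolved FFL sinogram frame
#'
#' A single 5 s acquisition: complex harmonic amplitudes indexed by
#' (angle, shift sample, harmonic order). The fundamental (order 1) is never
#' retained because the direct drive feedthrough is filtered in hardware.
#'
#' @slot values complex 3D array (nAngles x nSamples x length(harmonics))
#' @slot harmonics integer harmonic orders retained (all >= 2)
#' @slot timestamp acquisition time (s)
#' @export
setClass("SinogramFrame",
  representation(values = "array", harmonics = "integer",
                 timestamp = "numeric")
)

setValidity("SinogramFrame", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "values must be a 3D array")
  else if (d[3L] != length(object@harmonics))
    msg <- c(msg, "third dimension must match length(harmonics)")
  if (any(object@harmonics < 2L))
    msg <- c(msg, "harmonic orders must be >= 2 (fundamental is filtered out)")
  if (length(msg)) msg else TRUE
})

#' A sinogram time series with set/gap structure
#'
#' @slot values complex 4D array (nAngles x nSamples x nHarmonics x nFrames)
#' @slot harmonics integer harmonic orders retained
#' @slot timestamps frame timestamps (s, end of acquisition)
#' @slot setIndex 0-based set index of each frame
#' @slot geometry the [ScannerGeometry-class] used
#' @slot spion the [SpionModel-class] used
#' @export
setClass("SinogramSeries",
  representation(values = "array", harmonics = "integer",
                 timestamps = "numeric", setIndex = "integer",
                 geometry = "ScannerGeometry", spion = "SpionModel")
)

setValidity("SinogramSeries", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 4L) msg <- c(msg, "values must be a 4D array")
  else {
    if (d[3L] != length(object@harmonics))
      msg <- c(msg, "harmonic dimension mismatch")
    if (d[4L] != length(object@timestamps))
      msg <- c(msg, "frame dimension must match length(timestamps)")
    if (d[4L] != length(object@setIndex))
      msg <- c(msg, "setIndex must have one entry per frame")
  }
  if (is.unsorted(object@timestamps, strictly = TRUE))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Image time series (SummarizedExperiment-backed)
## ---------------------------------------------------------------------------

#' Reconstructed 2D image time series
#'
#' Extends SummarizedExperiment: rows are in-plane voxels (with grid
#' coordinates in `rowData`), columns are frames (with `timestamp`,
#' gap-aware `frameIndex`, `setIndex` and the capnia `state` in `colData`).
#' The single assay `"frames"` holds the voxel-by-frame signal matrix in
#' arbitrary units. Image dimensions and voxel size live in `metadata`.
#'
#' @export
#' @import SummarizedExperiment
setClass("ImageSeries", contains = "SummarizedExperiment")

setValidity("ImageSeries", function(object) {
  msg <- character()
  md <- S4Vectors::metadata(object)
  if (is.null(md$dim) || length(md$dim) != 2L)
    msg <- c(msg, "metadata$dim must give the 2D image dimensions")
  else if (prod(md$dim) != nrow(object))
    msg <- c(msg, "prod(metadata$dim) must equal the number of voxel rows")
  cd <- SummarizedExperiment::colData(object)
  if (!"timestamp" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'timestamp' column")
  else if (ncol(object) > 1L &&
           is.unsorted(cd$timestamp, strictly = TRUE))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (!"inMask" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain an 'inMask' column")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageSeries
#'
#' @param frames either a 3D array (nx x ny x nFrames) or a voxel-by-frame
#'   matrix (nx*ny x nFrames)
#' @param timestamps frame times (s), strictly increasing
#' @param dim image dimensions c(nx, ny); required when `frames` is a matrix
#' @param voxelSize in-plane voxel size (mm)
#' @param state capnia state per frame (0 = hypo, 1 = hyper); defaults to 0
#' @param setIndex 0-based acquisition set index per frame; inferred from
#'   timestamps when NULL (gaps detected as spacing > 1.5x median)
#' @param mask logical in-brain/ROI indicator per voxel; defaults to all TRUE
#' @return an [ImageSeries-class]
#' @examples
#' arr <- array(rnorm(4 * 4 * 10), c(4, 4, 10))
#' is1 <- ImageSeries(arr, timestamps = seq(5, 50, by = 5))
#' dim(frameMatrix(is1))
#' @export
ImageSeries <- function(frames, timestamps, dim = NULL, voxelSize = 0.9,
                        state = NULL, setIndex = NULL, mask = NULL) {
  if (is.array(frames) && length(base::dim(frames)) == 3L) {
    dim <- base::dim(frames)[1:2]
    frames <- matrix(frames, nrow = prod(dim))
  } else if (is.matrix(frames)) {
    if (is.null(dim))
      stop("'dim' is required when 'frames' is a voxel-by-frame matrix")
    stopifnot(prod(dim) == nrow(frames))
  } else stop("'frames' must be a 3D array or a matrix")
  nF <- ncol(frames)
  stopifnot(length(timestamps) == nF)
  if (is.null(state)) state <- rep(0, nF)
  if (is.null(setIndex)) setIndex <- inferSetIndex(timestamps)
  if (is.null(mask)) mask <- rep(TRUE, prod(dim))
  stopifnot(length(mask) == prod(dim), length(state) == nF)
  coords <- expand.grid(ix = seq_len(dim[1]), iy = seq_len(dim[2]))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(frames = unname(frames)),
    rowData = S4Vectors::DataFrame(ix = coords$ix, iy = coords$iy,
                                   inMask = as.logical(mask)),
    colData = S4Vectors::DataFrame(
      timestamp = as.numeric(timestamps),
      frameIndex = seq_len(nF) - 1L,
      setIndex = as.integer(setIndex),
      state = as.numeric(state)),
    metadata = list(dim = as.integer(dim), voxelSize = voxelSize))
  new("ImageSeries", se)
}

## infer 0-based set index from timestamp gaps
inferSetIndex <- function(timestamps) {
  n <- length(timestamps)
  if (n <= 1L) return(integer(n))
  dt <- diff(timestamps)
  gap <- dt > 1.5 * stats::median(dt)
  as.integer(cumsum(c(0L, gap)))
}

## ---------------------------------------------------------------------------
## Reconstruction operators
## ---------------------------------------------------------------------------

#' Simulated MPI system matrix
#'
#' Complex forward model: rows are (angle, sample, harmonic) measurement
#' channels, columns are voxels of the reconstruction grid (in-plane grid
#' replicated over z-slices, z fastest varying last; column j is the
#' harmonic-resolved response of a unit-mass source at voxel j).
#'
#' @slot matrix complex matrix (nAngles*nSamples*nHarmonics x nVoxels)
#' @slot gridDim reconstruction grid dimensions c(nx, ny, nz)
#' @slot voxelSize in-plane voxel size (mm)
#' @slot zOffsets z positions of the slices (mm)
#' @slot harmonics harmonic orders used
#' @slot geometry,spion the models the matrix was simulated from
#' @export
setClass("SystemMatrix",
  representation(matrix = "matrix", gridDim = "integer",
                 voxelSize = "numeric", zOffsets = "numeric",
                 harmonics = "integer", geometry = "ScannerGeometry",
                 spion = "SpionModel")
)

setValidity("SystemMatrix", function(object) {
  msg <- character()
  rows <- object@geometry@nAngles * object@geometry@nSamples *
    length(object@harmonics)
  if (nrow(object@matrix) != rows)
    msg <- c(msg, "row count must equal nAngles*nSamples*nHarmonics")
  if (ncol(object@matrix) != prod(object@gridDim))
    msg <- c(msg, "column count must equal prod(gridDim)")
  if (any(!is.finite(Mod(object@matrix))))
    msg <- c(msg, "matrix entries must be finite")
  if (length(msg)) msg else TRUE
})

#' Truncated-SVD inverse operator
#'
#' Pseudoinverse of a system matrix restricted to singular vectors whose
#' center-slice image holds at least `energyThreshold` of its spatial
#' spectral energy below `lowresBand` of the grid Nyquist frequency -- the
#' low-spatial-frequency ("non-noise") selection rule. Maps a stacked
#' real/imaginary measurement vector to the full voxel grid;
#' [reconstructFrame()] extracts the center slice.
#'
#' @slot pinv real matrix (nVoxels x 2*rows)
#' @slot retained number of singular vectors kept
#' @slot energyThreshold minimum low-frequency energy fraction
#' @slot lowresBand radial band as a fraction of Nyquist
#' @slot energyFraction low-frequency energy fraction of every vector
#' @slot singularValues all singular values of the stacked system matrix
#' @slot keep logical selection of singular vectors
#' @slot gridDim,voxelSize,zOffsets,harmonics grid/model bookkeeping
#' @export
setClass("InverseOperator",
  representation(pinv = "matrix", retained = "integer",
                 energyThreshold = "numeric", lowresBand = "numeric",
                 energyFraction = "numeric", singularValues = "numeric",
                 keep = "logical", gridDim = "integer",
                 voxelSize = "numeric", zOffsets = "numeric",
                 harmonics = "integer")
)

setValidity("InverseOperator", function(object) {
  msg <- character()
  if (object@retained < 1L) msg <- c(msg, "at least one retained vector")
  if (object@retained > min(dim(object@pinv)))
    msg <- c(msg, "retained must be <= min(rows, cols)")
  if (nrow(object@pinv) != prod(object@gridDim))
    msg <- c(msg, "pinv must map onto prod(gridDim) voxels")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Physiology / noise / GLM parameter objects
## ---------------------------------------------------------------------------

#' Hyper-/hypocapnia block protocol
#'
#' Alternating ventilation states, each lasting `stateDuration` seconds, for
#' `nCycles` full cycles, starting in `startState`. `deltaCbvFraction` is
#' the fractional CBV (and hence voxel Fe) modulation amplitude.
#'
#' @slot stateDuration seconds per capnic state (default 300)
#' @slot nCycles number of full hyper+hypo cycles (default 3)
#' @slot startState "hypo" or "hyper"
#' @slot deltaCbvFraction fractional CBV change in hypercapnia (default 0.25)
#' @export
setClass("CapniaProtocol",
  representation(stateDuration = "numeric", nCycles = "numeric",
                 startState = "character", deltaCbvFraction = "numeric")
)

setValidity("CapniaProtocol", function(object) {
  msg <- character()
  if (object@stateDuration <= 0) msg <- c(msg, "stateDuration must be > 0")
  if (!object@startState %in% c("hypo", "hyper"))
    msg <- c(msg, "startState must be 'hypo' or 'hyper'")
  if (object@deltaCbvFraction < 0 || object@deltaCbvFraction >= 1)
    msg <- c(msg, "deltaCbvFraction must be in [0, 1)")
  if (object@nCycles < 1) msg <- c(msg, "nCycles must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a CapniaProtocol
#' @param stateDuration,nCycles,startState,deltaCbvFraction see
#'   [CapniaProtocol-class]
#' @return a validated [CapniaProtocol-class]
#' @export
CapniaProtocol <- function(stateDuration = 300, nCycles = 3,
                           startState = "hypo", deltaCbvFraction = 0.25) {
  new("CapniaProtocol", stateDuration = stateDuration,
      nCycles = as.numeric(nCycles), startState = startState,
      deltaCbvFraction = deltaCbvFraction)
}

#' Measurement noise and artifact model
#'
#' Two-component noise sigma_tot = sqrt(sigma0^2 + (lambda*S)^2): additive
#' thermal noise of SD `sigma0` (A.U.) plus multiplicative per-frame gain
#' fluctuations of fractional SD `lambdaGain`. `quadrantGainDelta` is the
#' deterministic fractional gain difference between images from the two
#' half-rotations (the [10101 10101 ...] pattern with spectral lines at 0.2
#' and 0.4 cycles per sample). Optional slow drifts and an initial warm-up
#' transient complete the instrument model.
#'
#' @slot sigma0 thermal noise SD (A.U.)
#' @slot lambdaGain fractional gain-fluctuation SD
#' @slot quadrantGainDelta peak-to-peak fractional quadrant gain difference
#' @slot driftLinear linear drift (A.U./s)
#' @slot driftQuadratic quadratic drift (A.U./s^2)
#' @slot transientAmplitude warm-up transient amplitude (A.U.)
#' @slot transientTau warm-up transient time constant (s)
#' @export
setClass("NoiseModel",
  representation(sigma0 = "numeric", lambdaGain = "numeric",
                 quadrantGainDelta = "numeric", driftLinear = "numeric",
                 driftQuadratic = "numeric", transientAmplitude = "numeric",
                 transientTau = "numeric")
)

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@sigma0 < 0) msg <- c(msg, "sigma0 must be >= 0")
  if (object@lambdaGain < 0) msg <- c(msg, "lambdaGain must be >= 0")
  if (object@transientTau <= 0) msg <- c(msg, "transientTau must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a NoiseModel
#'
#' Defaults are the fitted instrument values sigma0 = 0.0133 A.U. and
#' lambda = 0.017; the quadrant gain difference defaults to 1% (the drive
#' current stability bound), drifts and transient to zero.
#'
#' @param sigma0,lambdaGain,quadrantGainDelta,driftLinear,driftQuadratic
#'   see [NoiseModel-class]
#' @param transientAmplitude,transientTau see [NoiseModel-class]
#' @return a validated [NoiseModel-class]
#' @export
NoiseModel <- function(sigma0 = 0.0133, lambdaGain = 0.017,
                       quadrantGainDelta = 0.01, driftLinear = 0,
                       driftQuadratic = 0, transientAmplitude = 0,
                       transientTau = 100) {
  new("NoiseModel", sigma0 = sigma0, lambdaGain = lambdaGain,
      quadrantGainDelta = quadrantGainDelta, driftLinear = driftLinear,
      driftQuadratic = driftQuadratic,
      transientAmplitude = transientAmplitude, transientTau = transientTau)
}

#' GLM model parameters
#'
#' @slot tau1 CO2 response function time constant (s)
#' @slot tau2 tracer blood-decay time constant (s)
#' @slot tauD warm-up transient time constant (s); by convention one third
#'   of the first activation half-period (100 s for 5 min blocks)
#' @slot deltaT activation delay (s), from the -20..+20 s grid
#' @slot mode one of "fmpi", "phantom", "bold"
#' @export
setClass("GLMParams",
  representation(tau1 = "numeric", tau2 = "numeric", tauD = "numeric",
                 deltaT = "numeric", mode = "character")
)

setValidity("GLMParams", function(object) {
  msg <- character()
  if (object@tau1 <= 0) msg <- c(msg, "tau1 must be > 0")
  if (object@tau2 <= 0) msg <- c(msg, "tau2 must be > 0")
  if (object@tauD <= 0) msg <- c(msg, "tauD must be > 0")
  if (!object@mode %in% c("fmpi", "phantom", "bold"))
    msg <- c(msg, "mode must be one of 'fmpi', 'phantom', 'bold'")
  if (length(msg)) msg else TRUE
})

#' Construct GLMParams
#'
#' Defaults are the reference hemodynamic values tau1 = 51 s, tau2 = 3100 s,
#' tauD = 100 s, no delay, fMPI mode.
#'
#' @param tau1,tau2,tauD,deltaT,mode see [GLMParams-class]
#' @return a validated [GLMParams-class]
#' @export
GLMParams <- function(tau1 = 51, tau2 = 3100, tauD = 100, deltaT = 0,
                      mode = "fmpi") {
  new("GLMParams", tau1 = tau1, tau2 = tau2, tauD = tauD,
      deltaT = deltaT, mode = mode)
}

#' Per-voxel GLM fit results
#'
#' @slot coefficients voxel-by-regressor coefficient matrix
#' @slot residualSd per-voxel residual SD, sqrt(SSR/(n-p))
#' @slot cnr per-voxel contrast-to-noise ratio (activation peak-to-peak over
#'   residual SD; the activation regressor is normalized to unit
#'   peak-to-peak, so this is beta_activation / residualSd)
#' @slot percentChange per-voxel percent signal change (dS/S, %)
#' @slot pValue two-sided t-test p-value on the activation coefficient
#' @slot tValue activation t statistic
#' @slot params the [GLMParams-class] used
#' @slot design the design matrix
#' @slot dim image dimensions c(nx, ny)
#' @slot mask in-mask indicator per voxel
#' @slot df residual degrees of freedom
#' @export
setClass("GLMFit",
  representation(coefficients = "matrix", residualSd = "numeric",
                 cnr = "numeric", percentChange = "numeric",
                 pValue = "numeric", tValue = "numeric",
                 params = "GLMParams", design = "matrix",
                 dim = "integer", mask = "logical", df = "numeric")
)

setValidity("GLMFit", function(object) {
  msg <- character()
  if (any(object@residualSd < 0, na.rm = TRUE))
    msg <- c(msg, "residualSd must be >= 0")
  if (nrow(object@coefficients) != length(object@residualSd))
    msg <- c(msg, "one residualSd per voxel required")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Metrics results
## ---------------------------------------------------------------------------

#' Dilution-series linearity fit
#'
#' @slot slope SNR per ng
#' @slot intercept SNR at zero mass
#' @slot rSquared coefficient of determination
#' @slot detectionLimitMass Fe mass (ng) at the reference SNR
#' @slot referenceSnr the SNR defining the detection limit (default 5)
#' @export
setClass("DilutionFit",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", detectionLimitMass = "numeric",
                 referenceSnr = "numeric")
)

setValidity("DilutionFit", function(object) {
  if (is.finite(object@rSquared) &&
      (object@rSquared < 0 || object@rSquared > 1))
    "rSquared must lie in [0, 1]" else TRUE
})

#' Two-component noise model fit
#'
#' @slot sigma0 fitted thermal noise SD (A.U.)
#' @slot lambdaGain fitted signal-proportional coefficient
#' @slot rSquared coefficient of determination of the variance regression
#' @export
setClass("NoiseFit",
  representation(sigma0 = "numeric", lambdaGain = "numeric",
                 rSquared = "numeric")
)

setValidity("NoiseFit", function(object) {
  if (object@sigma0 < 0 || object@lambdaGain < 0)
    "sigma0 and lambdaGain must be >= 0" else TRUE
})
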