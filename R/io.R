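## File formats and run configuration: sinogram container, NIfTI image
## series, capnia state-trace CSV, YAML run configs with schema validation.

#' Write / read a sinogram series container
#'
#' The native container is a single RDS file holding the full
#' [SinogramSeries-class] (geometry, tracer model, complex frame values,
#' timestamps and set structure) with a schema version; round-trips are
#' lossless. [exportSinogramCSV()] additionally writes an interchange CSV
#' (columns frame, angle, sample, harmonic, re, im) plus a JSON sidecar
#' with timestamps and metadata.
#'
#' @param series a [SinogramSeries-class]
#' @param path output file
#' @return `writeSinogramSeries` returns `path` invisibly;
#'   `readSinogramSeries` returns the series
#' @export
writeSinogramSeries <- function(series, path) {
  stopifnot(is(series, "SinogramSeries"))
  saveRDS(list(schemaVersion = "1.0", series = series), path)
  invisible(path)
}

#' @rdname writeSinogramSeries
#' @export
readSinogramSeries <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schemaVersion) || !is(obj$series, "SinogramSeries"))
    stop("not a sinogram series container: ", path)
  validObject(obj$series)
  obj$series
}

#' @rdname writeSinogramSeries
#' @param csvPath output CSV path; a `.json` sidecar is written next to it
#' @export
exportSinogramCSV <- function(series, csvPath) {
  d <- dim(series@values)
  idx <- expand.grid(sample = seq_len(d[2]), angle = seq_len(d[1]))
  rows <- do.call(rbind, lapply(seq_len(d[4]), function(f) {
    do.call(rbind, lapply(seq_len(d[3]), function(h) {
      v <- series@values[, , h, f]
      data.frame(frame = f, angle = rep(seq_len(d[1]), each = d[2]),
                 sample = rep(seq_len(d[2]), d[1]),
                 harmonic = series@harmonics[h],
                 re = as.vector(t(Re(v))), im = as.vector(t(Im(v))))
    }))
  }))
  utils::write.csv(rows, csvPath, row.names = FALSE)
  side <- sub("\\.csv$", ".json", csvPath)
  jsonlite::write_json(
    list(schemaVersion = "1.0", timestamps = series@timestamps,
         setIndex = series@setIndex, harmonics = series@harmonics),
    side, auto_unbox = FALSE, digits = NA)
  invisible(csvPath)
}

#' Write / read an image series as NIfTI plus JSON sidecar
#'
#' Frames are stored as a 4D NIfTI volume (x, y, 1, t) with the in-plane
#' voxel size in the header; timestamps, capnia state, set structure and
#' mask go to a JSON sidecar next to the image (same base name).
#'
#' @param series an [ImageSeries-class]
#' @param path output `.nii` / `.nii.gz` path
#' @return `writeImageSeriesNifti` returns `path` invisibly;
#'   `readImageSeriesNifti` returns the [ImageSeries-class]
#' @export
writeImageSeriesNifti <- function(series, path) {
  d <- imageDim(series)
  vs <- S4Vectors::metadata(series)$voxelSize
  nF <- ncol(series)
  arr <- array(frameMatrix(series), dim = c(d[1], d[2], 1L, nF))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vs, vs, 1, 1)
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(schemaVersion = "1.0", voxelSize = vs,
         timestamps = timestamps(series), state = capniaState(series),
         setIndex = setIndex(series), mask = as.logical(roiMask(series))),
    side, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeImageSeriesNifti
#' @export
readImageSeriesNifti <- function(path) {
  img <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  arr <- as.array(img)
  d <- dim(arr)
  ImageSeries(matrix(arr, d[1] * d[2]), timestamps = meta$timestamps,
              dim = d[1:2], voxelSize = meta$voxelSize,
              state = meta$state, setIndex = meta$setIndex,
              mask = meta$mask)
}

#' Write / read the capnia state trace CSV
#'
#' Two columns: `timestamp` (s, written to millisecond precision) and
#' `state` (1 = hypercapnia, 0 = hypocapnia), one row per switch event.
#'
#' @param trace data frame with `timestamp` and `state` columns
#' @param path CSV file path
#' @return `writeStateTrace` returns `path` invisibly; `readStateTrace`
#'   the data frame
#' @export
writeStateTrace <- function(trace, path) {
  stopifnot(all(c("timestamp", "state") %in% colnames(trace)))
  out <- data.frame(timestamp = sprintf("%.3f", trace$timestamp),
                    state = as.integer(trace$state))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeStateTrace
#' @export
readStateTrace <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df))
    stopifnot(all(c("timestamp", "state") %in% colnames(df)))
  df$timestamp <- as.numeric(df$timestamp)
  df
}

#' Switch events of a capnia protocol
#'
#' @param protocol a [CapniaProtocol-class]
#' @param delay shift applied to all events (s)
#' @return data frame of switch timestamps and the state entered
#' @export
protocolStateTrace <- function(protocol, delay = 0) {
  nStates <- 2 * protocol@nCycles
  ts <- (seq_len(nStates) - 1) * protocol@stateDuration + delay
  first <- if (protocol@startState == "hypo") 0L else 1L
  data.frame(timestamp = ts,
             state = rep(c(first, 1L - first), protocol@nCycles))
}

## --------------------------------------------------------------------------
## Run configuration (YAML)
## --------------------------------------------------------------------------

#' Default run configuration
#'
#' Nested list mirroring the YAML schema: blocks `scanner`, `spion`,
#' `phantom`, `protocol`, `noise`, `recon`, `glm`, plus `seed` and
#' `output_dir`. [readRunConfig()] loads a YAML file and merges it over
#' these defaults after validation; unknown fields or missing blocks raise
#' errors naming the offending path.
#'
#' @return the default configuration list
#' @export
defaultRunConfig <- function() {
  list(
    scanner = list(drive_frequency = 25e3, drive_amplitude = 8,
                   gradient = 2.83, fov_diameter = 30, n_angles = 27,
                   n_samples = 66, shift_frequency = 2.7,
                   shift_current = 42, rotation_rate = 0.1,
                   frame_period = 5, set_size = 5, set_gap = 5,
                   z_slices = 5, z_extent = 7),
    spion = list(moment_per_mass = 110, core_diameter = 25,
                 hydrodynamic_diameter = 70, field_scale = 2.5,
                 signal_gain = 1, blood_decay_tau = 3100),
    phantom = list(type = "brain", parenchyma_mass = 210,
                   vessel_factor = 20, top_mass = 250, n_wells = 5,
                   dilution_factor = 0.5, voxel_size = 3,
                   grid_dim = c(9, 9)),
    protocol = list(state_duration = 300, n_cycles = 3,
                    start_state = "hypo", delta_cbv_fraction = 0.25),
    noise = list(sigma0 = 0.0133, lambda_gain = 0.017,
                 quadrant_gain_delta = 0.01, drift_linear = 0,
                 drift_quadratic = 0, transient_amplitude = 0,
                 transient_tau = 100),
    recon = list(grid_dim = c(33, 33), voxel_size = 0.9,
                 harmonics = c(3, 5, 7, 9), z_slices = 1,
                 energy_threshold = 0.10, lowres_band = 0.15,
                 smoothing_fwhm = 3),
    glm = list(mode = "fmpi", tau1 = 51, tau2 = 3100,
               tau1_bounds = c(5, 300), tau2_bounds = c(600, 30000),
               delta_grid = seq(-20, 20, 5), alpha = 1e-12,
               optimize = TRUE),
    seed = 1L,
    output_dir = "fflmpi-run"
  )
}

#' @rdname defaultRunConfig
#' @param path YAML file
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname defaultRunConfig
#' @param config configuration list to validate and complete
#' @export
validateRunConfig <- function(config) {
  def <- defaultRunConfig()
  blocks <- setdiff(names(def), c("seed", "output_dir"))
  missing <- setdiff(blocks, names(config))
  if (length(missing))
    stop("configuration is missing required block(s): ",
         paste(missing, collapse = ", "))
  unknownTop <- setdiff(names(config), names(def))
  if (length(unknownTop))
    stop("unknown configuration field(s): ",
         paste(unknownTop, collapse = ", "))
  for (b in blocks) {
    unknown <- setdiff(names(config[[b]]), names(def[[b]]))
    if (length(unknown))
      stop("unknown configuration field(s): ",
           paste(paste0(b, ".", unknown), collapse = ", "))
    for (f in names(config[[b]])) {
      defv <- def[[b]][[f]]
      v <- config[[b]][[f]]
      if (is.numeric(defv) && !is.numeric(v))
        stop("configuration field ", b, ".", f, " must be numeric")
      if (is.character(defv) && !is.character(v))
        stop("configuration field ", b, ".", f, " must be a string")
    }
    config[[b]] <- utils::modifyList(def[[b]], config[[b]])
  }
  if (is.null(config$seed)) stop("configuration must set 'seed'")
  if (is.null(config$output_dir)) config$output_dir <- def$output_dir
  config
}

## builders from config blocks
configScanner <- function(cfg)
  ScannerGeometry(driveFrequency = cfg$drive_frequency,
                  driveAmplitude = cfg$drive_amplitude,
                  gradient = cfg$gradient, fovDiameter = cfg$fov_diameter,
                  nAngles = cfg$n_angles, nSamples = cfg$n_samples,
                  shiftFrequency = cfg$shift_frequency,
                  shiftCurrent = cfg$shift_current,
                  rotationRate = cfg$rotation_rate,
                  framePeriod = cfg$frame_period, setSize = cfg$set_size,
                  setGap = cfg$set_gap, zSlices = cfg$z_slices,
                  zExtent = cfg$z_extent)

configSpion <- function(cfg)
  SpionModel(momentPerMass = cfg$moment_per_mass,
             coreDiameter = cfg$core_diameter,
             hydrodynamicDiameter = cfg$hydrodynamic_diameter,
             fieldScale = cfg$field_scale, signalGain = cfg$signal_gain,
             bloodDecayTau = cfg$blood_decay_tau)

configProtocol <- function(cfg)
  CapniaProtocol(stateDuration = cfg$state_duration, nCycles = cfg$n_cycles,
                 startState = cfg$start_state,
                 deltaCbvFraction = cfg$delta_cbv_fraction)

configNoise <- function(cfg)
  NoiseModel(sigma0 = cfg$sigma0, lambdaGain = cfg$lambda_gain,
             quadrantGainDelta = cfg$quadrant_gain_delta,
             driftLinear = cfg$drift_linear,
             driftQuadratic = cfg$drift_quadratic,
             transientAmplitude = cfg$transient_amplitude,
             transientTau = cfg$transient_tau)

configPhantom <- function(cfg) {
  if (cfg$type == "brain")
    makeBrainPhantom(parenchymaMass = cfg$parenchyma_mass,
                     vesselFactor = cfg$vessel_factor,
                     voxelSize = cfg$voxel_size, gridDim = cfg$grid_dim)
  else if (cfg$type == "dilution")
    makeDilutionPhantom(topMass = cfg$top_mass, nWells = cfg$n_wells,
                        dilutionFactor = cfg$dilution_factor,
                        voxelSize = cfg$voxel_size, gridDim = cfg$grid_dim)
  else stop("unknown phantom type: ", cfg$type)
}
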