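## Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

getFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## a reduced geometry for cheap system matrices (7 angles x 10 samples)
smallGeometry <- function(...)
  ScannerGeometry(nAngles = 7, nSamples = 10, ...)

## full-size scanner with a 21 x 21 / 0.9 mm calibrated 2D reconstruction
calibratedRecon <- function() getFixture("recon21", function() {
  g <- ScannerGeometry()
  sp <- SpionModel()
  sm <- buildSystemMatrix(g, sp, gridDim = c(21, 21), voxelSize = 0.9)
  inv <- calibrateReconstruction(sm, selectSingularVectors(sm))
  list(geometry = g, spion = sp, sysmat = sm, inv = inv)
})

## small 2D system matrix on the reduced geometry (6 x 6 grid)
toySystemMatrix <- function() getFixture("toySysmat", function() {
  buildSystemMatrix(smallGeometry(), SpionModel(), gridDim = c(6, 6),
                    voxelSize = 3, harmonics = c(3L, 5L))
})

## constant-signal image series with the scanner's set structure
constantSeries <- function(value, nFrames, nVox = 1) {
  ts <- seq(5, by = 5, length.out = nFrames)
  ImageSeries(matrix(value, nVox, nFrames), timestamps = ts,
              dim = c(nVox, 1),
              setIndex = rep(seq_len(ceiling(nFrames / 5)) - 1L,
                             each = 5)[seq_len(nFrames)])
}

## standard 30 min protocol timing (300 frames, sets of 5)
standardSchedule <- function()
  getFixture("sched1800", function() frameSchedule(ScannerGeometry(), 1800))

## synthetic in/out phantom experiment: one well of `mass` ng at the image
## center, signal amplitude slope * mass * sigma0 A.U., moved in/out every
## 5 min for 30 min, corrupted with the default instrument noise model
phantomBlockSeries <- function(mass, seed, slope = 0.86, sigma0 = 0.0133) {
  sched <- standardSchedule()
  p <- CapniaProtocol()
  block <- capniaBlock(p, sched$timestamps)
  img <- matrix(0, 5, 5)
  img[3, 3] <- slope * mass * sigma0
  ser <- ImageSeries(outer(as.vector(img), block),
                     timestamps = sched$timestamps, dim = c(5, 5),
                     setIndex = sched$setIndex, state = block)
  injectNoise(ser, NoiseModel(), seed = seed)
}

## synthetic hypercapnia brain voxel series generated from the physiology
## model (tau1 = 51 s, tau2 = 3100 s) with baseline signal s0 A.U.
brainVoxelSeries <- function(noiseSd = 0, seed = 1, s0 = 1.54, delay = 0,
                             nVox = 4) {
  sched <- standardSchedule()
  p <- CapniaProtocol()
  sig <- s0 / 210 * cbvTimecourse(p, sched$timestamps, tau1 = 51,
                                  tau2 = 3100, baselineMass = 210,
                                  delay = delay)
  ser <- ImageSeries(matrix(rep(sig, each = nVox), nVox),
                     timestamps = sched$timestamps, dim = c(nVox, 1),
                     setIndex = sched$setIndex,
                     state = capniaBlock(p, sched$timestamps))
  if (noiseSd > 0)
    ser <- injectNoise(ser, NoiseModel(sigma0 = noiseSd, lambdaGain = 0,
                                       quadrantGainDelta = 0), seed = seed)
  ser
}

## local maxima of an image above a relative floor
localMaxima <- function(img, floor = 0.3) {
  n <- nrow(img); m <- ncol(img)
  out <- NULL
  for (i in 2:(n - 1)) for (j in 2:(m - 1)) {
    nb <- img[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (img[i, j] == max(nb) && img[i, j] > floor * max(img))
      out <- rbind(out, c(i, j))
  }
  out
}

## centered Gaussian blob image
gaussianBlob <- function(fwhm, n = 33, voxelSize = 0.9) {
  c0 <- (n + 1) / 2
  s <- fwhm / (2 * sqrt(2 * log(2))) / voxelSize
  outer(seq_len(n), seq_len(n), function(i, j)
    exp(-((i - c0)^2 + (j - c0)^2) / (2 * s^2)))
}
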