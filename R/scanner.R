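## Field-free-line projection physics: Langevin magnetization, harmonic
## decomposition, and sinogram acquisition.

#' Langevin magnetization function
#'
#' The equilibrium magnetization fraction of a superparamagnetic particle,
#' `coth(xi) - 1/xi`, as a function of the dimensionless field argument.
#' A series expansion (`xi/3 - xi^3/45 + 2 xi^5/945`) is used for
#' `|xi| < 1e-4` where the closed form suffers catastrophic cancellation.
#'
#' @param xi dimensionless field argument (any finite numeric vector)
#' @return magnetization fraction in (-1, 1); odd in `xi`
#' @examples
#' langevin(0)        # 0
#' langevin(1)        # 0.31304
#' langevin(1e6)      # ~1 (saturation)
#' @export
langevin <- function(xi) {
  out <- numeric(length(xi))
  small <- abs(xi) < 1e-4
  x <- xi[small]
  out[small] <- x / 3 - x^3 / 45 + 2 * x^5 / 945
  x <- xi[!small]
  out[!small] <- 1 / tanh(x) - 1 / x
  out
}

## L(xi)/xi, finite and smooth through xi = 0 (limit 1/3)
langevinRatio <- function(xi) {
  out <- numeric(length(xi))
  small <- abs(xi) < 1e-4
  x <- xi[small]
  out[small] <- 1 / 3 - x^2 / 45 + 2 * x^4 / 945
  x <- xi[!small]
  out[!small] <- (1 / tanh(x) - 1 / x) / x
  out
}

#' Projection angles and FFL shift offsets of a geometry
#'
#' Angles uniformly span the half rotation (a projection and its reverse are
#' equivalent); shift offsets are `nSamples` uniformly spaced FFL
#' displacements spanning the field of view.
#'
#' @param geometry a [ScannerGeometry-class]
#' @return numeric vector of angles (rad) / offsets (mm)
#' @export
projectionAngles <- function(geometry)
  pi * (seq_len(geometry@nAngles) - 1) / geometry@nAngles

#' @rdname projectionAngles
#' @export
shiftOffsets <- function(geometry) {
  n <- geometry@nSamples
  (seq_len(n) - (n + 1) / 2) * sampleSpacing(geometry)
}

#' Instantaneous local magnetic field
#'
#' Field at a point for one FFL configuration: the divergence-consistent
#' selection field `G * (s * s_hat - z * z_hat)` -- where `s` is the signed
#' in-plane distance from the FFL (line direction set by `angle`, translated
#' by `shiftOffset`) -- plus the uniform drive field along z,
#' `driveAmplitude * sin(2 pi f0 t)`.
#'
#' @param position length-3 position (mm) relative to the rotation axis
#' @param angle FFL line direction (rad)
#' @param shiftOffset FFL in-plane translation (mm)
#' @param geometry a [ScannerGeometry-class]
#' @param t time (s); drive phase is `2 pi f0 t`
#' @return field 3-vector (mT) in lab coordinates (x, y, z)
#' @examples
#' g <- ScannerGeometry()
#' localField(c(0, 0, 0), 0, 0, g, 0)       # zero on the line
#' localField(c(0, 1, 0), 0, 0, g, 0)       # 2.83 mT, 1 mm off-line
#' @export
localField <- function(position, angle, shiftOffset, geometry, t = 0) {
  stopifnot(length(position) == 3L, all(is.finite(position)))
  sHat <- c(-sin(angle), cos(angle), 0)
  s <- sum(position[1:2] * sHat[1:2]) - shiftOffset
  drive <- geometry@driveAmplitude *
    sin(2 * pi * geometry@driveFrequency * t)
  geometry@gradient * (s * sHat - c(0, 0, position[3])) + c(0, 0, drive)
}

## One drive period sampled at nT points with the half-wave antisymmetry of
## the sine enforced exactly (so the even-harmonic null at z = 0 is exact in
## floating point).
drivePhaseWave <- function(nT) {
  w <- sin(2 * pi * (seq_len(nT) - 1) / nT)
  if (nT %% 2 == 0) {
    h <- nT / 2
    w[(h + 1):nT] <- -w[1:h]
    w[h + 1] <- 0
  }
  w
}

## Core harmonic simulator, vectorized over (s, z) pairs.
## s: signed in-plane distance from the FFL (mm); z: through-plane (mm).
## Returns a complex matrix length(s) x length(harmonics): per-unit-mass
## (1 ng) harmonic amplitudes of the received dMz/dt signal, with the common
## 2*pi*f0 factor absorbed into spion@signalGain.
harmonicResponse <- function(s, z, geometry, spion, harmonics,
                             nTimesteps = 256) {
  stopifnot(length(s) == length(z))
  if (nTimesteps < 64)
    stop("nTimesteps must be >= 64 per drive period (aliasing guard)")
  nT <- as.integer(nTimesteps)
  P <- length(s)
  drive <- geometry@driveAmplitude * drivePhaseWave(nT)      # mT, 1 x nT
  bPerp <- geometry@gradient * s                             # mT, per pair
  bz0 <- -geometry@gradient * z
  ## P x nT field components
  Bz <- outer(bz0, rep(1, nT)) + outer(rep(1, P), drive)
  Bmag <- sqrt(bPerp^2 + Bz^2)
  xi <- Bmag / spion@fieldScale
  Mz <- matrix(langevinRatio(xi), P, nT) * Bz / spion@fieldScale
  ## DFT over the period; derivative in the frequency domain contributes a
  ## factor i*k (2*pi*f0 absorbed into the gain).
  k <- as.integer(harmonics)
  W <- exp(-2i * pi * outer((seq_len(nT) - 1) / nT, k))      # nT x nH
  coefs <- (Mz %*% W) * (2 / nT)
  sweep(coefs, 2L, 1i * k, `*`) * spion@signalGain
}

#' Harmonic amplitudes of a single point source
#'
#' Simulates one drive period of the magnetization of `feMass` ng of tracer
#' at a position, for one FFL configuration, and returns the complex
#' harmonic amplitudes of the received (dM/dt) signal. Amplitudes are exactly
#' linear in `feMass`.
#'
#' @param feMass tracer mass (ng), >= 0
#' @param position length-3 position (mm)
#' @param angle FFL direction (rad)
#' @param shiftOffset FFL translation (mm)
#' @param geometry a [ScannerGeometry-class]
#' @param spion a [SpionModel-class]
#' @param nTimesteps samples per drive period (>= 64; default 256)
#' @param harmonics integer harmonic orders to return (default 2:9)
#' @return named complex vector of harmonic amplitudes (A.U.)
#' @examples
#' g <- ScannerGeometry(); sp <- SpionModel()
#' simulateVoxelSignal(210, c(0, 0, 0), 0, 0, g, sp)   # odd harmonics only
#' @export
simulateVoxelSignal <- function(feMass, position, angle, shiftOffset,
                                geometry, spion, nTimesteps = 256,
                                harmonics = 2:9) {
  stopifnot(feMass >= 0, length(position) == 3L)
  sHat <- c(-sin(angle), cos(angle))
  s <- sum(position[1:2] * sHat) - shiftOffset
  amp <- harmonicResponse(s, position[3], geometry, spion,
                          harmonics, nTimesteps)
  stats::setNames(feMass * amp[1, ], paste0("h", harmonics))
}

#' Tabulated harmonic response for fast acquisition
#'
#' Precomputes the per-unit-mass harmonic response on a fine grid of signed
#' in-plane FFL distances for each requested z offset, and wraps it in
#' spline interpolators. [acquireFrame()] and [buildSystemMatrix()] evaluate
#' sources through this table, which keeps the forward model exactly linear
#' and makes repeated acquisition cheap.
#'
#' @param geometry a [ScannerGeometry-class]
#' @param spion a [SpionModel-class]
#' @param harmonics integer harmonic orders
#' @param zOffsets z positions (mm) to tabulate
#' @param sMax half-range of tabulated distances (mm); defaults to
#'   1.25 * fovDiameter, beyond which the response is treated as zero
#' @param nS number of distance samples (default 751)
#' @param nTimesteps samples per drive period (default 256)
#' @return an object of class `"HarmonicResponseTable"`
#' @export
harmonicResponseTable <- function(geometry, spion, harmonics,
                                  zOffsets = 0, sMax = NULL, nS = 751,
                                  nTimesteps = 256) {
  if (length(harmonics) < 1L) stop("at least one harmonic order is required")
  if (is.null(sMax)) sMax <- 1.25 * geometry@fovDiameter
  sGrid <- seq(-sMax, sMax, length.out = nS)
  zOffsets <- sort(unique(zOffsets))
  nH <- length(harmonics)
  nZ <- length(zOffsets)
  tab <- array(0i, dim = c(nS, nZ, nH))
  splines <- vector("list", nZ)
  for (zi in seq_len(nZ)) {
    amp <- harmonicResponse(sGrid, rep(zOffsets[zi], nS), geometry, spion,
                            harmonics, nTimesteps)
    tab[, zi, ] <- amp
    splines[[zi]] <- lapply(seq_len(nH), function(hi) list(
      re = stats::splinefun(sGrid, Re(amp[, hi]), method = "fmm"),
      im = stats::splinefun(sGrid, Im(amp[, hi]), method = "fmm")))
  }
  structure(list(sGrid = sGrid, sMax = sMax, zOffsets = zOffsets,
                 harmonics = as.integer(harmonics), table = tab,
                 splines = splines, nTimesteps = nTimesteps),
            class = "HarmonicResponseTable")
}

## Evaluate the tabulated response: complex vector for one (z, harmonic)
## at arbitrary distances (zero outside the tabulated range).
evalResponse <- function(response, s, zIndex, hIndex) {
  sp <- response$splines[[zIndex]][[hIndex]]
  out <- complex(real = sp$re(s), imaginary = sp$im(s))
  out[abs(s) > response$sMax] <- 0i
  out
}

## match z values against tabulated offsets (tolerance 1e-9 mm)
matchZ <- function(response, z) {
  idx <- vapply(z, function(zz) {
    d <- abs(response$zOffsets - zz)
    i <- which.min(d)
    if (d[i] > 1e-9) NA_integer_ else i
  }, integer(1))
  if (anyNA(idx))
    stop("response table does not cover z = ",
         paste(unique(z[is.na(idx)]), collapse = ", "), " mm")
  idx
}

## voxel center coordinates (mm) of a TracerMap
voxelCenters <- function(tracer) {
  d <- dim(tracer@grid)
  vs <- tracer@voxelSize
  ax <- function(n, v, o) (seq_len(n) - (n + 1) / 2) * v + o
  list(x = ax(d[1], vs[1], tracer@origin[1]),
       y = ax(d[2], vs[2], tracer@origin[2]),
       z = ax(d[3], vs[3], tracer@origin[3]))
}

## Forward response matrix for arbitrary source positions:
## (nAngles*nSamples*nHarmonics) x nPositions complex matrix.
## Row order: angle fastest... we fix: index = angle + nA*(sample-1) +
## nA*nS*(harmonic-1)? Use a fixed convention: sample index varies fastest
## within an angle block, harmonics outermost:
## row = (h-1)*nA*nS + (a-1)*nS + j.
forwardResponse <- function(x, y, z, geometry, spion, harmonics,
                            response = NULL) {
  nP <- length(x)
  stopifnot(length(y) == nP, length(z) == nP)
  if (is.null(response))
    response <- harmonicResponseTable(geometry, spion, harmonics,
                                      zOffsets = unique(z))
  if (!identical(as.integer(harmonics), response$harmonics))
    stop("response table harmonics do not match requested harmonics")
  zIdx <- matchZ(response, z)
  angles <- projectionAngles(geometry)
  offs <- shiftOffsets(geometry)
  nA <- length(angles); nS <- length(offs); nH <- length(harmonics)
  out <- matrix(0i, nrow = nA * nS * nH, ncol = nP)
  ## signed in-plane distance of every position from the (unshifted) FFL,
  ## per angle: d = -x sin(theta) + y cos(theta)
  D <- outer(-sin(angles), x) + outer(cos(angles), y)     # nA x nP
  for (zi in unique(zIdx)) {
    cols <- which(zIdx == zi)
    for (a in seq_len(nA)) {
      ## s values: nS x length(cols)
      sv <- outer(offs, rep(1, length(cols)))
      sv <- sweep(-sv, 2L, D[a, cols], `+`)
      for (hi in seq_len(nH)) {
        rows <- (hi - 1L) * nA * nS + (a - 1L) * nS + seq_len(nS)
        out[rows, cols] <- evalResponse(response, as.vector(sv), zi, hi)
      }
    }
  }
  out
}

#' Acquire one harmonic-resolved sinogram frame
#'
#' Sums the tabulated point-source response over all nonzero voxels of a
#' tracer map for every projection angle and FFL shift offset. The
#' acquisition is exactly additive (linear) in the tracer map.
#'
#' @param tracer a [TracerMap-class]; all in-plane voxel centers must lie
#'   within the field of view
#' @param geometry a [ScannerGeometry-class]
#' @param spion a [SpionModel-class]
#' @param timestamp frame time (s)
#' @param harmonics integer harmonic orders (default `c(3, 5, 7, 9)`, the
#'   2D odd-harmonic set)
#' @param response optional precomputed [harmonicResponseTable()] covering
#'   the tracer's z planes
#' @return a [SinogramFrame-class]
#' @export
acquireFrame <- function(tracer, geometry, spion, timestamp = 0,
                         harmonics = c(3L, 5L, 7L, 9L), response = NULL) {
  ctr <- voxelCenters(tracer)
  nz <- which(tracer@grid > 0, arr.ind = TRUE)
  nA <- geometry@nAngles; nS <- geometry@nSamples
  nH <- length(harmonics)
  vals <- array(0i, dim = c(nA, nS, nH))
  if (nrow(nz) > 0L) {
    x <- ctr$x[nz[, 1]]; y <- ctr$y[nz[, 2]]; z <- ctr$z[nz[, 3]]
    r <- sqrt(x^2 + y^2)
    if (any(r > geometry@fovDiameter / 2 + 1e-9)) {
      bad <- which.max(r)
      stop(sprintf(
        "tracer voxel at (%.2f, %.2f, %.2f) mm lies outside the %g mm FOV",
        x[bad], y[bad], z[bad], geometry@fovDiameter))
    }
    if (is.null(response))
      response <- harmonicResponseTable(geometry, spion, harmonics,
                                        zOffsets = unique(z))
    fw <- forwardResponse(x, y, z, geometry, spion, harmonics, response)
    masses <- tracer@grid[nz]
    meas <- as.vector(fw %*% masses)
    ## rows: sample fastest, then angle, then harmonic -> reorder to a x s x h
    vals <- aperm(array(meas, dim = c(nS, nA, nH)), c(2, 1, 3))
  }
  new("SinogramFrame", values = vals, harmonics = as.integer(harmonics),
      timestamp = timestamp)
}

#' Frame acquisition schedule
#'
#' End-of-acquisition timestamps and 0-based set indices of every frame
#' completing within `duration`, following the set/gap structure (sets of
#' `setSize` frames of `framePeriod` seconds, separated by `setGap`).
#'
#' @param geometry a [ScannerGeometry-class]
#' @param duration total wall-clock time (s)
#' @return list with `timestamps` (s) and `setIndex`
#' @examples
#' s <- frameSchedule(ScannerGeometry(), 1800)
#' length(s$timestamps)   # 300 frames in 30 min at an 83% duty cycle
#' @export
frameSchedule <- function(geometry, duration) {
  setPeriod <- geometry@setSize * geometry@framePeriod + geometry@setGap
  nSets <- ceiling(duration / setPeriod) + 1L
  ts <- numeric(0); si <- integer(0)
  for (k in seq_len(nSets) - 1L) {
    t0 <- k * setPeriod
    tf <- t0 + geometry@framePeriod * seq_len(geometry@setSize)
    keep <- tf <= duration + 1e-9
    ts <- c(ts, tf[keep]); si <- c(si, rep(k, sum(keep)))
  }
  list(timestamps = ts, setIndex = as.integer(si))
}

#' Acquire a sinogram time series
#'
#' Frames are spaced `framePeriod` apart in sets of `setSize`, separated by
#' `setGap` (the half-rotation re-trigger pause), giving the scanner's 83%
#' duty cycle at defaults. Timestamps are end-of-acquisition times.
#' Projections within a frame are treated as simultaneous: object dynamics
#' are slow relative to the 5 s frame.
#'
#' @param tracer either a static [TracerMap-class] or a function
#'   `function(t)` returning the TracerMap at time `t`
#' @param geometry a [ScannerGeometry-class]
#' @param spion a [SpionModel-class]
#' @param duration total wall-clock time (s)
#' @param harmonics integer harmonic orders
#' @param scale optional function `function(t)` returning a scalar
#'   multiplier applied to a static `tracer` at each frame time (fast path:
#'   by linearity the map is acquired once and rescaled)
#' @param response optional precomputed [harmonicResponseTable()]
#' @return a [SinogramSeries-class]
#' @export
acquireSeries <- function(tracer, geometry, spion, duration,
                          harmonics = c(3L, 5L, 7L, 9L), scale = NULL,
                          response = NULL) {
  stopifnot(duration > 0)
  sched <- frameSchedule(geometry, duration)
  nF <- length(sched$timestamps)
  nA <- geometry@nAngles; nS <- geometry@nSamples; nH <- length(harmonics)
  vals <- array(0i, dim = c(nA, nS, nH, nF))
  if (is(tracer, "TracerMap") && (is.null(scale) || is.function(scale))) {
    base <- acquireFrame(tracer, geometry, spion, 0, harmonics, response)
    for (i in seq_len(nF)) {
      f <- if (is.null(scale)) 1 else scale(sched$timestamps[i])
      vals[, , , i] <- base@values * f
    }
  } else if (is.function(tracer)) {
    for (i in seq_len(nF)) {
      fr <- acquireFrame(tracer(sched$timestamps[i]), geometry, spion,
                         sched$timestamps[i], harmonics, response)
      vals[, , , i] <- fr@values
    }
  } else stop("'tracer' must be a TracerMap or a function of time")
  new("SinogramSeries", values = vals, harmonics = as.integer(harmonics),
      timestamps = sched$timestamps, setIndex = sched$setIndex,
      geometry = geometry, spion = spion)
}

#' Extract one frame of a sinogram series
#'
#' @param series a [SinogramSeries-class]
#' @param i frame number (1-based)
#' @return a [SinogramFrame-class]
#' @export
sinogramFrame <- function(series, i) {
  stopifnot(i >= 1, i <= dim(series@values)[4])
  vals <- series@values[, , , i, drop = FALSE]
  dim(vals) <- dim(vals)[1:3]
  new("SinogramFrame", values = vals,
      harmonics = series@harmonics, timestamp = series@timestamps[i])
}
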