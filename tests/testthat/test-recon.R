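test_that("system matrix shape follows geometry and harmonic choice", {
  g <- ScannerGeometry(); sp <- SpionModel()
  ## 2D mode, odd harmonics, one slice: 27*66*4 = 7128 measurement rows
  sm <- buildSystemMatrix(g, sp, gridDim = c(5, 5), voxelSize = 3,
                          harmonics = c(3L, 5L, 7L, 9L))
  expect_equal(nrow(sm@matrix), 27 * 66 * 4)
  expect_equal(ncol(sm@matrix), 25)
  ## 3D mode, harmonics [2, 3], 5 slices: 27*66*2 rows, 25*5 columns
  sm3 <- buildSystemMatrix(g, sp, gridDim = c(5, 5), voxelSize = 3,
                           harmonics = c(2L, 3L), zSlices = 5)
  expect_equal(nrow(sm3@matrix), 27 * 66 * 2)
  expect_equal(ncol(sm3@matrix), 125)
  expect_error(buildSystemMatrix(g, sp, harmonics = integer(0)),
               "harmonic")
  expect_error(buildSystemMatrix(g, sp, gridDim = c(50, 50),
                                 voxelSize = 0.9), "field of view")
  ## column = acquisition response of a unit source at that voxel
  tab <- harmonicResponseTable(g, sp, c(3L, 5L, 7L, 9L), zOffsets = 0)
  smc <- buildSystemMatrix(g, sp, gridDim = c(5, 5), voxelSize = 3,
                           harmonics = c(3L, 5L, 7L, 9L), response = tab)
  src <- makeDilutionPhantom(1, 1, voxelSize = 3, gridDim = c(5, 5))
  fr <- acquireFrame(src, g, sp, response = tab)
  centerCol <- smc@matrix[, 13]
  meas <- as.vector(aperm(fr@values, c(2, 1, 3)))
  expect_equal(centerCol, meas, tolerance = 1e-14)
})

test_that("singular-vector selection obeys the low-frequency energy rule", {
  sm <- toySystemMatrix()
  A <- rbind(Re(sm@matrix), Im(sm@matrix))
  ## threshold 0 retains everything: operator equals the full pseudoinverse
  invAll <- selectSingularVectors(sm, energyThreshold = 0)
  expect_equal(retainedVectors(invAll), ncol(A))
  y <- sin(seq_len(nrow(A)))
  expect_equal(as.vector(invAll@pinv %*% y),
               as.vector(qr.solve(crossprod(A), crossprod(A, y))),
               tolerance = 1e-8)
  ## a pure-DC spatial vector has 100% low-frequency energy
  dc <- rep(1 / 6, 36)
  expect_equal(fflmpi:::lowFreqEnergyFraction(dc, c(6L, 6L, 1L), 0.15), 1)
  ## retained count is non-increasing in the threshold
  r <- vapply(c(0, 0.02, 0.05, 0.1, 0.3, 0.6), function(th)
    retainedVectors(selectSingularVectors(sm, energyThreshold = th,
                                          lowresBand = 0.5)), integer(1))
  expect_true(all(diff(r) <= 0))
  ## all vectors rejected -> actionable error
  expect_error(selectSingularVectors(sm, energyThreshold = 1.1),
               "relax")
  ## fixed-count override
  inv5 <- selectSingularVectors(sm, retainCount = 5)
  expect_equal(retainedVectors(inv5), 5L)
})

test_that("truncated pseudoinverse agrees with the subspace least-squares oracle", {
  ## oracle: minimize |A x - y| over x restricted to span of the retained
  ## right singular vectors, solved by explicit QR on A V_r
  sm <- toySystemMatrix()
  A <- rbind(Re(sm@matrix), Im(sm@matrix))
  sv <- svd(A)
  for (th in c(0.05, 0.1, 0.3)) {
    inv <- selectSingularVectors(sm, energyThreshold = th, lowresBand = 0.5)
    Vk <- sv$v[, inv@keep, drop = FALSE]
    set.seed(2)
    y <- rnorm(nrow(A))
    xOracle <- Vk %*% qr.solve(A %*% Vk, y)
    xPkg <- inv@pinv %*% y
    expect_lt(max(abs(xPkg - xOracle)), 1e-8 * max(abs(xOracle)))
  }
})

test_that("frame reconstruction is linear and localizes sources", {
  fx <- calibratedRecon()
  g <- fx$geometry; sp <- fx$spion; inv <- fx$inv
  ## zero sinogram -> zero image
  zero <- new("SinogramFrame",
              values = array(0i, c(27, 66, 4)),
              harmonics = c(3L, 5L, 7L, 9L), timestamp = 0)
  expect_true(all(reconstructFrame(zero, inv) == 0))
  ## noiseless centered point source: argmax at the source voxel
  src <- makeDilutionPhantom(100, 1)
  fr <- acquireFrame(src, g, sp)
  img <- reconstructFrame(fr, inv)
  expect_equal(which.max(img), (11 - 1) * 21 + 11)
  ## exact linearity
  fr2 <- fr; fr2@values <- 2.5 * fr@values
  expect_equal(reconstructFrame(fr2, inv), 2.5 * img, tolerance = 1e-13)
  ## two equal sources 12 mm apart resolve into two local maxima at their
  ## positions (fixed-count retention, the instrument's operating point)
  inv198 <- selectSingularVectors(fx$sysmat, retainCount = 198)
  ph2 <- makeDilutionPhantom(1, 2, 1,
                             wellPositions = matrix(c(-6, 0, 6, 0), 2,
                                                    byrow = TRUE))
  img2 <- reconstructFrame(acquireFrame(ph2, g, sp), inv198)
  lm2 <- localMaxima(img2)
  expect_equal(nrow(lm2), 2)
  xs <- sort((lm2[, 1] - 11) * 0.9)
  expect_lt(max(abs(xs - c(-6, 6))), 1)
  expect_true(all(abs((lm2[, 2] - 11) * 0.9) < 1))
})

test_that("out-of-plane sources are suppressed in the center slice", {
  g <- smallGeometry(); sp <- SpionModel()
  sm <- buildSystemMatrix(g, sp, gridDim = c(9, 9), voxelSize = 2,
                          harmonics = c(2L, 3L), zSlices = 5)
  inv <- selectSingularVectors(sm, energyThreshold = 0.05, lowresBand = 0.4)
  tab <- harmonicResponseTable(g, sp, c(2L, 3L), zOffsets = c(0, 2))
  mk <- function(z) TracerMap(array(100, c(1, 1, 1)), voxelSize = 1,
                              origin = c(0, 0, z))
  p0 <- max(reconstructFrame(
    acquireFrame(mk(0), g, sp, harmonics = c(2L, 3L), response = tab), inv))
  p2 <- max(reconstructFrame(
    acquireFrame(mk(2), g, sp, harmonics = c(2L, 3L), response = tab), inv))
  expect_lt(p2, p0)
})

test_that("gaussian smoothing preserves flux and sets the stated width", {
  img <- gaussianBlob(3)
  expect_identical(smoothImage(img, 0, 0.9), img)
  sm <- smoothImage(img, 3, 0.9)
  expect_lt(abs(sum(sm) - sum(img)) / sum(img), 1e-6)
  ## delta input: output FWHM 3 mm within half a voxel
  d <- matrix(0, 33, 33); d[17, 17] <- 1
  expect_equal(measurePsfFwhm(smoothImage(d, 3, 0.9), 0.9), 3,
               tolerance = 0.45 / 3)
})

test_that("PSF width measurement recovers known blob widths", {
  expect_equal(measurePsfFwhm(gaussianBlob(3.0), 0.9), 3.0,
               tolerance = 0.1 / 3)
  expect_equal(measurePsfFwhm(gaussianBlob(2.55), 0.9), 2.55,
               tolerance = 0.1 / 2.55)
  ## reconstructed simulator point source: record the pipeline value and
  ## check it is a physically sensible width for this operator
  fx <- calibratedRecon()
  img <- reconstructFrame(
    acquireFrame(makeDilutionPhantom(100, 1), fx$geometry, fx$spion),
    fx$inv)
  fw <- measurePsfFwhm(img, 0.9)
  expect_gt(fw, 1); expect_lt(fw, 10)
})
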