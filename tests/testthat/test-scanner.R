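test_that("langevin matches the closed form and its limits", {
  ## independent oracle: coth(x) - 1/x via the exponential form
  oracle <- function(x) (exp(2 * x) + 1) / (exp(2 * x) - 1) - 1 / x
  expect_identical(langevin(0), 0)
  expect_equal(langevin(1), oracle(1), tolerance = 1e-14)
  expect_equal(langevin(1), 0.3130352854993312, tolerance = 1e-12)
  expect_gt(langevin(1e6), 0.999)
  ## odd symmetry, exact
  x <- c(1e-6, 1e-4, 0.01, 0.5, 1, 3, 10, 50)
  expect_identical(langevin(-x), -langevin(x))
  ## strictly inside (-1, 1) and monotone
  xs <- seq(-30, 30, length.out = 401)
  L <- langevin(xs)
  expect_true(all(L > -1 & L < 1))
  expect_true(all(diff(L) > 0))
  ## the series branch and the closed form agree across the switch point
  ## (both sit on L(x)/x = 1/3 + O(x^2) in this regime)
  xs <- seq(0.5e-4, 2e-4, length.out = 301)
  expect_lt(max(abs(langevin(xs) / xs - 1 / 3)), 1e-7)
  expect_true(all(diff(langevin(xs)) > 0))
})

test_that("localField reproduces the FFL selection-field geometry", {
  g <- ScannerGeometry()
  ## on the line at z = 0 with the drive at a zero crossing: zero field
  expect_equal(localField(c(0, 0, 0), 0, 0, g, 0), c(0, 0, 0))
  ## 1 mm off-line in plane: gradient strength in mT
  expect_equal(sqrt(sum(localField(c(0, 1, 0), 0, 0, g, 0)^2)), 2.83,
               tolerance = 1e-12)
  ## z = 2 mm on the line: purely axial, twice the gradient
  B <- localField(c(0, 0, 2), 0, 0, g, 0)
  expect_equal(B[1:2], c(0, 0))
  expect_equal(abs(B[3]), 2 * 2.83, tolerance = 1e-12)
  ## drive field adds along z at amplitude driveAmplitude
  tQuarter <- 1 / (4 * g@driveFrequency)
  Bd <- localField(c(0, 0, 0), 0, 0, g, tQuarter)
  expect_equal(Bd[3], 8, tolerance = 1e-9)
  ## shift offset translates the line
  expect_equal(localField(c(0, 3, 0), 0, 3, g, 0), c(0, 0, 0),
               tolerance = 1e-12)
})

test_that("voxel harmonics: even-harmonic null at z = 0, mass linearity", {
  g <- ScannerGeometry(); sp <- SpionModel()
  expect_identical(
    unname(Mod(simulateVoxelSignal(0, c(1, 2, 0), 0.3, 1, g, sp))),
    rep(0, 8))
  ## even-harmonic null for any in-plane position / angle / shift
  set.seed(11)
  for (k in 1:8) {
    pos <- c(runif(2, -8, 8), 0)
    v <- simulateVoxelSignal(210, pos, runif(1, 0, pi), runif(1, -5, 5),
                             g, sp)
    even <- max(Mod(v[c("h2", "h4", "h6", "h8")]))
    odd <- max(Mod(v[c("h3", "h5", "h7", "h9")]))
    expect_lt(even, 1e-10 * odd)
  }
  ## off-plane source breaks the antisymmetry: 2nd harmonic appears
  v2 <- simulateVoxelSignal(210, c(1, 2, 2), 0.3, 1, g, sp)
  expect_gt(Mod(v2["h2"]), 1e-3 * Mod(v2["h3"]))
  ## exact linearity in mass
  v1 <- simulateVoxelSignal(1, c(1, 2, 1), 0.3, 1, g, sp)
  v210 <- simulateVoxelSignal(210, c(1, 2, 1), 0.3, 1, g, sp)
  expect_identical(v210, 210 * v1)
  ## aliasing guard
  expect_error(simulateVoxelSignal(1, c(0, 0, 0), 0, 0, g, sp,
                                   nTimesteps = 32), "64")
})

test_that("acquireFrame is linear, additive, and geometry-consistent", {
  g <- ScannerGeometry(); sp <- SpionModel()
  empty <- TracerMap(array(0, c(3, 3, 1)), voxelSize = 3)
  expect_true(all(acquireFrame(empty, g, sp)@values == 0))
  phA <- makeDilutionPhantom(250, 1)
  phB <- makeDilutionPhantom(125, 2)
  both <- TracerMap(tracerGrid(phA) + tracerGrid(phB), voxelSize = 3)
  tab <- harmonicResponseTable(g, sp, c(3L, 5L, 7L, 9L), zOffsets = 0)
  fA <- acquireFrame(phA, g, sp, response = tab)
  fB <- acquireFrame(phB, g, sp, response = tab)
  fAB <- acquireFrame(both, g, sp, response = tab)
  expect_lt(max(Mod(fAB@values - fA@values - fB@values)),
            1e-12 * max(Mod(fAB@values)))
  ## scalar homogeneity
  scaled <- TracerMap(3.5 * tracerGrid(phA), voxelSize = 3)
  fS <- acquireFrame(scaled, g, sp, response = tab)
  expect_equal(fS@values, 3.5 * fA@values, tolerance = 1e-14)
  ## centered point source: 3rd-harmonic projection peaks centrally at
  ## every angle
  p3 <- Mod(fA@values[, , 1])
  peaks <- apply(p3, 1, which.max)
  expect_true(all(peaks %in% c(33, 34)))
  ## total 3rd-harmonic energy monotone in source mass
  e <- vapply(c(10, 50, 100, 250), function(m) {
    fr <- acquireFrame(makeDilutionPhantom(m, 1), g, sp, response = tab)
    sum(Mod(fr@values[, , 1])^2)
  }, numeric(1))
  expect_true(all(diff(e) > 0))
  ## out-of-FOV tracer is rejected, naming the voxel position
  far <- TracerMap(array(c(rep(0, 8), 1), c(3, 3, 1)), voxelSize = 3,
                   origin = c(12, 12, 0))
  expect_error(acquireFrame(far, g, sp, response = tab), "FOV")
})

test_that("acquireSeries reproduces the set/gap timing and duty cycle", {
  g <- ScannerGeometry(); sp <- SpionModel()
  expect_equal(dutyCycle(g), 25 / 30, tolerance = 1e-12)
  s30 <- frameSchedule(g, 30)
  expect_length(s30$timestamps, 5)
  expect_equal(s30$timestamps, c(5, 10, 15, 20, 25))
  s1800 <- frameSchedule(g, 1800)
  expect_length(s1800$timestamps, 300)
  expect_equal(max(s1800$timestamps), 1795)
  expect_equal(max(s1800$setIndex), 59)
  ## constant tracer: all frames identical (noiseless path)
  ph <- makeDilutionPhantom(50, 1)
  ser <- acquireSeries(ph, g, sp, 60)
  expect_equal(dim(ser@values)[4], 10)
  for (i in 2:10)
    expect_identical(ser@values[, , , i], ser@values[, , , 1])
  ## a scale function modulates frames by linearity
  ser2 <- acquireSeries(ph, g, sp, 60, scale = function(t) t / 10)
  expect_equal(ser2@values[, , , 2],
               ser@values[, , , 1] * ser2@timestamps[2] / 10,
               tolerance = 1e-14)
})
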