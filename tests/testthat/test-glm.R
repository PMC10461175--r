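test_that("CO2 response kernel has the stated shape", {
  expect_equal(co2rf(0, 51), 0)
  expect_equal(co2rf(-5, 51), 0)
  ## argmax at t = tau1 (within one sample on a 1 s grid)
  tt <- seq(0, 500, by = 1)
  expect_equal(tt[which.max(co2rf(tt, 51))], 51, tolerance = 1)
  ## closed-form ratio co2rf(2 tau1) / co2rf(tau1) = 2 exp(-1)
  expect_equal(co2rf(102, 51) / co2rf(51, 51), 2 * exp(-1),
               tolerance = 1e-12)
  expect_error(co2rf(1, 0), "tau1")
})

test_that("activation regressor respects the GLM mode variants", {
  p <- CapniaProtocol()
  ts <- standardSchedule()$timestamps
  ## phantom mode: the shifted block itself (unit peak-to-peak)
  rp <- activationRegressor(p, ts, GLMParams(mode = "phantom"))
  expect_identical(as.numeric(rp), capniaBlock(p, ts))
  expect_equal(attr(rp, "pkpk"), 1)
  ## no decay: long plateaus approach 0/1 after unit-gain normalization
  pLong <- CapniaProtocol(stateDuration = 3000, nCycles = 1)
  tsL <- seq(0, 5995, by = 5)
  rb <- activationRegressor(pLong, tsL, GLMParams(mode = "bold"))
  expect_equal(max(rb), max(rb) - min(rb) + min(rb))
  expect_lt(abs(min(rb)), 0.02)
  expect_gt(max(rb), 0.98)
  ## fmpi decay shrinks later cycles relative to the first
  rf <- activationRegressor(p, ts, GLMParams(tau2 = 1500))
  firstPeak <- max(rf[ts < 700]); lastPeak <- max(rf[ts > 1300])
  expect_gt(firstPeak, lastPeak)
  ## a block that never switches within the sampled window is degenerate
  expect_error(
    activationRegressor(CapniaProtocol(stateDuration = 1e5),
                        ts, GLMParams(mode = "phantom")),
    "degenerate")
})

test_that("design matrix has the documented columns and full rank", {
  p <- CapniaProtocol()
  ts <- standardSchedule()$timestamps
  X <- buildDesign(ts, GLMParams(), p)
  expect_equal(colnames(X), c("activation", "constant", "linear",
                              "quadratic", "transient"))
  expect_equal(qr(X)$rank, 5)
  Xp <- buildDesign(ts, GLMParams(mode = "phantom"), p)
  expect_equal(ncol(Xp), 6)
  expect_equal(colnames(Xp)[6], "conditionalDrift")
  expect_equal(qr(Xp)$rank, 6)
  ## trend columns are centered and unit range
  expect_equal(max(X[, "linear"]) - min(X[, "linear"]), 1)
  expect_lt(abs(mean(X[, "linear"])), 1e-12)
  expect_error(buildDesign(ts[1:4], GLMParams(), p), "frames")
})

test_that("voxel OLS is exact on noiseless data and unbiased under noise", {
  p <- CapniaProtocol()
  sched <- standardSchedule()
  X <- buildDesign(sched$timestamps, GLMParams(), p)
  ## pure constant
  f0 <- fitVoxel(rep(3, nrow(X)), X)
  expect_equal(unname(f0$betas), c(0, 3, 0, 0, 0), tolerance = 1e-10)
  expect_lt(f0$residualSd, 1e-12)
  ## arbitrary coefficients recovered to machine precision
  beta <- c(2, 1, 0, 0, 0.5)
  f1 <- fitVoxel(as.vector(X %*% beta), X)
  expect_equal(unname(f1$betas), beta, tolerance = 1e-10)
  ## residual SD estimates the noise SD (chi-square expectation, 1000
  ## replicate voxels)
  set.seed(31)
  Y <- matrix(rnorm(1000 * nrow(X), 0, 0.02), 1000, nrow(X))
  ser <- ImageSeries(Y, timestamps = sched$timestamps, dim = c(1000, 1),
                     setIndex = sched$setIndex)
  fit <- fitGLM(ser, GLMParams(), p)
  expect_equal(mean(residualSd(fit)), 0.02, tolerance = 0.02)
})

test_that("CNR is scale invariant, capped when degenerate, monotone in effect", {
  p <- CapniaProtocol()
  ser <- brainVoxelSeries(noiseSd = 0.02, seed = 5)
  fit <- fitGLM(ser, GLMParams(), p)
  ser2 <- ser
  SummarizedExperiment::assay(ser2, "frames") <- 2 * frameMatrix(ser)
  fit2 <- fitGLM(ser2, GLMParams(), p)
  expect_equal(fit2@cnr, fit@cnr, tolerance = 1e-10)
  expect_equal(cnrMap(fit2), cnrMap(fit), tolerance = 1e-10)
  ## data exactly in the design span: residual SD 0, CNR capped, warning
  sched0 <- standardSchedule()
  X0 <- buildDesign(sched0$timestamps, GLMParams(), p)
  exact <- ImageSeries(matrix(as.vector(X0 %*% c(2, 1, 0, 0, 0.5)), 1),
                       timestamps = sched0$timestamps, dim = c(1, 1),
                       setIndex = sched0$setIndex)
  expect_warning(fitE <- fitGLM(exact, GLMParams(), p), "capped")
  expect_true(all(abs(fitE@cnr) == 1e12))
  ## CNR grows with the modulation depth at fixed noise
  sched <- standardSchedule()
  mkDelta <- function(d) {
    sig <- 1.54 / 210 * cbvTimecourse(CapniaProtocol(), sched$timestamps,
                                      tau1 = 51, tau2 = 3100,
                                      baselineMass = 210,
                                      deltaFraction = d)
    ser <- ImageSeries(matrix(sig, 1), timestamps = sched$timestamps,
                       dim = c(1, 1), setIndex = sched$setIndex)
    injectNoise(ser, NoiseModel(sigma0 = 0.02, lambdaGain = 0,
                                quadrantGainDelta = 0), seed = 17)
  }
  cnrs <- vapply(c(0.1, 0.2, 0.3), function(d)
    fitGLM(mkDelta(d), GLMParams(), p)@cnr[1], numeric(1))
  expect_true(all(diff(cnrs) > 0))
})

test_that("percent change reads the generator's CBV fraction", {
  p <- CapniaProtocol()
  ## noiseless synthetic brain at 25% modulation
  fit <- suppressWarnings(fitGLM(brainVoxelSeries(), GLMParams(), p))
  expect_equal(fit@percentChange[1], 25, tolerance = 3 / 25)
  ## over seeds with noise
  pcts <- vapply(1:5, function(s) {
    f <- fitGLM(brainVoxelSeries(noiseSd = 0.02, seed = s), GLMParams(), p)
    mean(f@percentChange)
  }, numeric(1))
  expect_equal(mean(pcts), 25, tolerance = 3 / 25)
  expect_equal(percentChangeMap(fit)[1, 1], fit@percentChange[1])
  ## non-positive baseline is flagged invalid
  sched <- standardSchedule()
  neg <- ImageSeries(matrix(-1, 1, length(sched$timestamps)),
                     timestamps = sched$timestamps, dim = c(1, 1),
                     setIndex = sched$setIndex)
  negF <- suppressWarnings(fitGLM(injectNoise(neg,
    NoiseModel(quadrantGainDelta = 0), seed = 2), GLMParams(), p))
  expect_true(is.na(negF@percentChange[1]))
})

test_that("activation map applies the corrected threshold", {
  p <- CapniaProtocol()
  ## noiseless activated series: every voxel survives
  fit0 <- suppressWarnings(fitGLM(brainVoxelSeries(), GLMParams(), p))
  act <- activationMap(fit0, alpha = 1e-12)
  expect_equal(attr(act, "nSurviving"), 4)
  ## alpha = 1: everything survives
  fitN <- fitGLM(brainVoxelSeries(noiseSd = 0.05, seed = 3),
                 GLMParams(), p)
  expect_equal(attr(activationMap(fitN, alpha = 1), "nSurviving"), 4)
})

test_that("tau and delay optimization recovers generator parameters", {
  p <- CapniaProtocol()
  ## noiseless: global minimum at the truth (tau within 1%, deltaT exact)
  opt <- optimizeParams(brainVoxelSeries(), p)
  expect_equal(opt$params@tau1, 51, tolerance = 0.01)
  expect_equal(opt$params@tau2, 3100, tolerance = 0.01)
  expect_identical(opt$params@deltaT, 0)
  ## the delay grid contains and recovers a +10 s shift
  opt10 <- optimizeParams(brainVoxelSeries(delay = 10), p)
  expect_identical(opt10$params@deltaT, 10)
  expect_equal(opt10$params@tau1, 51, tolerance = 0.02)
  ## reported objective matches an independent full-design OLS refit
  X <- buildDesign(timestamps(brainVoxelSeries()), opt$params, p)
  y <- colMeans(frameMatrix(brainVoxelSeries()))
  ## (the profiled objective uses a longer, renormalized kernel support
  ## than the final design, so agreement is to a few percent)
  ssRef <- sum(stats::lm.fit(X, y)$residuals^2)
  expect_equal(min(opt$ssGrid$ss), ssRef, tolerance = 0.05)
})

test_that("blood half-life identities", {
  expect_equal(bloodHalfLife(1 / log(2)), 1)
  expect_equal(bloodHalfLife(3100), 2148.7, tolerance = 1e-4)
  expect_equal(tau2FromHalfLife(48 * 60), 48 * 60 / log(2))
  expect_equal(bloodHalfLife(tau2FromHalfLife(1234)), 1234)
})
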