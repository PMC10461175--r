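test_that("dilution phantoms hold the geometric mass series", {
  expect_equal(wellMasses(250, 5, 0.5), c(250, 125, 62.5, 31.25, 15.625))
  ph <- makeDilutionPhantom(250, 5)
  expect_setequal(tracerGrid(ph)[tracerGrid(ph) > 0],
                  c(250, 125, 62.5, 31.25, 15.625))
  single <- makeDilutionPhantom(250, 1)
  expect_equal(sum(tracerGrid(single) > 0), 1)
  expect_equal(max(tracerGrid(single)), 250)
  ## undiluted stock 24 ug, first step to 2 ug, then halving down to 3.9 ng
  masses <- c(24e3, wellMasses(2e3, 10, 0.5))
  expect_length(masses, 11)
  expect_equal(signif(masses[11], 2), 3.9)
})

test_that("brain phantom: uniform parenchyma with 20x vessel hotspots", {
  ph <- makeBrainPhantom(210)
  vals <- unique(as.vector(tracerGrid(ph)))
  expect_setequal(vals, c(0, 210))
  expect_gt(sum(tracerGrid(ph) > 0), 10)
  expect_true(all(tracerGrid(makeBrainPhantom(0)) == 0))
  phv <- makeBrainPhantom(210, vesselPositions = matrix(c(0, 0), 1))
  expect_equal(max(tracerGrid(phv)), 4200)
  ## mask matches the nonzero region
  expect_equal(sum(phantomMask(ph)), sum(tracerGrid(ph) > 0))
})

test_that("capnia block alternates 5 min states with optional delay", {
  p <- CapniaProtocol()
  tt <- 0:1799
  b <- capniaBlock(p, tt)
  hyper <- (tt >= 300 & tt < 600) | (tt >= 900 & tt < 1200) |
    (tt >= 1500 & tt < 1800)
  expect_identical(b, as.numeric(hyper))
  ## +10 s delay moves edges later
  b10 <- capniaBlock(p, tt, delay = 10)
  expect_equal(which(diff(b10) == 1), which(diff(b) == 1) + 10)
  ## a single cycle has exactly one rising edge even past the protocol end
  p1 <- CapniaProtocol(nCycles = 1)
  b1 <- capniaBlock(p1, 0:2000)
  expect_equal(sum(diff(b1) == 1), 1)
  expect_error(capniaBlock(p, c(5, 1)), "sorted")
})

test_that("cbv timecourse: unit kernel gain, decay half-life", {
  p <- CapniaProtocol()
  tt <- seq(0, 1795, by = 5)
  ## no modulation, no decay: constant baseline
  flat <- cbvTimecourse(p, tt, tau1 = 51, tau2 = Inf, baselineMass = 210,
                        deltaFraction = 0)
  expect_equal(flat, rep(210, length(tt)))
  ## sustained hypercapnia asymptotes to baseline * (1 + delta)
  pLong <- CapniaProtocol(stateDuration = 3000, nCycles = 1)
  mL <- cbvTimecourse(pLong, 0:5999, tau1 = 51, tau2 = Inf,
                      baselineMass = 210)
  expect_equal(max(mL) - min(mL), 52.5, tolerance = 1e-6)
  expect_equal(max(mL), 210 * 1.25, tolerance = 1e-6)
  ## block always off: pure exponential decay with half-life tau2 ln 2
  m0 <- cbvTimecourse(p, 0:6000, tau1 = 51, tau2 = 3100,
                      baselineMass = 210, deltaFraction = 0)
  tHalf <- (0:6000)[min(which(m0 <= 105))]
  expect_equal(tHalf, 3100 * log(2), tolerance = 1e-3)
  expect_error(cbvTimecourse(p, tt, tau1 = -1, tau2 = 3100), "tau")
  expect_error(cbvTimecourse(p, tt, tau1 = 51, tau2 = 0), "tau")
})

test_that("injected noise follows sigma_tot = sqrt(sigma0^2 + (lambda S)^2)", {
  nF <- 10000
  ## all-zero noise model is the identity
  ser <- constantSeries(2, 500)
  zero <- NoiseModel(sigma0 = 0, lambdaGain = 0, quadrantGainDelta = 0)
  expect_identical(frameMatrix(injectNoise(ser, zero, seed = 1)),
                   frameMatrix(ser))
  ## thermal-only: per-voxel SD converges to sigma0
  serT <- constantSeries(0, nF)
  nmT <- NoiseModel(lambdaGain = 0, quadrantGainDelta = 0)
  sdT <- sd(frameMatrix(injectNoise(serT, nmT, seed = 3))[1, ])
  expect_equal(sdT, 0.0133, tolerance = 0.03)
  ## bright series: SD / S converges to lambda
  S <- 50
  serB <- constantSeries(S, nF)
  nmB <- NoiseModel(sigma0 = 0, quadrantGainDelta = 0)
  sdB <- sd(frameMatrix(injectNoise(serB, nmB, seed = 4))[1, ])
  expect_equal(sdB / S, 0.017, tolerance = 0.03)
  ## combined model within 5%
  S2 <- 2
  serC <- constantSeries(S2, nF)
  nmC <- NoiseModel(quadrantGainDelta = 0)
  sdC <- sd(frameMatrix(injectNoise(serC, nmC, seed = 5))[1, ])
  expect_equal(sdC, sqrt(0.0133^2 + (0.017 * S2)^2), tolerance = 0.05)
  ## deterministic given seed; caller's RNG untouched
  set.seed(99); before <- .Random.seed
  a <- injectNoise(serC, nmC, seed = 7)
  b <- injectNoise(serC, nmC, seed = 7)
  expect_identical(frameMatrix(a), frameMatrix(b))
  expect_identical(.Random.seed, before)
})

test_that("quadrant gain artifact produces lines at 0.2 and 0.4 c/sample only", {
  nF <- 2000
  ser <- constantSeries(2, nF)
  nm <- NoiseModel(sigma0 = 0, lambdaGain = 0, quadrantGainDelta = 0.01)
  x <- frameMatrix(injectNoise(ser, nm, seed = 1))[1, ]
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2
  f <- (seq_len(nF) - 1) / nF
  f <- pmin(f, 1 - f)
  peaks <- abs(f - 0.2) < 1e-9 | abs(f - 0.4) < 1e-9
  expect_gt(sum(P[peaks]), 0.999999 * sum(P))
  expect_lt(max(P[!peaks]), 1e-10 * max(P))
  ## drift and warm-up transient follow the stated deterministic forms
  ts <- seq(5, by = 5, length.out = 10)
  serD <- ImageSeries(matrix(0, 1, 10), timestamps = ts, dim = c(1, 1),
                      setIndex = rep(0:1, each = 5))
  nmD <- NoiseModel(sigma0 = 0, lambdaGain = 0, quadrantGainDelta = 0,
                    driftLinear = 2, driftQuadratic = 0.5,
                    transientAmplitude = 3, transientTau = 10)
  out <- frameMatrix(injectNoise(serD, nmD, seed = 1))[1, ]
  expect_equal(out, 2 * ts + 0.5 * ts^2 + 3 * exp(-ts / 10),
               tolerance = 1e-12)
})
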