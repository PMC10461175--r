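test_that("dilution fit: exact line, degenerate data, detection limit", {
  masses <- c(250, 125, 62.5, 31.25, 15.625)
  f <- dilutionFit(masses, 0.86 * masses)
  expect_equal(f@slope, 0.86, tolerance = 1e-12)
  expect_equal(f@intercept, 0, tolerance = 1e-12)
  expect_equal(f@rSquared, 1)
  expect_equal(f@detectionLimitMass, 5 / 0.86, tolerance = 1e-12)
  expect_equal(signif(f@detectionLimitMass, 2), 5.8)
  ## constant SNRs: slope 0, no invertible detection limit
  expect_warning(f0 <- dilutionFit(masses, rep(7, 5)), "invertible")
  expect_equal(f0@slope, 0, tolerance = 1e-12)
  expect_true(is.nan(f0@detectionLimitMass))
  expect_error(dilutionFit(c(1, 2), c(1, 2)), "3")
  ## intercept-zero variant
  fz <- dilutionFit(masses, 0.86 * masses + 0.5, interceptZero = TRUE)
  expect_equal(fz@intercept, 0)
  expect_gt(fz@slope, 0.86)
})

test_that("noise-model fit is exact on model-generated data", {
  S <- c(0.2, 0.5, 1, 2, 3.3)
  sds <- sqrt(0.0133^2 + (0.017 * S)^2)
  f <- fitNoiseModel(S, sds)
  expect_equal(f@sigma0, 0.0133, tolerance = 1e-12)
  expect_equal(f@lambdaGain, 0.017, tolerance = 1e-12)
  expect_equal(f@rSquared, 1, tolerance = 1e-12)
  ## lambda = 0 data: constant sigma_tot
  fl <- fitNoiseModel(S, rep(0.0133, 5))
  expect_equal(fl@lambdaGain, 0, tolerance = 1e-12)
  expect_equal(fl@sigma0, 0.0133, tolerance = 1e-12)
  ## fixed sigma0 variant
  ff <- fitNoiseModel(S, sds, sigma0 = 0.0133)
  expect_equal(ff@lambdaGain, 0.017, tolerance = 1e-12)
  ## decreasing SDs force a negative variance -> clamped with warning
  expect_warning(fn <- fitNoiseModel(c(1, 10), c(0.05, 0.01)), "clamp")
  expect_equal(fn@lambdaGain, 0)
  expect_error(fitNoiseModel(1, 0.01), "2")
})

test_that("equal-contribution SNR is the reciprocal of lambda", {
  expect_equal(round(equalContributionSnr(0.017)), 59)
  expect_equal(equalContributionSnr(1), 1)
  expect_identical(equalContributionSnr(0), Inf)
  ## identity over fits and models, lambda * SNR = 1
  for (lam in c(0.005, 0.017, 0.2)) {
    nf <- fitNoiseModel(c(1, 2, 4), sqrt(0.01^2 + (lam * c(1, 2, 4))^2))
    expect_equal(equalContributionSnr(nf) * nf@lambdaGain, 1,
                 tolerance = 1e-12)
  }
  expect_equal(equalContributionSnr(NoiseModel()), 1 / 0.017)
})

test_that("voxel iron accounting matches the dose arithmetic", {
  expect_equal(voxelFeMass(10, 64, 3, 0.05), 210.9375)
  expect_equal(floor(voxelFeMass(10, 64, 3, 0.05)),
               210)  # the conventionally quoted value
  expect_equal(voxelFeMass(bloodFraction = 0), 0)
  expect_equal(voxelFeMass(10, 64, 3, 1), 4218.75)
  ## pure-blood over parenchyma ratio equals the 20x vessel factor
  expect_equal(voxelFeMass(10, 64, 3, 1) / voxelFeMass(10, 64, 3, 0.05),
               20)
  ## linear in dose and blood fraction, cubic in voxel edge
  expect_equal(voxelFeMass(dose = 20), 2 * voxelFeMass(dose = 10))
  expect_equal(voxelFeMass(bloodFraction = 0.1),
               2 * voxelFeMass(bloodFraction = 0.05))
  expect_equal(voxelFeMass(voxelEdge = 6), 8 * voxelFeMass(voxelEdge = 3))
})

test_that("Fe mass at an SNR inverts the dilution line", {
  masses <- c(250, 125, 62.5, 31.25, 15.625)
  f <- dilutionFit(masses, 0.86 * masses)
  expect_equal(feMassAtSnr(58.8, f), 58.8 / 0.86, tolerance = 1e-10)
  expect_equal(round(feMassAtSnr(equalContributionSnr(0.017), f)), 68)
  expect_equal(feMassAtSnr(0, 0.86), 0)
  ## round trip through the line
  for (m in masses) expect_equal(feMassAtSnr(0.86 * m, f), m,
                                 tolerance = 1e-10)
  expect_error(feMassAtSnr(5, 0), "slope")
})
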