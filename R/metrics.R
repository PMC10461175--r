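## Sensitivity analyses: dilution linearity, detection limit, two-component
## noise-model fit, and voxel iron accounting.

#' Fit the dilution-series SNR line
#'
#' Ordinary least-squares line through (Fe mass, SNR) pairs. The detection
#' limit is the mass at which the fitted line crosses `referenceSnr`
#' (default SNR = 5): `(referenceSnr - intercept) / slope`, or
#' `referenceSnr / slope` with `interceptZero = TRUE`. A non-positive slope
#' leaves the limit `NaN` with a warning. Reported limits are conventionally
#' quoted to 2 significant figures (see `show`).
#'
#' @param masses Fe masses (ng), at least 3
#' @param snrs measured SNRs, same length
#' @param referenceSnr SNR defining the detection limit (default 5)
#' @param interceptZero constrain the intercept to 0 (default FALSE)
#' @return a [DilutionFit-class]
#' @examples
#' f <- dilutionFit(c(250, 125, 62.5), 0.86 * c(250, 125, 62.5))
#' f  # slope 0.86, R^2 = 1, detection limit 5.8 ng
#' @export
dilutionFit <- function(masses, snrs, referenceSnr = 5,
                        interceptZero = FALSE) {
  stopifnot(length(masses) == length(snrs))
  if (length(masses) < 3) stop("at least 3 dilution points are required")
  if (interceptZero) {
    slope <- sum(masses * snrs) / sum(masses^2)
    intercept <- 0
  } else {
    cf <- stats::coef(stats::lm(snrs ~ masses))
    intercept <- unname(cf[1]); slope <- unname(cf[2])
  }
  fitted <- intercept + slope * masses
  ssTot <- sum((snrs - mean(snrs))^2)
  r2 <- if (ssTot > 0) 1 - sum((snrs - fitted)^2) / ssTot else NA_real_
  if (!is.na(r2)) r2 <- min(max(r2, 0), 1)
  slopeTol <- 1e-10 * (max(abs(snrs)) + 1) / diff(range(masses))
  if (slope <= slopeTol) {
    warning("non-positive slope: detection limit is not invertible")
    limit <- NaN
  } else limit <- (referenceSnr - intercept) / slope
  new("DilutionFit", slope = slope, intercept = intercept, rSquared = r2,
      detectionLimitMass = limit, referenceSnr = referenceSnr)
}

#' Fit the two-component noise model
#'
#' Least squares for `sigma_tot = sqrt(sigma0^2 + (lambda * S)^2)` fitted in
#' variance space, where it is linear in the parameters:
#' `sigma^2 = sigma0^2 + lambda^2 * S^2`. Negative fitted variances are
#' clamped at zero with a warning. With `sigma0` supplied, only `lambda^2`
#' is estimated (the thermal floor is taken as measured).
#'
#' @param signalLevels signal levels S (A.U.), at least 2
#' @param sds time-series standard deviations at those levels
#' @param sigma0 optional known thermal noise SD (A.U.)
#' @return a [NoiseFit-class]
#' @examples
#' S <- c(0.2, 0.5, 1, 2, 3)
#' fitNoiseModel(S, sqrt(0.0133^2 + (0.017 * S)^2))  # exact recovery
#' @export
fitNoiseModel <- function(signalLevels, sds, sigma0 = NULL) {
  stopifnot(length(signalLevels) == length(sds))
  if (length(signalLevels) < 2) stop("at least 2 signal levels are required")
  y <- sds^2
  x <- signalLevels^2
  if (is.null(sigma0)) {
    cf <- stats::coef(stats::lm(y ~ x))
    s0sq <- unname(cf[1]); lsq <- unname(cf[2])
  } else {
    s0sq <- sigma0^2
    lsq <- sum(x * (y - s0sq)) / sum(x^2)
  }
  if (s0sq < 0 || lsq < 0) {
    ## warn only for materially negative variances, not rounding residue
    tolS <- 1e-12 * max(y); tolL <- 1e-12 * max(y) / max(x)
    if (s0sq < -tolS || lsq < -tolL)
      warning("negative fitted variance clamped at zero")
    s0sq <- max(s0sq, 0); lsq <- max(lsq, 0)
  }
  fitted <- s0sq + lsq * x
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - sum((y - fitted)^2) / ssTot else NA_real_
  new("NoiseFit", sigma0 = sqrt(s0sq), lambdaGain = sqrt(lsq),
      rSquared = r2)
}

#' SNR at which thermal and signal-proportional noise contribute equally
#'
#' The two variance components are equal when `lambda * S = sigma0`, i.e.
#' at image SNR `S / sigma0 = 1 / lambda` (~59 at the instrument's
#' lambda = 0.017). Infinite when lambda = 0.
#'
#' @param noise a [NoiseFit-class], [NoiseModel-class], or a bare numeric
#'   lambda
#' @return the equal-contribution SNR
#' @export
equalContributionSnr <- function(noise) {
  lambda <- if (is(noise, "NoiseFit")) noise@lambdaGain
    else if (is(noise, "NoiseModel")) noise@lambdaGain
    else as.numeric(noise)
  if (lambda == 0) Inf else 1 / lambda
}

#' Expected resting voxel Fe mass
#'
#' Iron content of an imaging voxel after an intravenous tracer dose:
#' blood Fe concentration `dose / bloodVolume` (mg/ml) times the voxel blood
#' volume `voxelEdge^3 * bloodFraction` (ul), converted to ng. The defaults
#' (10 mg/kg dose, 64 ml blood per kg, 3 mm voxel, 5% gray-matter blood
#' volume) give 210.9 ng, the expected resting-brain value; a pure-blood
#' voxel (`bloodFraction = 1`) carries about 20 times more, the large-vessel
#' ratio.
#'
#' @param dose injected dose (mg Fe per kg body weight)
#' @param bloodVolume blood volume per body weight (ml/kg)
#' @param voxelEdge voxel edge length (mm)
#' @param bloodFraction fraction of the voxel occupied by blood
#' @return Fe mass (ng); linear in dose and bloodFraction, cubic in
#'   voxelEdge
#' @examples
#' voxelFeMass()                       # 210.9 ng
#' 0.25 * voxelFeMass()                # ~52.5 ng change for a 25% CBV swing
#' @export
voxelFeMass <- function(dose = 10, bloodVolume = 64, voxelEdge = 3,
                        bloodFraction = 0.05) {
  stopifnot(bloodVolume > 0)
  (dose / bloodVolume) * voxelEdge^3 * bloodFraction * 1000
}

#' Fe mass corresponding to an SNR on the dilution line
#'
#' Inverse of the fitted dilution line: `(snr - intercept) / slope`.
#'
#' @param snr image SNR
#' @param fit a [DilutionFit-class] (or a bare numeric slope, zero
#'   intercept)
#' @return Fe mass (ng)
#' @examples
#' feMassAtSnr(59, 0.86)   # ~68 ng
#' @export
feMassAtSnr <- function(snr, fit) {
  if (is(fit, "DilutionFit")) {
    slope <- fit@slope; intercept <- fit@intercept
  } else {
    slope <- as.numeric(fit); intercept <- 0
  }
  if (slope == 0) stop("zero slope: the dilution line is not invertible")
  (snr - intercept) / slope
}
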