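## Five-regressor general linear model: CO2 response kernel, activation
## regressor, design construction, per-voxel OLS, tau/delay optimization,
## CNR / percent-change / activation maps.

#' CO2 response function kernel
#'
#' The hemodynamic CO2 response kernel `t * exp(-t / tau1)` for `t >= 0`
#' (0 for `t < 0`); it lumps gas-line delays, lung absorption, transport to
#' the brain and the vascular response. Its maximum sits at `t = tau1`.
#'
#' @param t time (s), any numeric vector
#' @param tau1 time constant (s), > 0
#' @return kernel values (unnormalized)
#' @examples
#' co2rf(51, 51) / co2rf(102, 51)  # peak at tau1; ratio 1 / (2 exp(-1))
#' @export
co2rf <- function(t, tau1) {
  if (tau1 <= 0) stop("tau1 must be > 0")
  ifelse(t >= 0, t * exp(-t / tau1), 0)
}

#' Activation regressor for the capnia GLM
#'
#' The capnic block waveform, shifted by `deltaT`, convolved with the
#' unit-steady-state-gain CO2 response kernel and multiplied by the tracer
#' decay `exp(-t / tau2)`, then rescaled to unit peak-to-peak amplitude so
#' the fitted coefficient reads directly in signal units (peak-to-peak
#' signal change). In `bold` mode the decay factor is 1 (no tracer); in
#' `phantom` mode both the decay and the CO2 kernel are 1, leaving the
#' shifted block itself.
#'
#' @param protocol a [CapniaProtocol-class]
#' @param timestamps frame times (s)
#' @param params a [GLMParams-class]
#' @return numeric regressor with attribute `"pkpk"`, the raw peak-to-peak
#'   amplitude absorbed by the normalization
#' @export
activationRegressor <- function(protocol, timestamps, params) {
  raw <- switch(params@mode,
    phantom = capniaBlock(protocol, timestamps, params@deltaT),
    bold = convolvedBlock(protocol, timestamps, params@tau1, params@deltaT),
    fmpi = convolvedBlock(protocol, timestamps, params@tau1, params@deltaT) *
      exp(-timestamps / params@tau2))
  pkpk <- max(raw) - min(raw)
  if (pkpk < 1e-12)
    stop("degenerate flat activation regressor (zero peak-to-peak)")
  structure(raw / pkpk, pkpk = pkpk)
}

#' Build the GLM design matrix
#'
#' Columns: (1) the unit peak-to-peak activation regressor, (2) a constant
#' baseline, (3) linear and (4) quadratic trends (centered and scaled to
#' unit range for conditioning), and (5) the initial warm-up transient
#' `exp(-t / tauD)`. In `phantom` mode a sixth, signal-conditional linear
#' drift column (the centered trend gated by the in-bore block, zero when
#' the phantom is out) is appended.
#'
#' @param timestamps frame times (s); at least one more frame than columns
#' @param params a [GLMParams-class]
#' @param protocol a [CapniaProtocol-class]
#' @return design matrix with an attribute `"pkpk"` (see
#'   [activationRegressor()]) and column names
#' @export
buildDesign <- function(timestamps, params, protocol) {
  n <- length(timestamps)
  nCols <- if (params@mode == "phantom") 6L else 5L
  if (n <= nCols)
    stop("need more frames than regressors (", nCols, ")")
  act <- activationRegressor(protocol, timestamps, params)
  tc <- timestamps - mean(timestamps)
  rng <- max(timestamps) - min(timestamps)
  lin <- tc / rng
  quad <- lin^2 - mean(lin^2)
  qrng <- max(quad) - min(quad)
  if (qrng > 0) quad <- quad / qrng
  trans <- exp(-timestamps / params@tauD)
  X <- cbind(activation = as.numeric(act), constant = 1, linear = lin,
             quadratic = quad, transient = trans)
  if (params@mode == "phantom") {
    gate <- capniaBlock(protocol, timestamps, params@deltaT)
    X <- cbind(X, conditionalDrift = lin * gate)
  }
  attr(X, "pkpk") <- attr(act, "pkpk")
  X
}

#' Ordinary least squares fit of one voxel series
#'
#' @param y signal values (one per frame)
#' @param design design matrix from [buildDesign()]
#' @return list with `betas` (named) and `residualSd` = sqrt(SSR / (n - p))
#' @export
fitVoxel <- function(y, design) {
  stopifnot(length(y) == nrow(design))
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) stop("design matrix is rank deficient")
  beta <- qr.coef(qrX, y)
  res <- y - design %*% beta
  list(betas = beta,
       residualSd = sqrt(sum(res^2) / (length(y) - ncol(design))))
}

## cap for CNR at (numerically) zero residual SD
.cnrCap <- 1e12

#' Fit the GLM to every voxel of an image series
#'
#' One QR decomposition serves all voxels. Returns per-voxel coefficients,
#' residual SD, contrast-to-noise ratio (activation coefficient -- the
#' peak-to-peak fitted activation amplitude, thanks to the unit peak-to-peak
#' normalization -- over residual SD), percent signal change, and the
#' two-sided t-test p-value on the activation coefficient with `n - p`
#' degrees of freedom.
#'
#' Percent signal change is `100 * delta`, the fractional CBV modulation
#' implied by the fit: the activation coefficient is divided by the raw
#' regressor peak-to-peak and by the baseline referenced to `t = 0` (the
#' constant coefficient, which sits at the series midpoint where the trend
#' columns are centered, decay-corrected back to zero by
#' `exp(+tMid / tau2)` in fmpi mode). Voxels with non-positive baseline are
#' flagged invalid (NA).
#'
#' @param series an [ImageSeries-class]
#' @param params a [GLMParams-class]
#' @param protocol a [CapniaProtocol-class]
#' @param design optional prebuilt design (from [buildDesign()])
#' @return a [GLMFit-class]
#' @export
fitGLM <- function(series, params, protocol, design = NULL) {
  if (is.null(design))
    design <- buildDesign(timestamps(series), params, protocol)
  v <- frameMatrix(series)
  n <- nrow(design); p <- ncol(design)
  qrX <- qr(design)
  if (qrX$rank < p) stop("design matrix is rank deficient")
  beta <- qr.coef(qrX, t(v))                       # p x nVox
  res <- t(v) - design %*% beta
  df <- n - p
  rsd <- sqrt(colSums(res^2) / df)
  betaAct <- beta["activation", ]
  betaConst <- beta["constant", ]
  cnr <- betaAct / rsd
  cnr[rsd == 0 & betaAct == 0] <- 0
  over <- !is.finite(cnr) | abs(cnr) > .cnrCap
  if (any(over)) {
    warning("near-zero residual SD with finite activation; CNR capped")
    cnr[over] <- sign(betaAct[over]) * .cnrCap
  }
  ## percent signal change referenced to t = 0
  tMid <- mean(timestamps(series))
  decayRef <- if (params@mode == "fmpi") exp(-tMid / params@tau2) else 1
  pkpk <- attr(design, "pkpk")
  pct <- ifelse(betaConst > 0,
                100 * betaAct * decayRef / (betaConst * pkpk), NA_real_)
  ## t test on the activation coefficient
  XtXinv <- chol2inv(qr.R(qrX))
  seScale <- sqrt(XtXinv[1, 1])
  tval <- betaAct / (rsd * seScale)
  pval <- 2 * stats::pt(-abs(tval), df)
  new("GLMFit", coefficients = t(beta), residualSd = rsd,
      cnr = cnr, percentChange = pct, pValue = pval, tValue = tval,
      params = params, design = design, dim = imageDim(series),
      mask = as.logical(roiMask(series)), df = df)
}

#' Optimize hemodynamic time constants and protocol delay
#'
#' Grid search over the protocol delay (default -20..+20 s in 5 s steps,
#' the coarse manual-synchronization correction) combined with bounded
#' quasi-Newton minimization of the mean in-mask residual sum of squares
#' over (tau1, tau2) (in log space, from a multistart grid). The objective
#' uses the mean in-mask voxel series -- a single global hemodynamic model;
#' the returned parameters are then applied voxelwise. In `bold` mode only
#' tau1 is optimized; in `phantom` mode only the delay.
#'
#' Ties across the delay grid are broken by smallest `|deltaT|`, then by
#' the earlier delay.
#'
#' @param series an [ImageSeries-class]
#' @param protocol a [CapniaProtocol-class]
#' @param tau1Bounds,tau2Bounds search bounds (s)
#' @param deltaGrid candidate delays (s)
#' @param mode GLM variant: "fmpi", "phantom" or "bold"
#' @param tauD transient time constant (s); default one third of the first
#'   activation half-period
#' @param nStarts multistart grid points per tau axis (default 3)
#' @return list with `params` (the optimal [GLMParams-class]), `fit` (the
#'   voxelwise [GLMFit-class] at the optimum), and `ssGrid` (a data frame
#'   of the delay grid search)
#' @export
optimizeParams <- function(series, protocol, tau1Bounds = c(5, 300),
                           tau2Bounds = c(600, 30000),
                           deltaGrid = seq(-20, 20, by = 5),
                           mode = "fmpi",
                           tauD = protocol@stateDuration / 3,
                           nStarts = 3) {
  ts <- timestamps(series)
  v <- frameMatrix(series)
  msk <- as.logical(roiMask(series))
  if (!any(msk)) stop("no in-mask voxels to optimize on")
  y <- colMeans(v[msk, , drop = FALSE])
  ## nuisance columns are tau-independent: residualize once, then the
  ## full-design residual SS is ss0 - <a_res, y_res>^2 / |a_res|^2 with a
  ## the (unnormalized) activation column
  refPar <- GLMParams(tauD = tauD, mode = if (mode == "phantom")
    "fmpi" else mode)
  Nfull <- buildDesign(ts, refPar, protocol)
  N <- Nfull[, setdiff(colnames(Nfull), "activation"), drop = FALSE]
  qrN <- qr(N)
  yr <- qr.resid(qrN, y)
  ss0 <- sum(yr^2)
  ssRaw <- function(raw) {
    if (max(raw) - min(raw) < 1e-12) return(Inf)
    ar <- qr.resid(qrN, raw)
    den <- sum(ar^2)
    if (den < 1e-200) return(Inf)
    ss0 - sum(ar * yr)^2 / den
  }
  ## cached FFT convolution machinery: block FFT per delay, kernel per tau1
  dtg <- 1
  spanMax <- 10 * tau1Bounds[2]
  grid <- seq(-spanMax, max(ts) + dtg, by = dtg)
  ku <- seq(0, spanMax, by = dtg)
  L <- stats::nextn(length(grid) + length(ku) - 1L, 2)
  padK <- rep(0, L - length(ku))
  convFor <- function(fx, tau1) {
    kernel <- co2rf(ku, tau1)
    kernel <- kernel / sum(kernel)
    conv <- Re(stats::fft(fx * stats::fft(c(kernel, padK)),
                          inverse = TRUE))[seq_along(grid)] / L
    stats::approx(grid, conv, xout = ts, rule = 2)$y
  }
  logGrid <- function(b, n) exp(seq(log(b[1]), log(b[2]), length.out = n))
  starts1 <- logGrid(tau1Bounds, nStarts)
  starts2 <- logGrid(tau2Bounds, nStarts)
  rows <- list()
  for (dt in deltaGrid) {
    if (mode == "phantom") {
      raw <- capniaBlock(protocol, ts, dt)
      gate <- raw
      Xp <- cbind(N, conditionalDrift = N[, "linear"] * gate)
      ssP <- if (max(raw) - min(raw) < 1e-12) Inf else
        sum(stats::lm.fit(cbind(raw, Xp), y)$residuals^2)
      rows[[length(rows) + 1L]] <- data.frame(
        deltaT = dt, tau1 = 51, tau2 = 3100, ss = ssP)
      next
    }
    blockFine <- capniaBlock(protocol, grid, dt)
    fx <- stats::fft(c(blockFine, rep(0, L - length(grid))))
    obj <- function(p) {
      tau1 <- exp(p[1])
      conv <- convFor(fx, tau1)
      if (mode == "bold") return(ssRaw(conv))
      ssRaw(conv * exp(-ts / exp(p[2])))
    }
    best <- NULL
    failures <- character()
    for (s1 in starts1) for (s2 in (if (mode == "bold") starts2[1] else starts2)) {
      opt <- tryCatch({
        if (mode == "bold") {
          o <- stats::optim(log(s1), obj, method = "L-BFGS-B",
            lower = log(tau1Bounds[1]), upper = log(tau1Bounds[2]),
            control = list(factr = 1e6))
          list(par = c(o$par, log(3100)), value = o$value,
               convergence = o$convergence)
        } else {
          stats::optim(c(log(s1), log(s2)), obj, method = "L-BFGS-B",
            lower = log(c(tau1Bounds[1], tau2Bounds[1])),
            upper = log(c(tau1Bounds[2], tau2Bounds[2])),
            control = list(factr = 1e6))
        }
      }, error = function(e) {
        failures <<- c(failures, conditionMessage(e)); NULL
      })
      if (!is.null(opt) && opt$convergence %in% c(0L, 1L) &&
          (is.null(best) || opt$value < best$value)) best <- opt
    }
    if (is.null(best))
      stop("optimizer failed to converge at every start for deltaT = ", dt,
           if (length(failures)) paste0("; errors: ",
             paste(unique(failures), collapse = " | ")) else "")
    rows[[length(rows) + 1L]] <- data.frame(
      deltaT = dt, tau1 = exp(best$par[1]), tau2 = exp(best$par[2]),
      ss = best$value)
  }
  grid <- do.call(rbind, rows)
  near <- grid$ss <= min(grid$ss) * (1 + 1e-10)
  cand <- grid[near, , drop = FALSE]
  cand <- cand[order(abs(cand$deltaT), cand$deltaT), , drop = FALSE]
  bestRow <- cand[1, ]
  params <- GLMParams(tau1 = bestRow$tau1, tau2 = bestRow$tau2,
                      tauD = tauD, deltaT = bestRow$deltaT, mode = mode)
  list(params = params, fit = fitGLM(series, params, protocol),
       ssGrid = grid)
}

#' Per-voxel result maps of a GLM fit
#'
#' `cnrMap()` returns the signed contrast-to-noise ratio image,
#' `percentChangeMap()` the percent-signal-change image, and
#' `activationMap()` the activation-coefficient image thresholded at the
#' Bonferroni-corrected significance level: a voxel survives when it is in
#' the mask and its activation p-value is below `alpha`, where `alpha` is
#' the already-corrected family-wise threshold (default 1e-12);
#' non-surviving voxels are NA.
#'
#' @param fit a [GLMFit-class]
#' @param alpha corrected significance threshold for [activationMap()]
#' @return a matrix image; `activationMap()` additionally carries the
#'   attribute `"nSurviving"`
#' @export
cnrMap <- function(fit)
  matrix(fit@cnr, fit@dim[1], fit@dim[2])

#' @rdname cnrMap
#' @export
percentChangeMap <- function(fit)
  matrix(fit@percentChange, fit@dim[1], fit@dim[2])

#' @rdname cnrMap
#' @export
activationMap <- function(fit, alpha = 1e-12) {
  surv <- fit@mask & is.finite(fit@pValue) & fit@pValue < alpha
  vals <- ifelse(surv, fit@coefficients[, "activation"], NA_real_)
  structure(matrix(vals, fit@dim[1], fit@dim[2]),
            nSurviving = sum(surv))
}

#' Tracer blood half-life from the decay constant
#'
#' `t_half = tau2 * ln(2)`; `tau2FromHalfLife()` is the inverse.
#'
#' @param tau2 blood decay time constant (s)
#' @param tHalf blood half-life (s)
#' @return time in seconds
#' @examples
#' bloodHalfLife(3100)          # 2148.7 s ~= 35.8 min
#' tau2FromHalfLife(48 * 60)    # ~4155 s
#' @export
bloodHalfLife <- function(tau2) tau2 * log(2)

#' @rdname bloodHalfLife
#' @export
tau2FromHalfLife <- function(tHalf) tHalf / log(2)
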