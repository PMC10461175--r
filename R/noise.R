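## Measurement noise and instrument artifact injection.

## run `expr` with a private RNG stream seeded by `seed`, restoring the
## caller's RNG state afterwards (no hidden global state is consumed)
withSeed <- function(seed, expr) {
  if (missing(seed) || is.null(seed))
    stop("an explicit integer 'seed' is required")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## deterministic alternating-quadrant gain: frames alternate between the two
## half-rotation classes within each set ([1 0 1 0 1] per set of five),
## giving gains 1 +- delta/2
quadrantGains <- function(setIdx, delta) {
  inSet <- unlist(lapply(split(seq_along(setIdx), setIdx), seq_along),
                  use.names = FALSE)
  ord <- order(unlist(split(seq_along(setIdx), setIdx), use.names = FALSE))
  parity <- (inSet[ord] - 1L) %% 2L
  1 + ifelse(parity == 0L, delta / 2, -delta / 2)
}

#' Inject instrument noise and artifacts
#'
#' Corrupts a series with the scanner's instrument model. Each frame value
#' `v` at wall-clock time `t` becomes
#' `g(t) * v * (1 + eps_gain) + drift(t) + transient(t) + eps_thermal`, with
#' `eps_thermal ~ N(0, sigma0)` per voxel and frame, `eps_gain ~ N(0,
#' lambdaGain)` drawn once per frame, and `g(t)` the deterministic
#' alternating-quadrant gain `1 +- quadrantGainDelta/2` by frame parity
#' within sets. The frame-to-frame SD of a constant-signal series therefore
#' follows `sigma_tot = sqrt(sigma0^2 + (lambda * S)^2)` (plus the small
#' deterministic quadrant term). `drift(t) = driftLinear * t +
#' driftQuadratic * t^2`; `transient(t) = transientAmplitude *
#' exp(-t / transientTau)`. Fully deterministic given `seed`; the caller's
#' RNG state is left untouched.
#'
#' For a [SinogramSeries-class] the gain terms are applied to the complex
#' harmonic amplitudes and thermal noise is added independently to the real
#' and imaginary parts; drift and transient offsets are image-domain
#' instrument effects and are applied only at image level.
#'
#' @param series an [ImageSeries-class] or [SinogramSeries-class]
#' @param noise a [NoiseModel-class]
#' @param seed integer seed (mandatory)
#' @return the corrupted series, same class as the input
#' @export
setGeneric("injectNoise", function(series, noise, seed)
  standardGeneric("injectNoise"))

#' @rdname injectNoise
#' @export
setMethod("injectNoise", "ImageSeries", function(series, noise, seed) {
  v <- frameMatrix(series)
  nV <- nrow(v); nF <- ncol(v)
  t <- timestamps(series)
  g <- quadrantGains(setIndex(series), noise@quadrantGainDelta)
  withSeed(seed, {
    epsGain <- stats::rnorm(nF, 0, noise@lambdaGain)
    out <- sweep(v, 2L, g * (1 + epsGain), `*`)
    offset <- noise@driftLinear * t + noise@driftQuadratic * t^2 +
      noise@transientAmplitude * exp(-t / noise@transientTau)
    out <- sweep(out, 2L, offset, `+`)
    if (noise@sigma0 > 0)
      out <- out + matrix(stats::rnorm(nV * nF, 0, noise@sigma0), nV, nF)
    SummarizedExperiment::assay(series, "frames") <- out
  })
  series
})

#' @rdname injectNoise
#' @export
setMethod("injectNoise", "SinogramSeries", function(series, noise, seed) {
  d <- dim(series@values)
  nF <- d[4]; nPerFrame <- prod(d[1:3])
  g <- quadrantGains(series@setIndex, noise@quadrantGainDelta)
  withSeed(seed, {
    epsGain <- stats::rnorm(nF, 0, noise@lambdaGain)
    for (i in seq_len(nF)) {
      fr <- series@values[, , , i] * (g[i] * (1 + epsGain[i]))
      if (noise@sigma0 > 0)
        fr <- fr + complex(
          real = stats::rnorm(nPerFrame, 0, noise@sigma0),
          imaginary = stats::rnorm(nPerFrame, 0, noise@sigma0))
      series@values[, , , i] <- fr
    }
  })
  series
})
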