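## Hypercapnia block physiology: state waveform, CO2 response kernel, and
## the tracer (CBV) timecourse.

#' Capnic state block waveform
#'
#' State indicator (1 = hypercapnia, 0 = hypocapnia) at the requested times,
#' for alternating states of `stateDuration` seconds starting in
#' `startState`, shifted later by `delay`. Before the (shifted) protocol
#' start the waveform holds the start state; after the last cycle it holds
#' the final state.
#'
#' @param protocol a [CapniaProtocol-class]
#' @param timestamps times (s), sorted
#' @param delay temporal shift (s); positive moves all edges later
#' @return numeric 0/1 vector, one value per timestamp
#' @examples
#' p <- CapniaProtocol()
#' b <- capniaBlock(p, c(0, 299, 300, 599, 600))
#' # 0 0 1 1 0 : hyper on [300, 600)
#' @export
capniaBlock <- function(protocol, timestamps, delay = 0) {
  if (is.unsorted(timestamps)) stop("timestamps must be sorted")
  total <- 2 * protocol@stateDuration * protocol@nCycles
  tt <- timestamps - delay
  tt <- pmin(pmax(tt, 0), total - 1e-9)
  phase <- floor(tt / protocol@stateDuration) %% 2
  if (protocol@startState == "hypo") as.numeric(phase == 1)
  else as.numeric(phase == 0)
}

## Block waveform convolved with the unit-steady-state-gain CO2 response
## kernel t*exp(-t/tau1), evaluated at `timestamps` on a dt-resolution grid.
## The kernel is normalized by its discrete sum so a sustained block
## asymptotes to exactly 1.
convolvedBlock <- function(protocol, timestamps, tau1, delay = 0, dt = 1) {
  if (tau1 <= 0) stop("tau1 must be > 0")
  span <- ceiling(10 * tau1 / dt) * dt        # kernel support
  tMax <- max(timestamps, 0)
  grid <- seq(-span, tMax + dt, by = dt)
  blockFine <- capniaBlock(protocol, grid, delay)
  ku <- seq(0, span, by = dt)
  kernel <- co2rf(ku, tau1)
  kernel <- kernel / sum(kernel)
  ## causal FFT convolution, zero-padded to a power of two for speed:
  ## y[i] = sum_j kernel[j] * block[i - j + 1]
  n <- length(blockFine); nk <- length(kernel)
  L <- stats::nextn(n + nk - 1L, 2)
  fx <- stats::fft(c(blockFine, rep(0, L - n)))
  fk <- stats::fft(c(kernel, rep(0, L - nk)))
  y <- Re(stats::fft(fx * fk, inverse = TRUE))[seq_len(n)] / L
  ok <- seq_along(blockFine) >= nk       # discard the warm-up edge
  stats::approx(grid[ok], y[ok], xout = timestamps, rule = 2)$y
}

#' Voxel tracer mass timecourse under the capnia protocol
#'
#' The block waveform is convolved with the unit-gain CO2 response kernel
#' `t * exp(-t / tau1)` and scales the baseline by `1 + deltaFraction * c(t)`;
#' the whole course then decays with the tracer blood clearance
#' `exp(-t / tau2)`:
#' `mass(t) = baselineMass * (1 + deltaFraction * (block (*) CO2RF)(t)) *
#' exp(-t / tau2)`.
#' Because the kernel has unit steady-state gain, a long hypercapnic plateau
#' asymptotes to `baselineMass * (1 + deltaFraction)` before decay.
#'
#' @param protocol a [CapniaProtocol-class]
#' @param timestamps evaluation times (s)
#' @param tau1 CO2 response time constant (s), > 0
#' @param tau2 tracer blood-decay time constant (s), > 0 (may be `Inf`)
#' @param baselineMass resting voxel Fe mass (ng)
#' @param deltaFraction fractional CBV modulation; defaults to the
#'   protocol's `deltaCbvFraction`
#' @param delay protocol shift (s)
#' @param dt convolution grid resolution (s, default 1)
#' @return Fe mass (ng) per timestamp
#' @examples
#' p <- CapniaProtocol()
#' m <- cbvTimecourse(p, seq(0, 1795, 5), tau1 = 51, tau2 = Inf,
#'                    baselineMass = 210)
#' max(m) - min(m)  # approaches the 52.5 ng plateau-to-plateau change
#' @export
cbvTimecourse <- function(protocol, timestamps, tau1 = 51, tau2 = 3100,
                          baselineMass = 210,
                          deltaFraction = protocol@deltaCbvFraction,
                          delay = 0, dt = 1) {
  if (tau1 <= 0 || tau2 <= 0) stop("tau1 and tau2 must be > 0")
  conv <- convolvedBlock(protocol, timestamps, tau1, delay, dt)
  baselineMass * (1 + deltaFraction * conv) * exp(-timestamps / tau2)
}
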