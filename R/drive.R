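## External drive: paroxysmal perturbation shape, optional Gaussian
## stimulation pulses, and the external population's Poisson spikes.

#' Construct a drive specification
#'
#' The commanded rate of the external population is
#' \deqn{\nu(t) = \beta + \alpha \left[ e^{-(t-T_1)^2 / 2\tau_{on}^2} \; (t < T_1);
#'   \; 1 \; (T_1 \le t \le T_2); \; e^{-(t-T_2)^2 / 2\tau_{off}^2} \; (t > T_2) \right]}
#' (continuous everywhere, equal to \eqn{\beta} far from the plateau), plus
#' any Gaussian stimulation pulses, clipped below at zero.
#'
#' Defaults: basal \eqn{\beta = 6} Hz; plateau from 2000 to 3000 ms (1 s
#' plateau); \eqn{\tau_{on} = \tau_{off} = 100} ms; \eqn{\alpha = 0} (no
#' perturbation).
#'
#' @param beta basal rate (Hz)
#' @param alpha plateau amplitude above basal (Hz)
#' @param T1,T2 plateau start / end (ms)
#' @param tauOn,tauOff Gaussian rise / decay time constants (ms)
#' @param pulses data.frame of stimulation pulses with columns `amplitude`
#'   (Hz, may be negative), `tPeak` (ms), `sigma` (ms); see [stimulusPulse()]
#' @return a [DriveSpec-class]
#' @examples
#' d <- driveSpec(alpha = 80)
#' perturbationRate(c(1000, 2500), d)
#' @export
driveSpec <- function(beta = 6, alpha = 0, T1 = 2000, T2 = 3000,
                      tauOn = 100, tauOff = tauOn, pulses = NULL) {
  if (is.null(pulses))
    pulses <- data.frame(amplitude = numeric(0), tPeak = numeric(0),
                         sigma = numeric(0))
  new("DriveSpec", beta = beta, alpha = alpha, T1 = T1, T2 = T2,
      tauOn = tauOn, tauOff = tauOff, pulses = pulses)
}

#' One Gaussian stimulation pulse
#'
#' @param amplitude rate offset at the peak (Hz); negative values inhibit
#' @param tPeak time of the maximum (ms)
#' @param sigma Gaussian width (ms); the reference protocol uses 10 ms
#' @return one-row data.frame, suitable for `rbind`-ing into
#'   [driveSpec()]'s `pulses`
#' @export
stimulusPulse <- function(amplitude, tPeak, sigma = 10) {
  if (sigma <= 0) stop("sigma must be > 0")
  data.frame(amplitude = amplitude, tPeak = tPeak, sigma = sigma)
}

#' Perturbation rate at given times
#'
#' Evaluates the plateau-with-Gaussian-flanks perturbation (no pulses, no
#' clipping; the shape is non-negative by construction).
#'
#' @param t times (ms), vectorized
#' @param drive a [DriveSpec-class]
#' @return rates (Hz)
#' @export
perturbationRate <- function(t, drive) {
  stopifnot(is(drive, "DriveSpec"))
  shape <- ifelse(t < drive@T1,
                  exp(-(t - drive@T1)^2 / (2 * drive@tauOn^2)),
                  ifelse(t <= drive@T2, 1,
                         exp(-(t - drive@T2)^2 / (2 * drive@tauOff^2))))
  drive@beta + drive@alpha * shape
}

#' Total commanded rate (perturbation + pulses, clipped at zero)
#'
#' @inheritParams perturbationRate
#' @return rates (Hz), never negative
#' @export
totalRate <- function(t, drive) {
  r <- perturbationRate(t, drive)
  p <- drive@pulses
  if (nrow(p))
    for (k in seq_len(nrow(p)))
      r <- r + p$amplitude[k] * exp(-(t - p$tPeak[k])^2 / (2 * p$sigma[k]^2))
  pmax(r, 0)
}

#' Generate the external population's Poisson spikes
#'
#' Bernoulli-per-step thinning: in each step of width `dt` every external
#' neuron spikes independently with probability \eqn{\nu(t) \, dt / 1000}
#' (at most one spike per neuron per step), which converges to the
#' inhomogeneous Poisson process for \eqn{\nu \, dt \ll 1}. Deterministic
#' given `seed`.
#'
#' @param rateFn function of time (ms) returning the commanded rate (Hz), or
#'   a [DriveSpec-class] (then [totalRate()] is used)
#' @param nNeurons number of external neurons
#' @param t0,t1 start and end of the window (ms)
#' @param dt step (ms); `rate * dt / 1000` must stay well below 1
#' @param seed integer seed
#' @return data.frame with columns `neuron` (1-based), `time` (ms, the end
#'   of the generating step), sorted by time
#' @export
generatePoissonSpikes <- function(rateFn, nNeurons, t0 = 0, t1, dt = 0.1,
                                  seed = 1) {
  if (is(rateFn, "DriveSpec")) {
    drive <- rateFn
    rateFn <- function(t) totalRate(t, drive)
  }
  nSteps <- as.integer(round((t1 - t0) / dt))
  tGrid <- t0 + (seq_len(nSteps) - 1) * dt
  rates <- rateFn(tGrid)
  if (any(rates < 0)) stop("rate function returned a negative rate")
  pr <- rates * dt / 1000
  if (any(pr >= 0.5))
    stop("rate * dt too large for Bernoulli thinning; reduce dt")
  set.seed(as.integer(seed))
  k <- rbinom(nSteps, nNeurons, pr)
  hot <- which(k > 0L)
  ids <- lapply(hot, function(s) sample.int(nNeurons, k[s]))
  data.frame(neuron = unlist(ids),
             time = rep.int(tGrid[hot] + dt, k[hot]),
             step = rep.int(hot - 1L, k[hot]))
}

setMethod("show", "DriveSpec", function(object) {
  cat(sprintf(
    "DriveSpec: beta=%g Hz, alpha=%g Hz, plateau [%g, %g] ms, tau=%g/%g ms\n",
    object@beta, object@alpha, object@T1, object@T2, object@tauOn,
    object@tauOff))
  if (nrow(object@pulses))
    cat(sprintf("  + %d pulse(s): %s\n", nrow(object@pulses),
                paste(sprintf("%+g Hz @ %g ms (sigma %g)",
                              object@pulses$amplitude, object@pulses$tPeak,
                              object@pulses$sigma), collapse = "; ")))
})
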