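## Neuron model parameter presets and pointwise dynamics.
##
## The RS (regular spiking, excitatory) and FS (fast spiking, inhibitory)
## presets are the published parameterizations for each model; every value
## can be overridden through `...` in the constructors.

.adexPresets <- list(
  RS = list(C = 200, gL = 10, EL = -65, VT = -50, DeltaT = 2, a = 0,
            b = 100, tauW = 1000, VD = -40, VR = -65, tRef = 5),
  # FS has a = b = 0, so w stays 0 and tauW is inert; any positive value works
  FS = list(C = 200, gL = 10, EL = -65, VT = -48, DeltaT = 0.5, a = 0,
            b = 0, tauW = 500, VD = -40, VR = -65, tRef = 5))

# RS gAbar is not part of the published set: RS adaptation is purely
# spike-triggered (deltaGA) with a 1 s decay. FS adaptation is off entirely.
.cadexPresets <- list(
  RS = list(C = 200, gL = 10, EL = -65, VT = -50, DeltaT = 2, gAbar = 0,
            EA = -65, VA = -30, DeltaA = 1, tauA = 1000, deltaGA = 1,
            VD = -40, VR = -65, tRef = 5),
  FS = list(C = 200, gL = 10, EL = -65, VT = -50, DeltaT = 0.5, gAbar = 0,
            EA = -70, VA = -45, DeltaA = 0.5, tauA = 0.01, deltaGA = 0,
            VD = -40, VR = -65, tRef = 5))

# Na/K conductances are in microsiemens (the nS figure sometimes quoted for
# these kinetics cannot generate action potentials at C = 200 pF); pass
# conductanceUnit = "nS" to load literal nanosiemens values.
.hhPresets <- list(
  RS = list(Cm = 200, gL = 10, gNa = 20, gK = 6, EL = -65, ENa = 60,
            EK = -90, VTshift = -50, VspikeDetect = 0),
  FS = list(Cm = 200, gL = 10, gNa = 20, gK = 6, EL = -65, ENa = 60,
            EK = -90, VTshift = -52, VspikeDetect = 0))

.applyOverrides <- function(preset, dots, who) {
  if (length(dots)) {
    bad <- setdiff(names(dots), names(preset))
    if (length(bad))
      stop(who, ": unknown parameter(s) ", paste(bad, collapse = ", "))
    preset[names(dots)] <- dots
  }
  preset
}

#' AdEx parameter presets
#'
#' Returns the published RS or FS parameter set for the adaptive exponential
#' integrate-and-fire neuron; any slot can be overridden by name. RS:
#' \eqn{V_T = -50} mV, \eqn{\Delta_T = 2} mV, \eqn{b = 100} pA,
#' \eqn{\tau_w = 1000} ms; FS: \eqn{V_T = -48} mV, \eqn{\Delta_T = 0.5} mV,
#' \eqn{b = 0}. Both: \eqn{C = 200} pF, \eqn{g_L = 10} nS,
#' \eqn{E_L = V_R = -65} mV, \eqn{a = 0}, 5 ms refractory. The numerical
#' spike-detection ceiling `VD` defaults to \eqn{-40} mV.
#'
#' @param cellClass "RS" or "FS"
#' @param ... named overrides of individual parameters
#' @return an [AdExParams-class] object
#' @examples
#' adexParams("RS")
#' adexParams("FS", VD = -35)
#' @export
adexParams <- function(cellClass = c("RS", "FS"), ...) {
  cellClass <- match.arg(cellClass)
  p <- .applyOverrides(.adexPresets[[cellClass]], list(...), "adexParams")
  do.call(new, c(list(Class = "AdExParams", cellClass = cellClass), p))
}

#' CAdEx parameter presets
#'
#' RS and FS parameter sets for the conductance-based adaptation variant of
#' AdEx. RS adaptation is spike-triggered only
#' (\eqn{\bar g_A = 0}, \eqn{\delta g_A = 1} nS, \eqn{\tau_A = 1} s);
#' FS adaptation is disabled (\eqn{\bar g_A = \delta g_A = 0}, and the
#' published \eqn{\tau_A = 0.01} ms is kept as printed — the engine's
#' exponential update keeps it stable).
#'
#' @inheritParams adexParams
#' @return a [CAdExParams-class] object
#' @export
cadexParams <- function(cellClass = c("RS", "FS"), ...) {
  cellClass <- match.arg(cellClass)
  p <- .applyOverrides(.cadexPresets[[cellClass]], list(...), "cadexParams")
  do.call(new, c(list(Class = "CAdExParams", cellClass = cellClass), p))
}

#' Hodgkin-Huxley parameter presets
#'
#' Traub-Miles-style single-compartment HH neuron; the RS/FS distinction is
#' the kinetics shift (\eqn{V_T = -50} mV excitatory, \eqn{-52} mV
#' inhibitory). `conductanceUnit = "uS"` (default) interprets `gNa`/`gK` as
#' microsiemens and converts to nS internally.
#'
#' @inheritParams adexParams
#' @param conductanceUnit "uS" or "nS", the unit of the supplied `gNa`, `gK`
#' @return an [HHParams-class] object
#' @export
hhParams <- function(cellClass = c("RS", "FS"), conductanceUnit = c("uS", "nS"),
                     ...) {
  cellClass <- match.arg(cellClass)
  conductanceUnit <- match.arg(conductanceUnit)
  p <- .applyOverrides(.hhPresets[[cellClass]], list(...), "hhParams")
  if (conductanceUnit == "uS") {
    p$gNa <- p$gNa * 1000
    p$gK <- p$gK * 1000
  }
  do.call(new, c(list(Class = "HHParams", cellClass = cellClass,
                      conductanceUnit = conductanceUnit), p))
}

#' Initial/neutral state for a neuron model
#'
#' Membrane potential at the leak reversal, adaptation at zero, HH gating at
#' its steady state for the initial voltage, not refractory.
#'
#' @param p a [NeuronParams-class] object
#' @return named list: `V`, and `w` (AdEx), `gA` (CAdEx) or `n`,`m`,`h` (HH),
#'   plus `refrac`
#' @export
neuronState <- function(p) {
  if (is(p, "AdExParams"))
    return(list(V = p@EL, w = 0, refrac = 0))
  if (is(p, "CAdExParams"))
    return(list(V = p@EL, gA = 0, refrac = 0))
  if (is(p, "HHParams")) {
    r <- hhRateConstants(p@EL, p@VTshift)
    return(list(V = p@EL,
                n = r$an / (r$an + r$bn),
                m = r$am / (r$am + r$bm),
                h = r$ah / (r$ah + r$bh),
                refrac = 0))
  }
  stop("unknown parameter class")
}

.checkFiniteState <- function(state, fields) {
  v <- unlist(state[fields])
  if (any(!is.finite(v))) stop("non-finite neuron state")
  invisible(TRUE)
}

#' AdEx right-hand sides
#'
#' Evaluates the two time derivatives of the AdEx neuron at a given state,
#' with the exponential spike-initiation term:
#' \eqn{\dot V = [g_L(E_L - V) + g_L\Delta_T e^{(V-V_T)/\Delta_T} - w + I_{syn}]/C},
#' \eqn{\dot w = [a(V - E_L) - w]/\tau_w}.
#'
#' @param state list with numeric `V` (mV) and `w` (pA)
#' @param p an [AdExParams-class]
#' @param Isyn synaptic (or injected) current, pA
#' @return named numeric `c(dV = mV/ms, dw = pA/ms)`
#' @export
adexDerivative <- function(state, p, Isyn = 0) {
  stopifnot(is(p, "AdExParams"))
  .checkFiniteState(state, c("V", "w"))
  if (!is.finite(Isyn)) stop("non-finite input current")
  V <- state$V; w <- state$w
  dV <- (p@gL * (p@EL - V) + p@gL * p@DeltaT * exp((V - p@VT) / p@DeltaT) -
           w + Isyn) / p@C
  dw <- (p@a * (V - p@EL) - w) / p@tauW
  c(dV = dV, dw = dw)
}

#' AdEx reset rule
#'
#' Applies the post-spike reset: `V` to `VR`, `w` incremented by `b`, and the
#' refractory clock armed to `tRef`. The caller must only invoke it once `V`
#' has reached the detection ceiling `VD`.
#'
#' @inheritParams adexDerivative
#' @return the updated state list
#' @export
adexReset <- function(state, p) {
  stopifnot(is(p, "AdExParams"))
  if (state$V < p@VD)
    stop("adexReset called with V < VD (no spike)")
  state$V <- p@VR
  state$w <- state$w + p@b
  state$refrac <- p@tRef
  state
}

#' CAdEx right-hand sides
#'
#' \eqn{\dot V = [g_L(E_L-V) + g_L\Delta_T e^{(V-V_T)/\Delta_T} + g_A(E_A - V) + I_{syn}]/C},
#' \eqn{\dot g_A = [\bar g_A/(1 + e^{(V_A - V)/\Delta_A}) - g_A]/\tau_A}.
#'
#' @param state list with numeric `V` (mV) and `gA` (nS)
#' @param p a [CAdExParams-class]
#' @param Isyn synaptic current, pA
#' @return named numeric `c(dV = mV/ms, dgA = nS/ms)`
#' @export
cadexDerivative <- function(state, p, Isyn = 0) {
  stopifnot(is(p, "CAdExParams"))
  .checkFiniteState(state, c("V", "gA"))
  if (!is.finite(Isyn)) stop("non-finite input current")
  V <- state$V; gA <- state$gA
  dV <- (p@gL * (p@EL - V) + p@gL * p@DeltaT * exp((V - p@VT) / p@DeltaT) +
           gA * (p@EA - V) + Isyn) / p@C
  dgA <- (p@gAbar / (1 + exp((p@VA - V) / p@DeltaA)) - gA) / p@tauA
  c(dV = dV, dgA = dgA)
}

#' CAdEx reset rule
#'
#' `V` to `VR`, `gA` incremented by `deltaGA`, refractory clock armed.
#'
#' @inheritParams cadexDerivative
#' @return the updated state list
#' @export
cadexReset <- function(state, p) {
  stopifnot(is(p, "CAdExParams"))
  if (state$V < p@VD)
    stop("cadexReset called with V < VD (no spike)")
  state$V <- p@VR
  state$gA <- state$gA + p@deltaGA
  state$refrac <- p@tRef
  state
}

#' Traub-style HH rate constants
#'
#' The six voltage-dependent transition rates (1/ms) of the n, m, h gating
#' variables, with the removable singularities of the \eqn{x/(e^{x/s}-1)}
#' terms evaluated by their analytic limit.
#'
#' @param V membrane potential (mV)
#' @param VTshift kinetics shift (mV)
#' @return list `an`, `bn`, `am`, `bm`, `ah`, `bh`
#' @export
hhRateConstants <- function(V, VTshift) {
  vtrap <- function(x, s)
    ifelse(abs(x / s) < 1e-9, s * (1 - x / (2 * s)), x / (exp(x / s) - 1))
  D <- V - VTshift
  list(an = 0.032 * vtrap(15 - D, 5),
       bn = 0.5 * exp((10 - D) / 40),
       am = 0.32 * vtrap(13 - D, 4),
       bm = 0.28 * vtrap(D - 40, 5),
       ah = 0.128 * exp((17 - D) / 18),
       bh = 4 / (1 + exp((40 - D) / 5)))
}

#' HH right-hand sides
#'
#' \eqn{\dot V = [-g_L(V-E_L) - g_K n^4 (V-E_K) - g_{Na} m^3 h (V-E_{Na}) + I_{syn}]/C_m}
#' and the standard \eqn{\dot x = \alpha_x(V)(1-x) - \beta_x(V) x} for
#' \eqn{x \in \{n, m, h\}}.
#'
#' @param state list with `V` (mV) and gating `n`, `m`, `h` in \[0,1\]
#' @param p an [HHParams-class]
#' @param Isyn synaptic current, pA
#' @param tol tolerance on the gating-range check
#' @return named numeric `c(dV, dn, dm, dh)`
#' @export
hhDerivative <- function(state, p, Isyn = 0, tol = 1e-6) {
  stopifnot(is(p, "HHParams"))
  .checkFiniteState(state, c("V", "n", "m", "h"))
  g <- c(state$n, state$m, state$h)
  if (any(g < -tol | g > 1 + tol))
    stop("gating variable outside [0,1]")
  V <- state$V
  r <- hhRateConstants(V, p@VTshift)
  dV <- (-p@gL * (V - p@EL) - p@gK * state$n^4 * (V - p@EK) -
           p@gNa * state$m^3 * state$h * (V - p@ENa) + Isyn) / p@Cm
  c(dV = dV,
    dn = r$an * (1 - state$n) - r$bn * state$n,
    dm = r$am * (1 - state$m) - r$bm * state$m,
    dh = r$ah * (1 - state$h) - r$bh * state$h)
}

#' Spike detection rule
#'
#' AdEx/CAdEx emit a spike when the membrane potential reaches the detection
#' ceiling `VD`; HH spikes are upward crossings of `VspikeDetect`.
#'
#' @param modelKind "adex", "cadex" or "hh"
#' @param Vprev,Vnow membrane potential at the previous and current step (mV)
#' @param p the matching [NeuronParams-class]
#' @return logical
#' @export
detectSpike <- function(modelKind = c("adex", "cadex", "hh"), Vprev, Vnow, p) {
  modelKind <- match.arg(modelKind)
  if (modelKind == "hh")
    return(Vprev < p@VspikeDetect && Vnow >= p@VspikeDetect)
  Vnow >= p@VD
}

#' @describeIn adexParams fetch a preset by model name
#' @param model "adex", "cadex" or "hh"
#' @export
neuronParams <- function(model = c("adex", "cadex", "hh"),
                         cellClass = c("RS", "FS"), ...) {
  model <- match.arg(model)
  switch(model,
    adex = adexParams(cellClass, ...),
    cadex = cadexParams(cellClass, ...),
    hh = hhParams(cellClass, ...))
}

# flat key/value form used for serialization and by the engine
paramsToList <- function(p) {
  sn <- setdiff(slotNames(p), "cellClass")
  out <- lapply(sn, function(s) slot(p, s))
  names(out) <- sn
  out
}

#' Write / read a parameter preset as flat JSON
#'
#' Serializes one named parameter set per (model, cell class) pair as a flat
#' key/value JSON object, and reads it back.
#'
#' @param p a [NeuronParams-class]
#' @param path file path
#' @return `readParams` returns the reconstructed parameter object
#' @export
writeParams <- function(p, path) {
  kind <- switch(class(p), AdExParams = "adex", CAdExParams = "cadex",
                 HHParams = "hh")
  x <- c(list(model = kind, cellClass = p@cellClass), paramsToList(p))
  x$conductanceUnit <- NULL
  if (kind == "hh") x$conductanceUnit <- "nS"  # slots already converted
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeParams
#' @export
readParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- x$model; cellClass <- x$cellClass
  x$model <- NULL; x$cellClass <- NULL
  do.call(neuronParams, c(list(model = model, cellClass = cellClass), x))
}

setMethod("show", "NeuronParams", function(object) {
  kind <- class(object)
  cat(sprintf("%s preset '%s'\n", kind, object@cellClass))
  p <- paramsToList(object)
  p <- p[!vapply(p, is.character, TRUE)]
  cat(" ", paste(sprintf("%s=%g", names(p), unlist(p)), collapse = ", "),
      "\n")
})
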