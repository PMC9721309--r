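#' @import methods
#' @importFrom stats rbinom runif cor sd quantile setNames
#' @importFrom utils head tail write.table read.table
NULL

#' Virtual parent of the per-model parameter classes
#'
#' Common parent for [AdExParams-class], [CAdExParams-class] and
#' [HHParams-class]. The `cellClass` slot records which electrophysiological
#' class ("RS" regular spiking, putative excitatory; "FS" fast spiking,
#' putative inhibitory) the parameter set describes.
#'
#' @slot cellClass character, "RS" or "FS".
#' @exportClass NeuronParams
setClass("NeuronParams",
  representation("VIRTUAL", cellClass = "character"))

#' Adaptive exponential integrate-and-fire parameters
#'
#' Parameters of the AdEx neuron
#' \deqn{C \dot V = g_L(E_L - V) + g_L \Delta_T e^{(V - V_T)/\Delta_T} - w + I_{syn}}
#' \deqn{\tau_w \dot w = a (V - E_L) - w}
#' with reset \eqn{V \to V_R}, \eqn{w \to w + b} and a refractory clamp of
#' `tRef` ms whenever `V` reaches the numerical detection ceiling `VD`.
#'
#' @slot C capacitance (pF)
#' @slot gL leak conductance (nS)
#' @slot EL leak reversal (mV)
#' @slot VT threshold slope-point (mV)
#' @slot DeltaT spike-initiation slope factor (mV)
#' @slot a subthreshold adaptation conductance (nS)
#' @slot b spike-triggered adaptation increment (pA)
#' @slot tauW adaptation time constant (ms)
#' @slot VD numerical spike-detection ceiling (mV)
#' @slot VR reset potential (mV)
#' @slot tRef refractory period (ms)
#' @seealso [adexParams()]
#' @exportClass AdExParams
setClass("AdExParams", contains = "NeuronParams",
  representation(C = "numeric", gL = "numeric", EL = "numeric",
    VT = "numeric", DeltaT = "numeric", a = "numeric", b = "numeric",
    tauW = "numeric", VD = "numeric", VR = "numeric", tRef = "numeric"))

setValidity("AdExParams", function(object) {
  v <- unlist(lapply(slotNames(object), function(s) slot(object, s)[1]))
  if (any(!is.finite(suppressWarnings(as.numeric(
        v[setdiff(names(v), "cellClass")])))))
    return("all numeric parameters must be finite")
  msg <- character()
  if (object@C <= 0) msg <- c(msg, "C must be > 0")
  if (object@gL <= 0) msg <- c(msg, "gL must be > 0")
  if (object@DeltaT <= 0) msg <- c(msg, "DeltaT must be > 0")
  if (object@tauW <= 0) msg <- c(msg, "tauW must be > 0")
  if (object@VR >= object@VD) msg <- c(msg, "VR must be < VD")
  if (object@tRef < 0) msg <- c(msg, "tRef must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Conductance-based adaptive exponential (CAdEx) parameters
#'
#' Like AdEx, but adaptation acts as a conductance \eqn{g_A} with reversal
#' \eqn{E_A} and sigmoidal voltage activation:
#' \deqn{C \dot V = g_L(E_L - V) + g_L \Delta_T e^{(V-V_T)/\Delta_T} + g_A (E_A - V) + I_{syn}}
#' \deqn{\tau_A \dot g_A = \bar g_A / (1 + e^{(V_A - V)/\Delta_A}) - g_A}
#' with reset \eqn{V \to V_R}, \eqn{g_A \to g_A + \delta g_A}.
#'
#' @slot C,gL,EL,VT,DeltaT,VD,VR,tRef as in [AdExParams-class]
#' @slot gAbar maximal adaptation conductance (nS)
#' @slot EA adaptation reversal (mV)
#' @slot VA adaptation half-activation voltage (mV)
#' @slot DeltaA adaptation activation slope (mV)
#' @slot tauA adaptation time constant (ms)
#' @slot deltaGA spike-triggered conductance increment (nS)
#' @seealso [cadexParams()]
#' @exportClass CAdExParams
setClass("CAdExParams", contains = "NeuronParams",
  representation(C = "numeric", gL = "numeric", EL = "numeric",
    VT = "numeric", DeltaT = "numeric", gAbar = "numeric", EA = "numeric",
    VA = "numeric", DeltaA = "numeric", tauA = "numeric",
    deltaGA = "numeric", VD = "numeric", VR = "numeric", tRef = "numeric"))

setValidity("CAdExParams", function(object) {
  msg <- character()
  if (object@C <= 0) msg <- c(msg, "C must be > 0")
  if (object@gL <= 0) msg <- c(msg, "gL must be > 0")
  if (object@DeltaT <= 0) msg <- c(msg, "DeltaT must be > 0")
  if (object@tauA <= 0) msg <- c(msg, "tauA must be > 0")
  if (object@DeltaA <= 0) msg <- c(msg, "DeltaA must be > 0")
  if (object@gAbar < 0) msg <- c(msg, "gAbar must be >= 0")
  if (object@deltaGA < 0) msg <- c(msg, "deltaGA must be >= 0")
  if (object@VR >= object@VD) msg <- c(msg, "VR must be < VD")
  if (object@tRef < 0) msg <- c(msg, "tRef must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Hodgkin-Huxley (Traub-Miles kinetics) parameters
#'
#' Single-compartment HH neuron
#' \deqn{C_m \dot V = -g_L (V - E_L) - g_K n^4 (V - E_K) - g_{Na} m^3 h (V - E_{Na}) + I_{syn}}
#' with Traub-style gating kinetics shifted by `VTshift`. There is no reset;
#' spikes are counted as upward crossings of `VspikeDetect` (with a 1 ms
#' lockout in the engine).
#'
#' `conductanceUnit` records the unit of `gNa`/`gK`/`gL` as loaded ("nS" or
#' "uS"); internally everything is converted to nS.
#'
#' @slot Cm capacitance (pF)
#' @slot gL,gNa,gK conductances (nS, after conversion)
#' @slot EL,ENa,EK reversal potentials (mV)
#' @slot VTshift gating kinetics shift (mV)
#' @slot VspikeDetect crossing level for spike counting (mV)
#' @slot conductanceUnit character, unit the Na/K conductances were given in
#' @seealso [hhParams()]
#' @exportClass HHParams
setClass("HHParams", contains = "NeuronParams",
  representation(Cm = "numeric", gL = "numeric", gNa = "numeric",
    gK = "numeric", EL = "numeric", ENa = "numeric", EK = "numeric",
    VTshift = "numeric", VspikeDetect = "numeric",
    conductanceUnit = "character"))

setValidity("HHParams", function(object) {
  msg <- character()
  if (object@Cm <= 0) msg <- c(msg, "Cm must be > 0")
  if (any(c(object@gL, object@gNa, object@gK) < 0))
    msg <- c(msg, "conductances must be >= 0")
  if (object@ENa <= object@EK) msg <- c(msg, "ENa must be > EK")
  if (length(msg)) msg else TRUE
})

#' Two-population spiking network with an external Poisson population
#'
#' Container for the sparse random network: an excitatory (RS) and an
#' inhibitory (FS) population, plus an external excitatory (EXT) population
#' the size of RS whose neurons fire as Poisson processes at the commanded
#' drive rate. Connectivity is Erdos-Renyi per ordered block, stored as
#' sparse boolean patterns of dimension (source x target).
#'
#' @slot populations data.frame with columns `name`, `size`, `modelKind`,
#'   `cellClass`
#' @slot params named list of [NeuronParams-class] objects for RS and FS
#' @slot blocks named list of `ngCMatrix` adjacency patterns, names like
#'   `"FS->RS"`; rows index source neurons, columns target neurons
#' @slot config list echoing the build configuration (probabilities, synaptic
#'   constants, seed, derived per-block seeds)
#' @slot cache environment holding the flattened edge arrays the engine uses
#' @seealso [buildNetwork()], [inDegrees()], [connectivityBlock()]
#' @exportClass SpikingNetwork
setClass("SpikingNetwork",
  representation(populations = "data.frame", params = "list",
    blocks = "list", config = "list", cache = "environment"))

setValidity("SpikingNetwork", function(object) {
  msg <- character()
  pops <- object@populations
  need <- c("name", "size", "modelKind")
  if (!all(need %in% names(pops)))
    msg <- c(msg, "populations must have columns name, size, modelKind")
  else if (any(pops$size <= 0))
    msg <- c(msg, "population sizes must be > 0")
  for (bn in names(object@blocks)) {
    st <- strsplit(bn, "->", fixed = TRUE)[[1]]
    b <- object@blocks[[bn]]
    ns <- pops$size[match(st[1], pops$name)]
    nt <- pops$size[match(st[2], pops$name)]
    if (!isTRUE(nrow(b) == ns && ncol(b) == nt))
      msg <- c(msg, sprintf("block %s has wrong dimensions", bn))
  }
  if (length(msg)) msg else TRUE
})

#' Time course of the external drive
#'
#' The commanded firing rate of the external population: a basal rate
#' `beta` plus a paroxysmal plateau of height `alpha` between `T1` and `T2`
#' with Gaussian-shaped rise (`tauOn`) and decay (`tauOff`), optionally
#' summed with Gaussian stimulation pulses and clipped below at zero.
#'
#' @slot beta basal rate (Hz)
#' @slot alpha plateau amplitude above basal (Hz)
#' @slot T1,T2 plateau start and end (ms)
#' @slot tauOn,tauOff rise and decay time constants (ms)
#' @slot pulses data.frame with columns `amplitude` (Hz, may be negative),
#'   `tPeak` (ms), `sigma` (ms)
#' @seealso [driveSpec()], [perturbationRate()], [totalRate()]
#' @exportClass DriveSpec
setClass("DriveSpec",
  representation(beta = "numeric", alpha = "numeric", T1 = "numeric",
    T2 = "numeric", tauOn = "numeric", tauOff = "numeric",
    pulses = "data.frame"))

setValidity("DriveSpec", function(object) {
  msg <- character()
  if (object@beta < 0) msg <- c(msg, "beta must be >= 0")
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  if (object@T1 >= object@T2) msg <- c(msg, "T1 must be < T2")
  if (object@tauOn <= 0 || object@tauOff <= 0)
    msg <- c(msg, "tauOn and tauOff must be > 0")
  p <- object@pulses
  if (nrow(p) && !all(c("amplitude", "tPeak", "sigma") %in% names(p)))
    msg <- c(msg, "pulses needs columns amplitude, tPeak, sigma")
  if (nrow(p) && any(p$sigma <= 0)) msg <- c(msg, "pulse sigma must be > 0")
  if (length(msg)) msg else TRUE
})

#' Result of one network simulation
#'
#' @slot spikes data.frame with columns `population` ("RS", "FS" or "EXT"),
#'   `neuron` (1-based index within its population) and `time` (ms)
#' @slot vm matrix of sampled membrane potentials, samples x neurons (mV)
#' @slot vmTime sample times (ms)
#' @slot vmNeurons 1-based indices (within `vmPopulation`) of the recorded
#'   neurons
#' @slot vmPopulation which population the voltage samples come from
#' @slot drive data.frame `t`, `rate`: the commanded external rate (Hz)
#' @slot duration simulated time (ms)
#' @slot dt integration step (ms)
#' @slot config list echoing network config, drive, seeds
#' @slot finalState list of state vectors at the last step
#' @seealso [runSimulation()], [populationRate()], [classifyPropagation()]
#' @exportClass SimulationResult
setClass("SimulationResult",
  representation(spikes = "data.frame", vm = "matrix", vmTime = "numeric",
    vmNeurons = "integer", vmPopulation = "character", drive = "data.frame",
    duration = "numeric", dt = "numeric", config = "list",
    finalState = "list"))

setValidity("SimulationResult", function(object) {
  msg <- character()
  sp <- object@spikes
  if (!all(c("population", "neuron", "time") %in% names(sp)))
    msg <- c(msg, "spikes must have columns population, neuron, time")
  else if (nrow(sp) &&
           (min(sp$time) < 0 || max(sp$time) > object@duration + 1e-9))
    msg <- c(msg, "spike times must lie within [0, duration]")
  if (length(msg)) msg else TRUE
})
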