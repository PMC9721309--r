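## Time-stepping engine. The hot loop lives in compiled code (src/engine.cpp):
## forward Euler on the membrane potential, exact exponential decay of the
## synaptic conductances, one-step spike delivery, refractory clamp at VR.

.modelCode <- c(adex = 0L, cadex = 1L, hh = 2L)

.initialStateVectors <- function(net) {
  s <- populationSizes(net)
  N <- s[["RS"]] + s[["FS"]]
  model <- net@config$model
  V <- c(rep(net@params$RS@EL, s[["RS"]]), rep(net@params$FS@EL, s[["FS"]]))
  out <- list(V = V, w = rep(0, N), gE = rep(0, N), gI = rep(0, N),
              refrac = rep(0, N), n = numeric(0), m = numeric(0),
              h = numeric(0))
  if (model == "hh") {
    g <- lapply(list(RS = net@params$RS, FS = net@params$FS), function(p) {
      r <- hhRateConstants(p@EL, p@VTshift)
      c(n = r$an / (r$an + r$bn), m = r$am / (r$am + r$bm),
        h = r$ah / (r$ah + r$bh))
    })
    out$n <- c(rep(g$RS[["n"]], s[["RS"]]), rep(g$FS[["n"]], s[["FS"]]))
    out$m <- c(rep(g$RS[["m"]], s[["RS"]]), rep(g$FS[["m"]], s[["FS"]]))
    out$h <- c(rep(g$RS[["h"]], s[["RS"]]), rep(g$FS[["h"]], s[["FS"]]))
  }
  out
}

.stateFromList <- function(net, state) {
  init <- .initialStateVectors(net)
  for (f in names(state)) {
    if (f == "gA") init$w <- state$gA else init[[f]] <- state[[f]]
  }
  init
}

#' Run a full network simulation
#'
#' Advances the network from rest (or a supplied state) for `duration` ms at
#' step `dt`, with external Poisson spikes drawn from the drive
#' specification. Bit-reproducible for fixed (network, `seed`, `dt`).
#'
#' Each step: synaptic conductances decay by \eqn{e^{-dt/\tau_{syn}}} and
#' receive the quanta emitted in the previous step (\eqn{Q_E = } `QE` per
#' excitatory, \eqn{Q_I = } `QI` per inhibitory presynaptic spike); the
#' synaptic current \eqn{I_{syn} = g_E (E_E - V) + g_I (E_I - V)} drives the
#' neuron update; threshold crossings are reset and armed refractory (V held
#' at `VR`, adaptation still integrating, quanta still accumulating).
#'
#' @param net a [SpikingNetwork-class]
#' @param drive a [DriveSpec-class]
#' @param duration simulated time (ms)
#' @param dt integration step (ms)
#' @param seed drive seed (external spike realization)
#' @param recordPopulation population whose membrane potentials to sample
#'   ("RS" or "FS"), or `NULL` for no voltage recording
#' @param recordIds 1-based neuron indices within `recordPopulation`
#'   (default: all)
#' @param recordEvery sampling cadence for membrane potentials (ms)
#' @param iBias constant injected current (pA): scalar, or one value per
#'   internal neuron
#' @param initState optional named list of state vectors (as in the
#'   `finalState` slot) to start from
#' @param extSpikes optional precomputed external spikes (data.frame with
#'   columns `neuron`, `step`), overriding internal generation — used e.g.
#'   to replay one drive realization at a different `dt`
#' @param keepExtSpikes include the external population's spikes in the
#'   result's spike table (population "EXT")
#' @return a [SimulationResult-class]
#' @examples
#' net <- buildNetwork(networkConfig(N = 100), seed = 1)
#' res <- runSimulation(net, driveSpec(), duration = 200, seed = 1)
#' head(spikes(res))
#' @export
runSimulation <- function(net, drive, duration = 4000, dt = 0.1, seed = 1,
                          recordPopulation = NULL, recordIds = NULL,
                          recordEvery = 1, iBias = 0, initState = NULL,
                          extSpikes = NULL, keepExtSpikes = TRUE) {
  stopifnot(is(net, "SpikingNetwork"), is(drive, "DriveSpec"))
  if (duration <= 0) stop("duration must be > 0")
  s <- populationSizes(net)
  nRS <- s[["RS"]]; nFS <- s[["FS"]]; nExt <- s[["EXT"]]
  nSteps <- as.integer(round(duration / dt))

  if (is.null(extSpikes)) {
    extSpikes <- generatePoissonSpikes(drive, nExt, t0 = 0, t1 = duration,
                                       dt = dt, seed = seed)
  } else if (!"step" %in% names(extSpikes)) {
    # spike at the end of step s lands in step s when replayed at finer dt
    extSpikes$step <- pmin(as.integer(ceiling(extSpikes$time / dt - 1e-9)) -
                             1L, nSteps - 1L)
  }
  extSpikes <- extSpikes[order(extSpikes$step), , drop = FALSE]
  extSpikes <- extSpikes[extSpikes$step < nSteps, , drop = FALSE]

  edges <- edgeArrays(net)
  model <- net@config$model

  recIds0 <- integer(0)
  recEverySteps <- 0L
  if (!is.null(recordPopulation)) {
    recordPopulation <- match.arg(recordPopulation, c("RS", "FS"))
    nPop <- s[[recordPopulation]]
    if (is.null(recordIds)) recordIds <- seq_len(nPop)
    off <- if (recordPopulation == "RS") 0L else nRS
    recIds0 <- as.integer(recordIds - 1L + off)
    recEverySteps <- max(1L, as.integer(round(recordEvery / dt)))
  } else {
    recordIds <- integer(0)
  }

  st <- if (is.null(initState)) .initialStateVectors(net)
        else .stateFromList(net, initState)

  out <- simCore(.modelCode[[model]],
                 paramsToList(net@params$RS), paramsToList(net@params$FS),
                 nRS, nFS, nExt,
                 edges$srcPtr, edges$srcTgt, edges$srcQ,
                 as.integer(extSpikes$step), as.integer(extSpikes$neuron - 1L),
                 dt, nSteps, 0,
                 net@config$EE, net@config$EI, net@config$tauSyn,
                 st$V, st$w, st$gE, st$gI, st$refrac, st$n, st$m, st$h,
                 as.numeric(iBias), recIds0, recEverySteps)

  gid <- out$spikeId
  spk <- data.frame(
    population = ifelse(gid < nRS, "RS", "FS"),
    neuron = ifelse(gid < nRS, gid + 1L, gid - nRS + 1L),
    time = out$spikeTime, stringsAsFactors = FALSE)
  if (keepExtSpikes && nrow(extSpikes)) {
    spk <- rbind(spk, data.frame(population = "EXT",
                                 neuron = extSpikes$neuron,
                                 time = (extSpikes$step + 1) * dt,
                                 stringsAsFactors = FALSE))
  }
  spk <- spk[order(spk$time), , drop = FALSE]
  rownames(spk) <- NULL

  tTrace <- seq(0, duration - dt, by = max(1, dt))
  driveDf <- data.frame(t = tTrace, rate = totalRate(tTrace, drive))

  new("SimulationResult", spikes = spk, vm = out$vm, vmTime = out$vmTime,
      vmNeurons = as.integer(recordIds),
      vmPopulation = if (length(recIds0)) recordPopulation else character(0),
      drive = driveDf, duration = duration, dt = dt,
      config = list(network = net@config,
                    drive = list(beta = drive@beta, alpha = drive@alpha,
                                 T1 = drive@T1, T2 = drive@T2,
                                 tauOn = drive@tauOn, tauOff = drive@tauOff,
                                 pulses = drive@pulses),
                    driveSeed = seed, dt = dt, duration = duration),
      finalState = out$state)
}

#' Advance a network state by one (or a few) explicit steps
#'
#' Low-level access to the integration kernel: starts from a supplied state,
#' applies `nSteps` steps of width `dt`, optionally injecting external
#' spikes at the first step. Used for step-contract checks; normal
#' simulations go through [runSimulation()].
#'
#' @param net a [SpikingNetwork-class]
#' @param state named list of state vectors (`V`, `w`/`gA`, `gE`, `gI`,
#'   `refrac`, HH gating) — missing entries start at rest
#' @param dt step (ms)
#' @param nSteps number of steps
#' @param extIds 1-based external neurons spiking during the first step
#' @param iBias constant injected current (pA)
#' @return list with `state` (updated vectors) and `spikes` (global 0-based
#'   ids and times of internal spikes)
#' @export
advanceStep <- function(net, state = list(), dt = 0.1, nSteps = 1L,
                        extIds = integer(0), iBias = 0) {
  stopifnot(is(net, "SpikingNetwork"))
  s <- populationSizes(net)
  edges <- edgeArrays(net)
  st <- .stateFromList(net, state)
  out <- simCore(.modelCode[[net@config$model]],
                 paramsToList(net@params$RS), paramsToList(net@params$FS),
                 s[["RS"]], s[["FS"]], s[["EXT"]],
                 edges$srcPtr, edges$srcTgt, edges$srcQ,
                 rep(0L, length(extIds)), as.integer(extIds - 1L),
                 dt, as.integer(nSteps), 0,
                 net@config$EE, net@config$EI, net@config$tauSyn,
                 st$V, st$w, st$gE, st$gI, st$refrac, st$n, st$m, st$h,
                 as.numeric(iBias), integer(0), 0L)
  list(state = out$state,
       spikes = data.frame(id = out$spikeId, time = out$spikeTime))
}

#' Simulate one isolated neuron
#'
#' Runs a single neuron of the given parameter set under a constant injected
#' current, recording its membrane potential every step. Convenience built
#' on the same compiled kernel as the network engine.
#'
#' @param p a [NeuronParams-class]
#' @param duration simulated time (ms)
#' @param dt step (ms)
#' @param iBias injected current (pA)
#' @param model neuron model; inferred from `class(p)` by default
#' @return list with `time`, `V` (sampled every step), `spikeTimes`, and the
#'   final `state`
#' @export
simulateNeuron <- function(p, duration = 1000, dt = 0.1, iBias = 0,
                           model = NULL) {
  if (is.null(model))
    model <- switch(class(p), AdExParams = "adex", CAdExParams = "cadex",
                    HHParams = "hh")
  nSteps <- as.integer(round(duration / dt))
  st <- neuronState(p)
  isHH <- model == "hh"
  out <- simCore(.modelCode[[model]], paramsToList(p), paramsToList(p),
                 1L, 0L, 0L,
                 c(0L, 0L), integer(0), 1.5,
                 integer(0), integer(0),
                 dt, nSteps, 0, 0, -80, 5,
                 st$V, if (isHH) 0 else st[[2]], 0, 0, 0,
                 if (isHH) st$n else numeric(0),
                 if (isHH) st$m else numeric(0),
                 if (isHH) st$h else numeric(0),
                 iBias, 0L, 1L)
  list(time = out$vmTime, V = as.numeric(out$vm), spikeTimes = out$spikeTime,
       state = out$state)
}

#' @rdname spikes
#' @export
setMethod("spikes", "SimulationResult", function(object) object@spikes)

#' @rdname membranePotentials
#' @export
setMethod("membranePotentials", "SimulationResult", function(object) {
  v <- object@vm
  attr(v, "time") <- object@vmTime
  attr(v, "neurons") <- object@vmNeurons
  attr(v, "population") <- object@vmPopulation
  v
})

#' @rdname driveTrace
#' @export
setMethod("driveTrace", "SimulationResult", function(object) object@drive)

setMethod("show", "SimulationResult", function(object) {
  sp <- object@spikes
  counts <- table(factor(sp$population, levels = c("RS", "FS", "EXT")))
  cat(sprintf("SimulationResult: %g ms at dt=%g ms\n", object@duration,
              object@dt))
  cat(sprintf("  spikes: RS=%d, FS=%d, EXT=%d\n", counts[["RS"]],
              counts[["FS"]], counts[["EXT"]]))
  if (length(object@vmNeurons))
    cat(sprintf("  Vm: %d %s neurons x %d samples\n",
                length(object@vmNeurons), object@vmPopulation,
                length(object@vmTime)))
})

#' Persist / load a simulation result as a plain-text container
#'
#' Writes a directory holding `spikes.tsv` (population, neuron, time),
#' `spikes_flat.tsv` (two columns: time_ms, global 0-based neuron id —
#' the compact interchange format), `vm.tsv`, `drive.tsv` and
#' `config.json`.
#'
#' @param res a [SimulationResult-class]
#' @param dir output directory
#' @return `readSimulationResult` returns the reconstructed object (without
#'   the final engine state)
#' @export
writeSimulationResult <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(res@spikes, file.path(dir, "spikes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  sizes <- c(RS = 0L, FS = NA_integer_, EXT = NA_integer_)
  cfgN <- res@config$network
  nRS <- round(cfgN$N * (1 - cfgN$fracInhibitory))
  gid <- ifelse(res@spikes$population == "RS", res@spikes$neuron - 1L,
          ifelse(res@spikes$population == "FS", nRS + res@spikes$neuron - 1L,
                 cfgN$N + res@spikes$neuron - 1L))
  write.table(data.frame(time_ms = res@spikes$time, neuron = gid),
              file.path(dir, "spikes_flat.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (length(res@vmNeurons)) {
    vm <- as.data.frame(res@vm)
    names(vm) <- paste0("n", res@vmNeurons)
    vm <- cbind(t = res@vmTime, vm)
    write.table(vm, file.path(dir, "vm.tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  write.table(res@drive, file.path(dir, "drive.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cfg <- res@config
  cfg$network$blockSeeds <- as.list(cfg$network$blockSeeds)
  cfg$duration <- res@duration
  cfg$vmPopulation <- res@vmPopulation
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname writeSimulationResult
#' @export
readSimulationResult <- function(dir) {
  spk <- read.table(file.path(dir, "spikes.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  drv <- read.table(file.path(dir, "drive.tsv"), header = TRUE, sep = "\t")
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  vmPath <- file.path(dir, "vm.tsv")
  vm <- matrix(numeric(0), 0, 0); vmTime <- numeric(0); vmN <- integer(0)
  if (file.exists(vmPath)) {
    v <- read.table(vmPath, header = TRUE, sep = "\t")
    vmTime <- v$t
    vm <- as.matrix(v[, -1, drop = FALSE])
    vmN <- as.integer(sub("^n", "", colnames(vm)))
    dimnames(vm) <- NULL
  }
  new("SimulationResult", spikes = spk, vm = vm, vmTime = vmTime,
      vmNeurons = vmN,
      vmPopulation = if (length(vmN)) as.character(cfg$vmPopulation)
                     else character(0),
      drive = drv, duration = as.numeric(cfg$duration),
      dt = as.numeric(cfg$dt), config = cfg, finalState = list())
}
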