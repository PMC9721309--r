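# Shared fixtures: small networks are built in code, never stored.

smallConfig <- function(N = 100, model = "adex", ...) {
  networkConfig(N = N, model = model, ...)
}

smallNet <- function(N = 100, model = "adex", seed = 1, ...) {
  buildNetwork(smallConfig(N = N, model = model, ...), seed = seed)
}

# a network with no internal synapses: isolates single-neuron dynamics
isolatedNet <- function(N = 100, model = "adex", seed = 1) {
  buildNetwork(networkConfig(N = N, model = model, pDefault = 0, pIE = 0,
                             pII = 0), seed = seed)
}

# a SimulationResult fabricated from an explicit spike table (and optional
# voltage samples), for observable-level contract tests
makeResult <- function(spk, N = 100, duration = 1000, vm = NULL,
                       vmTime = numeric(0), vmNeurons = integer(0),
                       vmPopulation = character(0), drive = driveSpec()) {
  if (is.null(vm)) vm <- matrix(numeric(0), 0, 0)
  new("SimulationResult", spikes = spk, vm = vm, vmTime = vmTime,
      vmNeurons = vmNeurons, vmPopulation = vmPopulation,
      drive = data.frame(t = 0, rate = drive@beta),
      duration = duration, dt = 0.1,
      config = list(network = list(N = N, fracInhibitory = 0.2),
                    drive = list(beta = drive@beta, alpha = drive@alpha,
                                 T1 = drive@T1, T2 = drive@T2,
                                 tauOn = drive@tauOn,
                                 tauOff = drive@tauOff)),
      finalState = list())
}

`%inr%` <- function(x, rng) x >= rng[1] & x <= rng[2]

emptySpikes <- function() {
  data.frame(population = character(0), neuron = integer(0),
             time = numeric(0), stringsAsFactors = FALSE)
}
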