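#' Number of afferent connections per target neuron
#'
#' Column sums of a connectivity block: for each neuron of the target
#' population, the number of connections it receives from the source
#' population.
#'
#' @param object a [SpikingNetwork-class]
#' @param source,target population names ("RS", "FS", "EXT")
#' @return integer vector, one count per target neuron
#' @examples
#' net <- buildNetwork(networkConfig(N = 100), seed = 1)
#' inDegrees(net, "FS", "RS")
#' @export
setGeneric("inDegrees", function(object, source, target)
  standardGeneric("inDegrees"))

#' Population sizes of a network
#' @param object a [SpikingNetwork-class]
#' @return named integer vector (RS, FS, EXT)
#' @export
setGeneric("populationSizes", function(object)
  standardGeneric("populationSizes"))

#' Extract one adjacency block
#' @param object a [SpikingNetwork-class]
#' @param source,target population names
#' @return `ngCMatrix`, rows = source neurons, columns = target neurons
#' @export
setGeneric("connectivityBlock", function(object, source, target)
  standardGeneric("connectivityBlock"))

#' Spike table of a simulation
#' @param object a [SimulationResult-class]
#' @return data.frame with columns population, neuron, time
#' @export
setGeneric("spikes", function(object) standardGeneric("spikes"))

#' Sampled membrane potentials
#' @param object a [SimulationResult-class]
#' @return matrix, samples x recorded neurons; `attr(.,"time")` holds sample
#'   times (ms)
#' @export
setGeneric("membranePotentials", function(object)
  standardGeneric("membranePotentials"))

#' Commanded external drive trace
#' @param object a [SimulationResult-class]
#' @return data.frame `t` (ms), `rate` (Hz)
#' @export
setGeneric("driveTrace", function(object) standardGeneric("driveTrace"))
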