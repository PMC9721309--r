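## Quantitative read-outs: population rates, the propagation classifier,
## per-neuron rate statistics, raster sortings, inhibitory in-degree
## coarse-graining and the Kuramoto order parameter on phase-mapped
## membrane potentials.

#' Binned population firing rate
#'
#' Histogram of spike counts of one population (or of the whole internal
#' network) normalized by population size and bin width:
#' \eqn{\nu(t) = n_{spk} / (N \, \Delta T)}. The reference binning is
#' \eqn{\Delta T = 5} ms, the single-neuron refractory time, which caps the
#' rate at 200 Hz for AdEx/CAdEx.
#'
#' @param result a [SimulationResult-class]
#' @param population "RS", "FS", "EXT", or "all" for RS+FS together
#' @param binWidth bin width (ms)
#' @return data.frame with columns `t` (bin centers, ms) and `rate` (Hz)
#' @export
populationRate <- function(result, population = "RS", binWidth = 5) {
  stopifnot(is(result, "SimulationResult"))
  sp <- result@spikes
  cfgN <- result@config$network
  sizes <- c(RS = round(cfgN$N * (1 - cfgN$fracInhibitory)),
             FS = round(cfgN$N * cfgN$fracInhibitory))
  sizes <- c(sizes, EXT = sizes[["RS"]], all = cfgN$N)
  if (!population %in% names(sizes)) stop("unknown population")
  if (population == "all") sel <- sp$population %in% c("RS", "FS")
  else sel <- sp$population == population
  edges <- seq(0, result@duration, by = binWidth)
  if (edges[length(edges)] < result@duration)
    edges <- c(edges, result@duration)
  counts <- if (any(sel))
    tabulate(findInterval(sp$time[sel], edges, left.open = TRUE,
                          all.inside = TRUE), length(edges) - 1)
  else rep(0L, length(edges) - 1)
  widths <- diff(edges)
  data.frame(t = (head(edges, -1) + tail(edges, -1)) / 2,
             rate = counts / (sizes[[population]] * widths / 1000))
}

#' Classify a run as propagative or non-propagative
#'
#' A run is propagative when the excitatory population develops a firing
#' rate larger than the incoming input: the RS rate averaged over the
#' plateau \eqn{[T_1, T_2]} is compared with the commanded plateau rate
#' \eqn{\beta + \alpha}. `deltaRate` is the signed difference
#' \eqn{\Delta = \bar\nu_e - (\beta + \alpha)} and the label is
#' "propagative" iff \eqn{\Delta > 0} (strict).
#'
#' @param result a [SimulationResult-class]
#' @param drive the [DriveSpec-class] used for the run (defaults to the one
#'   echoed in the result's config)
#' @param binWidth bin width for the rate estimate (ms)
#' @return list with `label` ("propagative"/"non_propagative"), `deltaRate`
#'   (Hz), `meanRate` (Hz), `inputRate` (Hz) and `window` (ms)
#' @export
classifyPropagation <- function(result, drive = NULL, binWidth = 5) {
  stopifnot(is(result, "SimulationResult"))
  if (is.null(drive)) {
    d <- result@config$drive
    drive <- driveSpec(beta = d$beta, alpha = d$alpha, T1 = d$T1, T2 = d$T2,
                       tauOn = d$tauOn, tauOff = d$tauOff)
  }
  if (drive@T2 > result@duration + 1e-9)
    stop("classification window [T1, T2] not covered by the simulation")
  rs <- populationRate(result, "RS", binWidth)
  sel <- rs$t >= drive@T1 & rs$t <= drive@T2
  if (!any(sel)) stop("no rate bins inside [T1, T2]")
  meanRate <- mean(rs$rate[sel])
  input <- drive@beta + drive@alpha
  delta <- meanRate - input
  list(label = if (delta > 0) "propagative" else "non_propagative",
       deltaRate = delta, meanRate = meanRate, inputRate = input,
       window = c(drive@T1, drive@T2))
}

#' Time-averaged single-neuron firing rates
#'
#' Total number of spikes after a discarded transient divided by the
#' remaining integration time.
#'
#' @param result a [SimulationResult-class]
#' @param population "RS" or "FS"
#' @param transient initial interval to discard (ms)
#' @return numeric vector of rates (Hz), one per neuron of the population
#' @export
singleNeuronRates <- function(result, population = "RS", transient = 500) {
  stopifnot(is(result, "SimulationResult"))
  if (transient >= result@duration)
    stop("transient must be shorter than the simulation")
  cfgN <- result@config$network
  sizes <- c(RS = round(cfgN$N * (1 - cfgN$fracInhibitory)),
             FS = round(cfgN$N * cfgN$fracInhibitory))
  sizes <- c(sizes, EXT = sizes[["RS"]])
  sp <- result@spikes
  sel <- sp$population == population & sp$time > transient
  counts <- tabulate(sp$neuron[sel], sizes[[population]])
  counts / ((result@duration - transient) / 1000)
}

#' Pearson correlation between per-neuron rates and in-degrees
#'
#' @param rates per-neuron firing rates (Hz)
#' @param degrees per-neuron in-degrees (same order)
#' @return Pearson correlation coefficient
#' @export
degreeRateCorrelation <- function(rates, degrees) {
  if (length(rates) != length(degrees))
    stop("rates and degrees must have the same length")
  cor(rates, degrees)
}

#' Partition a population by exact inhibitory in-degree
#'
#' Groups neurons that receive exactly the same number of inhibitory (FS)
#' connections — a discrete one-to-one sampling of the inhibitory in-degree
#' distribution (Binomial with mean \eqn{p \, N_{FS} \approx 100} at
#' default scale, realizing roughly sixty to seventy nonempty groups).
#'
#' @param net a [SpikingNetwork-class]
#' @param population target population, "RS" or "FS"
#' @return list of groups, sorted by in-degree; each has `key` (the
#'   in-degree), `members` (1-based neuron indices within the population)
#' @export
groupByInhibitoryIndegree <- function(net, population = "RS") {
  deg <- inDegrees(net, "FS", population)
  keys <- sort(unique(deg))
  lapply(keys, function(k) list(key = k, members = which(deg == k)))
}

#' Mean membrane potential per group
#'
#' Arithmetic mean of the recorded membrane potentials over each group's
#' members at each sample time. The recorded population of `result` must
#' match the population the groups were built on.
#'
#' @param result a [SimulationResult-class] with voltage recording
#' @param groups output of [groupByInhibitoryIndegree()]
#' @return matrix, time samples x groups; columns named by group key;
#'   `attr(.,"time")` holds the sample times
#' @export
groupMeanPotential <- function(result, groups) {
  vm <- result@vm
  if (!length(vm)) stop("result has no membrane potential recording")
  idx <- match(seq_len(max(result@vmNeurons)), result@vmNeurons)
  out <- vapply(groups, function(g) {
    cols <- idx[g$members]
    if (any(is.na(cols))) stop("group member not among recorded neurons")
    rowMeans(vm[, cols, drop = FALSE])
  }, numeric(nrow(vm)))
  colnames(out) <- vapply(groups, function(g) as.character(g$key), "")
  attr(out, "time") <- result@vmTime
  out
}

#' Kuramoto order parameter of phase-mapped membrane potentials
#'
#' Maps voltages linearly from \eqn{[V_R, V_D]} to phases
#' \eqn{\theta \in [0, \pi]} (clipping excursions outside the range, e.g.
#' HH overshoot) and returns the mean resultant
#' \eqn{R e^{i\Psi} = \frac{1}{N}\sum_j e^{i\theta_j}}. The half-circle
#' mapping avoids identifying \eqn{V_R} with \eqn{V_D}. \eqn{R = 1} means
#' full alignment, \eqn{R = 0} none; \eqn{\Psi \in [0, \pi]} is the mean
#' phase.
#'
#' @param V membrane potentials (mV)
#' @param VR,VD phase-map range: reset potential and detection ceiling (mV)
#' @return named numeric `c(R = , Psi = )`
#' @examples
#' kuramotoOrder(c(-65, -65), -65, -40)       # R = 1
#' kuramotoOrder(c(-65, -40), -65, -40)       # antipodal: R = 0
#' @export
kuramotoOrder <- function(V, VR = -65, VD = -40) {
  if (!length(V)) stop("empty group: Kuramoto order undefined")
  if (VR >= VD) stop("VR must be < VD")
  theta <- pi * (pmin(pmax(V, VR), VD) - VR) / (VD - VR)
  z <- mean(exp(1i * theta))
  psi <- Arg(z)
  if (psi < 0) psi <- psi + 2 * pi  # numerically below the real axis
  c(R = Mod(z), Psi = psi)
}

#' Group time series of mu_V, Kuramoto R and mean phase Psi
#'
#' Tidy per-group observables: for every inhibitory in-degree group and
#' every voltage sample time, the group mean membrane potential, the
#' Kuramoto order parameter R and the mean phase Psi.
#'
#' @inheritParams groupMeanPotential
#' @param VR,VD phase-map range for the Kuramoto mapping; default: the
#'   recorded population's reset potential and detection ceiling
#' @return data.frame with columns `group`, `n`, `t`, `muV`, `R`, `Psi`
#' @export
groupProfiles <- function(result, groups, VR = NULL, VD = NULL) {
  vm <- result@vm
  if (!length(vm)) stop("result has no membrane potential recording")
  pop <- result@vmPopulation
  pars <- result@config$network
  if (is.null(VR) || is.null(VD)) {
    pd <- neuronParams(pars$model, pop)
    if (is(pd, "HHParams")) {
      if (is.null(VR)) VR <- -65
      if (is.null(VD)) VD <- pd@VspikeDetect
    } else {
      if (is.null(VR)) VR <- pd@VR
      if (is.null(VD)) VD <- pd@VD
    }
  }
  idx <- match(seq_len(max(result@vmNeurons)), result@vmNeurons)
  res <- lapply(groups, function(g) {
    cols <- idx[g$members]
    sub <- vm[, cols, drop = FALSE]
    theta <- pi * (pmin(pmax(sub, VR), VD) - VR) / (VD - VR)
    z <- rowMeans(exp(1i * theta))
    psi <- Arg(z)
    psi[psi < 0] <- psi[psi < 0] + 2 * pi
    data.frame(group = g$key, n = length(cols), t = result@vmTime,
               muV = rowMeans(sub), R = Mod(z), Psi = psi)
  })
  do.call(rbind, res)
}

#' Raster sort order
#'
#' Permutation of neuron indices for raster display: a stable ascending
#' sort by total spike count during the simulation, or by inhibitory
#' in-degree (ties broken by original index).
#'
#' @param result a [SimulationResult-class]
#' @param key "spike_count" or "inhibitory_indegree"
#' @param population "RS" or "FS"
#' @param net the network (required for the in-degree key)
#' @return integer permutation of `seq_len(N_pop)`
#' @export
sortRaster <- function(result, key = c("spike_count", "inhibitory_indegree"),
                       population = "RS", net = NULL) {
  key <- match.arg(key)
  cfgN <- result@config$network
  nPop <- if (population == "RS") round(cfgN$N * (1 - cfgN$fracInhibitory))
          else round(cfgN$N * cfgN$fracInhibitory)
  v <- if (key == "spike_count") {
    sp <- result@spikes
    sel <- sp$population == population
    tabulate(sp$neuron[sel], nPop)
  } else {
    if (is.null(net)) stop("net is required for the in-degree key")
    inDegrees(net, "FS", population)
  }
  order(v, seq_along(v))
}
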