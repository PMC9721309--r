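## Sparse random two-population network plus the external Poisson population.
##
## Every ordered block (RS/FS/EXT -> RS/FS) is Erdos-Renyi: each ordered pair
## is connected independently with the block's probability. Blocks are drawn
## from independent sub-streams derived from the master connectivity seed, so
## regenerating with a different inhibitory probability reshuffles only the
## inhibitory blocks.

#' Network build configuration
#'
#' Defaults follow the reference cortical patch: 10,000 neurons split 80/20
#' into excitatory (RS) and inhibitory (FS) populations, an external
#' excitatory population the size of RS, 5% connection probability
#' everywhere, quantal conductances \eqn{Q_E = 1.5} nS and \eqn{Q_I = 5} nS,
#' reversals \eqn{E_E = 0} mV and \eqn{E_I = -80} mV, and a 5 ms synaptic
#' decay.
#'
#' @param N total number of internal neurons (RS + FS)
#' @param fracInhibitory fraction of internal neurons that are FS
#' @param pDefault connection probability for all non-inhibitory blocks
#' @param pIE,pII FS->RS and FS->FS connection probabilities (grid-searchable)
#' @param QE,QI quantal synaptic conductances (nS)
#' @param EE,EI synaptic reversal potentials (mV)
#' @param tauSyn synaptic decay time constant (ms)
#' @param model neuron model at the nodes: "adex", "cadex" or "hh"
#' @param paramsRS,paramsFS optional [NeuronParams-class] overrides; defaults
#'   are the presets for `model`
#' @return a list of class `networkConfig`
#' @export
networkConfig <- function(N = 10000, fracInhibitory = 0.2, pDefault = 0.05,
                          pIE = pDefault, pII = pDefault, QE = 1.5, QI = 5,
                          EE = 0, EI = -80, tauSyn = 5,
                          model = c("adex", "cadex", "hh"),
                          paramsRS = NULL, paramsFS = NULL) {
  model <- match.arg(model)
  nFS <- N * fracInhibitory
  if (abs(nFS - round(nFS)) > 1e-9)
    stop("N * fracInhibitory must be an integer population size")
  probs <- c(pDefault = pDefault, pIE = pIE, pII = pII)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (QE <= 0 || QI <= 0) stop("QE and QI must be > 0")
  if (tauSyn <= 0) stop("tauSyn must be > 0")
  cfg <- list(N = as.integer(N), fracInhibitory = fracInhibitory,
              pDefault = pDefault, pIE = pIE, pII = pII, QE = QE, QI = QI,
              EE = EE, EI = EI, tauSyn = tauSyn, model = model,
              paramsRS = if (is.null(paramsRS)) neuronParams(model, "RS")
                         else paramsRS,
              paramsFS = if (is.null(paramsFS)) neuronParams(model, "FS")
                         else paramsFS)
  class(cfg) <- "networkConfig"
  cfg
}

#' Draw one Erdos-Renyi connectivity block
#'
#' Connects each ordered (source, target) pair independently with probability
#' `p`; deterministic for a given `seed`. Generation is column-wise: each
#' target's in-degree is Binomial(`nSource`, `p`) with a uniform subset of
#' sources, which is exactly the independent-pairs law. When
#' `excludeSelf = TRUE` (within-population blocks) the diagonal is excluded.
#'
#' @param nSource,nTarget population sizes
#' @param p connection probability in \[0,1\]
#' @param seed integer seed
#' @param excludeSelf drop self-connections (source i -> target i)
#' @return a sparse pattern matrix (`ngCMatrix`), rows = sources,
#'   columns = targets
#' @examples
#' b <- buildConnectivity(200, 800, 0.05, seed = 7)
#' mean(Matrix::colSums(b)) # ~ 10
#' @export
buildConnectivity <- function(nSource, nTarget, p, seed, excludeSelf = FALSE) {
  if (p < 0 || p > 1) stop("p must lie in [0,1]")
  set.seed(as.integer(seed))
  nEff <- if (excludeSelf) nSource - 1L else nSource
  k <- rbinom(nTarget, nEff, p)
  src <- lapply(seq_len(nTarget), function(j) {
    if (k[j] == 0L) return(integer())
    s <- sample.int(nEff, k[j])
    if (excludeSelf) s <- s + (s >= j)  # skip the diagonal slot
    s
  })
  Matrix::sparseMatrix(i = unlist(src), j = rep.int(seq_len(nTarget), k),
                       dims = c(nSource, nTarget))
}

.blockNames <- c("RS->RS", "RS->FS", "FS->RS", "FS->FS", "EXT->RS",
                 "EXT->FS")

#' Build the full network
#'
#' Constructs RS (\eqn{0.8 N}), FS (\eqn{0.2 N}) and EXT (same size as RS)
#' populations and all six connectivity blocks. Each block is drawn from its
#' own seed sub-stream derived once from `seed`, so rebuilding with different
#' inhibitory probabilities (`pIE`, `pII`) changes only the FS-> blocks.
#'
#' @param cfg a [networkConfig()]
#' @param seed master connectivity seed
#' @return a [SpikingNetwork-class]
#' @examples
#' net <- buildNetwork(networkConfig(N = 500), seed = 42)
#' populationSizes(net)
#' @export
buildNetwork <- function(cfg = networkConfig(), seed = 1) {
  stopifnot(inherits(cfg, "networkConfig"))
  nFS <- as.integer(round(cfg$N * cfg$fracInhibitory))
  nRS <- cfg$N - nFS
  nExt <- nRS
  set.seed(as.integer(seed))
  blockSeeds <- sample.int(.Machine$integer.max - 1L, length(.blockNames))
  names(blockSeeds) <- .blockNames
  sizes <- c(RS = nRS, FS = nFS, EXT = nExt)
  probs <- c("RS->RS" = cfg$pDefault, "RS->FS" = cfg$pDefault,
             "FS->RS" = cfg$pIE, "FS->FS" = cfg$pII,
             "EXT->RS" = cfg$pDefault, "EXT->FS" = cfg$pDefault)
  blocks <- lapply(.blockNames, function(bn) {
    st <- strsplit(bn, "->", fixed = TRUE)[[1]]
    buildConnectivity(sizes[[st[1]]], sizes[[st[2]]], probs[[bn]],
                      seed = blockSeeds[[bn]],
                      excludeSelf = st[1] == st[2])
  })
  names(blocks) <- .blockNames
  pops <- data.frame(
    name = c("RS", "FS", "EXT"),
    size = as.integer(sizes),
    modelKind = c(cfg$model, cfg$model, "poisson"),
    cellClass = c("RS", "FS", NA),
    stringsAsFactors = FALSE)
  conf <- cfg[c("N", "fracInhibitory", "pDefault", "pIE", "pII", "QE", "QI",
                "EE", "EI", "tauSyn", "model")]
  conf$connectivitySeed <- as.integer(seed)
  conf$blockSeeds <- blockSeeds
  new("SpikingNetwork", populations = pops,
      params = list(RS = cfg$paramsRS, FS = cfg$paramsFS),
      blocks = blocks, config = conf, cache = new.env(parent = emptyenv()))
}

#' @rdname populationSizes
#' @export
setMethod("populationSizes", "SpikingNetwork", function(object) {
  setNames(object@populations$size, object@populations$name)
})

#' @rdname connectivityBlock
#' @export
setMethod("connectivityBlock", "SpikingNetwork",
  function(object, source, target) {
    bn <- paste0(source, "->", target)
    if (!bn %in% names(object@blocks))
      stop("no such block: ", bn)
    object@blocks[[bn]]
  })

#' @rdname inDegrees
#' @export
setMethod("inDegrees", "SpikingNetwork", function(object, source, target) {
  as.integer(Matrix::colSums(connectivityBlock(object, source, target)))
})

setMethod("show", "SpikingNetwork", function(object) {
  s <- populationSizes(object)
  cat(sprintf("SpikingNetwork (%s): RS=%d, FS=%d, EXT=%d\n",
              object@config$model, s[["RS"]], s[["FS"]], s[["EXT"]]))
  cat(sprintf("  p(default)=%.3g, p(FS->RS)=%.3g, p(FS->FS)=%.3g, seed=%d\n",
              object@config$pDefault, object@config$pIE, object@config$pII,
              object@config$connectivitySeed))
  ec <- vapply(object@blocks, function(b) length(b@i), 1)
  cat("  edges:", paste(sprintf("%s=%d", names(ec), ec), collapse = ", "),
      "\n")
})

# Flattened edge arrays in the source-major layout the engine consumes:
# sources ordered RS, FS, EXT; targets are 0-based global internal indices
# (RS then FS); srcQ is +QE for excitatory sources and -QI for FS sources
# (the sign routes the quantum to gE or gI). Cached on the network.
edgeArrays <- function(net) {
  cache <- net@cache
  if (!is.null(cache$edges)) return(cache$edges)
  s <- populationSizes(net)
  nRS <- s[["RS"]]; nFS <- s[["FS"]]; nExt <- s[["EXT"]]
  srcOffset <- c(RS = 0L, FS = nRS, EXT = nRS + nFS)
  tgtOffset <- c(RS = 0L, FS = nRS)
  srcAll <- integer(0); tgtAll <- integer(0)
  for (bn in names(net@blocks)) {
    st <- strsplit(bn, "->", fixed = TRUE)[[1]]
    tb <- Matrix::t(net@blocks[[bn]])  # columns = sources, @i = targets
    cnt <- diff(tb@p)
    srcAll <- c(srcAll, rep.int(seq_len(ncol(tb)) - 1L, cnt) +
                  srcOffset[[st[1]]])
    tgtAll <- c(tgtAll, tb@i + tgtOffset[[st[2]]])
  }
  o <- order(srcAll)
  nSrcTotal <- nRS + nFS + nExt
  srcPtr <- c(0L, cumsum(tabulate(srcAll + 1L, nbins = nSrcTotal)))
  edges <- list(
    srcPtr = as.integer(srcPtr),
    srcTgt = tgtAll[o],
    srcQ = c(rep(net@config$QE, nRS), rep(-net@config$QI, nFS),
             rep(net@config$QE, nExt)))
  cache$edges <- edges
  edges
}

#' Export / import a network as a plain-text container
#'
#' Writes a directory with `populations.tsv`, `config.json` and one 0-based
#' two-column edge list per connectivity block (`<source>_<target>.tsv`),
#' plus MatrixMarket pattern files (`.mtx`) for interoperability.
#'
#' @param net a [SpikingNetwork-class]
#' @param dir directory to create/fill
#' @return `readNetwork` returns the reconstructed [SpikingNetwork-class]
#' @export
writeNetwork <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(net@populations, file.path(dir, "populations.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  conf <- net@config
  conf$blockSeeds <- as.list(conf$blockSeeds)
  jsonlite::write_json(conf, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (bn in names(net@blocks)) {
    b <- net@blocks[[bn]]
    el <- data.frame(source = b@i,
                     target = rep.int(seq_len(ncol(b)) - 1L, diff(b@p)))
    fn <- gsub("->", "_", bn, fixed = TRUE)
    write.table(el, file.path(dir, paste0(fn, ".tsv")), sep = "\t",
                row.names = FALSE, quote = FALSE)
    Matrix::writeMM(b, file.path(dir, paste0(fn, ".mtx")))
  }
  invisible(dir)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(dir) {
  pops <- read.table(file.path(dir, "populations.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  conf <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  sizes <- setNames(pops$size, pops$name)
  blocks <- lapply(.blockNames, function(bn) {
    st <- strsplit(bn, "->", fixed = TRUE)[[1]]
    fn <- file.path(dir, paste0(gsub("->", "_", bn, fixed = TRUE), ".tsv"))
    el <- read.table(fn, header = TRUE, sep = "\t")
    Matrix::sparseMatrix(i = el$source + 1L, j = el$target + 1L,
                         dims = c(sizes[[st[1]]], sizes[[st[2]]]))
  })
  names(blocks) <- .blockNames
  new("SpikingNetwork", populations = pops,
      params = list(RS = neuronParams(conf$model, "RS"),
                    FS = neuronParams(conf$model, "FS")),
      blocks = blocks, config = conf,
      cache = new.env(parent = emptyenv()))
}
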