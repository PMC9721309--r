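# Integration loop: conductance decay, quantal delivery, refractoriness,
# reproducibility, numerical convergence.

test_that("synaptic conductances decay exponentially (closed form)", {
  net <- isolatedNet(N = 100)
  # one step of width tau_syn: gE = 3 * e^-1
  st <- advanceStep(net, state = list(gE = rep(3, 100)), dt = 5, nSteps = 1)
  expect_equal(st$state$gE, rep(3 * exp(-1), 100), tolerance = 1e-12)

  # many small steps against the closed form, machine-level tolerance
  st <- advanceStep(net, state = list(gE = rep(3, 100), gI = rep(1, 100)),
                    dt = 0.1, nSteps = 500)
  expect_equal(st$state$gE, rep(3 * exp(-50 / 5), 100), tolerance = 1e-12)
  expect_equal(st$state$gI, rep(1 * exp(-50 / 5), 100), tolerance = 1e-12)
})

test_that("a presynaptic spike increments its targets by exactly Q", {
  net <- smallNet(N = 100, seed = 3)
  tgts <- which(connectivityBlock(net, "EXT", "RS")[5, ])
  stopifnot(length(tgts) > 0)
  # external neuron 5 spikes during step 1; quanta land at step 2
  out <- advanceStep(net, dt = 0.1, nSteps = 2, extIds = 5)
  gE <- out$state$gE[seq_len(80)]  # RS slice
  expect_equal(gE[tgts], rep(net@config$QE, length(tgts)), tolerance = 1e-12)
  expect_true(all(gE[-tgts] == 0))
})

test_that("driving force vanishes at the inhibitory reversal", {
  net <- isolatedNet(N = 100)
  V0 <- rep(net@config$EI, 100)  # -80 mV
  a <- advanceStep(net, state = list(V = V0, gI = rep(50, 100)), dt = 0.1)
  b <- advanceStep(net, state = list(V = V0, gI = rep(0, 100)), dt = 0.1)
  expect_equal(a$state$V, b$state$V, tolerance = 1e-12)
})

test_that("simulations are bit-reproducible under fixed seeds", {
  net <- smallNet(N = 100, seed = 5)
  d <- driveSpec(beta = 80, alpha = 0)
  r1 <- runSimulation(net, d, duration = 500, seed = 17)
  r2 <- runSimulation(net, d, duration = 500, seed = 17)
  expect_identical(spikes(r1), spikes(r2))
  expect_identical(r1@finalState, r2@finalState)
})

test_that("without drive the AdEx network stays silent at its fixed point", {
  net <- smallNet(N = 100, seed = 2)
  res <- runSimulation(net, driveSpec(beta = 0, alpha = 0), duration = 500,
                       seed = 1, recordPopulation = "RS")
  expect_identical(sum(spikes(res)$population != "EXT"), 0L)
  # resting V equals the subthreshold fixed point (oracle: root search)
  p <- net@params$RS
  f <- function(V) p@gL * (p@EL - V) + p@gL * p@DeltaT *
    exp((V - p@VT) / p@DeltaT)
  Vfix <- uniroot(f, c(-65.5, -55), tol = 1e-12)$root
  vm <- membranePotentials(res)
  expect_equal(unname(vm[nrow(vm), 1]), Vfix, tolerance = 1e-4)
})

test_that("refractoriness caps per-neuron firing at one spike per 5 ms", {
  net <- smallNet(N = 100, seed = 5)
  res <- runSimulation(net, driveSpec(beta = 300, alpha = 0),
                       duration = 1000, seed = 3, keepExtSpikes = FALSE)
  sp <- spikes(res)
  expect_gt(nrow(sp), 100)  # strongly driven: the fixture does fire
  for (pop in c("RS", "FS")) {
    byN <- split(sp$time[sp$population == pop], sp$neuron[sp$population ==
                                                            pop])
    gaps <- unlist(lapply(byN, diff))
    if (length(gaps)) expect_gte(min(gaps), 5 - 1e-9)
  }
  # conductances can never be negative
  expect_true(all(res@finalState$gE >= 0))
  expect_true(all(res@finalState$gI >= 0))
})

test_that("halving dt changes fixture spike counts by < 5%", {
  net <- smallNet(N = 100, seed = 7)
  d <- driveSpec(beta = 150, alpha = 0)
  ext <- generatePoissonSpikes(d, 80, t0 = 0, t1 = 1000, dt = 0.1,
                               seed = 11)
  r1 <- runSimulation(net, d, duration = 1000, dt = 0.1, extSpikes = ext,
                      keepExtSpikes = FALSE)
  r2 <- runSimulation(net, d, duration = 1000, dt = 0.05,
                      extSpikes = ext[, c("neuron", "time")],
                      keepExtSpikes = FALSE)
  n1 <- nrow(spikes(r1)); n2 <- nrow(spikes(r2))
  expect_gt(n1, 200)
  expect_lt(abs(n1 - n2) / n1, 0.05)
})

test_that("FS outpaces RS under shared drive (adaptation asymmetry)", {
  net <- buildNetwork(networkConfig(N = 1000), seed = 4)
  res <- runSimulation(net, driveSpec(beta = 40, alpha = 0),
                       duration = 1000, seed = 6, keepExtSpikes = FALSE)
  rs <- mean(singleNeuronRates(res, "RS", transient = 200))
  fs <- mean(singleNeuronRates(res, "FS", transient = 200))
  expect_gt(fs, rs)
})

test_that("a non-finite state raises the divergence error", {
  expect_error(simulateNeuron(adexParams("RS"), duration = 10, iBias = NaN),
               "diverged")
})

test_that("simulation results round-trip through the text container", {
  net <- smallNet(N = 100, seed = 5)
  res <- runSimulation(net, driveSpec(beta = 100, alpha = 0),
                       duration = 200, seed = 2, recordPopulation = "RS",
                       recordIds = 1:5)
  dir <- tempfile()
  writeSimulationResult(res, dir)
  expect_true(all(file.exists(file.path(dir,
    c("spikes.tsv", "spikes_flat.tsv", "vm.tsv", "drive.tsv",
      "config.json")))))
  back <- readSimulationResult(dir)
  expect_equal(spikes(back), spikes(res))
  expect_equal(back@vm, res@vm, tolerance = 1e-12)
  expect_equal(back@duration, res@duration)
  unlink(dir, recursive = TRUE)
})
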