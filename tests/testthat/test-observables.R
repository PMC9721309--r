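# Rates, the propagation classifier, in-degree statistics, coarse-graining
# and the Kuramoto order parameter.

test_that("population rate normalizes by size and bin width", {
  # empty spike table: all-zero series
  r <- populationRate(makeResult(emptySpikes(), N = 100, duration = 100),
                      "RS", 5)
  expect_identical(nrow(r), 20L)
  expect_true(all(r$rate == 0))

  # one spike among 80 RS neurons in a 5 ms bin: 1/(80 * 0.005) = 2.5 Hz
  spk <- data.frame(population = "RS", neuron = 1L, time = 2.5)
  r <- populationRate(makeResult(spk, N = 100, duration = 100), "RS", 5)
  expect_equal(r$rate[1], 1 / (80 * 0.005))
  expect_true(all(r$rate[-1] == 0))

  # every neuron firing once per bin pins the rate at 1000/binWidth = 200 Hz
  spk <- expand.grid(neuron = 1:80, bin = 0:19)
  spk <- data.frame(population = "RS", neuron = spk$neuron,
                    time = spk$bin * 5 + 2.5)
  r <- populationRate(makeResult(spk, N = 100, duration = 100), "RS", 5)
  expect_true(all(abs(r$rate - 200) < 1e-9))
})

test_that("propagation classifier compares plateau RS rate with beta+alpha", {
  d <- driveSpec(beta = 6, alpha = 80, T1 = 100, T2 = 200)

  # silenced excitatory population: non-propagative
  v <- classifyPropagation(makeResult(emptySpikes(), duration = 300,
                                      drive = d), d)
  expect_identical(v$label, "non_propagative")
  expect_equal(v$deltaRate, -86)

  # RS pinned at 200 Hz during the window: propagative
  spk <- expand.grid(neuron = 1:80, bin = 0:59)
  spk <- data.frame(population = "RS", neuron = spk$neuron,
                    time = spk$bin * 5 + 2.5)
  v <- classifyPropagation(makeResult(spk, duration = 300, drive = d), d)
  expect_identical(v$label, "propagative")
  expect_equal(v$deltaRate, 200 - 86, tolerance = 1e-9)

  # exact equality is non-propagative (strict inequality): input 100 Hz
  # needs exactly 40 spikes per 5 ms bin from 80 neurons
  d100 <- driveSpec(beta = 6, alpha = 94, T1 = 100, T2 = 200)
  spk <- expand.grid(neuron = seq_len(40), bin = 20:39)
  spk <- data.frame(population = "RS", neuron = spk$neuron,
                    time = spk$bin * 5 + 2.5)
  v <- classifyPropagation(makeResult(spk, duration = 300, drive = d100),
                           d100)
  expect_identical(v$label, "non_propagative")
  expect_equal(v$deltaRate, 0, tolerance = 1e-9)

  # monotonicity: adding excitatory spikes can only push toward propagative
  set.seed(1)
  spk <- data.frame(population = "RS",
                    neuron = sample(80, 300, TRUE),
                    time = runif(300, 0, 300))
  base <- classifyPropagation(makeResult(spk, duration = 300, drive = d), d)
  extra <- rbind(spk, data.frame(population = "RS",
                                 neuron = sample(80, 100, TRUE),
                                 time = runif(100, 100, 200)))
  more <- classifyPropagation(makeResult(extra, duration = 300, drive = d),
                              d)
  expect_gt(more$deltaRate, base$deltaRate)

  expect_error(classifyPropagation(makeResult(emptySpikes(),
                                              duration = 150, drive = d),
                                   d), "not covered")
})

test_that("single-neuron rates discard the transient", {
  spk <- data.frame(population = "RS", neuron = 3L,
                    time = seq(600, 2500, length.out = 10))
  r <- singleNeuronRates(makeResult(spk, duration = 2500), "RS",
                         transient = 500)
  expect_equal(r[3], 10 / 2)   # 10 spikes in 2 s
  expect_true(all(r[-3] == 0))
  expect_error(singleNeuronRates(makeResult(spk, duration = 2500), "RS",
                                 transient = 2500), "transient")
})

test_that("degree-rate correlation behaves like Pearson's rho", {
  deg <- rbinom(500, 2000, 0.05)
  expect_equal(degreeRateCorrelation(0.1 * deg, deg), 1)
  expect_equal(degreeRateCorrelation(-0.1 * deg, deg), -1)
  set.seed(42)
  expect_lt(abs(degreeRateCorrelation(rnorm(8000), rbinom(8000, 2000,
                                                          0.05))), 0.05)
  expect_error(degreeRateCorrelation(1:3, 1:4), "same length")
})

test_that("in-degree groups partition the population", {
  net <- smallNet(N = 200, seed = 6)
  for (pop in c("RS", "FS")) {
    gr <- groupByInhibitoryIndegree(net, pop)
    members <- unlist(lapply(gr, `[[`, "members"))
    expect_identical(sort(members), seq_along(members))
    expect_identical(length(members), populationSizes(net)[[pop]])
    keys <- vapply(gr, `[[`, 1L, "key")
    expect_identical(keys, sort(keys))
    deg <- inDegrees(net, "FS", pop)
    for (g in gr) expect_true(all(deg[g$members] == g$key))
  }
  # p = 1 collapses everything into a single group
  netFull <- buildNetwork(networkConfig(N = 50, pIE = 1, pII = 1), seed = 1)
  expect_identical(length(groupByInhibitoryIndegree(netFull, "RS")), 1L)
})

test_that("group mean membrane potential averages members", {
  vm <- cbind(c(-70, -65), c(-60, -65), c(-50, -65))
  res <- makeResult(emptySpikes(), duration = 2, vm = vm, vmTime = c(0, 1),
                    vmNeurons = 1:3, vmPopulation = "RS")
  groups <- list(list(key = 1L, members = c(1L, 2L)),
                 list(key = 2L, members = 3L))
  mu <- groupMeanPotential(res, groups)
  expect_equal(unname(mu[, "1"]), c(-65, -65))  # (-70-60)/2, all at VR
  expect_equal(unname(mu[, "2"]), c(-50, -65))  # single member: its own V
  expect_equal(attr(mu, "time"), c(0, 1))
})

test_that("Kuramoto order parameter matches direct complex sums", {
  # identical potentials: full alignment
  expect_equal(kuramotoOrder(rep(-55, 10), -65, -40)[["R"]], 1)
  # antipodal pair VR / VD: cancellation
  expect_equal(kuramotoOrder(c(-65, -40), -65, -40)[["R"]], 0,
               tolerance = 1e-12)
  # phases {0, pi/2, pi/2, pi}: |(1 + 2i - 1)/4| = 0.5, Psi = pi/2
  V <- c(-65, -52.5, -52.5, -40)
  k <- kuramotoOrder(V, -65, -40)
  expect_equal(k[["R"]], 0.5, tolerance = 1e-12)
  expect_equal(k[["Psi"]], pi / 2, tolerance = 1e-12)

  # sample-size invariance: duplicating the data leaves R unchanged
  set.seed(3)
  V <- runif(50, -80, -30)
  expect_equal(kuramotoOrder(c(V, V), -65, -40), kuramotoOrder(V, -65, -40),
               tolerance = 1e-12)

  # R stays in [0,1] and clipping confines out-of-range voltages
  for (i in 1:20) {
    V <- runif(30, -120, 40)
    k <- kuramotoOrder(V, -65, -40)
    expect_true(k[["R"]] >= 0 && k[["R"]] <= 1)
    expect_true(k[["Psi"]] >= 0 && k[["Psi"]] <= pi + 1e-12)
  }
  expect_error(kuramotoOrder(numeric(0)), "empty")
  expect_error(kuramotoOrder(-50, VR = -40, VD = -65), "VR must be")
})

test_that("groupProfiles agrees with per-group direct evaluation", {
  net <- smallNet(N = 100, seed = 9)
  res <- runSimulation(net, driveSpec(beta = 150, alpha = 0),
                       duration = 300, seed = 4, recordPopulation = "RS")
  groups <- groupByInhibitoryIndegree(net, "RS")
  gp <- groupProfiles(res, groups)
  expect_identical(sort(unique(gp$group)),
                   vapply(groups, `[[`, 1L, "key"))
  # cross-check one group at one time against kuramotoOrder / mean
  g <- groups[[which.max(vapply(groups, function(g) length(g$members),
                                1L))]]
  vm <- membranePotentials(res)
  tIdx <- 100
  direct <- kuramotoOrder(vm[tIdx, g$members], -65, -40)
  row <- gp[gp$group == g$key & gp$t == res@vmTime[tIdx], ]
  expect_equal(row$R, direct[["R"]], tolerance = 1e-12)
  expect_equal(row$muV, mean(vm[tIdx, g$members]), tolerance = 1e-12)
})

test_that("raster sorting is stable, ordered and idempotent", {
  spk <- data.frame(population = "RS",
                    neuron = rep(c(3L, 1L, 2L), c(5, 2, 2)),
                    time = seq(1, 9))
  res <- makeResult(spk, N = 100, duration = 10)
  perm <- sortRaster(res, "spike_count")
  counts <- tabulate(spk$neuron, 80)
  expect_true(!is.unsorted(counts[perm]))
  # ties keep original order: neurons 1 and 2 both have 2 spikes
  expect_lt(which(perm == 1), which(perm == 2))
  # all-equal key: identity permutation
  resEmpty <- makeResult(emptySpikes(), N = 100, duration = 10)
  expect_identical(sortRaster(resEmpty, "spike_count"), 1:80)
  # applying the permutation twice equals applying it once to sorted data
  expect_identical(perm[order(seq_along(perm))], perm)

  net <- smallNet(N = 100, seed = 2)
  permDeg <- sortRaster(res, "inhibitory_indegree", net = net)
  deg <- inDegrees(net, "FS", "RS")
  expect_true(!is.unsorted(deg[permDeg]))
})
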