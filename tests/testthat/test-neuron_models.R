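# Pointwise dynamics, resets and spike detection for the three neuron models.

test_that("AdEx derivatives match hand evaluation", {
  rs <- adexParams("RS")

  # at rest with a = 0 the adaptation derivative vanishes
  d <- adexDerivative(list(V = -65, w = 0), rs, Isyn = 0)
  expect_equal(d[["dw"]], 0)

  # at V = VT both leak and exponential term contribute:
  # (gL(EL-VT) + gL*DeltaT*e^0)/C = (10*(-15) + 20)/200 = -0.65 mV/ms
  d <- adexDerivative(list(V = -50, w = 0), rs, Isyn = 0)
  expect_equal(d[["dV"]], -0.65, tolerance = 1e-12)

  # below EL the leak depolarizes
  d <- adexDerivative(list(V = -80, w = 0), rs, Isyn = 0)
  expect_gt(d[["dV"]], 0)

  expect_error(adexDerivative(list(V = NaN, w = 0), rs), "non-finite")
  expect_error(adexDerivative(list(V = -65, w = 0), rs, Isyn = Inf),
               "non-finite")
})

test_that("AdEx reset follows V -> VR, w -> w + b and arms refractoriness", {
  rs <- adexParams("RS")
  fs <- adexParams("FS")

  st <- adexReset(list(V = -40, w = 50, refrac = 0), rs)
  expect_equal(st$V, -65)
  expect_equal(st$w, 150)     # b = 100 pA
  expect_equal(st$refrac, 5)

  st <- adexReset(list(V = -40, w = 0, refrac = 0), fs)
  expect_equal(st$V, -65)
  expect_equal(st$w, 0)       # b = 0 for FS

  # two resets increment w by 2b in total; V maps to VR both times
  st <- adexReset(list(V = -40, w = 0, refrac = 0), rs)
  st$V <- -35  # drive back above the ceiling
  st <- adexReset(st, rs)
  expect_equal(st$w, 200)
  expect_equal(st$V, -65)

  expect_error(adexReset(list(V = -60, w = 0, refrac = 0), rs), "V < VD")
})

test_that("CAdEx derivatives match hand evaluation", {
  rs <- cadexParams("RS")

  # with gAbar = 0 and gA = 0 the adaptation derivative vanishes
  d <- cadexDerivative(list(V = -65, gA = 0), rs, Isyn = 0)
  expect_equal(d[["dgA"]], 0)

  # at half-activation the sigmoid is 1/2: dgA = (gAbar/2)/tauA
  p <- cadexParams("RS", gAbar = 4, tauA = 10)
  d <- cadexDerivative(list(V = p@VA, gA = 0), p, Isyn = 0)
  expect_equal(d[["dgA"]], (4 / 2) / 10, tolerance = 1e-12)

  # adaptation current gA (EA - V) = 2 * (-70 + 65) = -10 pA
  p <- cadexParams("RS", EA = -70)
  d0 <- cadexDerivative(list(V = -65, gA = 0), p, Isyn = 0)
  d2 <- cadexDerivative(list(V = -65, gA = 2), p, Isyn = 0)
  expect_equal((d2[["dV"]] - d0[["dV"]]) * p@C, -10, tolerance = 1e-12)
})

test_that("CAdEx reset increments gA additively", {
  rs <- cadexParams("RS")
  fs <- cadexParams("FS")

  st <- cadexReset(list(V = -40, gA = 0, refrac = 0), rs)
  expect_equal(st$gA, 1)      # deltaGA = 1 nS
  expect_equal(st$V, -65)
  st$V <- -40
  st <- cadexReset(st, rs)
  expect_equal(st$gA, 2)      # strictly additive

  st <- cadexReset(list(V = -40, gA = 0.5, refrac = 0), fs)
  expect_equal(st$gA, 0.5)    # FS deltaGA = 0
})

test_that("HH derivative terms and singular rate values are correct", {
  p <- hhParams("RS", gL = 0)
  # at V = ENa with n = 0 and gL = 0 every current vanishes
  d <- hhDerivative(list(V = p@ENa, n = 0, m = 1, h = 1), p, Isyn = 0)
  expect_equal(d[["dV"]], 0)

  # removable singularities: value at the singular point equals the
  # two-sided limit evaluated just off it
  p <- hhParams("RS")
  for (Vs in c(p@VTshift + 15, p@VTshift + 13, p@VTshift + 40)) {
    r0 <- hhRateConstants(Vs, p@VTshift)
    rp <- hhRateConstants(Vs + 1e-6, p@VTshift)
    rm <- hhRateConstants(Vs - 1e-6, p@VTshift)
    for (nm in names(r0)) {
      expect_equal(r0[[nm]], (rp[[nm]] + rm[[nm]]) / 2, tolerance = 1e-6,
                   label = nm)
    }
  }

  expect_error(hhDerivative(list(V = -65, n = 1.5, m = 0, h = 0), p),
               "outside")
})

test_that("HH resting potential matches the root of the full RHS", {
  p <- hhParams("RS")
  # oracle: root-find dV/dt = 0 with gating at steady state
  rhs <- function(V) {
    r <- hhRateConstants(V, p@VTshift)
    st <- list(V = V, n = r$an / (r$an + r$bn), m = r$am / (r$am + r$bm),
               h = r$ah / (r$ah + r$bh))
    hhDerivative(st, p)[["dV"]]
  }
  Vfix <- uniroot(rhs, c(-90, -50), tol = 1e-10)$root
  # the simulated neuron relaxes to that fixed point
  tr <- simulateNeuron(p, duration = 500, dt = 0.01)
  expect_equal(tail(tr$V, 1), Vfix, tolerance = 1e-3)
  expect_length(tr$spikeTimes, 0)
})

test_that("HH gating variables stay inside [0,1] along trajectories", {
  p <- hhParams("RS")
  for (bias in c(0, 300, 800)) {
    for (dur in c(100, 400, 1000)) {
      tr <- simulateNeuron(p, duration = dur, dt = 0.01, iBias = bias)
      g <- unlist(tr$state[c("n", "m", "h")])
      expect_true(all(g >= 0 & g <= 1))
    }
  }
  # a driven HH neuron actually fires (the uS conductance scale works)
  tr <- simulateNeuron(p, duration = 500, dt = 0.01, iBias = 500)
  expect_gt(length(tr$spikeTimes), 3)
})

test_that("spike detection: ceiling rule for AdEx/CAdEx, crossing for HH", {
  rs <- adexParams("RS")
  hh <- hhParams("RS")
  expect_true(detectSpike("adex", -50, rs@VD, rs))
  expect_false(detectSpike("adex", -50, -45, rs))
  expect_true(detectSpike("cadex", -50, -40, cadexParams("RS")))
  expect_true(detectSpike("hh", -10, 5, hh))    # upward crossing of 0
  expect_false(detectSpike("hh", 5, -10, hh))   # downward
  expect_false(detectSpike("hh", 5, 10, hh))    # already above, no crossing
})

test_that("with a = b = 0 AdEx relaxes to the EIF fixed point", {
  p <- adexParams("RS", b = 0)
  # oracle: brute-force root of gL(EL-V) + gL*DeltaT*exp((V-VT)/DeltaT) = 0
  f <- function(V) p@gL * (p@EL - V) + p@gL * p@DeltaT *
    exp((V - p@VT) / p@DeltaT)
  Vfix <- uniroot(f, c(-65.5, -55), tol = 1e-12)$root
  tr <- simulateNeuron(p, duration = 1000, dt = 0.01)
  expect_equal(tail(tr$V, 1), Vfix, tolerance = 1e-6)
})

test_that("tonic AdEx firing matches a 10x finer reference within 1%", {
  p <- adexParams("RS")
  coarse <- simulateNeuron(p, duration = 2000, dt = 0.01, iBias = 500)
  fine <- simulateNeuron(p, duration = 2000, dt = 0.001, iBias = 500)
  isi <- function(tr) mean(diff(tr$spikeTimes[-(1:2)]))  # drop transient
  expect_gt(length(coarse$spikeTimes), 5)
  expect_equal(isi(coarse), isi(fine), tolerance = 0.01)
})

test_that("parameter presets validate and round-trip through JSON", {
  expect_error(adexParams("RS", C = -1), "C must be")
  expect_error(cadexParams("RS", DeltaA = 0), "DeltaA")
  expect_error(hhParams("RS", EK = 100), "ENa must be > EK")
  expect_error(adexParams("RS", nonsense = 1), "unknown parameter")

  tmp <- tempfile(fileext = ".json")
  for (p in list(adexParams("FS"), cadexParams("RS"), hhParams("FS"))) {
    writeParams(p, tmp)
    q <- readParams(tmp)
    expect_equal(class(q), class(p))
    for (s in setdiff(slotNames(p), "conductanceUnit"))
      expect_equal(slot(q, s), slot(p, s), label = s)
  }
  unlink(tmp)
})
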