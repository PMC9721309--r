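## Config-driven experiment drivers: perturbation-shape grids, inhibitory
## connectivity grids, the timed counter-stimulation protocol, and the
## steady-state versus dynamic in-degree group profiles.

.deriveSeeds <- function(baseSeed, n) {
  set.seed(as.integer(baseSeed))
  matrix(sample.int(.Machine$integer.max - 1L, 2L * n), ncol = 2,
         dimnames = list(NULL, c("connectivity", "drive")))
}

.runAndClassify <- function(net, drive, duration, dt, driveSeed,
                            binWidth = 5) {
  res <- tryCatch(
    runSimulation(net, drive, duration = duration, dt = dt, seed = driveSeed,
                  keepExtSpikes = FALSE),
    error = function(e) e)
  if (inherits(res, "error"))
    return(list(ok = FALSE, message = conditionMessage(res)))
  cls <- classifyPropagation(res, drive, binWidth = binWidth)
  list(ok = TRUE, label = cls$label, delta = cls$deltaRate)
}

#' Grid search over perturbation amplitude and slope
#'
#' For each (alpha, tau) cell, runs `nSeeds` simulations with fresh
#' connectivity and drive seeds and records the fraction of propagative
#' outcomes, together with the mean and SD over realizations of the
#' rate difference \eqn{\Delta = \bar\nu_e - (\beta+\alpha)} (the continuous
#' read-out used for HH networks). Diverged runs are counted and excluded,
#' never silently dropped.
#'
#' @param cfg a [networkConfig()]
#' @param alphas plateau amplitudes to screen (Hz)
#' @param taus rise/decay time constants to screen (ms)
#' @param nSeeds realizations per cell
#' @param beta basal rate (Hz)
#' @param T1,T2 plateau window (ms)
#' @param duration,dt simulation length and step (ms)
#' @param baseSeed master seed from which all per-run seeds derive
#' @return data.frame with one row per grid cell: `alpha`, `tau`, `n`,
#'   `nDiverged`, `fracPropagative`, `meanDelta`, `sdDelta`
#' @export
gridPerturbation <- function(cfg, alphas = seq(50, 120, by = 10),
                             taus = seq(20, 140, by = 20), nSeeds = 10,
                             beta = 6, T1 = 2000, T2 = 3000,
                             duration = T2, dt = 0.1, baseSeed = 1) {
  seeds <- .deriveSeeds(baseSeed, nSeeds)
  grid <- expand.grid(alpha = alphas, tau = taus)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    alpha <- grid$alpha[g]; tau <- grid$tau[g]
    drive <- driveSpec(beta = beta, alpha = alpha, T1 = T1, T2 = T2,
                       tauOn = tau)
    out <- lapply(seq_len(nSeeds), function(s) {
      net <- buildNetwork(cfg, seed = seeds[s, "connectivity"])
      .runAndClassify(net, drive, duration, dt, seeds[s, "drive"])
    })
    ok <- vapply(out, `[[`, TRUE, "ok")
    labs <- vapply(out[ok], `[[`, "", "label")
    deltas <- vapply(out[ok], `[[`, 1, "delta")
    data.frame(alpha = alpha, tau = tau, n = sum(ok),
               nDiverged = sum(!ok),
               fracPropagative = mean(labs == "propagative"),
               meanDelta = mean(deltas), sdDelta = sd(deltas))
  })
  out <- do.call(rbind, rows)
  attr(out, "seeds") <- seeds
  out
}

#' Grid search over the inhibitory connection probabilities
#'
#' Varies only the FS->RS (`pIE`) and FS->FS (`pII`) connection
#' probabilities at a fixed perturbation; because each connectivity block is
#' drawn from its own seed sub-stream, the excitatory and external blocks
#' are bit-identical across grid cells for a given realization.
#'
#' @inheritParams gridPerturbation
#' @param pIEs,pIIs probabilities to screen
#' @param alpha,tau perturbation amplitude (Hz) and time constant (ms)
#' @return data.frame with one row per cell: `pIE`, `pII`, `n`,
#'   `nDiverged`, `fracPropagative`, `meanDelta`, `sdDelta`
#' @export
gridInhibitoryConnectivity <- function(cfg,
                                       pIEs = seq(0.04, 0.06, by = 0.005),
                                       pIIs = seq(0.04, 0.06, by = 0.005),
                                       nSeeds = 10, alpha = 80, tau = 100,
                                       beta = 6, T1 = 2000, T2 = 3000,
                                       duration = T2, dt = 0.1,
                                       baseSeed = 1) {
  seeds <- .deriveSeeds(baseSeed, nSeeds)
  drive <- driveSpec(beta = beta, alpha = alpha, T1 = T1, T2 = T2,
                     tauOn = tau)
  grid <- expand.grid(pIE = pIEs, pII = pIIs)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cfgCell <- cfg
    cfgCell$pIE <- grid$pIE[g]
    cfgCell$pII <- grid$pII[g]
    out <- lapply(seq_len(nSeeds), function(s) {
      net <- buildNetwork(cfgCell, seed = seeds[s, "connectivity"])
      .runAndClassify(net, drive, duration, dt, seeds[s, "drive"])
    })
    ok <- vapply(out, `[[`, TRUE, "ok")
    labs <- vapply(out[ok], `[[`, "", "label")
    deltas <- vapply(out[ok], `[[`, 1, "delta")
    data.frame(pIE = grid$pIE[g], pII = grid$pII[g], n = sum(ok),
               nDiverged = sum(!ok),
               fracPropagative = mean(labs == "propagative"),
               meanDelta = mean(deltas), sdDelta = sd(deltas))
  })
  out <- do.call(rbind, rows)
  attr(out, "seeds") <- seeds
  out
}

#' Timed Gaussian counter-stimulation protocol
#'
#' With the network connectivity held fixed, each drive realization is first
#' run without stimulation and labelled propagative or non-propagative;
#' it is then rerun with a single Gaussian rate pulse (width `sigma`) at
#' each requested peak time and amplitude, using the same drive seed.
#' "Prevented" events are baseline-propagative runs turned non-propagative
#' by the pulse; "triggered" events are the converse. Fractions are
#' reported against both baseline denominators.
#'
#' @inheritParams gridPerturbation
#' @param tPeaks pulse peak times (ms)
#' @param amplitudes pulse amplitudes (Hz, may be negative)
#' @param nRealizations number of drive realizations
#' @param alpha,tau perturbation amplitude (Hz) and time constant (ms)
#' @param sigma pulse width (ms)
#' @param connectivitySeed seed of the single fixed network
#' @return data.frame with one row per (tPeak, amplitude):
#'   `nPropagativeBaseline`, `nNonPropagativeBaseline`, `nPrevented`,
#'   `nTriggered`, `fracPrevented`, `fracTriggered`. The baseline labels are
#'   attached as `attr(., "baseline")`.
#' @export
stimulationProtocol <- function(cfg,
                                tPeaks = c(1500, 1850, 1950, 1975, 2000,
                                           2500),
                                amplitudes = c(1, 5, -1, -5),
                                nRealizations = 20, alpha = 80, tau = 100,
                                sigma = 10, beta = 6, T1 = 2000, T2 = 3000,
                                duration = T2, dt = 0.1,
                                connectivitySeed = 1, baseSeed = 1) {
  net <- buildNetwork(cfg, seed = connectivitySeed)
  set.seed(as.integer(baseSeed))
  driveSeeds <- sample.int(.Machine$integer.max - 1L, nRealizations)
  base <- driveSpec(beta = beta, alpha = alpha, T1 = T1, T2 = T2,
                    tauOn = tau)
  baseline <- vapply(driveSeeds, function(s) {
    r <- .runAndClassify(net, base, duration, dt, s)
    if (!r$ok) NA_character_ else r$label
  }, "")
  usable <- !is.na(baseline)
  grid <- expand.grid(tPeak = tPeaks, amplitude = amplitudes)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    pulse <- stimulusPulse(grid$amplitude[g], grid$tPeak[g], sigma)
    stim <- driveSpec(beta = beta, alpha = alpha, T1 = T1, T2 = T2,
                      tauOn = tau, pulses = pulse)
    lab2 <- vapply(which(usable), function(i) {
      r <- .runAndClassify(net, stim, duration, dt, driveSeeds[i])
      if (!r$ok) NA_character_ else r$label
    }, "")
    b <- baseline[usable]
    ok <- !is.na(lab2)
    nProp <- sum(b[ok] == "propagative")
    nNon <- sum(b[ok] == "non_propagative")
    nPrev <- sum(b[ok] == "propagative" & lab2[ok] == "non_propagative")
    nTrig <- sum(b[ok] == "non_propagative" & lab2[ok] == "propagative")
    data.frame(tPeak = grid$tPeak[g], amplitude = grid$amplitude[g],
               nPropagativeBaseline = nProp,
               nNonPropagativeBaseline = nNon,
               nPrevented = nPrev, nTriggered = nTrig,
               fracPrevented = if (nProp) nPrev / nProp else 0,
               fracTriggered = if (nNon) nTrig / nNon else 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- data.frame(driveSeed = driveSeeds,
                                      label = baseline)
  out
}

.profileFromRun <- function(res, groups, sel = NULL) {
  gp <- groupProfiles(res, groups)
  if (!is.null(sel)) gp <- gp[sel(gp$t), , drop = FALSE]
  agg <- aggregate(gp[, c("muV", "R")], by = list(group = gp$group), mean)
  agg
}

#' Steady-state in-degree group profiles
#'
#' Runs the network under a constant external rate, discards a transient,
#' and averages the group mean membrane potential and Kuramoto R over time
#' and over drive realizations, for each inhibitory in-degree group.
#'
#' @inheritParams gridPerturbation
#' @param fixedRate constant external rate (Hz)
#' @param nSeeds drive realizations
#' @param population profiled population
#' @param transient discarded initial interval (ms)
#' @param connectivitySeed seed of the fixed network
#' @return data.frame `group`, `muV`, `muVse`, `R`, `Rse`, `n` (realizations)
#' @export
staticProfile <- function(cfg, fixedRate = 6, nSeeds = 5, duration = 2000,
                          transient = 500, population = "RS", dt = 0.1,
                          connectivitySeed = 1, baseSeed = 1) {
  net <- buildNetwork(cfg, seed = connectivitySeed)
  groups <- groupByInhibitoryIndegree(net, population)
  drive <- driveSpec(beta = fixedRate, alpha = 0)
  set.seed(as.integer(baseSeed))
  seeds <- sample.int(.Machine$integer.max - 1L, nSeeds)
  per <- lapply(seeds, function(s) {
    res <- runSimulation(net, drive, duration = duration, dt = dt, seed = s,
                         recordPopulation = population,
                         keepExtSpikes = FALSE)
    .profileFromRun(res, groups, sel = function(t) t > transient)
  })
  .combineProfiles(per)
}

#' Dynamic in-degree group profiles at a pre-onset instant
#'
#' Runs the ramping perturbation up to `captureTime` and snapshots the group
#' mean membrane potential and Kuramoto R at that instant, averaged over
#' drive realizations with standard errors.
#'
#' @inheritParams staticProfile
#' @param alpha,tau perturbation amplitude (Hz) and time constant (ms)
#' @param captureTime snapshot time (ms), typically just before onset
#' @return data.frame `group`, `muV`, `muVse`, `R`, `Rse`, `n`
#' @export
dynamicProfile <- function(cfg, alpha = 80, tau = 100, captureTime = 1950,
                           nSeeds = 5, beta = 6, T1 = 2000, T2 = 3000,
                           population = "RS", dt = 0.1,
                           connectivitySeed = 1, baseSeed = 1) {
  net <- buildNetwork(cfg, seed = connectivitySeed)
  groups <- groupByInhibitoryIndegree(net, population)
  drive <- driveSpec(beta = beta, alpha = alpha, T1 = T1, T2 = T2,
                     tauOn = tau)
  set.seed(as.integer(baseSeed))
  seeds <- sample.int(.Machine$integer.max - 1L, nSeeds)
  per <- lapply(seeds, function(s) {
    res <- runSimulation(net, drive, duration = captureTime, dt = dt,
                         seed = s, recordPopulation = population,
                         keepExtSpikes = FALSE)
    tLast <- max(res@vmTime)
    .profileFromRun(res, groups, sel = function(t) t == tLast)
  })
  .combineProfiles(per)
}

# average per-realization group profiles; SE over realizations
.combineProfiles <- function(per) {
  all <- do.call(rbind, Map(cbind, per, rep = seq_along(per)))
  n <- length(per)
  agg <- aggregate(all[, c("muV", "R")], by = list(group = all$group), mean)
  se <- aggregate(all[, c("muV", "R")], by = list(group = all$group),
                  function(x) sd(x) / sqrt(length(x)))
  data.frame(group = agg$group, muV = agg$muV, muVse = se$muV,
             R = agg$R, Rse = se$R, n = n)
}

#' @importFrom stats aggregate
NULL
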