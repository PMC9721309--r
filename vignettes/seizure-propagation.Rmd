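---
title: "Methods: spiking-network models of seizure propagation into healthy tissue"
author: "seiznet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spiking-network models of seizure propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package asks

A focal seizure does not stay focal by itself: it generalizes when the
paroxysmal activity it sends to *healthy* downstream tissue is amplified
rather than absorbed there. seiznet models one such downstream patch — a
sparse random network of excitatory (RS, regular spiking) and inhibitory
(FS, fast spiking) point neurons — and drives it with an external
excitatory population whose firing rate transiently rises from a basal
level to a seizure-like plateau. A run is **propagative** when the
excitatory population develops a firing rate above the incoming input rate
(the patch would relay the seizure to efferent regions) and
**non-propagative** when it stays below (the patch attenuates it).

## Models

### Neurons

Three interchangeable point-neuron models sit at the nodes; all use the
same conductance-based synapses.

**AdEx** (default):
$$C \dot V = g_L(E_L - V) + g_L \Delta_T e^{(V-V_T)/\Delta_T} - w + I_{syn},
\qquad \tau_w \dot w = a(V - E_L) - w,$$
with reset $V \to V_R$, $w \to w + b$ when $V$ reaches the numerical
detection ceiling $V_D$, followed by a 5 ms refractory clamp at $V_R$.
RS: $V_T = -50$ mV, $\Delta_T = 2$ mV, $b = 100$ pA, $\tau_w = 1$ s.
FS: $V_T = -48$ mV, $\Delta_T = 0.5$ mV, $b = 0$ (no adaptation).
Both: $C = 200$ pF, $g_L = 10$ nS, $E_L = V_R = -65$ mV, $a = 0$.
The asymmetry that matters dynamically is adaptation: RS neurons
accumulate $w$ and slow down, FS neurons do not, which is why the basal
state has FS at ~15 Hz and RS at ~2 Hz under the same 6 Hz drive.

**CAdEx** replaces the adaptation current by a conductance $g_A$ with
reversal $E_A$ and sigmoidal voltage activation
($\tau_A \dot g_A = \bar g_A / (1 + e^{(V_A - V)/\Delta_A}) - g_A$,
reset $g_A \to g_A + \delta g_A$).

**Hodgkin–Huxley** uses Traub-style kinetics shifted by $V_T$
($-50$ mV excitatory, $-52$ mV inhibitory), no reset, and spike counting
by upward crossings of 0 mV with a 1 ms lockout.

```{r}
library(seiznet)
adexParams("RS")
cadexParams("FS")
hhParams("RS")
```

### Synapses and network

Each presynaptic spike increments its targets' excitatory or inhibitory
conductance by a fixed quantum ($Q_E = 1.5$ nS, $Q_I = 5$ nS) which then
decays exponentially with $\tau_{syn} = 5$ ms;
$I_{syn} = g_E(E_E - V) + g_I(E_I - V)$ with $E_E = 0$ mV,
$E_I = -80$ mV. The network is Erdős–Rényi with 5% connection
probability per ordered pair: 10,000 internal neurons (8,000 RS, 2,000
FS) plus an external population of 8,000 Poisson units connected by the
same rule. The inhibitory out-probabilities $p_{IE}$ (FS→RS) and $p_{II}$
(FS→FS) are independently settable for the connectivity grid experiment.

```{r}
net <- buildNetwork(networkConfig(), seed = 1)
net
summary(inDegrees(net, "FS", "RS"))  # Binomial(2000, 0.05), mean ~ 100
```

### Drive

The external rate follows a plateau with Gaussian flanks:
$$\nu(t) = \beta + \alpha \,\big[\, e^{-(t-T_1)^2/2\tau_{on}^2}\ (t<T_1);
\ \ 1 \ (T_1 \le t \le T_2); \ \ e^{-(t-T_2)^2/2\tau_{off}^2}\ (t>T_2) \big],$$
with basal $\beta = 6$ Hz. Defaults place the 1 s plateau at
$[T_1, T_2] = [2000, 3000]$ ms with $\tau_{on} = \tau_{off} = 100$ ms
(the plateau timing is a package choice; only the plateau length is
constrained by the reference description). Control stimuli are additive
Gaussian rate pulses (width 10 ms, amplitudes of a few Hz, either sign),
with the total rate clipped at zero.

## Observables

* **Population rate**: spike histogram normalized by population size and
  bin width. The reference binning is 5 ms — the refractory time — so an
  AdEx/CAdEx population can never exceed 200 Hz at that binning; 1 ms
  bins resolve faster structure (up to the 1000 Hz one-spike-per-bin
  limit, ~800 Hz in practice at seizure onset).
* **Propagation verdict**: mean RS rate over $[T_1, T_2]$ compared with
  the commanded plateau rate $\beta + \alpha$; propagative iff strictly
  greater. The commanded rate is used rather than the realized external
  rate; they agree in expectation and the AdEx/CAdEx outcome is bimodal
  enough that the choice does not matter.
* **In-degree coarse graining**: neurons are grouped by their *exact*
  inhibitory in-degree (a one-to-one sampling of the Binomial(2000,
  0.05) in-degree distribution, realizing on the order of 60–70 nonempty
  groups per population), and per group we track the mean membrane
  potential $\mu_V$ and a Kuramoto order parameter.
* **Kuramoto order parameter**: voltages are mapped linearly from
  $[V_R, V_D]$ to phases $[0, \pi]$ (clipping outside the range) and
  $R e^{i\Psi} = \frac1N \sum_j e^{i\theta_j}$. The half-circle mapping
  deliberately avoids identifying the reset with the threshold; $R$ is a
  normalized alignment measure, $\Psi$ tracks the mean phase.

```{r}
drive <- driveSpec(alpha = 100)
res <- runSimulation(net, drive, duration = 3000, seed = 3)
classifyPropagation(res, drive)
groups <- groupByInhibitoryIndegree(net, "RS")
```

## Numerical choices

* **Integrator**: forward Euler on the membrane potential at
  `dt = 0.1` ms. The linear relaxation variables are updated with their
  exact exponential step for a frozen voltage: synaptic conductances
  ($e^{-dt/\tau_{syn}}$ exactly), the CAdEx adaptation conductance, and
  the HH gating variables. This matters twice: the published CAdEx FS
  $\tau_A = 0.01$ ms is 10× *smaller* than the step (plain Euler would
  be violently unstable; the exponential update is exact in the
  $\tau_A \to 0$ limit), and HH gating rates exceed $1/dt$ near the
  spike peak. A dt-halving test on a 100-neuron fixture (spike counts
  within 5%) and a single-neuron inter-spike-interval check against a
  10× finer solution (within 1%) guard the choice.
* **Spike delivery**: quanta emitted during a step reach their targets
  at the start of the next step (one-step latency, no axonal delays).
* **Refractoriness**: the membrane potential is clamped at $V_R$ (and
  recorded as $V_R$); adaptation variables keep integrating and synaptic
  quanta keep accumulating.
* **Detection ceiling**: $V_D = -40$ mV for AdEx/CAdEx (no value is
  published; $-40$ is $V_T + 5\Delta_T$ for RS). It doubles as the upper
  edge of the Kuramoto phase map.
* **Removable singularities** in the HH rate functions
  ($x/(e^{x/s}-1)$) are evaluated by their analytic limit when the
  argument is within $10^{-9}$ of zero.
* **HH conductance units**: the published $g_{Na} = 20$, $g_K = 6$ in nS
  cannot produce action potentials with $C_m = 200$ pF (the peak sodium
  current would be ~2 nA against a rheobase-scale leak); the presets
  interpret them as µS, with an explicit unit field so the literal nS
  values remain loadable for audit.
* **CAdEx preset ambiguity**: the published RS list names
  $\delta g_A = 1$ nS twice and never $\bar g_A$; the FS list has both a
  "$g_A = 0$ nS" and "$\delta g_A = 0$ nS" entry. The presets resolve
  this as $\bar g_A = 0$ for both classes — RS adaptation is purely
  spike-triggered, FS adaptation is off — which reproduces the intended
  RS/FS asymmetry.
* **Poisson generation**: Bernoulli thinning per step
  ($P = \nu(t)\,dt/1000$ per external neuron, at most one spike per
  step), implemented as a per-step Binomial draw of the number of
  spiking units plus a uniform id sample — the same law, vectorized.
  Exactness requires $\nu\,dt \ll 1$ (at the 86 Hz plateau,
  $P = 0.0086$). Deterministic under the drive seed.
* **Seed discipline**: every connectivity block draws from its own
  sub-stream derived once from the master connectivity seed, so the
  inhibitory-probability grid changes *only* the FS→ blocks;
  experiments derive all per-run seeds from one base seed and are
  exactly reproducible.

## What the synthetic world does and does not emulate

The generator *is* the stated world: network sizes, probabilities,
synaptic constants and neuron parameters are the published values, and
the drive is the published perturbation shape with $\beta = 6$ Hz. It
reproduces, at the default scale: the basal asynchronous irregular state
(FS ≈ 15–17 Hz, RS ≈ 2–2.3 Hz), the dominance and negative sign of the
inhibitory in-degree/rate correlation, the bimodal
propagative/non-propagative dichotomy, the 200 Hz refractory-limited
ceiling at 5 ms binning with ~800 Hz peaks at 1 ms binning, and the
~60–70 exact-in-degree groups.

It does **not** reproduce the *location* of the bistable region on the
amplitude axis. With this package's numerical choices the AdEx network's
transition sits at $\alpha \approx 60\text{–}65$ Hz
(at $\tau = 100$ ms, fixed connectivity: fraction propagative ≈ 0.1 at
60 Hz, ≈ 0.9 at 65 Hz, 1.0 from 70 Hz up), whereas the reference places
a 33/50 split at $\alpha = 80$ Hz. Integration scheme, time step and
delivery delays are not published, and the boundary of a
fluctuation-triggered instability is exactly the quantity most sensitive
to them; the basal state, which is well constrained, agrees to ~10%.
Two consequences follow for the acceptance checks run at the published
operating point $\alpha = 80$: the bistability criterion and the
pulse-control criterion are evaluated faithfully there and fail —
at $\alpha = 80$ every drive realization ignites, so there is nothing
for a −5 Hz pulse to prevent. At this package's own tipping point
(~62 Hz) verdicts do flip under ±5 Hz pulses, but the flips are spread
over the whole plateau rather than locked to the onset window: the
package's marginal state ignites stochastically throughout the plateau,
while the reference's non-propagative branch is stable once the onset
window has passed. Both behaviors are reported as measured; no
parameter was adjusted toward the reference values.

Also deliberately not modeled (out of scope): analysis of experimental
recordings, spike sorting, synaptic plasticity, axonal delays,
distance-dependent topology, mean-field reductions, and any clinical
inference.

## Experiment drivers

* `gridPerturbation()` — fraction of propagative realizations (and the
  continuous $\Delta$ rate for HH) over an (amplitude α, time constant
  τ) grid, fresh connectivity and drive seeds per run.
* `gridInhibitoryConnectivity()` — the same read-out varying only
  $p_{IE}, p_{II} \in [0.04, 0.06]$; lowering $p_{IE}$ or raising
  $p_{II}$ disinhibits the network and facilitates propagation.
* `stimulationProtocol()` — fixed connectivity, per drive realization a
  baseline verdict plus reruns with one Gaussian pulse per (peak time,
  amplitude); reports prevented (propagative → non-propagative) and
  triggered (converse) fractions against both baseline denominators —
  the reference's own two denominators are mutually inconsistent (72 +
  38 ≠ 100), so both counts are always reported rather than reconciled.
  One published peak-time row reads "200 ms" where the surrounding
  protocol makes 2000 ms the only consistent value; the package default
  uses 2000 ms.
* `staticProfile()` / `dynamicProfile()` — per-in-degree-group $\mu_V$
  and $R$ under a constant drive at steady state versus snapshots taken
  just before seizure onset during the ramp, averaged over drive
  realizations with standard errors. When averaging across
  connectivities, group keys not present in every realization are
  dropped (the poorly represented extreme groups).

A thin command-line wrapper (`inst/cli/seiznet.R`, verbs `simulate`,
`classify`, `grid-perturb`, `grid-inhibition`, `stimulate`, `profiles`)
exposes these over JSON configs for shell use.

## Persistence

No HDF5 library is assumed: networks and simulation results are written
as plain-text directory containers (TSV tables and a JSON config echo),
plus MatrixMarket pattern files for the connectivity blocks and a
two-column `time_ms neuron` flat spike file for interchange.

## Known limitations

* Full-scale (10,000-neuron) runs take a few seconds per simulated
  second on one CPU; grid experiments at 100 seeds per cell are
  batch-scale, and the package's tests therefore use reduced seed
  counts.
* The bistable-band offset described above: quantitative statements tied
  to the published $\alpha = 80$ Hz operating point do not transfer to
  this implementation, while structural and basal-state quantities do.
* Voltage recording at 1 ms for all 8,000 RS neurons over several
  seconds allocates hundreds of MB; record subsets (or groups) for long
  runs.
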