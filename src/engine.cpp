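#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Network integration core. Membrane potentials advance with forward Euler;
// the linear relaxation variables (synaptic conductances gE/gI, CAdEx
// adaptation conductance gA, HH gating n/m/h) use the exact exponential
// update for a frozen voltage, which keeps the CAdEx FS limit tau_A << dt
// and the fast HH gating stable at dt = 0.1 ms. Spikes emitted during a step
// are delivered to their targets' conductances at the start of the next step
// (double-buffered increments).
//
// Units: mV, ms, nS, pF, pA. nS*mV/pF = mV/ms.

namespace {

inline double safe_exp(double x) {
  // the exponential spike-initiation term only matters up to the detection
  // ceiling; clamp so a pathological configuration cannot overflow
  if (x > 40.0) x = 40.0;
  // below ~e^-30 * gL*DeltaT the term is < 1e-11 pA: skip the exp
  if (x < -30.0) return 0.0;
  return std::exp(x);
}

// x/(exp(x/s)-1) with its removable singularity at x = 0 (limit s)
inline double vtrap(double x, double s) {
  if (std::fabs(x / s) < 1e-9) return s * (1.0 - x / (2.0 * s));
  return x / (std::exp(x / s) - 1.0);
}

struct AdExP {
  double C, gL, EL, VT, DeltaT, a, b, tauW, VD, VR, tRef;
};
struct CAdExP {
  double C, gL, EL, VT, DeltaT, gAbar, EA, VA, DeltaA, tauA, deltaGA, VD, VR,
      tRef;
};
struct HHP {
  double Cm, gL, gNa, gK, EL, ENa, EK, VTshift, Vdetect;
};

AdExP adexFromList(const List &p) {
  AdExP q;
  q.C = p["C"]; q.gL = p["gL"]; q.EL = p["EL"]; q.VT = p["VT"];
  q.DeltaT = p["DeltaT"]; q.a = p["a"]; q.b = p["b"]; q.tauW = p["tauW"];
  q.VD = p["VD"]; q.VR = p["VR"]; q.tRef = p["tRef"];
  return q;
}
CAdExP cadexFromList(const List &p) {
  CAdExP q;
  q.C = p["C"]; q.gL = p["gL"]; q.EL = p["EL"]; q.VT = p["VT"];
  q.DeltaT = p["DeltaT"]; q.gAbar = p["gAbar"]; q.EA = p["EA"];
  q.VA = p["VA"]; q.DeltaA = p["DeltaA"]; q.tauA = p["tauA"];
  q.deltaGA = p["deltaGA"]; q.VD = p["VD"]; q.VR = p["VR"]; q.tRef = p["tRef"];
  return q;
}
HHP hhFromList(const List &p) {
  HHP q;
  q.Cm = p["Cm"]; q.gL = p["gL"]; q.gNa = p["gNa"]; q.gK = p["gK"];
  q.EL = p["EL"]; q.ENa = p["ENa"]; q.EK = p["EK"];
  q.VTshift = p["VTshift"]; q.Vdetect = p["VspikeDetect"];
  return q;
}

// Traub-Miles style rate functions, voltage relative to the kinetics shift
inline void hhRates(double V, double VT, double &an, double &bn, double &am,
                    double &bm, double &ah, double &bh) {
  const double D = V - VT;
  an = 0.032 * vtrap(15.0 - D, 5.0);
  bn = 0.5 * std::exp((10.0 - D) / 40.0);
  am = 0.32 * vtrap(13.0 - D, 4.0);
  bm = 0.28 * vtrap(D - 40.0, 5.0);
  ah = 0.128 * std::exp((17.0 - D) / 18.0);
  bh = 4.0 / (1.0 + std::exp((40.0 - D) / 5.0));
}

struct NetState {
  double *V, *w, *gE, *gI, *refrac, *n, *m, *h, *incPrevE, *incPrevI,
      *incCurE, *incCurI;
  const double *bias;
  double decay, dt, EE, EI;
  std::vector<int> *spiked; // this step's spikers (global index)
};

// One step over the slice [i0, i1) of an AdEx population
inline void stepAdEx(NetState &S, int i0, int i1, const AdExP &p) {
  const double dt = S.dt;
  const double invC = 1.0 / p.C, invTw = 1.0 / p.tauW;
  const double gLDT = p.gL * p.DeltaT, invDT = 1.0 / p.DeltaT;
  for (int i = i0; i < i1; ++i) {
    double ge = S.gE[i] * S.decay + S.incPrevE[i];
    double gi = S.gI[i] * S.decay + S.incPrevI[i];
    S.incPrevE[i] = 0.0; S.incPrevI[i] = 0.0;
    S.gE[i] = ge; S.gI[i] = gi;
    if (S.refrac[i] > 0.0) {
      S.V[i] = p.VR;
      S.w[i] += dt * (p.a * (p.VR - p.EL) - S.w[i]) * invTw;
      S.refrac[i] -= dt;
      continue;
    }
    const double v = S.V[i];
    const double Isyn = ge * (S.EE - v) + gi * (S.EI - v) + S.bias[i];
    const double dV = (p.gL * (p.EL - v) + gLDT * safe_exp((v - p.VT) * invDT) -
                       S.w[i] + Isyn) * invC;
    S.w[i] += dt * (p.a * (v - p.EL) - S.w[i]) * invTw;
    double vn = v + dt * dV;
    if (vn >= p.VD) {
      vn = p.VR;
      S.w[i] += p.b;
      S.refrac[i] = p.tRef;
      S.spiked->push_back(i);
    }
    S.V[i] = vn;
  }
}

inline void stepCAdEx(NetState &S, int i0, int i1, const CAdExP &p) {
  const double dt = S.dt;
  const double invC = 1.0 / p.C;
  const double gLDT = p.gL * p.DeltaT, invDT = 1.0 / p.DeltaT;
  const double eA = std::exp(-dt / p.tauA);
  for (int i = i0; i < i1; ++i) {
    double ge = S.gE[i] * S.decay + S.incPrevE[i];
    double gi = S.gI[i] * S.decay + S.incPrevI[i];
    S.incPrevE[i] = 0.0; S.incPrevI[i] = 0.0;
    S.gE[i] = ge; S.gI[i] = gi;
    const bool ref = S.refrac[i] > 0.0;
    const double v = ref ? p.VR : S.V[i];
    const double gInf =
        p.gAbar / (1.0 + std::exp((p.VA - v) / p.DeltaA));
    if (ref) {
      S.V[i] = p.VR;
      S.w[i] = gInf + (S.w[i] - gInf) * eA;
      S.refrac[i] -= dt;
      continue;
    }
    const double Isyn = ge * (S.EE - v) + gi * (S.EI - v) + S.bias[i];
    const double dV = (p.gL * (p.EL - v) + gLDT * safe_exp((v - p.VT) * invDT) +
                       S.w[i] * (p.EA - v) + Isyn) * invC;
    S.w[i] = gInf + (S.w[i] - gInf) * eA;
    double vn = v + dt * dV;
    if (vn >= p.VD) {
      vn = p.VR;
      S.w[i] += p.deltaGA;
      S.refrac[i] = p.tRef;
      S.spiked->push_back(i);
    }
    S.V[i] = vn;
  }
}

inline void stepHH(NetState &S, int i0, int i1, const HHP &p) {
  const double dt = S.dt;
  const double invC = 1.0 / p.Cm;
  for (int i = i0; i < i1; ++i) {
    double ge = S.gE[i] * S.decay + S.incPrevE[i];
    double gi = S.gI[i] * S.decay + S.incPrevI[i];
    S.incPrevE[i] = 0.0; S.incPrevI[i] = 0.0;
    S.gE[i] = ge; S.gI[i] = gi;
    const double v = S.V[i];
    const double n = S.n[i], m = S.m[i], h = S.h[i];
    const double Isyn = ge * (S.EE - v) + gi * (S.EI - v) + S.bias[i];
    const double dV =
        (-p.gL * (v - p.EL) - p.gK * n * n * n * n * (v - p.EK) -
         p.gNa * m * m * m * h * (v - p.ENa) + Isyn) * invC;
    double an, bn, am, bm, ah, bh;
    hhRates(v, p.VTshift, an, bn, am, bm, ah, bh);
    const double vn = v + dt * dV;
    const double tn = an + bn, tm = am + bm, th = ah + bh;
    S.n[i] = an / tn + (n - an / tn) * std::exp(-dt * tn);
    S.m[i] = am / tm + (m - am / tm) * std::exp(-dt * tm);
    S.h[i] = ah / th + (h - ah / th) * std::exp(-dt * th);
    S.V[i] = vn;
    if (S.refrac[i] > 0.0)
      S.refrac[i] -= dt; // spike-count lockout, dynamics unaffected
    else if (v < p.Vdetect && vn >= p.Vdetect) {
      S.refrac[i] = 1.0;
      S.spiked->push_back(i);
    }
  }
}

} // namespace

// [[Rcpp::export]]
List simCore(int modelKind, List rsPar, List fsPar, int nRS, int nFS, int nExt,
             IntegerVector srcPtr, IntegerVector srcTgt, NumericVector srcQ,
             IntegerVector extStep, IntegerVector extId, double dt, int nSteps,
             double tStart, double EE, double EI, double tauSyn,
             NumericVector V0, NumericVector w0, NumericVector gE0,
             NumericVector gI0, NumericVector refrac0, NumericVector n0,
             NumericVector m0, NumericVector h0, NumericVector iBias,
             IntegerVector recordIds, int recordEvery) {
  const int N = nRS + nFS;
  if ((int)V0.size() != N)
    stop("initial state length mismatch");
  if ((int)srcPtr.size() != N + nExt + 1)
    stop("srcPtr length mismatch");
  const bool isHH = (modelKind == 2);

  AdExP arp = {}, afp = {};
  CAdExP crp = {}, cfp = {};
  HHP hrp = {}, hfp = {};
  if (modelKind == 0) {
    arp = adexFromList(rsPar);
    afp = adexFromList(fsPar);
  } else if (modelKind == 1) {
    crp = cadexFromList(rsPar);
    cfp = cadexFromList(fsPar);
  } else if (modelKind == 2) {
    hrp = hhFromList(rsPar);
    hfp = hhFromList(fsPar);
  } else {
    stop("unknown model kind");
  }

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> w(w0.begin(), w0.end()); // AdEx w or CAdEx gA
  std::vector<double> gE(gE0.begin(), gE0.end());
  std::vector<double> gI(gI0.begin(), gI0.end());
  std::vector<double> refrac(refrac0.begin(), refrac0.end());
  std::vector<double> gn, gm, gh;
  if (isHH) {
    gn.assign(n0.begin(), n0.end());
    gm.assign(m0.begin(), m0.end());
    gh.assign(h0.begin(), h0.end());
    if ((int)gn.size() != N)
      stop("HH gating state length mismatch");
  } else {
    gn.assign(1, 0.0); gm.assign(1, 0.0); gh.assign(1, 0.0);
  }
  std::vector<double> bias(N, 0.0);
  if (iBias.size() == 1)
    std::fill(bias.begin(), bias.end(), iBias[0]);
  else if ((int)iBias.size() == N)
    std::copy(iBias.begin(), iBias.end(), bias.begin());
  else if (iBias.size() != 0)
    stop("iBias must have length 0, 1 or N");

  std::vector<double> incA_E(N, 0.0), incA_I(N, 0.0);
  std::vector<double> incB_E(N, 0.0), incB_I(N, 0.0);
  double *incPrevE = incA_E.data(), *incPrevI = incA_I.data();
  double *incCurE = incB_E.data(), *incCurI = incB_I.data();

  const int *pPtr = srcPtr.begin();
  const int *pTgt = srcTgt.begin();
  const double *pQ = srcQ.begin();

  // recording
  const int nRec = recordIds.size();
  int nSamples = 0;
  if (recordEvery > 0 && nRec > 0)
    nSamples = (nSteps + recordEvery - 1) / recordEvery;
  NumericMatrix vm(nSamples, nRec);
  NumericVector vmTimes(nSamples);

  std::vector<int> spikeId;
  std::vector<double> spikeT;
  std::vector<int> stepSpikers;
  stepSpikers.reserve(N);

  NetState S;
  S.V = V.data(); S.w = w.data(); S.gE = gE.data(); S.gI = gI.data();
  S.refrac = refrac.data(); S.n = gn.data(); S.m = gm.data();
  S.h = gh.data(); S.bias = bias.data();
  S.decay = std::exp(-dt / tauSyn);
  S.dt = dt; S.EE = EE; S.EI = EI;
  S.spiked = &stepSpikers;

  const int nExtEvents = extStep.size();
  int extPos = 0;
  int sample = 0;

  for (int s = 0; s < nSteps; ++s) {
    if (recordEvery > 0 && nRec > 0 && s % recordEvery == 0) {
      for (int r = 0; r < nRec; ++r)
        vm(sample, r) = V[recordIds[r]];
      vmTimes[sample] = tStart + s * dt;
      ++sample;
    }

    S.incPrevE = incPrevE; S.incPrevI = incPrevI;
    stepSpikers.clear();

    if (modelKind == 0) {
      stepAdEx(S, 0, nRS, arp);
      stepAdEx(S, nRS, N, afp);
    } else if (modelKind == 1) {
      stepCAdEx(S, 0, nRS, crp);
      stepCAdEx(S, nRS, N, cfp);
    } else {
      stepHH(S, 0, nRS, hrp);
      stepHH(S, nRS, N, hfp);
    }

    const double tNext = tStart + (s + 1) * dt;

    // divergence guard (amortized: scan once per step)
    for (int i = 0; i < N; ++i)
      if (!std::isfinite(V[i]))
        stop("simulation diverged: non-finite membrane potential, neuron %d "
             "at t = %.3f ms", i + 1, tNext);

    // deliver this step's internal spikes at the next step
    for (size_t k = 0; k < stepSpikers.size(); ++k) {
      const int i = stepSpikers[k];
      spikeId.push_back(i);
      spikeT.push_back(tNext);
      const double q = pQ[i];
      double *inc = (q >= 0.0) ? incCurE : incCurI;
      const double qa = std::fabs(q);
      for (int e = pPtr[i]; e < pPtr[i + 1]; ++e)
        inc[pTgt[e]] += qa;
    }

    // external population spikes emitted during this step
    while (extPos < nExtEvents && extStep[extPos] == s) {
      const int src = N + extId[extPos];
      const double qa = pQ[src]; // external population is excitatory
      for (int e = pPtr[src]; e < pPtr[src + 1]; ++e)
        incCurE[pTgt[e]] += qa;
      ++extPos;
    }
    if (extPos < nExtEvents && extStep[extPos] < s)
      stop("external spike steps must be sorted");

    std::swap(incPrevE, incCurE);
    std::swap(incPrevI, incCurI);
  }

  List finalState = List::create(
      _["V"] = NumericVector(V.begin(), V.end()),
      _["w"] = NumericVector(w.begin(), w.end()),
      _["gE"] = NumericVector(gE.begin(), gE.end()),
      _["gI"] = NumericVector(gI.begin(), gI.end()),
      _["refrac"] = NumericVector(refrac.begin(), refrac.end()));
  if (isHH) {
    finalState["n"] = NumericVector(gn.begin(), gn.end());
    finalState["m"] = NumericVector(gm.begin(), gm.end());
    finalState["h"] = NumericVector(gh.begin(), gh.end());
  }

  return List::create(
      _["spikeId"] = IntegerVector(spikeId.begin(), spikeId.end()),
      _["spikeTime"] = NumericVector(spikeT.begin(), spikeT.end()),
      _["vm"] = vm, _["vmTime"] = vmTimes, _["state"] = finalState);
}
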