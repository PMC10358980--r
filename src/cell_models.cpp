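// Ionic cell models for the monodomain reaction step.
//
// Both models advance the membrane state over one PDE step (dt_ms) using
// nsub reaction substeps: Rush-Larsen updates for gating variables and
// forward Euler for concentrations and the membrane potential.  The
// diffusion operator is handled on the R side (implicit, sparse).
//
// nygren: human atrial cell (Nygren et al. 1998), 28 state variables plus
//   Vm.  Internal time unit is seconds (rate constants as published);
//   dt is converted from ms.
// alievpanfilov: two-variable phenomenological excitable model, used for
//   fast tests and for desk-scale reentry fixtures.  The dimensionless
//   potential u is mapped to mV as Vm = 100*u - 80.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double F_CONST = 96487.0;   // C/mol
static const double R_CONST = 8314.0;    // mJ/(mol K)
static const double T_CONST = 306.15;    // K

// state indices for the Nygren model
enum {
  S_M, S_H1, S_H2, S_DL, S_FL1, S_FL2, S_R, S_S, S_RSUS, S_SSUS, S_N, S_PA,
  S_NAI, S_KI, S_CAI, S_CAD, S_NAC, S_KC, S_CAC,
  S_OC, S_OTC, S_OTMGC, S_OTMGMG, S_OCALSE,
  S_CAUP, S_CAREL, S_F1, S_F2, N_STATE
};

// [[Rcpp::export]]
double nygren_vrest_cpp() { return -74.2525; }

// [[Rcpp::export]]
NumericMatrix nygren_init_cpp(int n) {
  NumericMatrix st(N_STATE, n);
  double init[N_STATE];
  init[S_M] = 3.2017e-3;  init[S_H1] = 0.8814;   init[S_H2] = 0.8742;
  init[S_DL] = 1.3005e-5; init[S_FL1] = 0.9986;  init[S_FL2] = 0.9986;
  init[S_R] = 1.0678e-3;  init[S_S] = 0.9490;    init[S_RSUS] = 1.5949e-4;
  init[S_SSUS] = 0.9912;  init[S_N] = 4.8357e-3; init[S_PA] = 1.0e-4;
  init[S_NAI] = 8.5547;   init[S_KI] = 129.435;  init[S_CAI] = 6.729e-5;
  init[S_CAD] = 7.2495e-5; init[S_NAC] = 130.011; init[S_KC] = 5.3581;
  init[S_CAC] = 1.8147;
  init[S_OC] = 0.0275;    init[S_OTC] = 0.0133;  init[S_OTMGC] = 0.1961;
  init[S_OTMGMG] = 0.7094; init[S_OCALSE] = 0.4369;
  init[S_CAUP] = 0.6646;  init[S_CAREL] = 0.6465;
  init[S_F1] = 0.4284;    init[S_F2] = 0.0028;
  for (int j = 0; j < n; ++j)
    for (int k = 0; k < N_STATE; ++k) st(k, j) = init[k];
  return st;
}

static inline double rl(double x, double xinf, double tau, double dt) {
  return xinf + (x - xinf) * std::exp(-dt / tau);
}

// Advance all nodes by dt_ms using nsub substeps.  vm in mV, istim in
// mV/ms (added directly to dV/dt).  vm and state are modified in place.
// [[Rcpp::export]]
void nygren_step_cpp(NumericVector vm, NumericMatrix state,
                     NumericVector istim, double dt_ms, int nsub) {
  const int n = vm.size();
  const double dt = (dt_ms / nsub) / 1000.0;  // seconds
  const double RTF = R_CONST * T_CONST / F_CONST;  // ~26.38 mV
  const double Cm = 0.05;          // nF
  const double PNa = 0.0016;       // nL/s
  const double Voli = 0.005884, Volc = 0.136 * 0.005884;
  const double Vold = 0.02 * 0.005884, Volrel = 4.41e-5, Volup = 3.969e-4;
  const double phiNaEn = -1.68;    // pA, electroneutral Na influx

  for (int j = 0; j < n; ++j) {
    double V = vm[j];
    double *s = &state(0, j);
    const double stim_mV_per_s = istim[j] * 1000.0;
    for (int sub = 0; sub < nsub; ++sub) {
      const double Nai = s[S_NAI], Ki = s[S_KI], Cai = s[S_CAI];
      const double Cad = s[S_CAD], Nac = s[S_NAC], Kc = s[S_KC],
                   Cac = s[S_CAC];
      const double ENa = RTF * std::log(Nac / Nai);
      const double EK = RTF * std::log(Kc / Ki);
      const double ECa = 0.5 * RTF * std::log(Cac / Cai);

      // INa (GHK form); guard the V ~ 0 singularity
      double vf = V / RTF;
      double ghk = (std::fabs(vf) < 1e-6)
        ? RTF * (std::exp((V - ENa) / RTF) - 1.0) / (1.0 + 0.5 * vf)
        : V * (std::exp((V - ENa) / RTF) - 1.0) / (std::exp(vf) - 1.0);
      const double iNa = PNa * s[S_M] * s[S_M] * s[S_M] *
        (0.9 * s[S_H1] + 0.1 * s[S_H2]) * Nac * F_CONST / RTF * ghk;

      const double fCa = Cad / (Cad + 0.025);
      const double iCaL = 6.75 * s[S_DL] *
        (fCa * s[S_FL1] + (1.0 - fCa) * s[S_FL2]) * (V - 60.0);

      const double iT = 7.5 * s[S_R] * s[S_S] * (V - EK);
      const double iSus = 2.75 * s[S_RSUS] * s[S_SSUS] * (V - EK);
      const double iKs = 1.0 * s[S_N] * (V - EK);
      const double pii = 1.0 / (1.0 + std::exp((V + 55.0) / 24.0));
      const double iKr = 0.5 * s[S_PA] * pii * (V - EK);
      const double iK1 = 3.0 * std::pow(Kc, 0.4457) * (V - EK) /
        (1.0 + std::exp(1.5 * (V - EK + 3.6) / RTF));
      const double iBNa = 0.060599 * (V - ENa);
      const double iBCa = 0.078681 * (V - ECa);
      const double na15 = std::pow(Nai, 1.5);
      const double iNaK = 70.8253 * Kc / (Kc + 1.0) * na15 /
        (na15 + 36.4829) * (V + 150.0) / (V + 200.0);  // 11^1.5 = 36.4829
      const double iCaP = 4.0 * Cai / (Cai + 0.0002);
      const double nai3 = Nai * Nai * Nai, nac3 = Nac * Nac * Nac;
      const double iNaCa = 0.0374842 *
        (nai3 * Cac * std::exp(0.45 * V / RTF) -
         nac3 * Cai * std::exp(-0.55 * V / RTF)) /
        (1.0 + 0.0003 * (nac3 * Cai + nai3 * Cac));

      const double iTot = iNa + iCaL + iT + iSus + iK1 + iKr + iKs +
        iBNa + iBCa + iNaK + iCaP + iNaCa;

      // gates: Rush-Larsen
      double minf = 1.0 / (1.0 + std::exp(-(V + 27.12) / 8.21));
      double taum = 4.2e-5 * std::exp(-std::pow((V + 25.57) / 28.8, 2)) + 2.4e-5;
      double hinf = 1.0 / (1.0 + std::exp((V + 63.6) / 5.3));
      double tauh1 = 0.03 / (1.0 + std::exp((V + 35.1) / 3.2)) + 3.0e-4;
      double tauh2 = 0.12 / (1.0 + std::exp((V + 35.1) / 3.2)) + 3.0e-3;
      double dlinf = 1.0 / (1.0 + std::exp(-(V + 9.0) / 5.8));
      double taudl = 0.0027 * std::exp(-std::pow((V + 35.0) / 30.0, 2)) + 0.002;
      double flinf = 1.0 / (1.0 + std::exp((V + 27.4) / 7.1));
      double taufl1 = 0.161 * std::exp(-std::pow((V + 40.0) / 14.4, 2)) + 0.010;
      double taufl2 = 1.3323 * std::exp(-std::pow((V + 40.0) / 14.2, 2)) + 0.0626;
      double rinf = 1.0 / (1.0 + std::exp(-(V - 1.0) / 11.0));
      double taur = 0.0035 * std::exp(-std::pow(V / 30.0, 2)) + 0.0015;
      double sinf = 1.0 / (1.0 + std::exp((V + 40.5) / 11.5));
      double taus = 0.4812 * std::exp(-std::pow((V + 52.45) / 14.97, 2)) + 0.01414;
      double rsusinf = 1.0 / (1.0 + std::exp(-(V + 4.3) / 8.0));
      double taursus = 0.009 / (1.0 + std::exp((V + 5.0) / 12.0)) + 5.0e-4;
      double ssusinf = 0.4 / (1.0 + std::exp((V + 20.0) / 10.0)) + 0.6;
      double taussus = 0.047 / (1.0 + std::exp((V + 60.0) / 10.0)) + 0.3;
      double ninf = 1.0 / (1.0 + std::exp(-(V - 19.9) / 12.7));
      double taun = 0.7 + 0.4 * std::exp(-std::pow((V - 20.0) / 20.0, 2));
      double painf = 1.0 / (1.0 + std::exp(-(V + 15.0) / 6.0));
      double taupa = 0.03118 + 0.21718 *
        std::exp(-std::pow((V + 20.1376) / 22.1996, 2));

      s[S_M] = rl(s[S_M], minf, taum, dt);
      s[S_H1] = rl(s[S_H1], hinf, tauh1, dt);
      s[S_H2] = rl(s[S_H2], hinf, tauh2, dt);
      s[S_DL] = rl(s[S_DL], dlinf, taudl, dt);
      s[S_FL1] = rl(s[S_FL1], flinf, taufl1, dt);
      s[S_FL2] = rl(s[S_FL2], flinf, taufl2, dt);
      s[S_R] = rl(s[S_R], rinf, taur, dt);
      s[S_S] = rl(s[S_S], sinf, taus, dt);
      s[S_RSUS] = rl(s[S_RSUS], rsusinf, taursus, dt);
      s[S_SSUS] = rl(s[S_SSUS], ssusinf, taussus, dt);
      s[S_N] = rl(s[S_N], ninf, taun, dt);
      s[S_PA] = rl(s[S_PA], painf, taupa, dt);

      // Ca handling
      const double idi = (Cad - Cai) * 2.0 * F_CONST * Vold / 0.010;
      const double iup = 2800.0 *
        (Cai / 0.0003 - 0.16 * s[S_CAUP] / 0.5) /
        ((Cai + 0.0003) / 0.0003 + 0.4 * (s[S_CAUP] + 0.5) / 0.5);
      const double itr = (s[S_CAUP] - s[S_CAREL]) * 2.0 * F_CONST *
        Volrel / 0.010;
      const double reli = std::pow(Cai / (Cai + 0.0003), 4);
      const double reld = std::pow(Cad / (Cad + 0.003), 4);
      const double ract = 203.8 * (reli + reld);
      const double rinact = 33.96 + 339.6 * reli;
      const double f2frac = s[S_F2] / (s[S_F2] + 0.25);
      const double irel = 200000.0 * f2frac * f2frac * (s[S_CAREL] - Cai);

      const double dOC = 200000.0 * Cai * (1.0 - s[S_OC]) - 476.0 * s[S_OC];
      const double dOTC = 78400.0 * Cai * (1.0 - s[S_OTC]) - 392.0 * s[S_OTC];
      const double dOTMgC = 200000.0 * Cai *
        (1.0 - s[S_OTMGC] - s[S_OTMGMG]) - 6.6 * s[S_OTMGC];
      const double dOTMgMg = 2000.0 * 2.5 *
        (1.0 - s[S_OTMGC] - s[S_OTMGMG]) - 666.0 * s[S_OTMGMG];
      const double dOCalse = 480.0 * s[S_CAREL] * (1.0 - s[S_OCALSE]) -
        400.0 * s[S_OCALSE];

      const double dCai =
        -(-idi + iBCa + iCaP - 2.0 * iNaCa + iup - irel) /
        (2.0 * Voli * F_CONST) -
        (0.045 * dOC + 0.08 * dOTC + 0.16 * dOTMgC);
      // cytosolic buffering makes Cai stiff (|dJ/dCai| ~ 4e4 /s): advance
      // Cai by the exponential (linearized) rule instead of forward Euler
      const double bCai = 0.045 * 200000.0 * (1.0 - s[S_OC]) +
        0.08 * 78400.0 * (1.0 - s[S_OTC]) +
        0.16 * 200000.0 * (1.0 - s[S_OTMGC] - s[S_OTMGMG]);
      const double caiFac = (bCai * dt > 1e-8)
        ? (1.0 - std::exp(-bCai * dt)) / bCai : dt;
      const double dCad = -(iCaL + idi) / (2.0 * Vold * F_CONST);
      const double dCaup = (iup - itr) / (2.0 * Volup * F_CONST);
      const double dCarel = (itr - irel) / (2.0 * Volrel * F_CONST) -
        31.0 * dOCalse;
      const double dNai = -(iNa + iBNa + 3.0 * iNaK + 3.0 * iNaCa + phiNaEn) /
        (Voli * F_CONST);
      const double dKi = -(iT + iSus + iK1 + iKs + iKr - 2.0 * iNaK) /
        (Voli * F_CONST);
      const double dNac = (130.0 - Nac) / 14.3 +
        (iNa + iBNa + 3.0 * iNaK + 3.0 * iNaCa + phiNaEn) / (Volc * F_CONST);
      const double dKc = (5.4 - Kc) / 10.0 +
        (iT + iSus + iK1 + iKs + iKr - 2.0 * iNaK) / (Volc * F_CONST);
      const double dCac = (1.8 - Cac) / 24.7 +
        (iCaL + iBCa + iCaP - 2.0 * iNaCa) / (2.0 * Volc * F_CONST);

      s[S_OC] += dt * dOC;       s[S_OTC] += dt * dOTC;
      s[S_OTMGC] += dt * dOTMgC; s[S_OTMGMG] += dt * dOTMgMg;
      s[S_OCALSE] += dt * dOCalse;
      s[S_CAI] += caiFac * dCai; s[S_CAD] += dt * dCad;
      s[S_CAUP] += dt * dCaup;   s[S_CAREL] += dt * dCarel;
      s[S_NAI] += dt * dNai;     s[S_KI] += dt * dKi;
      s[S_NAC] += dt * dNac;     s[S_KC] += dt * dKc;
      s[S_CAC] += dt * dCac;
      s[S_F1] += dt * (0.815 * (1.0 - s[S_F1] - s[S_F2]) - ract * s[S_F1]);
      s[S_F2] += dt * (ract * s[S_F1] - rinact * s[S_F2]);

      V += dt * (-iTot / Cm + stim_mV_per_s);
    }
    vm[j] = V;
  }
}

// ---------------------------------------------------------------------------
// Aliev-Panfilov two-variable model
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double ap_vrest_cpp() { return -80.0; }

// [[Rcpp::export]]
NumericMatrix ap_init_cpp(int n) {
  NumericMatrix st(1, n);  // recovery variable v
  for (int j = 0; j < n; ++j) st(0, j) = 0.0;
  return st;
}

// pars: (k, a, eps0, mu1, mu2, tscale_ms_per_unit)
// [[Rcpp::export]]
void ap_step_cpp(NumericVector vm, NumericMatrix state,
                 NumericVector istim, double dt_ms, int nsub,
                 NumericVector pars) {
  const int n = vm.size();
  const double kk = pars[0], a = pars[1], eps0 = pars[2], mu1 = pars[3],
               mu2 = pars[4];
  const double tscale = pars[5];  // ms per time unit
  const double dt = (dt_ms / nsub) / tscale;
  for (int j = 0; j < n; ++j) {
    double u = (vm[j] + 80.0) / 100.0;
    double v = state(0, j);
    const double stim_u = istim[j] * tscale / 100.0;  // mV/ms -> du/dtau
    for (int sub = 0; sub < nsub; ++sub) {
      const double eps = eps0 + mu1 * v / (u + mu2);
      const double du = -kk * u * (u - a) * (u - 1.0) - u * v + stim_u;
      const double dv = eps * (-v - kk * u * (u - a - 1.0));
      u += dt * du;
      v += dt * dv;
    }
    vm[j] = 100.0 * u - 80.0;
    state(0, j) = v;
  }
}
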