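#ifndef FIBROFOCAL_MODEL_H
#define FIBROFOCAL_MODEL_H

#include <cmath>
#include <vector>

// Courtemanche-Ramirez-Nattel (1998) human atrial myocyte model and the
// MacCannell et al. (2007) active fibroblast model.  Currents are expressed
// per unit membrane capacitance (pA/pF); voltages in mV, time in ms,
// concentrations in mM.  State layout for one myocyte (V held separately):
//   0 m, 1 h, 2 j, 3 oa, 4 oi, 5 ua, 6 ui, 7 xr, 8 xs, 9 d, 10 f, 11 fca,
//   12 u, 13 v, 14 w, 15 Nai, 16 Ki, 17 Cai, 18 Caup, 19 Carel
// Fibroblast state: 0 r (IKv activation), 1 s (IKv inactivation).

namespace crn {

const int NSTATE = 20;

// physical constants
const double Rgas = 8.3143;      // J/(mol K)
const double Temp = 310.0;       // K
const double Frdy = 96.4867;     // C/mmol
const double RTF  = Rgas * Temp / Frdy;   // ~26.71 mV

// cell geometry / capacitance
const double Cm     = 100.0;     // pF
const double Vi     = 13668.0;   // um^3, intracellular volume
const double Vup    = 1109.52;   // um^3, SR uptake compartment
const double Vrel   = 96.48;     // um^3, SR release compartment

// external concentrations (mM)
const double Ko  = 5.4;
const double Nao = 140.0;
const double Cao = 1.8;

// maximum conductances (nS/pF) and current scalings
const double gNa   = 7.8;
const double gK1   = 0.09;
const double gto   = 0.1652;
const double gKr   = 0.029411765;
const double gKs   = 0.12941176;
const double gCaL  = 0.12375;
const double gbCa  = 0.001131;
const double gbNa  = 0.0006744375;
const double INaK_max  = 0.59933874;  // pA/pF
const double KmNai = 10.0;
const double KmKo  = 1.5;
const double INaCa_max = 1600.0;      // pA/pF
const double KmNa  = 87.5;
const double KmCa  = 1.38;
const double ksat  = 0.1;
const double gam   = 0.35;
const double IpCa_max  = 0.275;       // pA/pF

// Ca handling
const double krel    = 30.0;     // 1/ms
const double Iup_max = 0.005;    // mM/ms
const double Kup     = 0.00092;  // mM
const double Caup_max = 15.0;    // mM
const double tau_tr  = 180.0;    // ms
const double tau_fca = 2.0;      // ms
const double tau_u   = 8.0;      // ms

// buffers
const double CMDN_max = 0.05;
const double TRPN_max = 0.07;
const double CSQN_max = 10.0;
const double KmCmdn   = 0.00238;
const double KmTrpn   = 0.0005;
const double KmCsqn   = 0.8;

const double KQ10 = 3.0;

// published initial (resting) conditions
inline void init_state(double* y, double& V) {
  V = -81.18;
  y[0] = 2.908e-3;  y[1] = 9.649e-1;  y[2] = 9.775e-1;
  y[3] = 3.043e-2;  y[4] = 9.992e-1;
  y[5] = 4.966e-3;  y[6] = 9.986e-1;
  y[7] = 3.296e-5;  y[8] = 1.869e-2;
  y[9] = 1.367e-4;  y[10] = 9.996e-1; y[11] = 7.755e-1;
  y[12] = 0.0;      y[13] = 1.0;      y[14] = 9.992e-1;
  y[15] = 11.17;    y[16] = 139.0;    y[17] = 1.013e-4;
  y[18] = 1.488;    y[19] = 1.488;
}

// guard against removable singularities x/(1-exp(-x)) style terms
inline double safe_div(double num, double den, double lim) {
  return (std::fabs(den) < 1e-10) ? lim : num / den;
}

// voltage-dependent gate steady states (inf) and time constants (tau)
// order: m h j oa oi ua ui xr xs d f w
inline void gate_rates(double V, double* inf, double* tau) {
  // INa m gate
  double am = (std::fabs(V + 47.13) < 1e-10)
      ? 3.2
      : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  double bm = 0.08 * std::exp(-V / 11.0);
  inf[0] = am / (am + bm); tau[0] = 1.0 / (am + bm);
  // h, j gates (piecewise at -40 mV)
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V))
         * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  inf[1] = ah / (ah + bh); tau[1] = 1.0 / (ah + bh);
  inf[2] = aj / (aj + bj); tau[2] = 1.0 / (aj + bj);
  // Ito oa / oi
  double aoa = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double boa = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  inf[3] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  tau[3] = 1.0 / ((aoa + boa) * KQ10);
  double aoi = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  double boi = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  inf[4] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  tau[4] = 1.0 / ((aoi + boi) * KQ10);
  // IKur ua / ui
  double aua = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double bua = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  inf[5] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  tau[5] = 1.0 / ((aua + bua) * KQ10);
  double aui = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  double bui = std::exp((V - 158.0) / 16.0);
  inf[6] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  tau[6] = 1.0 / ((aui + bui) * KQ10);
  // IKr xr
  double axr = safe_div(0.0003 * (V + 14.1),
                        1.0 - std::exp(-(V + 14.1) / 5.0), 0.0015);
  double bxr = safe_div(7.3898e-5 * (V - 3.3328),
                        std::exp((V - 3.3328) / 5.1237) - 1.0, 3.7862e-4);
  inf[7] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  tau[7] = 1.0 / (axr + bxr);
  // IKs xs
  double axs = safe_div(4e-5 * (V - 19.9),
                        1.0 - std::exp(-(V - 19.9) / 17.0), 6.8e-4);
  double bxs = safe_div(3.5e-5 * (V - 19.9),
                        std::exp((V - 19.9) / 9.0) - 1.0, 3.15e-4);
  inf[8] = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  tau[8] = 0.5 / (axs + bxs);
  // ICaL d, f
  double e1 = std::exp(-(V + 10.0) / 6.24);
  tau[9] = (std::fabs(V + 10.0) < 1e-10)
      ? 1.0 / (6.24 * 0.07) // limit of (1-e)/(0.035 x (1+e)) as x -> 0
      : (1.0 - e1) / (0.035 * (V + 10.0) * (1.0 + e1));
  inf[9] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  inf[10] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  tau[10] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  // Irel w
  double e2 = std::exp(-(V - 7.9) / 5.0);
  tau[11] = (std::fabs(V - 7.9) < 1e-10)
      ? 6.0 * 0.2 / 1.3
      : 6.0 * (1.0 - e2) / ((1.0 + 0.3 * e2) * (V - 7.9));
  inf[11] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
}

struct Currents {
  double INa, IK1, Ito, IKur, IKr, IKs, ICaL, IpCa, INaK, INaCa, IbNa, IbCa;
  double Irel, Iup, Iupleak, Itr, Fn;
  double Iion; // total membrane current, pA/pF
};

// all membrane currents and SR fluxes; f_* are the regional multiplicative
// factors applied to gto, gCaL, gKr
inline void currents(double V, const double* y, double f_gto, double f_gCaL,
                     double f_gKr, Currents& c) {
  double Nai = y[15], Ki = y[16], Cai = y[17], Caup = y[18], Carel = y[19];
  double ENa = RTF * std::log(Nao / Nai);
  double EK  = RTF * std::log(Ko / Ki);
  double ECa = 0.5 * RTF * std::log(Cao / Cai);

  c.INa  = gNa * y[0] * y[0] * y[0] * y[1] * y[2] * (V - ENa);
  c.IK1  = gK1 * (V - EK) / (1.0 + std::exp(0.07 * (V + 80.0)));
  c.Ito  = f_gto * gto * y[3] * y[3] * y[3] * y[4] * (V - EK);
  double gkur = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  c.IKur = gkur * y[5] * y[5] * y[5] * y[6] * (V - EK);
  c.IKr  = f_gKr * gKr * y[7] * (V - EK) / (1.0 + std::exp((V + 15.0) / 22.4));
  c.IKs  = gKs * y[8] * y[8] * (V - EK);
  c.ICaL = f_gCaL * gCaL * y[9] * y[10] * y[11] * (V - 65.0);
  c.IpCa = IpCa_max * Cai / (0.0005 + Cai);
  double sig = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  double fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF)
                           + 0.0365 * sig * std::exp(-V / RTF));
  c.INaK = INaK_max * fnak * (1.0 / (1.0 + std::pow(KmNai / Nai, 1.5)))
           * Ko / (Ko + KmKo);
  double eg  = std::exp(gam * V / RTF);
  double egm = std::exp((gam - 1.0) * V / RTF);
  c.INaCa = INaCa_max * (eg * Nai * Nai * Nai * Cao - egm * Nao * Nao * Nao * Cai)
            / ((KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao)
               * (1.0 + ksat * egm));
  c.IbNa = gbNa * (V - ENa);
  c.IbCa = gbCa * (V - ECa);

  c.Irel = krel * y[12] * y[12] * y[13] * y[14] * (Carel - Cai);
  c.Iup  = Iup_max / (1.0 + Kup / Cai);
  c.Iupleak = Iup_max * Caup / Caup_max;
  c.Itr  = (Caup - Carel) / tau_tr;
  c.Fn   = 1e-12 * Vrel * c.Irel
           - 5e-13 / Frdy * (0.5 * c.ICaL * Cm - 0.2 * c.INaCa * Cm);

  c.Iion = c.INa + c.IK1 + c.Ito + c.IKur + c.IKr + c.IKs + c.ICaL
           + c.IpCa + c.INaK + c.INaCa + c.IbNa + c.IbCa;
}

// lookup tables over the voltage axis for a fixed dt (Rush-Larsen factors
// exp(-dt/tau) and steady states, plus V-dependent current coefficients)
struct Tables {
  double vmin, dv, inv_dv;
  int n;
  std::vector<double> inf[12], rl[12];
  std::vector<double> c_ik1;    // gK1 / (1+exp(0.07(V+80)))
  std::vector<double> c_gkur;   // gKur(V)
  std::vector<double> c_ikr;    // gKr / (1+exp((V+15)/22.4))
  std::vector<double> c_fnak;   // fNaK(V)
  std::vector<double> c_eg, c_egm; // exp(gam V F/RT), exp((gam-1) V F/RT)

  void build(double dt, double vlo = -120.0, double vhi = 80.0, double step = 0.02) {
    vmin = vlo; dv = step; inv_dv = 1.0 / step;
    n = (int)std::floor((vhi - vlo) / step) + 2;
    for (int g = 0; g < 12; ++g) { inf[g].resize(n); rl[g].resize(n); }
    c_ik1.resize(n); c_gkur.resize(n); c_ikr.resize(n);
    c_fnak.resize(n); c_eg.resize(n); c_egm.resize(n);
    double gi[12], gt[12];
    double sig = (std::exp(Nao / 67.3) - 1.0) / 7.0;
    for (int i = 0; i < n; ++i) {
      double V = vmin + i * dv;
      gate_rates(V, gi, gt);
      for (int g = 0; g < 12; ++g) {
        inf[g][i] = gi[g];
        rl[g][i] = std::exp(-dt / gt[g]);
      }
      c_ik1[i]  = gK1 / (1.0 + std::exp(0.07 * (V + 80.0)));
      c_gkur[i] = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
      c_ikr[i]  = gKr / (1.0 + std::exp((V + 15.0) / 22.4));
      c_fnak[i] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF)
                             + 0.0365 * sig * std::exp(-V / RTF));
      c_eg[i]   = std::exp(gam * V / RTF);
      c_egm[i]  = std::exp((gam - 1.0) * V / RTF);
    }
  }

  inline double at(const std::vector<double>& a, double V) const {
    double x = (V - vmin) * inv_dv;
    if (x < 0) x = 0;
    if (x > n - 2) x = n - 2;
    int i = (int)x;
    double w = x - i;
    return a[i] * (1.0 - w) + a[i + 1] * w;
  }
};

// one table-driven time step for a myocyte: computes Iion at the current
// state, then advances gates (Rush-Larsen) and concentrations (forward
// Euler).  Returns Iion in pA/pF.
inline double step(double V, double* y, const Tables& T, double dt,
                   double f_gto, double f_gCaL, double f_gKr,
                   double rl_fca, double rl_u) {
  double Nai = y[15], Ki = y[16], Cai = y[17], Caup = y[18], Carel = y[19];
  double ENa = RTF * std::log(Nao / Nai);
  double EK  = RTF * std::log(Ko / Ki);
  double ECa = 0.5 * RTF * std::log(Cao / Cai);

  double INa  = gNa * y[0] * y[0] * y[0] * y[1] * y[2] * (V - ENa);
  double IK1  = T.at(T.c_ik1, V) * (V - EK);
  double Ito  = f_gto * gto * y[3] * y[3] * y[3] * y[4] * (V - EK);
  double IKur = T.at(T.c_gkur, V) * y[5] * y[5] * y[5] * y[6] * (V - EK);
  double IKr  = f_gKr * T.at(T.c_ikr, V) * y[7] * (V - EK);
  double IKs  = gKs * y[8] * y[8] * (V - EK);
  double ICaL = f_gCaL * gCaL * y[9] * y[10] * y[11] * (V - 65.0);
  double IpCa = IpCa_max * Cai / (0.0005 + Cai);
  double INaK = INaK_max * T.at(T.c_fnak, V)
                * (1.0 / (1.0 + std::pow(KmNai / Nai, 1.5))) * Ko / (Ko + KmKo);
  double eg = T.at(T.c_eg, V), egm = T.at(T.c_egm, V);
  double INaCa = INaCa_max * (eg * Nai * Nai * Nai * Cao - egm * Nao * Nao * Nao * Cai)
                 / ((KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao)
                    * (1.0 + ksat * egm));
  double IbNa = gbNa * (V - ENa);
  double IbCa = gbCa * (V - ECa);

  double Irel = krel * y[12] * y[12] * y[13] * y[14] * (Carel - Cai);
  double Iup  = Iup_max / (1.0 + Kup / Cai);
  double Iupleak = Iup_max * Caup / Caup_max;
  double Itr  = (Caup - Carel) / tau_tr;

  // voltage-gated gates via tables
  for (int g = 0; g < 12; ++g) {
    int yi = (g < 11) ? g : 14;  // table index 11 = w gate, state index 14
    double gi = T.at(T.inf[g], V);
    double r  = T.at(T.rl[g], V);
    y[yi] = gi + (y[yi] - gi) * r;
  }
  // fca (Cai dependent, tau = 2 ms)
  double fca_inf = 1.0 / (1.0 + Cai / 0.00035);
  y[11] = fca_inf + (y[11] - fca_inf) * rl_fca;
  // u, v (Fn dependent)
  double Fn = 1e-12 * Vrel * Irel - 5e-13 / Frdy * (0.5 * ICaL * Cm - 0.2 * INaCa * Cm);
  double eu = std::exp(-(Fn - 3.4175e-13) / 13.67e-16);
  double u_inf = 1.0 / (1.0 + eu);
  double tau_v = 1.91 + 2.09 / (1.0 + eu);
  double v_inf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  y[12] = u_inf + (y[12] - u_inf) * rl_u;
  y[13] = v_inf + (y[13] - v_inf) * std::exp(-dt / tau_v);

  // concentrations (forward Euler); currents here in pA (x Cm)
  double dNai = (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) * Cm / (Frdy * Vi);
  double dKi  = (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs) * Cm / (Frdy * Vi);
  double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) * Cm / (2.0 * Frdy * Vi)
              + (Vup * (Iupleak - Iup) + Irel * Vrel) / Vi;
  double kc = Cai + KmCmdn, kt = Cai + KmTrpn;
  double B2 = 1.0 + TRPN_max * KmTrpn / (kt * kt) + CMDN_max * KmCmdn / (kc * kc);
  double dCaup  = Iup - Iupleak - Itr * Vrel / Vup;
  double kq = Carel + KmCsqn;
  double dCarel = (Itr - Irel) / (1.0 + CSQN_max * KmCsqn / (kq * kq));

  y[15] += dt * dNai;
  y[16] += dt * dKi;
  y[17] += dt * B1 / B2;
  y[18] += dt * dCaup;
  y[19] += dt * dCarel;

  return INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + INaK + INaCa
         + IbNa + IbCa;
}

} // namespace crn

namespace fb {

// MacCannell et al. (2007) active fibroblast: IKv, IK1, INaK, IbNa.
const int NSTATE = 2;
const double Cm_fb = 6.3;        // pF
const double Ko   = 5.3581;      // mM
const double Ki   = 129.4349;
const double Nao  = 130.0110;
const double Nai  = 8.5547;
const double gKv  = 0.25;        // nS/pF
const double gK1  = 0.4822;      // nS/pF
const double INaK_max = 2.002;   // pA/pF
const double KmK  = 1.0;
const double KmNa = 11.0;
const double VrevNaK = -150.0;   // mV
const double BNaK = -200.0;      // mV
const double gbNa = 0.0095;      // nS/pF

inline double EK()  { return crn::RTF * std::log(Ko / Ki); }
inline double ENa() { return crn::RTF * std::log(Nao / Nai); }

inline void init_state(double* y, double& V) {
  V = -49.6;
  y[0] = 0.0597;   // r at rest (approx; relaxes quickly)
  y[1] = 0.9946;   // s
}

inline void gate_rates(double V, double* inf, double* tau) {
  inf[0] = 1.0 / (1.0 + std::exp(-(V + 20.0) / 11.0));
  double xr = (V + 20.0) / 25.9;
  tau[0] = 20.3 + 138.0 * std::exp(-xr * xr);
  inf[1] = 1.0 / (1.0 + std::exp((V + 23.0) / 7.0));
  double xs = (V + 23.0) / 22.7;
  tau[1] = 1574.0 + 5268.0 * std::exp(-xs * xs);
}

struct Currents {
  double IKv, IK1, INaK, IbNa, Iion;
};

inline void currents(double V, const double* y, Currents& c) {
  double ek = EK(), ena = ENa();
  c.IKv = gKv * y[0] * y[1] * (V - ek);
  double vk = V - ek;
  double a = 0.1 / (1.0 + std::exp(0.06 * (vk - 200.0)));
  double b = (3.0 * std::exp(0.0002 * (vk + 100.0)) + std::exp(0.1 * (vk - 10.0)))
             / (1.0 + std::exp(-0.5 * vk));
  c.IK1 = gK1 * a / (a + b) * vk;
  double na15 = std::pow(Nai, 1.5);
  c.INaK = INaK_max * (Ko / (Ko + KmK)) * (na15 / (na15 + std::pow(KmNa, 1.5)))
           * (V - VrevNaK) / (V - BNaK);
  c.IbNa = gbNa * (V - ena);
  c.Iion = c.IKv + c.IK1 + c.INaK + c.IbNa;
}

struct Tables {
  double vmin, dv, inv_dv;
  int n;
  std::vector<double> inf_r, inf_s, rl_r, rl_s, c_k1, c_nak;

  void build(double dt, double vlo = -120.0, double vhi = 80.0, double step = 0.02) {
    vmin = vlo; dv = step; inv_dv = 1.0 / step;
    n = (int)std::floor((vhi - vlo) / step) + 2;
    inf_r.resize(n); inf_s.resize(n); rl_r.resize(n); rl_s.resize(n);
    c_k1.resize(n); c_nak.resize(n);
    double gi[2], gt[2];
    double ek = EK();
    double na15 = std::pow(Nai, 1.5);
    double naf = INaK_max * (Ko / (Ko + KmK)) * (na15 / (na15 + std::pow(KmNa, 1.5)));
    for (int i = 0; i < n; ++i) {
      double V = vmin + i * dv;
      gate_rates(V, gi, gt);
      inf_r[i] = gi[0]; rl_r[i] = std::exp(-dt / gt[0]);
      inf_s[i] = gi[1]; rl_s[i] = std::exp(-dt / gt[1]);
      double vk = V - ek;
      double a = 0.1 / (1.0 + std::exp(0.06 * (vk - 200.0)));
      double b = (3.0 * std::exp(0.0002 * (vk + 100.0)) + std::exp(0.1 * (vk - 10.0)))
                 / (1.0 + std::exp(-0.5 * vk));
      c_k1[i] = gK1 * a / (a + b) * vk;
      c_nak[i] = naf * (V - VrevNaK) / (V - BNaK);
    }
  }

  inline double at(const std::vector<double>& a, double V) const {
    double x = (V - vmin) * inv_dv;
    if (x < 0) x = 0;
    if (x > n - 2) x = n - 2;
    int i = (int)x;
    double w = x - i;
    return a[i] * (1.0 - w) + a[i + 1] * w;
  }
};

inline double step(double V, double* y, const Tables& T) {
  double ek = EK(), ena = ENa();
  double Iion = gKv * y[0] * y[1] * (V - ek) + T.at(T.c_k1, V)
                + T.at(T.c_nak, V) + gbNa * (V - ena);
  double ri = T.at(T.inf_r, V), si = T.at(T.inf_s, V);
  y[0] = ri + (y[0] - ri) * T.at(T.rl_r, V);
  y[1] = si + (y[1] - si) * T.at(T.rl_s, V);
  return Iion;
}

} // namespace fb

#endif
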