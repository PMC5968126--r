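#include <Rcpp.h>
#include "model.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_crn_init_state() {
  double y[crn::NSTATE], V;
  crn::init_state(y, V);
  NumericVector out(crn::NSTATE + 1);
  out[0] = V;
  for (int i = 0; i < crn::NSTATE; ++i) out[i + 1] = y[i];
  out.attr("names") = CharacterVector::create(
      "V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f",
      "fca", "u", "v", "w", "Nai", "Ki", "Cai", "Caup", "Carel");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fb_init_state() {
  double y[fb::NSTATE], V;
  fb::init_state(y, V);
  NumericVector out = NumericVector::create(
      _["V"] = V, _["r"] = y[0], _["s"] = y[1]);
  return out;
}

// Membrane currents of the CRN myocyte at a given state (direct formula
// evaluation, no lookup tables), plus gate steady states / time constants.
// [[Rcpp::export]]
List cpp_crn_currents(double V, NumericVector state,
                      double f_gto, double f_gcal, double f_gkr) {
  if (state.size() != crn::NSTATE)
    stop("state must have %d elements", crn::NSTATE);
  std::vector<double> y(state.begin(), state.end());
  crn::Currents c;
  crn::currents(V, y.data(), f_gto, f_gcal, f_gkr, c);
  double gi[12], gt[12];
  crn::gate_rates(V, gi, gt);
  CharacterVector gn = CharacterVector::create(
      "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f", "w");
  NumericVector inf(12), tau(12);
  for (int i = 0; i < 12; ++i) { inf[i] = gi[i]; tau[i] = gt[i]; }
  inf.attr("names") = gn; tau.attr("names") = gn;
  return List::create(
      _["currents"] = NumericVector::create(
          _["INa"] = c.INa, _["IK1"] = c.IK1, _["Ito"] = c.Ito,
          _["IKur"] = c.IKur, _["IKr"] = c.IKr, _["IKs"] = c.IKs,
          _["ICaL"] = c.ICaL, _["IpCa"] = c.IpCa, _["INaK"] = c.INaK,
          _["INaCa"] = c.INaCa, _["IbNa"] = c.IbNa, _["IbCa"] = c.IbCa),
      _["I_ion"] = c.Iion,
      _["fluxes"] = NumericVector::create(
          _["Irel"] = c.Irel, _["Iup"] = c.Iup, _["Iupleak"] = c.Iupleak,
          _["Itr"] = c.Itr, _["Fn"] = c.Fn),
      _["gate_inf"] = inf, _["gate_tau"] = tau);
}

// [[Rcpp::export]]
List cpp_fb_currents(double V, NumericVector state) {
  if (state.size() != fb::NSTATE) stop("state must have 2 elements (r, s)");
  std::vector<double> y(state.begin(), state.end());
  fb::Currents c;
  fb::currents(V, y.data(), c);
  double gi[2], gt[2];
  fb::gate_rates(V, gi, gt);
  return List::create(
      _["currents"] = NumericVector::create(
          _["IKv"] = c.IKv, _["IK1"] = c.IK1, _["INaK"] = c.INaK,
          _["IbNa"] = c.IbNa),
      _["I_ion"] = c.Iion,
      _["gate_inf"] = NumericVector::create(_["r"] = gi[0], _["s"] = gi[1]),
      _["gate_tau"] = NumericVector::create(_["r"] = gt[0], _["s"] = gt[1]));
}

// Pace a single CRN myocyte: rectangular stimulus of stim_dur ms and
// stim_amp pA/pF (depolarizing positive) at the start of each cycle.
// Records V of the final beat at sample_dt resolution.
// [[Rcpp::export]]
List cpp_pace_single_cell(double f_gto, double f_gcal, double f_gkr,
                          double bcl, int n_beats, double dt,
                          double stim_amp, double stim_dur,
                          double sample_dt, NumericVector init) {
  crn::Tables T;
  T.build(dt);
  double rl_fca = std::exp(-dt / crn::tau_fca);
  double rl_u = std::exp(-dt / crn::tau_u);

  double y[crn::NSTATE], V;
  if (init.size() == crn::NSTATE + 1) {
    V = init[0];
    for (int i = 0; i < crn::NSTATE; ++i) y[i] = init[i + 1];
  } else {
    crn::init_state(y, V);
  }

  long steps_per_beat = (long)std::llround(bcl / dt);
  long stim_steps = (long)std::llround(stim_dur / dt);
  long sample_every = std::max((long)1, (long)std::llround(sample_dt / dt));
  long n_samp = steps_per_beat / sample_every + 1;

  NumericVector t_out(n_samp), v_out(n_samp);
  long k = 0;
  for (int b = 0; b < n_beats; ++b) {
    bool last = (b == n_beats - 1);
    if (last) { t_out[0] = 0.0; v_out[0] = V; k = 1; }
    for (long s = 0; s < steps_per_beat; ++s) {
      double Iion = crn::step(V, y, T, dt, f_gto, f_gcal, f_gkr, rl_fca, rl_u);
      double Ist = (s < stim_steps) ? stim_amp : 0.0;
      V += dt * (-Iion + Ist);
      if (!std::isfinite(V) || std::fabs(V) > 200.0)
        stop("numerical divergence in single-cell pacing (V = %f at beat %d)",
             V, b + 1);
      if (last && ((s + 1) % sample_every == 0) && k < n_samp) {
        t_out[k] = (s + 1) * dt;
        v_out[k] = V;
        ++k;
      }
    }
  }
  NumericVector fin(crn::NSTATE + 1);
  fin[0] = V;
  for (int i = 0; i < crn::NSTATE; ++i) fin[i + 1] = y[i];
  fin.attr("names") = cpp_crn_init_state().attr("names");
  return List::create(_["t"] = t_out[Range(0, k - 1)],
                      _["V"] = v_out[Range(0, k - 1)],
                      _["final_state"] = fin);
}

// Relax an uncoupled fibroblast toward its resting steady state.
// [[Rcpp::export]]
NumericVector cpp_fb_relax(double duration, double dt) {
  fb::Tables T;
  T.build(dt);
  double y[fb::NSTATE], V;
  fb::init_state(y, V);
  long n = (long)std::llround(duration / dt);
  for (long s = 0; s < n; ++s) {
    double Iion = fb::step(V, y, T);
    V += dt * (-Iion);
    if (!std::isfinite(V)) stop("numerical divergence in fibroblast relaxation");
  }
  return NumericVector::create(_["V"] = V, _["r"] = y[0], _["s"] = y[1]);
}
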