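#include <Rcpp.h>
#include "model.h"
using namespace Rcpp;

// Monodomain reaction-diffusion on a regular voxel lattice, Godunov operator
// splitting: membrane reaction (CRN myocytes / MacCannell fibroblasts) then
// explicit diffusion through a 7-point anisotropic Laplacian with no-flux
// boundaries (harmonic-mean face conductivities).
//
// label: 0 = non-conducting, 1 = myocyte, 2 = fibroblast (per voxel)
// Dl:    longitudinal diffusivity per voxel (mm^2/ms); transverse = Dl * anis
// fiber_axis: 0/1/2 -> x/y/z longitudinal axis (shared by the whole grid)
// fb_scale: multiplier on the fibroblast membrane current density, standing
//           for fibroblast density / surface-to-volume in a voxel
// LAT: first upward crossing of lat_thresh after stimulus onset (t = 0);
//      an equilibration phase of equil_ms runs at negative times first.
// [[Rcpp::export]]
List cpp_solve_monodomain(IntegerVector dims, double spacing,
                          IntegerVector label,
                          NumericVector fto, NumericVector fcal,
                          NumericVector fkr,
                          NumericVector Dl, NumericVector anis,
                          int fiber_axis,
                          NumericVector myo_init, NumericVector fb_init,
                          IntegerVector stim_idx, double stim_dur,
                          double stim_amp,
                          double duration, double dt,
                          double equil_ms, double dt_equil,
                          double sample_dt, bool record_all,
                          IntegerVector probes,
                          double fb_scale, bool early_stop,
                          double lat_thresh = -40.0,
                          double stim_period = 0.0,
                          int state_probe = -1) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  if ((long)label.size() != n) stop("label length does not match dims");
  const double h2 = spacing * spacing;

  std::vector<int> lab(label.begin(), label.end());
  std::vector<double> vfto(fto.begin(), fto.end());
  std::vector<double> vfca(fcal.begin(), fcal.end());
  std::vector<double> vfkr(fkr.begin(), fkr.end());

  // compact membrane-state storage
  std::vector<long> myo_ids, fb_ids;
  for (long i = 0; i < n; ++i) {
    if (lab[i] == 1) myo_ids.push_back(i);
    else if (lab[i] == 2) fb_ids.push_back(i);
    else if (lab[i] != 0) stop("labels must be 0, 1 or 2");
  }
  const long n_myo = (long)myo_ids.size(), n_fb = (long)fb_ids.size();
  if (n_myo + n_fb == 0) stop("grid has no conducting voxels");

  std::vector<double> ym((size_t)n_myo * crn::NSTATE),
      yf((size_t)n_fb * fb::NSTATE);
  std::vector<double> V(n), Vn(n), lat(n, NA_REAL);
  double v_myo0 = myo_init[0], v_fb0 = fb_init[0];
  for (long i = 0; i < n; ++i) V[i] = (lab[i] == 2) ? v_fb0 : v_myo0;
  for (long k = 0; k < n_myo; ++k)
    for (int s = 0; s < crn::NSTATE; ++s)
      ym[k * crn::NSTATE + s] = myo_init[s + 1];
  for (long k = 0; k < n_fb; ++k)
    for (int s = 0; s < fb::NSTATE; ++s)
      yf[k * fb::NSTATE + s] = fb_init[s + 1];

  // face conductances (between i and i + stride along each axis)
  auto axisD = [&](long i, int ax) -> double {
    if (lab[i] == 0) return 0.0;
    return (ax == fiber_axis) ? Dl[i] : Dl[i] * anis[i];
  };
  const long sx = 1, sy = nx, sz = (long)nx * ny;
  std::vector<double> gxm(n, 0.0), gym(n, 0.0), gzm(n, 0.0);
  for (long z = 0; z < nz; ++z)
    for (long y = 0; y < ny; ++y)
      for (long x = 0; x < nx; ++x) {
        long i = x + nx * (y + (long)ny * z);
        if (x < nx - 1) {
          double a = axisD(i, 0), b = axisD(i + sx, 0);
          gxm[i] = (a > 0 && b > 0) ? 2 * a * b / (a + b) : 0.0;
        }
        if (y < ny - 1) {
          double a = axisD(i, 1), b = axisD(i + sy, 1);
          gym[i] = (a > 0 && b > 0) ? 2 * a * b / (a + b) : 0.0;
        }
        if (nz > 1 && z < nz - 1) {
          double a = axisD(i, 2), b = axisD(i + sz, 2);
          gzm[i] = (a > 0 && b > 0) ? 2 * a * b / (a + b) : 0.0;
        }
      }

  // stimulus mask
  std::vector<char> stim_mask(n, 0);
  for (int k = 0; k < stim_idx.size(); ++k) {
    long i = stim_idx[k];
    if (i < 0 || i >= n) stop("stimulus index outside grid");
    if (lab[i] == 0) stop("stimulus on a non-conducting voxel");
    stim_mask[i] = 1;
  }

  crn::Tables Tm, Tm_eq;
  fb::Tables Tf, Tf_eq;
  Tm.build(dt); Tf.build(dt);
  if (equil_ms > 0) { Tm_eq.build(dt_equil); Tf_eq.build(dt_equil); }

  // sampling
  long n_samp_max = (long)std::floor(duration / sample_dt) + 1;
  std::vector<double> t_samp;
  std::vector<double> probe_rec;   // probes.size() x samples, column-major
  std::vector<double> movie_rec;   // n x samples if record_all
  t_samp.reserve(n_samp_max);
  auto take_sample = [&](double t) {
    t_samp.push_back(t);
    for (int p = 0; p < probes.size(); ++p) probe_rec.push_back(V[probes[p]]);
    if (record_all)
      movie_rec.insert(movie_rec.end(), V.begin(), V.end());
  };

  long n_conducting = n_myo + n_fb, n_activated = 0;
  double stop_after = -1.0;
  bool blow = false; double blow_v = 0, blow_t = 0;

  std::vector<double> Vpre(n);
  auto do_step = [&](double t, double step_dt, bool stimulating,
                     crn::Tables& TM, fb::Tables& TF,
                     double rlf, double rlu, bool track_lat) {
    if (track_lat) std::copy(V.begin(), V.end(), Vpre.begin());
    // reaction
    for (long k = 0; k < n_myo; ++k) {
      long i = myo_ids[k];
      double Ii = crn::step(V[i], &ym[k * crn::NSTATE], TM, step_dt,
                            vfto[i], vfca[i], vfkr[i], rlf, rlu);
      double Ist = (stimulating && stim_mask[i]) ? stim_amp : 0.0;
      V[i] += step_dt * (-Ii + Ist);
    }
    for (long k = 0; k < n_fb; ++k) {
      long i = fb_ids[k];
      double Ii = fb::step(V[i], &yf[k * fb::NSTATE], TF) * fb_scale;
      double Ist = (stimulating && stim_mask[i]) ? stim_amp : 0.0;
      V[i] += step_dt * (-Ii + Ist);
    }
    // diffusion + LAT detection
    const double r = step_dt / h2;
    const double* v = V.data();
    double* vn = Vn.data();
    for (long z = 0; z < nz; ++z)
      for (long y = 0; y < ny; ++y) {
        long i = nx * (y + (long)ny * z);
        for (long x = 0; x < nx; ++x, ++i) {
          if (lab[i] == 0) { vn[i] = v[i]; continue; }
          double acc = 0.0;
          if (x < nx - 1 && gxm[i] != 0) acc += gxm[i] * (v[i + sx] - v[i]);
          if (x > 0 && gxm[i - sx] != 0) acc += gxm[i - sx] * (v[i - sx] - v[i]);
          if (y < ny - 1 && gym[i] != 0) acc += gym[i] * (v[i + sy] - v[i]);
          if (y > 0 && gym[i - sy] != 0) acc += gym[i - sy] * (v[i - sy] - v[i]);
          if (nz > 1) {
            if (z < nz - 1 && gzm[i] != 0) acc += gzm[i] * (v[i + sz] - v[i]);
            if (z > 0 && gzm[i - sz] != 0) acc += gzm[i - sz] * (v[i - sz] - v[i]);
          }
          double nv = v[i] + r * acc;
          vn[i] = nv;
          if (track_lat && nv >= lat_thresh && Vpre[i] < lat_thresh &&
              ISNAN(lat[i])) {
            lat[i] = t + step_dt * (lat_thresh - Vpre[i]) / (nv - Vpre[i]);
            ++n_activated;
          }
          if (nv > 200.0 || nv < -200.0 || nv != nv) {
            blow = true; blow_v = nv; blow_t = t;
          }
        }
      }
    V.swap(Vn);
  };

  // equilibration (no stimulus, negative time, no LAT bookkeeping)
  if (equil_ms > 0) {
    double rlf = std::exp(-dt_equil / crn::tau_fca);
    double rlu = std::exp(-dt_equil / crn::tau_u);
    long n_eq = (long)std::llround(equil_ms / dt_equil);
    for (long s = 0; s < n_eq && !blow; ++s)
      do_step(-equil_ms + s * dt_equil, dt_equil, false, Tm_eq, Tf_eq,
              rlf, rlu, false);
    if (blow)
      stop("numerical blow-up during equilibration (V = %f)", blow_v);
  }

  double rlf = std::exp(-dt / crn::tau_fca);
  double rlu = std::exp(-dt / crn::tau_u);
  long n_steps = (long)std::llround(duration / dt);
  long stim_steps = (long)std::llround(stim_dur / dt);
  long sample_every = std::max((long)1, (long)std::llround(sample_dt / dt));
  long period_steps = (stim_period > 0)
      ? (long)std::llround(stim_period / dt) : 0;
  take_sample(0.0);
  double t_end = duration;
  for (long s = 0; s < n_steps; ++s) {
    double t = s * dt;
    bool stimulating = (period_steps > 0)
        ? (s % period_steps) < stim_steps : s < stim_steps;
    do_step(t, dt, stimulating, Tm, Tf, rlf, rlu, true);
    if (blow)
      stop("numerical blow-up at t = %f ms (V = %f); reduce dt",
           blow_t, blow_v);
    if ((s + 1) % sample_every == 0) take_sample((s + 1) * dt);
    if (early_stop) {
      if (stop_after < 0.0 && n_activated == n_conducting)
        stop_after = t + 5.0;
      if (stop_after > 0.0 && t >= stop_after) { t_end = t; break; }
    }
  }

  long ns = (long)t_samp.size();
  NumericMatrix probe_V(probes.size(), ns);
  for (long c = 0; c < ns; ++c)
    for (int p = 0; p < probes.size(); ++p)
      probe_V(p, c) = probe_rec[c * probes.size() + p];

  List out = List::create(
      _["lat"] = NumericVector(lat.begin(), lat.end()),
      _["t"] = NumericVector(t_samp.begin(), t_samp.end()),
      _["probe_V"] = probe_V,
      _["final_V"] = NumericVector(V.begin(), V.end()),
      _["t_end"] = t_end,
      _["n_activated"] = (double)n_activated,
      _["n_conducting"] = (double)n_conducting);
  if (record_all) {
    NumericMatrix movie(n, ns);
    std::copy(movie_rec.begin(), movie_rec.end(), movie.begin());
    out["V"] = movie;
  }
  if (state_probe >= 0) {
    if (state_probe >= n || lab[state_probe] != 1)
      stop("state probe must be a myocyte voxel");
    long slot = -1;
    for (long k = 0; k < n_myo; ++k)
      if (myo_ids[k] == state_probe) { slot = k; break; }
    NumericVector st(crn::NSTATE + 1);
    st[0] = V[state_probe];
    for (int k = 0; k < crn::NSTATE; ++k)
      st[k + 1] = ym[slot * crn::NSTATE + k];
    out["probe_state"] = st;
  }
  return out;
}
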