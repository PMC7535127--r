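// Monodomain Fenton-Karma solver on an irregular voxel domain.
// Explicit Euler in time, 7-point heterogeneous-D Laplacian in space with
// face diffusivities precomputed on the R side (zero face = no-flux).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct FKPar {
  double tau_d, tau_r, tau_si, tau_0;
  double tau_v_plus, tau_v1_minus, tau_v2_minus;
  double tau_w_plus, tau_w_minus;
  double u_c, u_v, u_c_si, k;
};

static FKPar unpack(const List& p) {
  FKPar q;
  q.tau_d = p["tau_d"]; q.tau_r = p["tau_r"]; q.tau_si = p["tau_si"];
  q.tau_0 = p["tau_0"];
  q.tau_v_plus = p["tau_v_plus"];
  q.tau_v1_minus = p["tau_v1_minus"]; q.tau_v2_minus = p["tau_v2_minus"];
  q.tau_w_plus = p["tau_w_plus"]; q.tau_w_minus = p["tau_w_minus"];
  q.u_c = p["u_c"]; q.u_v = p["u_v"]; q.u_c_si = p["u_c_si"]; q.k = p["k"];
  return q;
}

// Saturated logistic activation of the slow inward current:
// (1 + tanh(x)) / 2 with exact 0/1 tails beyond |x| = 6. The saturation
// makes the rest state an exact fixed point of the reaction terms.
static inline double si_gate(double x) {
  if (x <= -6.0) return 0.0;
  if (x >= 6.0) return 1.0;
  return 1.0 / (1.0 + std::exp(-2.0 * x));
}

// Reaction currents and gate derivatives for one voxel; returns du/dt (reaction only).
static inline double fk_react(double u, double& v, double& w,
                              const FKPar& p, double dt) {
  const bool gate = u >= p.u_c;
  double dv, dw, Jfi, Jso;
  if (gate) {
    dv = -v / p.tau_v_plus;
    dw = -w / p.tau_w_plus;
    Jfi = -v * (1.0 - u) * (u - p.u_c) / p.tau_d;
    Jso = 1.0 / p.tau_r;
  } else {
    const double tvm = (u >= p.u_v) ? p.tau_v1_minus : p.tau_v2_minus;
    dv = (1.0 - v) / tvm;
    dw = (1.0 - w) / p.tau_w_minus;
    Jfi = 0.0;
    Jso = u / p.tau_0;
  }
  const double Jsi = -w * si_gate(p.k * (u - p.u_c_si)) / p.tau_si;
  v += dt * dv; if (v < 0.0) v = 0.0; else if (v > 1.0) v = 1.0;
  w += dt * dw; if (w < 0.0) w = 0.0; else if (w > 1.0) w = 1.0;
  return -(Jfi + Jso + Jsi);
}

// [[Rcpp::export(name = ".fk_reaction_step")]]
List fk_reaction_step(NumericVector u, NumericVector v, NumericVector w,
                      List params, double dt) {
  const FKPar p = unpack(params);
  const int n = u.size();
  NumericVector un(n), vn(n), wn(n);
  for (int i = 0; i < n; ++i) {
    double vv = v[i], ww = w[i];
    const double du = fk_react(u[i], vv, ww, p, dt);
    un[i] = u[i] + dt * du;
    vn[i] = vv; wn[i] = ww;
  }
  return List::create(_["u"] = un, _["v"] = vn, _["w"] = wn);
}

// [[Rcpp::export(name = ".het_laplacian")]]
NumericVector het_laplacian(const IntegerMatrix& nb, const NumericMatrix& Dface,
                            const NumericVector& u, double dx) {
  const int n = u.size();
  const double inv = 1.0 / (dx * dx);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int f = 0; f < 6; ++f) {
      const int j = nb(i, f);
      if (j >= 0) acc += Dface(i, f) * (u[j] - u[i]);
    }
    out[i] = acc * inv;
  }
  return out;
}

// Full explicit-Euler run.
// nb: n x 6 neighbour ranks (0-based, -1 = missing face); Dface: n x 6 face
// diffusivities (mm^2/ms, already 0 on no-flux faces); stimuli: list of
// (onset, duration, amplitude, idx[0-based]); snapshots of u every
// record_every ms starting at t0.
// [[Rcpp::export(name = ".fk_run")]]
List fk_run(const IntegerMatrix& nb, const NumericMatrix& Dface,
            NumericVector u, NumericVector v, NumericVector w,
            List params, double dx, double dt, double duration,
            double record_every, List stimuli,
            bool reaction, double t0) {
  const FKPar p = unpack(params);
  const int n = u.size();
  const double inv = 1.0 / (dx * dx);
  const long nsteps = (long) std::lround(duration / dt);
  const long rec_stride = std::max(1L, (long) std::lround(record_every / dt));
  const int nrec = (int)(nsteps / rec_stride) + 1;

  NumericMatrix snaps(n, nrec);
  NumericVector times(nrec);
  const int nstim = stimuli.size();
  std::vector<double> s_on(nstim), s_off(nstim), s_amp(nstim);
  std::vector<IntegerVector> s_idx(nstim);
  for (int s = 0; s < nstim; ++s) {
    List st = stimuli[s];
    s_on[s] = as<double>(st["onset"]);
    s_off[s] = s_on[s] + as<double>(st["duration"]);
    s_amp[s] = as<double>(st["amplitude"]);
    s_idx[s] = as<IntegerVector>(st["idx"]);
  }

  // raw views (column-major matrices)
  const int* NB = INTEGER(nb);
  const double* DF = REAL(Dface);
  double* U = REAL(u);
  double* V = REAL(v);
  double* W = REAL(w);
  double* SN = REAL(snaps);
  std::vector<double> unew(n);
  double* UN = unew.data();
  int irec = 0;
  std::copy(U, U + n, SN); times[0] = t0; irec = 1;

  for (long step = 0; step < nsteps; ++step) {
    const double t = t0 + step * dt;
    // fused diffusion + reaction Jacobi pass
    for (int i = 0; i < n; ++i) {
      const double ui = U[i];
      double acc = 0.0;
      for (int f = 0; f < 6; ++f) {
        const int j = NB[i + f * n];
        if (j >= 0) acc += DF[i + f * n] * (U[j] - ui);
      }
      double du = acc * inv;
      if (reaction) {
        double vv = V[i], ww = W[i];
        du += fk_react(ui, vv, ww, p, dt);
        V[i] = vv; W[i] = ww;
      }
      UN[i] = ui + dt * du;
    }
    // stimuli (additive forcing on u while active)
    for (int s = 0; s < nstim; ++s) {
      if (t >= s_on[s] && t < s_off[s]) {
        const int* ix = INTEGER(s_idx[s]);
        const int ns = s_idx[s].size();
        const double a = s_amp[s] * dt;
        for (int m = 0; m < ns; ++m) UN[ix[m]] += a;
      }
    }
    std::copy(UN, UN + n, U);

    if ((step + 1) % rec_stride == 0 && irec < nrec) {
      std::copy(U, U + n, SN + (size_t)irec * n);
      times[irec] = t0 + (step + 1) * dt;
      ++irec;
    }
    if ((step & 2047) == 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(U[i]))
          stop("non-finite membrane potential at t = %f ms (voxel %d)",
               t, i + 1);
      }
      Rcpp::checkUserInterrupt();
    }
  }
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(U[i])) stop("non-finite state at end of run (voxel %d)", i + 1);

  return List::create(_["u_snaps"] = snaps, _["times"] = times,
                      _["u"] = u, _["v"] = v, _["w"] = w);
}

static inline double wrap_pi(double x) {
  while (x > M_PI) x -= 2.0 * M_PI;
  while (x < -M_PI) x += 2.0 * M_PI;
  return x;
}

// Layer-wise plaquette winding-number phase-singularity detection.
// u_now/u_delayed/mask are full 3-D arrays (column-major, dims dm).
// Returns an m x 4 matrix (x, y, z in mm at plaquette centers, chirality).
// [[Rcpp::export(name = ".detect_tips_raw")]]
NumericMatrix detect_tips_raw(NumericVector u_now, NumericVector u_delayed,
                              LogicalVector mask, IntegerVector dm,
                              double dx, double ustar) {
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const double* UN = REAL(u_now);
  const double* UD = REAL(u_delayed);
  const int* M = LOGICAL(mask);
  std::vector<double> out;            // x,y,z,chir quadruples
  std::vector<double> th((size_t)nx * ny);
  const double NAv = NA_REAL;
  for (int k = 0; k < nz; ++k) {
    const size_t off = (size_t)k * nx * ny;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const size_t id = off + (size_t)j * nx + i;
        th[(size_t)j * nx + i] = M[id] ?
          std::atan2(UD[id] - ustar, UN[id] - ustar) : NAv;
      }
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        const double t00 = th[(size_t)j * nx + i];
        const double t10 = th[(size_t)j * nx + i + 1];
        const double t11 = th[(size_t)(j + 1) * nx + i + 1];
        const double t01 = th[(size_t)(j + 1) * nx + i];
        if (ISNAN(t00) || ISNAN(t10) || ISNAN(t11) || ISNAN(t01)) continue;
        const double wind = wrap_pi(t10 - t00) + wrap_pi(t11 - t10) +
                            wrap_pi(t01 - t11) + wrap_pi(t00 - t01);
        if (std::fabs(wind) > M_PI) {
          out.push_back((i + 1) * dx);
          out.push_back((j + 1) * dx);
          out.push_back((k + 0.5) * dx);
          out.push_back(wind > 0 ? 1.0 : -1.0);
        }
      }
  }
  const int m = out.size() / 4;
  NumericMatrix res(m, 4);
  for (int r = 0; r < m; ++r)
    for (int c = 0; c < 4; ++c) res(r, c) = out[4 * r + c];
  return res;
}

// Single-cell (0-D) integration; records u at record_every.
// [[Rcpp::export(name = ".fk_cell")]]
List fk_cell(List params, double dt, double duration,
             NumericVector stim_onset, NumericVector stim_duration,
             NumericVector stim_amplitude, double record_every,
             double u0, double v0, double w0) {
  const FKPar p = unpack(params);
  const long nsteps = (long) std::lround(duration / dt);
  const long rec_stride = std::max(1L, (long) std::lround(record_every / dt));
  const int nrec = (int)(nsteps / rec_stride) + 1;
  NumericVector tu(nrec), tt(nrec), tv(nrec), tw(nrec);
  double u = u0, v = v0, w = w0;
  tu[0] = u; tv[0] = v; tw[0] = w; tt[0] = 0.0;
  int irec = 1;
  const int nstim = stim_onset.size();
  for (long step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    double du = fk_react(u, v, w, p, dt);
    for (int s = 0; s < nstim; ++s)
      if (t >= stim_onset[s] && t < stim_onset[s] + stim_duration[s])
        du += stim_amplitude[s];
    u += dt * du;
    if ((step + 1) % rec_stride == 0 && irec < nrec) {
      tu[irec] = u; tv[irec] = v; tw[irec] = w;
      tt[irec] = (step + 1) * dt; ++irec;
    }
  }
  return List::create(_["t"] = tt, _["u"] = tu, _["v"] = tv, _["w"] = tw,
                      _["u_end"] = u, _["v_end"] = v, _["w_end"] = w);
}
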