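// Simulation kernels for the canine epicardial action potential model.
//
// State vector y = (V, m, h, s, f, xr, xs). Gates z, r, d, y are
// instantaneous (algebraic functions of V) and never integrated.
// Parameter vector layout (length 37, fixed order; see R/params.R):
//   0 gNa  1 Em   2 km   3 tau_m  4 Eh   5 kh   6 delta_h 7 tau_h0
//   8 gK1  9 Ez  10 kz
//  11 gto 12 Er  13 kr  14 Es  15 ks  16 tau_s
//  17 gCaL 18 Ed 19 kd  20 Ef  21 kf  22 tau_f
//  23 gKr 24 Exr 25 kxr 26 tau_xr 27 Ey 28 ky
//  29 gKs 30 Exs 31 kxs 32 tau_xs
//  33 ENa 34 EK  35 ECa 36 Cm
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Params {
  double gNa, Em, km, tau_m, Eh, kh, delta_h, tau_h0;
  double gK1, Ez, kz;
  double gto, Er, kr, Es, ks, tau_s;
  double gCaL, Ed, kd, Ef, kf, tau_f;
  double gKr, Exr, kxr, tau_xr, Ey, ky;
  double gKs, Exs, kxs, tau_xs;
  double ENa, EK, ECa, Cm;
};

static Params unpack(const NumericVector& p) {
  if (p.size() != 37) stop("parameter vector must have length 37");
  Params P;
  P.gNa = p[0]; P.Em = p[1]; P.km = p[2]; P.tau_m = p[3];
  P.Eh = p[4]; P.kh = p[5]; P.delta_h = p[6]; P.tau_h0 = p[7];
  P.gK1 = p[8]; P.Ez = p[9]; P.kz = p[10];
  P.gto = p[11]; P.Er = p[12]; P.kr = p[13]; P.Es = p[14]; P.ks = p[15];
  P.tau_s = p[16];
  P.gCaL = p[17]; P.Ed = p[18]; P.kd = p[19]; P.Ef = p[20]; P.kf = p[21];
  P.tau_f = p[22];
  P.gKr = p[23]; P.Exr = p[24]; P.kxr = p[25]; P.tau_xr = p[26];
  P.Ey = p[27]; P.ky = p[28];
  P.gKs = p[29]; P.Exs = p[30]; P.kxs = p[31]; P.tau_xs = p[32];
  P.ENa = p[33]; P.EK = p[34]; P.ECa = p[35]; P.Cm = p[36];
  return P;
}

// sigmoid steady states: activation uses the '-' sign, inactivation '+'
static inline double act_inf(double V, double E, double k) {
  return 1.0 / (1.0 + std::exp(-(V - E) / k));
}
static inline double inact_inf(double V, double E, double k) {
  return 1.0 / (1.0 + std::exp((V - E) / k));
}
static inline double tau_h_of(double V, const Params& P) {
  double u = (V - P.Eh) / P.kh;
  return 2.0 * P.tau_h0 * std::exp(P.delta_h * u) / (1.0 + std::exp(u));
}

// six ionic currents; instantaneous gates evaluated at the supplied V
static inline void currents(const double* y, const Params& P, double* I) {
  const double V = y[0];
  const double m = y[1], h = y[2], s = y[3], f = y[4], xr = y[5], xs = y[6];
  I[0] = P.gNa * m * m * m * h * h * (V - P.ENa);            // INa
  I[1] = P.gK1 * inact_inf(V, P.Ez, P.kz) * (V - P.EK);      // IK1
  I[2] = P.gto * act_inf(V, P.Er, P.kr) * s * (V - P.EK);    // Ito
  I[3] = P.gCaL * act_inf(V, P.Ed, P.kd) * f * (V - P.ECa);  // ICaL
  I[4] = P.gKr * xr * inact_inf(V, P.Ey, P.ky) * (V - P.EK); // IKr
  I[5] = P.gKs * xs * (V - P.EK);                            // IKs
}

static inline void deriv(const double* y, const Params& P, double Istim,
                         double* dy) {
  double I[6];
  currents(y, P, I);
  const double V = y[0];
  double Iion = I[0] + I[1] + I[2] + I[3] + I[4] + I[5];
  dy[0] = (Istim - Iion) / P.Cm;
  dy[1] = (act_inf(V, P.Em, P.km) - y[1]) / P.tau_m;
  dy[2] = (inact_inf(V, P.Eh, P.kh) - y[2]) / tau_h_of(V, P);
  dy[3] = (inact_inf(V, P.Es, P.ks) - y[3]) / P.tau_s;
  dy[4] = (inact_inf(V, P.Ef, P.kf) - y[4]) / P.tau_f;
  dy[5] = (act_inf(V, P.Exr, P.kxr) - y[5]) / P.tau_xr;
  dy[6] = (act_inf(V, P.Exs, P.kxs) - y[6]) / P.tau_xs;
}

// ---------------------------------------------------------------------------
// Dormand-Prince 5(4) adaptive integrator with square-pulse stimuli.
// Integration is split at pulse on/off boundaries so the RHS is smooth
// within each segment; output is cubic-Hermite interpolated onto the
// uniform dt_out grid.
// ---------------------------------------------------------------------------

struct Solver {
  Params P;
  double rtol, atol, hmax;
  long max_steps;
  Solver(const Params& P_, double rtol_, double atol_, double hmax_)
    : P(P_), rtol(rtol_), atol(atol_), hmax(hmax_), max_steps(50000000L) {}

  // integrate over [t0, t1] with constant stimulus; optionally sample onto
  // grid points (absolute times) in [grid_lo, grid_hi) given by
  // t_k = k * dt_out; writer callback receives (k, y7, dy7).
  template <class Writer>
  void segment(double t0, double t1, double* y, double Istim,
               double dt_out, Writer&& write, double* vmax,
               long& nsteps) {
    double t = t0;
    double k1[7], k2[7], k3[7], k4[7], k5[7], k6[7], k7[7];
    double ytmp[7], ynew[7], err[7];
    deriv(y, P, Istim, k1);
    double h = std::min(hmax, t1 - t0);
    if (h <= 0) return;
    h = std::min(h, 0.01);
    // next output index strictly above t0 (t0 itself written by caller)
    long kout = (long)std::floor(t0 / dt_out) + 1;
    while (t < t1) {
      if (nsteps++ > max_steps) stop("ODE solver exceeded step limit");
      if (h > t1 - t) h = t1 - t;
      // DP45 stages
      for (int i = 0; i < 7; i++) ytmp[i] = y[i] + h * (0.2 * k1[i]);
      deriv(ytmp, P, Istim, k2);
      for (int i = 0; i < 7; i++)
        ytmp[i] = y[i] + h * (3.0/40.0*k1[i] + 9.0/40.0*k2[i]);
      deriv(ytmp, P, Istim, k3);
      for (int i = 0; i < 7; i++)
        ytmp[i] = y[i] + h * (44.0/45.0*k1[i] - 56.0/15.0*k2[i] + 32.0/9.0*k3[i]);
      deriv(ytmp, P, Istim, k4);
      for (int i = 0; i < 7; i++)
        ytmp[i] = y[i] + h * (19372.0/6561.0*k1[i] - 25360.0/2187.0*k2[i]
                              + 64448.0/6561.0*k3[i] - 212.0/729.0*k4[i]);
      deriv(ytmp, P, Istim, k5);
      for (int i = 0; i < 7; i++)
        ytmp[i] = y[i] + h * (9017.0/3168.0*k1[i] - 355.0/33.0*k2[i]
                              + 46732.0/5247.0*k3[i] + 49.0/176.0*k4[i]
                              - 5103.0/18656.0*k5[i]);
      deriv(ytmp, P, Istim, k6);
      for (int i = 0; i < 7; i++)
        ynew[i] = y[i] + h * (35.0/384.0*k1[i] + 500.0/1113.0*k3[i]
                              + 125.0/192.0*k4[i] - 2187.0/6784.0*k5[i]
                              + 11.0/84.0*k6[i]);
      deriv(ynew, P, Istim, k7);
      // embedded 4th-order error
      static const double e1 = 35.0/384.0 - 5179.0/57600.0;
      static const double e3 = 500.0/1113.0 - 7571.0/16695.0;
      static const double e4 = 125.0/192.0 - 393.0/640.0;
      static const double e5 = -2187.0/6784.0 + 92097.0/339200.0;
      static const double e6 = 11.0/84.0 - 187.0/2100.0;
      static const double e7 = -1.0/40.0;
      double errnorm = 0.0;
      for (int i = 0; i < 7; i++) {
        err[i] = h * (e1*k1[i] + e3*k3[i] + e4*k4[i] + e5*k5[i]
                      + e6*k6[i] + e7*k7[i]);
        double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        double r = err[i] / sc;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / 7.0);
      if (!std::isfinite(errnorm)) {
        h *= 0.25;
        if (h < 1e-12) stop("ODE solver failed: step size underflow");
        deriv(y, P, Istim, k1);
        continue;
      }
      if (errnorm <= 1.0) {
        // accept; dense output via cubic Hermite on [t, t+h]
        double tnew = t + h;
        while (kout * dt_out <= tnew + 1e-12 && kout * dt_out <= t1 + 1e-12) {
          double ts = kout * dt_out;
          double th = (ts - t) / h;
          double h00 = (1 + 2*th) * (1-th) * (1-th);
          double h10 = th * (1-th) * (1-th);
          double h01 = th * th * (3 - 2*th);
          double h11 = th * th * (th - 1);
          double ys[7], dys[7];
          for (int i = 0; i < 7; i++)
            ys[i] = h00*y[i] + h10*h*k1[i] + h01*ynew[i] + h11*h*k7[i];
          for (int i = 1; i < 7; i++)
            ys[i] = std::min(1.0, std::max(0.0, ys[i]));
          deriv(ys, P, Istim, dys);
          write(kout, ys, dys);
          kout++;
        }
        bool clamped = false;
        for (int i = 1; i < 7; i++) {
          if (ynew[i] < 0.0) { ynew[i] = 0.0; clamped = true; }
          if (ynew[i] > 1.0) { ynew[i] = 1.0; clamped = true; }
        }
        for (int i = 0; i < 7; i++) y[i] = ynew[i];
        if (vmax && y[0] > *vmax) *vmax = y[0];
        t = tnew;
        if (clamped) deriv(y, P, Istim, k1);
        else for (int i = 0; i < 7; i++) k1[i] = k7[i];
        double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
        h *= std::min(5.0, std::max(0.2, fac));
        h = std::min(h, hmax);
      } else {
        double fac = 0.9 * std::pow(errnorm, -0.2);
        h *= std::max(0.1, fac);
        if (h < 1e-12) stop("ODE solver failed: step size underflow");
      }
    }
  }
};

// build segment boundaries and per-segment stimulus amplitudes from pulses
// (matrix with columns onset, duration, amplitude); pulses assumed disjoint
static void build_segments(const NumericMatrix& pulses, double t_end,
                           std::vector<double>& bnd,
                           std::vector<double>& amp) {
  std::vector<double> times;
  times.push_back(0.0);
  times.push_back(t_end);
  for (int j = 0; j < pulses.nrow(); j++) {
    double on = pulses(j, 0), off = pulses(j, 0) + pulses(j, 1);
    if (on > 0 && on < t_end) times.push_back(on);
    if (off > 0 && off < t_end) times.push_back(off);
  }
  std::sort(times.begin(), times.end());
  times.erase(std::unique(times.begin(), times.end(),
              [](double a, double b){ return std::fabs(a-b) < 1e-12; }),
              times.end());
  bnd = times;
  amp.assign(bnd.size() - 1, 0.0);
  for (size_t s = 0; s + 1 < bnd.size(); s++) {
    double tm = 0.5 * (bnd[s] + bnd[s+1]);
    for (int j = 0; j < pulses.nrow(); j++) {
      if (tm >= pulses(j, 0) && tm < pulses(j, 0) + pulses(j, 1))
        amp[s] += pulses(j, 2);
    }
  }
}

static inline double stim_at(const NumericMatrix& pulses, double t) {
  double a = 0.0;
  for (int j = 0; j < pulses.nrow(); j++)
    if (t >= pulses(j, 0) && t < pulses(j, 0) + pulses(j, 1)) a += pulses(j, 2);
  return a;
}

// [[Rcpp::export]]
List cpp_simulate(NumericVector par, NumericVector y0, NumericMatrix pulses,
                  double duration, double dt_out, double rtol, double atol,
                  double hmax, bool store_states, bool with_currents) {
  Params P = unpack(par);
  if (y0.size() != 7) stop("initial state must have length 7");
  long n = (long)std::floor(duration / dt_out + 0.5);
  double t_end = n * dt_out;
  NumericVector t(n + 1), V(n + 1), dVdt(n + 1);
  NumericMatrix Y = store_states ? NumericMatrix(n + 1, 7) : NumericMatrix(0, 0);
  NumericMatrix Cur = with_currents ? NumericMatrix(n + 1, 6) : NumericMatrix(0, 0);
  double y[7];
  for (int i = 0; i < 7; i++) y[i] = y0[i];
  for (long k = 0; k <= n; k++) t[k] = k * dt_out;
  // write initial point
  {
    double dy[7];
    deriv(y, P, stim_at(pulses, 0.0), dy);
    V[0] = y[0]; dVdt[0] = dy[0];
    if (store_states) for (int i = 0; i < 7; i++) Y(0, i) = y[i];
    if (with_currents) {
      double I[6]; currents(y, P, I);
      for (int i = 0; i < 6; i++) Cur(0, i) = I[i];
    }
  }
  std::vector<double> bnd, amp;
  build_segments(pulses, t_end, bnd, amp);
  Solver S(P, rtol, atol, hmax);
  long nsteps = 0;
  for (size_t s = 0; s + 1 < bnd.size(); s++) {
    double Istim = amp[s];
    S.segment(bnd[s], bnd[s+1], y, Istim, dt_out,
      [&](long k, const double* ys, const double* dys) {
        if (k <= n) {
          V[k] = ys[0]; dVdt[k] = dys[0];
          if (store_states) for (int i = 0; i < 7; i++) Y(k, i) = ys[i];
          if (with_currents) {
            double I[6]; currents(ys, P, I);
            for (int i = 0; i < 6; i++) Cur(k, i) = I[i];
          }
        }
      }, nullptr, nsteps);
  }
  for (int i = 0; i < 7; i++)
    if (!std::isfinite(y[i])) stop("ODE solver produced non-finite state");
  NumericVector yfin(7);
  for (int i = 0; i < 7; i++) yfin[i] = y[i];
  List out = List::create(_["t"] = t, _["V"] = V, _["dVdt"] = dVdt,
                          _["final_state"] = yfin);
  if (store_states) out["states"] = Y;
  if (with_currents) out["currents"] = Cur;
  return out;
}

// maximum V reached within [0, horizon] under a single pulse at t = 0
// [[Rcpp::export]]
double cpp_peak_v(NumericVector par, NumericVector y0, double amp,
                  double stim_dur, double horizon, double rtol, double atol,
                  double hmax) {
  Params P = unpack(par);
  double y[7];
  for (int i = 0; i < 7; i++) y[i] = y0[i];
  Solver S(P, rtol, atol, hmax);
  double vmax = y[0];
  long nsteps = 0;
  auto nowrite = [](long, const double*, const double*) {};
  S.segment(0.0, stim_dur, y, amp, horizon * 2, nowrite, &vmax, nsteps);
  S.segment(stim_dur, horizon, y, 0.0, horizon * 2, nowrite, &vmax, nsteps);
  return vmax;
}

// bisection for the minimum depolarizing stimulus amplitude
// [[Rcpp::export]]
double cpp_find_threshold(NumericVector par, NumericVector y0, double lo,
                          double hi, double rel_tol, double stim_dur,
                          double horizon, double v_criterion, double rtol,
                          double atol, double hmax) {
  if (cpp_peak_v(par, y0, hi, stim_dur, horizon, rtol, atol, hmax)
      <= v_criterion)
    return NA_REAL;  // bracket failure: even hi is subthreshold
  for (int it = 0; it < 100 && (hi - lo) > rel_tol * hi; it++) {
    double mid = 0.5 * (lo + hi);
    if (cpp_peak_v(par, y0, mid, stim_dur, horizon, rtol, atol, hmax)
        > v_criterion)
      hi = mid;
    else
      lo = mid;
  }
  return hi;
}

// pace at fixed cycle length; returns the trace of the final beat (state
// carried over continuously) and the end state
// [[Rcpp::export]]
List cpp_pace_last(NumericVector par, NumericVector y0, double bcl,
                   int n_beats, double amp, double stim_dur, double dt_out,
                   double rtol, double atol, double hmax, bool store_states,
                   bool with_currents) {
  Params P = unpack(par);
  double y[7];
  for (int i = 0; i < 7; i++) y[i] = y0[i];
  Solver S(P, rtol, atol, hmax);
  long nsteps = 0;
  auto nowrite = [](long, const double*, const double*) {};
  for (int b = 0; b < n_beats - 1; b++) {
    S.segment(0.0, stim_dur, y, amp, bcl * 2, nowrite, nullptr, nsteps);
    S.segment(stim_dur, bcl, y, 0.0, bcl * 2, nowrite, nullptr, nsteps);
    for (int i = 0; i < 7; i++)
      if (!std::isfinite(y[i])) stop("ODE solver produced non-finite state");
  }
  NumericVector ystart(7);
  for (int i = 0; i < 7; i++) ystart[i] = y[i];
  NumericMatrix pulses(1, 3);
  pulses(0, 0) = 0.0; pulses(0, 1) = stim_dur; pulses(0, 2) = amp;
  List tr = cpp_simulate(par, ystart, pulses, bcl, dt_out, rtol, atol, hmax,
                         store_states, with_currents);
  tr["beat_start_state"] = ystart;
  return tr;
}

// ---------------------------------------------------------------------------
// 1D monodomain strand: chi*(Cm dV/dt + Iion) = d/dx( sigma dV/dx )
// Lie splitting: Rush-Larsen/forward-Euler reaction step, then backward
// Euler diffusion (Thomas tridiagonal solve) with no-flux boundaries.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_strand(NumericVector par, NumericVector y0, int n_nodes, double dx,
                double dt, double duration, double chi, double sigma_b,
                int n_stim_nodes, double stim_amp, double stim_dur,
                int probe_node, double dt_out) {
  Params P = unpack(par);
  const int N = n_nodes;
  std::vector<double> V(N), m(N), h(N), s(N), f(N), xr(N), xs(N);
  for (int i = 0; i < N; i++) {
    V[i] = y0[0]; m[i] = y0[1]; h[i] = y0[2]; s[i] = y0[3];
    f[i] = y0[4]; xr[i] = y0[5]; xs[i] = y0[6];
  }
  const double D = sigma_b / (chi * P.Cm);  // cm^2 / ms
  const double r = D * dt / (dx * dx);
  // backward-Euler tridiagonal coefficients (Neumann: reflecting ends)
  std::vector<double> a(N, -r), b(N, 1 + 2 * r), c(N, -r);
  b[0] = 1 + r; b[N-1] = 1 + r; a[0] = 0; c[N-1] = 0;
  std::vector<double> cp(N), dp(N), Vn(N);
  std::vector<double> act(N, NA_REAL), Vprev(N);
  long n_steps = (long)std::floor(duration / dt + 0.5);
  long out_every = std::max(1L, (long)std::floor(dt_out / dt + 0.5));
  long n_out = n_steps / out_every + 1;
  NumericVector t_out(n_out), v_probe(n_out);
  t_out[0] = 0.0; v_probe[0] = V[probe_node];
  long kout = 1;
  for (long step = 0; step < n_steps; step++) {
    double t = step * dt;
    for (int i = 0; i < N; i++) Vprev[i] = V[i];
    // reaction step (forward Euler on V, Rush-Larsen on gates)
    for (int i = 0; i < N; i++) {
      double ys[7] = {V[i], m[i], h[i], s[i], f[i], xr[i], xs[i]};
      double I[6];
      currents(ys, P, I);
      double Iion = I[0] + I[1] + I[2] + I[3] + I[4] + I[5];
      double Istim = (i < n_stim_nodes && t < stim_dur) ? stim_amp : 0.0;
      double Vi = V[i];
      V[i] += dt * (Istim - Iion) / P.Cm;
      m[i]  += (act_inf(Vi, P.Em, P.km) - m[i]) *
               (1.0 - std::exp(-dt / P.tau_m));
      h[i]  += (inact_inf(Vi, P.Eh, P.kh) - h[i]) *
               (1.0 - std::exp(-dt / tau_h_of(Vi, P)));
      s[i]  += (inact_inf(Vi, P.Es, P.ks) - s[i]) *
               (1.0 - std::exp(-dt / P.tau_s));
      f[i]  += (inact_inf(Vi, P.Ef, P.kf) - f[i]) *
               (1.0 - std::exp(-dt / P.tau_f));
      xr[i] += (act_inf(Vi, P.Exr, P.kxr) - xr[i]) *
               (1.0 - std::exp(-dt / P.tau_xr));
      xs[i] += (act_inf(Vi, P.Exs, P.kxs) - xs[i]) *
               (1.0 - std::exp(-dt / P.tau_xs));
    }
    // diffusion step: Thomas algorithm
    cp[0] = c[0] / b[0];
    dp[0] = V[0] / b[0];
    for (int i = 1; i < N; i++) {
      double mden = b[i] - a[i] * cp[i-1];
      cp[i] = c[i] / mden;
      dp[i] = (V[i] - a[i] * dp[i-1]) / mden;
    }
    Vn[N-1] = dp[N-1];
    for (int i = N - 2; i >= 0; i--) Vn[i] = dp[i] - cp[i] * Vn[i+1];
    for (int i = 0; i < N; i++) {
      if (!std::isfinite(Vn[i])) stop("strand solver produced non-finite V");
      V[i] = Vn[i];
    }
    // activation detection: first upward crossing of -70 mV
    double tnew = (step + 1) * dt;
    for (int i = 0; i < N; i++) {
      if (ISNA(act[i]) && Vprev[i] < -70.0 && V[i] >= -70.0) {
        double frac = (-70.0 - Vprev[i]) / (V[i] - Vprev[i]);
        act[i] = t + frac * dt;
      }
    }
    if ((step + 1) % out_every == 0 && kout < n_out) {
      t_out[kout] = tnew;
      v_probe[kout] = V[probe_node];
      kout++;
    }
  }
  NumericVector x(N), act_out(N), v_final(N);
  for (int i = 0; i < N; i++) {
    x[i] = i * dx;
    act_out[i] = act[i];
    v_final[i] = V[i];
  }
  return List::create(_["x"] = x, _["activation_time"] = act_out,
                      _["t"] = t_out, _["v_probe"] = v_probe,
                      _["v_final"] = v_final);
}

// vectorized RHS / current evaluation used by the R-level module surface
// [[Rcpp::export]]
NumericMatrix cpp_derivs(NumericVector par, NumericMatrix states,
                         NumericVector istim) {
  Params P = unpack(par);
  int n = states.nrow();
  if (states.ncol() != 7) stop("states must have 7 columns");
  NumericMatrix out(n, 7);
  double y[7], dy[7];
  for (int j = 0; j < n; j++) {
    for (int i = 0; i < 7; i++) y[i] = states(j, i);
    deriv(y, P, istim[j % istim.size()], dy);
    for (int i = 0; i < 7; i++) out(j, i) = dy[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_currents(NumericVector par, NumericMatrix states) {
  Params P = unpack(par);
  int n = states.nrow();
  if (states.ncol() != 7) stop("states must have 7 columns");
  NumericMatrix out(n, 6);
  double y[7], I[6];
  for (int j = 0; j < n; j++) {
    for (int i = 0; i < 7; i++) y[i] = states(j, i);
    currents(y, P, I);
    for (int i = 0; i < 6; i++) out(j, i) = I[i];
  }
  return out;
}
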