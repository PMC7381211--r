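// Core AdEx integrators.
//
// Two independent code paths:
//   * adex_rkf45_cpp : adaptive Runge-Kutta-Fehlberg 4(5) with
//     event-localised spike handling (production integrator).
//   * adex_rk4_cpp   : plain fixed-step RK4 with grid crossing
//     interpolation, kept deliberately simple as a cross-check oracle.
//
// Model definition shared by both (but coded separately on purpose):
//   C_m dV/dt = -g_L (V - E_L) + g_L Delta_T exp((V - V_T)/Delta_T) + I(t) - w
//   tau_w dw/dt = a (V - E_L) - w
// with V read as min(V, V_peak) in both right-hand sides (the state clamp
// used by reference AdEx implementations: it keeps the stiff exponential
// upswing from contaminating the slow adaptation variable within a step),
// the exponential argument additionally capped at +30, spike emission when
// V crosses V_peak (reset to V_r, w += b), and a 1-ms refractory period
// during which V is clamped at V_r while w relaxes exactly.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct AdexP {
  double C_m, g_L, E_L, Delta_T, V_T, V_peak, V_r, a, b, tau_w, tau_ref;
};

// protocol kinds
enum { PROTO_ZERO = 0, PROTO_STEP = 1, PROTO_SINUSOID = 2 };

struct Proto {
  int kind;
  double amplitude, offset, frequency, onset, duration; // ms / pA / Hz
};

inline double stim_current(const Proto& pr, double t) {
  switch (pr.kind) {
  case PROTO_STEP:
    return (t >= pr.onset && t < pr.onset + pr.duration) ? pr.amplitude : 0.0;
  case PROTO_SINUSOID:
    if (t < pr.onset) return 0.0;
    return pr.offset +
           pr.amplitude * std::sin(2.0 * M_PI * pr.frequency * (t - pr.onset) / 1000.0);
  default:
    return 0.0;
  }
}

inline void adex_rhs(const AdexP& p, double V, double w, double I,
                     double& dV, double& dw) {
  double Vc = V < p.V_peak ? V : p.V_peak;
  double arg = (Vc - p.V_T) / p.Delta_T;
  if (arg > 30.0) arg = 30.0;
  dV = (-p.g_L * (Vc - p.E_L) + p.g_L * p.Delta_T * std::exp(arg) + I - w) / p.C_m;
  dw = (p.a * (Vc - p.E_L) - w) / p.tau_w;
}

// Classic Fehlberg 4(5) tableau.
const double B21 = 1.0 / 4.0;
const double B31 = 3.0 / 32.0, B32 = 9.0 / 32.0;
const double B41 = 1932.0 / 2197.0, B42 = -7200.0 / 2197.0, B43 = 7296.0 / 2197.0;
const double B51 = 439.0 / 216.0, B52 = -8.0, B53 = 3680.0 / 513.0,
             B54 = -845.0 / 4104.0;
const double B61 = -8.0 / 27.0, B62 = 2.0, B63 = -3544.0 / 2565.0,
             B64 = 1859.0 / 4104.0, B65 = -11.0 / 40.0;
// 4th order weights
const double C41 = 25.0 / 216.0, C43 = 1408.0 / 2565.0, C44 = 2197.0 / 4104.0,
             C45 = -1.0 / 5.0;
// 5th order weights
const double C51 = 16.0 / 135.0, C53 = 6656.0 / 12825.0, C54 = 28561.0 / 56430.0,
             C55 = -9.0 / 50.0, C56 = 2.0 / 55.0;

struct StepOut {
  double V4, w4, V5, w5; // 4th and 5th order solutions
};

// One RKF45 trial step of size h from (V, w) at time t. The stimulus is
// evaluated at the stage times (continuous-time protocol).
inline StepOut rkf45_step(const AdexP& p, const Proto& pr, double t, double V,
                          double w, double h) {
  double k1V, k1w, k2V, k2w, k3V, k3w, k4V, k4w, k5V, k5w, k6V, k6w;
  adex_rhs(p, V, w, stim_current(pr, t), k1V, k1w);
  adex_rhs(p, V + h * B21 * k1V, w + h * B21 * k1w,
           stim_current(pr, t + h / 4.0), k2V, k2w);
  adex_rhs(p, V + h * (B31 * k1V + B32 * k2V), w + h * (B31 * k1w + B32 * k2w),
           stim_current(pr, t + 3.0 * h / 8.0), k3V, k3w);
  adex_rhs(p, V + h * (B41 * k1V + B42 * k2V + B43 * k3V),
           w + h * (B41 * k1w + B42 * k2w + B43 * k3w),
           stim_current(pr, t + 12.0 * h / 13.0), k4V, k4w);
  adex_rhs(p, V + h * (B51 * k1V + B52 * k2V + B53 * k3V + B54 * k4V),
           w + h * (B51 * k1w + B52 * k2w + B53 * k3w + B54 * k4w),
           stim_current(pr, t + h), k5V, k5w);
  adex_rhs(p, V + h * (B61 * k1V + B62 * k2V + B63 * k3V + B64 * k4V + B65 * k5V),
           w + h * (B61 * k1w + B62 * k2w + B63 * k3w + B64 * k4w + B65 * k5w),
           stim_current(pr, t + h / 2.0), k6V, k6w);
  StepOut o;
  o.V4 = V + h * (C41 * k1V + C43 * k3V + C44 * k4V + C45 * k5V);
  o.w4 = w + h * (C41 * k1w + C43 * k3w + C44 * k4w + C45 * k5w);
  o.V5 = V + h * (C51 * k1V + C53 * k3V + C54 * k4V + C55 * k5V + C56 * k6V);
  o.w5 = w + h * (C51 * k1w + C53 * k3w + C54 * k4w + C55 * k5w + C56 * k6w);
  return o;
}

struct Recorder {
  double dt;               // 0 => record nothing
  double next;             // next sample time
  std::vector<double> t, V, w;
  void init(double dt_) {
    dt = dt_;
    next = 0.0;
  }
  // record samples in [t0, t1] by linear interpolation between the
  // endpoint states (accepted steps are <= 0.1 ms, well below any
  // feature's resolution)
  void span(double t0, double V0, double w0, double t1, double V1, double w1) {
    if (dt <= 0.0) return;
    while (next <= t1 + 1e-12) {
      double f = (t1 > t0) ? (next - t0) / (t1 - t0) : 0.0;
      if (f < 0.0) f = 0.0;
      if (f > 1.0) f = 1.0;
      t.push_back(next);
      V.push_back(V0 + f * (V1 - V0));
      w.push_back(w0 + f * (w1 - w0));
      next += dt;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List adex_rkf45_cpp(NumericVector params, List protocol, double t_total,
                    double rtol, double atol, double h_max, double h_min,
                    double spike_tol, double record_dt, double max_steps) {
  AdexP p;
  p.C_m = params["C_m"];
  p.g_L = params["g_L"];
  p.E_L = params["E_L"];
  p.Delta_T = params["Delta_T"];
  p.V_T = params["V_T"];
  p.V_peak = params["V_peak"];
  p.V_r = params["V_r"];
  p.a = params["a"];
  p.b = params["b"];
  p.tau_w = params["tau_w"];
  p.tau_ref = params["tau_ref"];

  Proto pr;
  pr.kind = as<int>(protocol["kind_code"]);
  pr.amplitude = as<double>(protocol["amplitude"]);
  pr.offset = as<double>(protocol["offset"]);
  pr.frequency = as<double>(protocol["frequency"]);
  pr.onset = as<double>(protocol["onset"]);
  pr.duration = as<double>(protocol["duration"]);

  double V = p.E_L, w = 0.0, t = 0.0;
  std::vector<double> spikes;
  Recorder rec;
  rec.init(record_dt);
  rec.span(0.0, V, w, 0.0, V, w);

  long n_accept = 0, n_reject = 0, n_minstep = 0;

  // integration breakpoints: stimulus discontinuities and final time
  std::vector<double> breaks;
  if (pr.kind == PROTO_STEP) {
    if (pr.onset > 0 && pr.onset < t_total) breaks.push_back(pr.onset);
    double off = pr.onset + pr.duration;
    if (off > 0 && off < t_total) breaks.push_back(off);
  } else if (pr.kind == PROTO_SINUSOID && pr.onset > 0 && pr.onset < t_total) {
    breaks.push_back(pr.onset);
  }
  breaks.push_back(t_total);
  std::size_t ib = 0;

  double h = h_max;
  const long max_iter = (long)max_steps; // step budget; exceeding it errors
  long iter = 0;

  while (t < t_total - 1e-12) {
    if (++iter > max_iter)
      stop("integration exceeded the step budget at t = %f ms", t);
    while (ib < breaks.size() && t >= breaks[ib] - 1e-12) ++ib;
    double t_stop = (ib < breaks.size()) ? breaks[ib] : t_total;
    if (h > h_max) h = h_max;
    if (t + h > t_stop) h = t_stop - t;
    if (h < 1e-14) { t = t_stop; continue; }

    StepOut s = rkf45_step(p, pr, t, V, w, h);

    if (!R_finite(s.V4) || !R_finite(s.w4)) {
      // treat as a crossing if the state exploded upward, else shrink
      if (s.V4 > p.V_peak || !R_finite(s.V4)) s.V4 = p.V_peak + 1.0;
    }

    // error estimate of the embedded pair (may be NaN after an overflow)
    double errV = std::fabs(s.V4 - s.V5) / (atol + rtol * std::fabs(s.V4));
    double errw = std::fabs(s.w4 - s.w5) / (atol + rtol * std::fabs(s.w4));
    double err = errV > errw ? errV : errw;
    bool err_ok = R_finite(err) && err <= 1.0;
    // crossings are only localised on steps that pass error control or
    // are already below the event resolution; larger failing steps are
    // shrunk first so the bisected trajectory is accurate
    double h_evt = 10.0 * spike_tol;
    if (h_evt < h_min) h_evt = h_min;

    if (s.V4 >= p.V_peak && (err_ok || h <= h_evt)) {
      // spike inside (t, t+h]: bisect the step for the crossing time
      double lo = 0.0, hi = h;
      while (hi - lo > spike_tol) {
        double mid = 0.5 * (lo + hi);
        StepOut sm = rkf45_step(p, pr, t, V, w, mid);
        double Vm = R_finite(sm.V4) ? sm.V4 : (p.V_peak + 1.0);
        if (Vm >= p.V_peak) hi = mid; else lo = mid;
      }
      StepOut sc = rkf45_step(p, pr, t, V, w, hi);
      double t_sp = t + hi;
      rec.span(t, V, w, t_sp, p.V_peak, sc.w4);
      spikes.push_back(t_sp);
      if (spikes.size() > 1000000)
        stop("more than 1e6 spikes: aborting (parameters likely pathological)");
      // reset + refractory: V clamped at V_r, w relaxes exactly toward
      // a (V_r - E_L) with time constant tau_w
      double w0 = sc.w4 + p.b;
      double t_end = t_sp + p.tau_ref;
      if (t_end > t_total) t_end = t_total;
      double w_inf = p.a * (p.V_r - p.E_L);
      double w_end = w_inf + (w0 - w_inf) * std::exp(-(t_end - t_sp) / p.tau_w);
      // record within refractory with the exact exponential (sampled
      // linearly between endpoints; tau_w >= 1 ms so this is smooth)
      rec.span(t_sp, p.V_r, w0, t_end, p.V_r, w_end);
      V = p.V_r;
      w = w_end;
      t = t_end;
      h = h_max;
      n_accept++;
      continue;
    }

    if (err_ok || h <= h_min) {
      if (h <= h_min && !err_ok) n_minstep++;
      rec.span(t, V, w, t + h, s.V5, s.w5);
      V = s.V5;  // local extrapolation: advance with the 5th-order solution
      w = s.w5;
      t += h;
      n_accept++;
    } else {
      n_reject++;
    }
    double fac = (R_finite(err) && err > 0.0) ? 0.9 * std::pow(err, -0.2) : 0.2;
    if (err == 0.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < h_min) h = h_min;
  }

  return List::create(
      _["time"] = wrap(rec.t), _["V"] = wrap(rec.V), _["w"] = wrap(rec.w),
      _["spikes"] = wrap(spikes),
      _["n_accepted"] = (double)n_accept, _["n_rejected"] = (double)n_reject,
      _["n_min_step"] = (double)n_minstep);
}

// ---------------------------------------------------------------------------
// Fixed-step RK4 oracle. Independent coding of the same model: grid
// stepping, spike crossing located by linear interpolation within the grid
// step, refractory release at the first grid point >= spike + tau_ref.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List adex_rk4_cpp(NumericVector params, List protocol, double t_total,
                  double dt) {
  double C_m = params["C_m"], g_L = params["g_L"], E_L = params["E_L"],
         Delta_T = params["Delta_T"], V_T = params["V_T"],
         V_peak = params["V_peak"], V_r = params["V_r"], a = params["a"],
         b = params["b"], tau_w = params["tau_w"], tau_ref = params["tau_ref"];
  int kind = as<int>(protocol["kind_code"]);
  double amplitude = as<double>(protocol["amplitude"]);
  double offset = as<double>(protocol["offset"]);
  double frequency = as<double>(protocol["frequency"]);
  double onset = as<double>(protocol["onset"]);
  double duration = as<double>(protocol["duration"]);

  double V = E_L, w = 0.0;
  long n = (long)std::floor(t_total / dt + 0.5);
  std::vector<double> spikes;
  double ref_until = -1.0;

#define ORACLE_I(tt)                                                          \
  (kind == 1 ? (((tt) >= onset && (tt) < onset + duration) ? amplitude : 0.0) \
   : kind == 2                                                                \
       ? ((tt) < onset ? 0.0                                                  \
                       : offset + amplitude * std::sin(2.0 * M_PI * frequency * \
                                                       ((tt) - onset) / 1000.0)) \
       : 0.0)

#define ORACLE_RHS(VV, ww, II, dV, dw)                                        \
  {                                                                           \
    double Vc_ = (VV) < V_peak ? (VV) : V_peak;                               \
    double arg_ = (Vc_ - V_T) / Delta_T;                                      \
    if (arg_ > 30.0) arg_ = 30.0;                                             \
    dV = (-g_L * (Vc_ - E_L) + g_L * Delta_T * std::exp(arg_) + (II) - ww) /  \
         C_m;                                                                 \
    dw = (a * (Vc_ - E_L) - ww) / tau_w;                                      \
  }

  for (long i = 0; i < n; i++) {
    double t = i * dt;
    double h = dt;
    if (t < ref_until) {
      // V clamped; advance w alone (RK4 at V = V_r) until the exact
      // refractory release time, then continue with a partial step
      double hold = (ref_until < t + dt ? ref_until : t + dt) - t;
      double k1, k2, k3, k4, tmp;
      ORACLE_RHS(V_r, w, 0.0, tmp, k1);
      ORACLE_RHS(V_r, w + 0.5 * hold * k1, 0.0, tmp, k2);
      ORACLE_RHS(V_r, w + 0.5 * hold * k2, 0.0, tmp, k3);
      ORACLE_RHS(V_r, w + hold * k3, 0.0, tmp, k4);
      (void)tmp;
      w += hold * (k1 + 2 * k2 + 2 * k3 + k4) / 6.0;
      V = V_r;
      if (ref_until >= t + dt) continue;
      t = ref_until;
      h = (i + 1) * dt - ref_until;
      if (h <= 0.0) continue;
    }
    double I1 = ORACLE_I(t), I2 = ORACLE_I(t + 0.5 * h), I3 = ORACLE_I(t + h);
    double k1V, k1w, k2V, k2w, k3V, k3w, k4V, k4w;
    ORACLE_RHS(V, w, I1, k1V, k1w);
    ORACLE_RHS(V + 0.5 * h * k1V, w + 0.5 * h * k1w, I2, k2V, k2w);
    ORACLE_RHS(V + 0.5 * h * k2V, w + 0.5 * h * k2w, I2, k3V, k3w);
    ORACLE_RHS(V + h * k3V, w + h * k3w, I3, k4V, k4w);
    double Vn = V + h * (k1V + 2 * k2V + 2 * k3V + k4V) / 6.0;
    double wn = w + h * (k1w + 2 * k2w + 2 * k3w + k4w) / 6.0;
    if (Vn >= V_peak) {
      // redo the crossing step on a 16-fold finer grid and interpolate
      // linearly inside the crossing substep (the upswing is far too
      // steep for a single-step linear interpolation)
      int m = 16;
      double hs = h / m, ts = t, Vs = V, ws = w, t_sp = t + h;
      for (int j = 0; j < m; j++) {
        double Ia = ORACLE_I(ts), Ib = ORACLE_I(ts + 0.5 * hs),
               Ic = ORACLE_I(ts + hs);
        double a1V, a1w, a2V, a2w, a3V, a3w, a4V, a4w;
        ORACLE_RHS(Vs, ws, Ia, a1V, a1w);
        ORACLE_RHS(Vs + 0.5 * hs * a1V, ws + 0.5 * hs * a1w, Ib, a2V, a2w);
        ORACLE_RHS(Vs + 0.5 * hs * a2V, ws + 0.5 * hs * a2w, Ib, a3V, a3w);
        ORACLE_RHS(Vs + hs * a3V, ws + hs * a3w, Ic, a4V, a4w);
        double Vq = Vs + hs * (a1V + 2 * a2V + 2 * a3V + a4V) / 6.0;
        double wq = ws + hs * (a1w + 2 * a2w + 2 * a3w + a4w) / 6.0;
        if (Vq >= V_peak) {
          double f = (V_peak - Vs) / (Vq - Vs);
          if (f < 0.0) f = 0.0;
          if (f > 1.0) f = 1.0;
          t_sp = ts + f * hs;
          wn = wq;
          break;
        }
        Vs = Vq;
        ws = wq;
        ts += hs;
      }
      spikes.push_back(t_sp);
      V = V_r;
      w = wn + b;
      ref_until = t_sp + tau_ref;
    } else {
      V = Vn;
      w = wn;
    }
  }
#undef ORACLE_I
#undef ORACLE_RHS

  return List::create(_["spikes"] = wrap(spikes), _["V_final"] = V,
                      _["w_final"] = w);
}
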