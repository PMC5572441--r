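#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Conductance-based exponential-synapse LIF ("IfCondExp") network simulator.
//
// Units: mV, nS, nF, ms, nA. Membrane equation
//   C_m dv/dt = 0.001*(g_leak*(v_rest - v) + g*(e_exc - v)) + I_offset
//   dg/dt     = -g / tau_exc
// (the 0.001 converts nS*mV = pA to nA; dv/dt is then in mV/ms).
//
// Spike propagation and threshold handling are synchronous on a grid with
// user-defined step dt: input spikes are delivered at the grid point
// ceil(t/dt)*dt (never before their true time), the threshold v >= v_th is
// checked at grid points only, and the ODE is advanced between grid points
// either by one naive explicit Euler step (method 0) or by an adaptive
// Runge-Kutta-Fehlberg 4(5) integrator with absolute error target abs_tol
// (method 1). During the refractory period the membrane is clamped at
// v_reset while the synaptic conductance keeps evolving; the refractory
// window is rounded up to whole grid steps.

struct Pars {
  double v_rest, v_th, v_reset, tau_ref, g_leak, c_m, e_exc, tau_exc;
};

static inline double f_v(const Pars &p, double v, double g, double I) {
  return (0.001 * (p.g_leak * (p.v_rest - v) + g * (p.e_exc - v)) + I) / p.c_m;
}
static inline double f_g(const Pars &p, double g) { return -g / p.tau_exc; }

// advance (v, g) over an interval of length len with adaptive RKF45;
// updates vmax with every accepted sub-step endpoint
static void rkf45_interval(const Pars &p, double I, double len, double abs_tol,
                           double &v, double &g, double &vmax) {
  double t = 0.0, h = len;
  const double h_min = 1e-6;
  int guard = 0;
  while (t < len && ++guard < 100000) {
    if (h > len - t) h = len - t;
    // Fehlberg stages (autonomous system)
    double k1v = f_v(p, v, g, I),                        k1g = f_g(p, g);
    double v2 = v + h * k1v / 4.0,                       g2 = g + h * k1g / 4.0;
    double k2v = f_v(p, v2, g2, I),                      k2g = f_g(p, g2);
    double v3 = v + h * (3 * k1v + 9 * k2v) / 32.0;
    double g3 = g + h * (3 * k1g + 9 * k2g) / 32.0;
    double k3v = f_v(p, v3, g3, I),                      k3g = f_g(p, g3);
    double v4 = v + h * (1932 * k1v - 7200 * k2v + 7296 * k3v) / 2197.0;
    double g4 = g + h * (1932 * k1g - 7200 * k2g + 7296 * k3g) / 2197.0;
    double k4v = f_v(p, v4, g4, I),                      k4g = f_g(p, g4);
    double v5 = v + h * (439.0 / 216 * k1v - 8 * k2v + 3680.0 / 513 * k3v -
                         845.0 / 4104 * k4v);
    double g5 = g + h * (439.0 / 216 * k1g - 8 * k2g + 3680.0 / 513 * k3g -
                         845.0 / 4104 * k4g);
    double k5v = f_v(p, v5, g5, I),                      k5g = f_g(p, g5);
    double v6 = v + h * (-8.0 / 27 * k1v + 2 * k2v - 3544.0 / 2565 * k3v +
                         1859.0 / 4104 * k4v - 11.0 / 40 * k5v);
    double g6 = g + h * (-8.0 / 27 * k1g + 2 * k2g - 3544.0 / 2565 * k3g +
                         1859.0 / 4104 * k4g - 11.0 / 40 * k5g);
    double k6v = f_v(p, v6, g6, I),                      k6g = f_g(p, g6);
    double v_hi = v + h * (16.0 / 135 * k1v + 6656.0 / 12825 * k3v +
                           28561.0 / 56430 * k4v - 9.0 / 50 * k5v +
                           2.0 / 55 * k6v);
    double g_hi = g + h * (16.0 / 135 * k1g + 6656.0 / 12825 * k3g +
                           28561.0 / 56430 * k4g - 9.0 / 50 * k5g +
                           2.0 / 55 * k6g);
    double v_lo = v + h * (25.0 / 216 * k1v + 1408.0 / 2565 * k3v +
                           2197.0 / 4104 * k4v - k5v / 5.0);
    double g_lo = g + h * (25.0 / 216 * k1g + 1408.0 / 2565 * k3g +
                           2197.0 / 4104 * k4g - k5g / 5.0);
    double err = std::max(std::fabs(v_hi - v_lo), std::fabs(g_hi - g_lo));
    if (err <= abs_tol || h <= h_min) {
      t += h;
      v = v_hi;
      g = g_hi;
      if (v > vmax) vmax = v;
      if (!std::isfinite(v) || !std::isfinite(g))
        stop("integration diverged (rkf45, step size %f ms)", h);
    }
    double fac = err > 0 ? 0.9 * std::pow(abs_tol / err, 0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < h_min) h = h_min;
  }
}

// [[Rcpp::export]]
List lif_run_cpp(int n_neurons,
                 NumericVector spike_time, IntegerVector spike_channel,
                 IntegerVector syn_start, IntegerVector syn_target,
                 NumericVector syn_weight,
                 double t_end, double dt, int method, double abs_tol,
                 NumericVector pars, double i_offset,
                 IntegerVector trace_neurons) {
  Pars p;
  p.v_rest = pars[0]; p.v_th = pars[1]; p.v_reset = pars[2];
  p.tau_ref = pars[3]; p.g_leak = pars[4]; p.c_m = pars[5];
  p.e_exc = pars[6]; p.tau_exc = pars[7];

  const int n_steps = (int)std::ceil(t_end / dt - 1e-9);
  const int refr_steps = (int)std::ceil(p.tau_ref / dt - 1e-9);
  const double v_eq = p.v_rest + 1000.0 * i_offset / p.g_leak;

  // order input spikes by delivery grid step
  const int n_sp = spike_time.size();
  std::vector<int> order(n_sp), step_of(n_sp);
  for (int i = 0; i < n_sp; ++i) {
    order[i] = i;
    int s = (int)std::ceil(spike_time[i] / dt - 1e-9);
    step_of[i] = s < 0 ? 0 : s;
  }
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return step_of[a] < step_of[b]; });

  std::vector<double> v(n_neurons, p.v_rest), g(n_neurons, 0.0);
  std::vector<double> vmax(n_neurons, p.v_rest);
  std::vector<int> refr_until(n_neurons, -1);  // last clamped grid step
  std::vector<std::vector<double>> spikes(n_neurons);

  const int n_tr = trace_neurons.size();
  NumericMatrix trace(n_tr > 0 ? n_steps + 1 : 0, n_tr);

  int ptr = 0;
  for (int k = 0; k <= n_steps; ++k) {
    const double now = k * dt;
    // deliver input spikes scheduled for this grid point
    while (ptr < n_sp && step_of[order[ptr]] == k) {
      int ch = spike_channel[order[ptr]];
      for (int s = syn_start[ch]; s < syn_start[ch + 1]; ++s)
        g[syn_target[s]] += syn_weight[s];
      ++ptr;
    }
    // synchronous threshold handling
    for (int i = 0; i < n_neurons; ++i) {
      if (k <= refr_until[i]) {
        v[i] = p.v_reset;
      } else if (v[i] >= p.v_th) {
        spikes[i].push_back(now);
        v[i] = p.v_reset;
        refr_until[i] = k + refr_steps;
      }
    }
    for (int j = 0; j < n_tr; ++j) trace(k, j) = v[trace_neurons[j]];
    if (k == n_steps) break;
    // advance the interval [k*dt, (k+1)*dt)
    for (int i = 0; i < n_neurons; ++i) {
      if (g[i] < 1e-12) g[i] = 0.0;
      bool clamped = (k + 1) <= refr_until[i];
      if (!clamped && g[i] == 0.0 && std::fabs(v[i] - v_eq) < 1e-9) {
        v[i] = v_eq;  // exact fixed point: nothing to integrate
        continue;
      }
      if (method == 0) {  // naive explicit Euler, one step per grid interval
        double vn = v[i] + dt * f_v(p, v[i], g[i], i_offset);
        double gn = g[i] + dt * f_g(p, g[i]);
        if (!std::isfinite(vn) || !std::isfinite(gn))
          stop("integration diverged (euler, step size %f ms)", dt);
        if (!clamped) v[i] = vn;
        g[i] = gn < 0 ? 0.0 : gn;
        if (v[i] > vmax[i]) vmax[i] = v[i];
      } else {
        if (clamped) {
          g[i] *= std::exp(-dt / p.tau_exc);
        } else {
          rkf45_interval(p, i_offset, dt, abs_tol, v[i], g[i], vmax[i]);
        }
      }
    }
  }

  List sp(n_neurons);
  for (int i = 0; i < n_neurons; ++i) sp[i] = NumericVector(spikes[i].begin(), spikes[i].end());
  return List::create(_["spikes"] = sp,
                      _["trace"] = trace,
                      _["vmax"] = NumericVector(vmax.begin(), vmax.end()),
                      _["n_steps"] = n_steps);
}
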