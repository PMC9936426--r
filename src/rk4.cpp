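// Fixed-step integrator core.
//
// The R side enumerates one sparse effective topology per switch-rule flag
// combination (bitmask); the C++ loop re-evaluates the mask once per step
// from the step-start state, holds it across the four Runge-Kutta
// sub-stages, keeps clamped nodes bit-identical, and tracks convergence
// (largest |dx/dt| among free nodes below tol, sustained) plus a trailing
// window used for oscillation averaging.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Topo {
  std::vector<int> a_src, a_tgt, i_src, i_tgt;
  std::vector<double> a_w, i_w, suma, sumi;
};

inline void deriv(const Topo& tp, const std::vector<double>& x,
                  const std::vector<double>& h, const std::vector<double>& E,
                  const std::vector<double>& gamma,
                  const std::vector<int>& clamp_idx,
                  std::vector<double>& sax, std::vector<double>& six,
                  std::vector<double>& dx) {
  const int n = (int)x.size();
  std::fill(sax.begin(), sax.end(), 0.0);
  std::fill(six.begin(), six.end(), 0.0);
  for (size_t k = 0; k < tp.a_src.size(); ++k)
    sax[tp.a_tgt[k]] += tp.a_w[k] * x[tp.a_src[k]];
  for (size_t k = 0; k < tp.i_src.size(); ++k)
    six[tp.i_tgt[k]] += tp.i_w[k] * x[tp.i_src[k]];
  for (int j = 0; j < n; ++j) {
    double om;
    const bool has_a = tp.suma[j] > 0.0, has_i = tp.sumi[j] > 0.0;
    if (!has_a && !has_i) {
      om = 0.0;
    } else {
      double act = 1.0, inh = 1.0;
      if (has_a)
        act = (1.0 + tp.suma[j]) / tp.suma[j] * sax[j] / (1.0 + sax[j]);
      if (has_i)
        inh = 1.0 - (1.0 + tp.sumi[j]) / tp.sumi[j] * six[j] / (1.0 + six[j]);
      om = act * inh;
      if (om < 0.0) om = 0.0;
      if (om > 1.0) om = 1.0;
    }
    const double tt = std::exp(-h[j] * (om - 0.5));
    double s;
    if (std::isfinite(tt)) s = (tt - E[j]) / ((1.0 - E[j]) * (1.0 + tt));
    else s = 1.0 / (1.0 - E[j]);
    dx[j] = s - gamma[j] * x[j];
  }
  for (size_t k = 0; k < clamp_idx.size(); ++k) dx[clamp_idx[k]] = 0.0;
}

} // namespace

// [[Rcpp::export(name = ".rk4_core")]]
List rk4_core(List topos, NumericVector h_, NumericVector gamma_,
              IntegerVector clamp_idx_, NumericVector clamp_vals_,
              IntegerVector watch_idx_, NumericVector thresholds_,
              NumericVector x0, double dt, int n_steps, int sustain_needed,
              double tol, bool euler, bool record, int stride,
              double win_start_t, double osc_tol) {
  const int n = x0.size();
  const int n_rules = watch_idx_.size();

  std::vector<Topo> tps(topos.size());
  for (int t = 0; t < topos.size(); ++t) {
    List tl = topos[t];
    IntegerVector as = tl["a_src"], at = tl["a_tgt"], is = tl["i_src"],
                  it = tl["i_tgt"];
    NumericVector aw = tl["a_w"], iw = tl["i_w"], sa = tl["suma"],
                  si = tl["sumi"];
    tps[t].a_src.assign(as.begin(), as.end());
    tps[t].a_tgt.assign(at.begin(), at.end());
    tps[t].a_w.assign(aw.begin(), aw.end());
    tps[t].i_src.assign(is.begin(), is.end());
    tps[t].i_tgt.assign(it.begin(), it.end());
    tps[t].i_w.assign(iw.begin(), iw.end());
    tps[t].suma.assign(sa.begin(), sa.end());
    tps[t].sumi.assign(si.begin(), si.end());
  }

  std::vector<double> h(h_.begin(), h_.end()), gamma(gamma_.begin(), gamma_.end());
  std::vector<double> E(n);
  for (int j = 0; j < n; ++j) E[j] = std::exp(0.5 * h[j]);
  std::vector<int> clamp_idx(clamp_idx_.begin(), clamp_idx_.end());
  std::vector<double> clamp_vals(clamp_vals_.begin(), clamp_vals_.end());
  std::vector<int> watch_idx(watch_idx_.begin(), watch_idx_.end());
  std::vector<double> thresholds(thresholds_.begin(), thresholds_.end());

  std::vector<double> x(x0.begin(), x0.end());
  for (size_t k = 0; k < clamp_idx.size(); ++k) x[clamp_idx[k]] = clamp_vals[k];

  std::vector<double> sax(n), six(n), k1(n), k2(n), k3(n), k4(n), xs(n);
  std::vector<double> wsum(n, 0.0), wmin(n, R_PosInf), wmax(n, R_NegInf);
  int wn = 0;

  NumericMatrix states;
  NumericVector times;
  int rec = 0;
  if (record) {
    const int n_rec = n_steps / stride + 1;
    states = NumericMatrix(n_rec, n);
    times = NumericVector(n_rec);
    for (int j = 0; j < n; ++j) states(0, j) = x[j];
    times[0] = 0.0;
    rec = 1;
  }

  bool converged = false, violation = false;
  int sustain = 0, step = 0, mask = 0;
  double t = 0.0;

  for (step = 1; step <= n_steps; ++step) {
    mask = 0;
    for (int r = 0; r < n_rules; ++r)
      if (x[watch_idx[r]] > thresholds[r]) mask |= (1 << r);
    const Topo& tp = tps[mask];

    deriv(tp, x, h, E, gamma, clamp_idx, sax, six, k1);
    if (!euler) {
      for (int j = 0; j < n; ++j) xs[j] = x[j] + 0.5 * dt * k1[j];
      deriv(tp, xs, h, E, gamma, clamp_idx, sax, six, k2);
      for (int j = 0; j < n; ++j) xs[j] = x[j] + 0.5 * dt * k2[j];
      deriv(tp, xs, h, E, gamma, clamp_idx, sax, six, k3);
      for (int j = 0; j < n; ++j) xs[j] = x[j] + dt * k3[j];
      deriv(tp, xs, h, E, gamma, clamp_idx, sax, six, k4);
      for (int j = 0; j < n; ++j)
        x[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    } else {
      for (int j = 0; j < n; ++j) x[j] += dt * k1[j];
    }
    for (size_t k = 0; k < clamp_idx.size(); ++k)
      x[clamp_idx[k]] = clamp_vals[k];

    double lo = 0.0, hi = 0.0;
    for (int j = 0; j < n; ++j) {
      if (!std::isfinite(x[j]))
        stop("non-finite state at step %d", step);
      if (x[j] < lo) lo = x[j];
      if (x[j] - 1.0 > hi) hi = x[j] - 1.0;
    }
    if (lo < -1e-12 || hi > 1e-12) { violation = true; break; }
    for (int j = 0; j < n; ++j) {
      if (x[j] < 0.0) x[j] = 0.0;
      if (x[j] > 1.0) x[j] = 1.0;
    }
    t = step * dt;

    if (record && step % stride == 0) {
      for (int j = 0; j < n; ++j) states(rec, j) = x[j];
      times[rec] = t;
      ++rec;
    }
    if (t >= win_start_t) {
      ++wn;
      for (int j = 0; j < n; ++j) {
        wsum[j] += x[j];
        if (x[j] < wmin[j]) wmin[j] = x[j];
        if (x[j] > wmax[j]) wmax[j] = x[j];
      }
    }

    double res = 0.0;
    for (int j = 0; j < n; ++j) {
      const double a = std::fabs(k1[j]);
      if (a > res) res = a;  // clamped entries are exactly 0
    }
    if (res < tol) {
      if (++sustain >= sustain_needed) { converged = true; break; }
    } else {
      sustain = 0;
    }
  }

  bool oscillating = false;
  NumericVector final_x(n);
  for (int j = 0; j < n; ++j) final_x[j] = x[j];
  if (!converged && !violation && wn > 0) {
    double amp = 0.0;
    for (int j = 0; j < n; ++j)
      if (wmax[j] - wmin[j] > amp) amp = wmax[j] - wmin[j];
    if (amp > osc_tol) {
      oscillating = true;
      for (int j = 0; j < n; ++j) final_x[j] = wsum[j] / wn;
      for (size_t k = 0; k < clamp_idx.size(); ++k)
        final_x[clamp_idx[k]] = clamp_vals[k];
    }
  }

  List out = List::create(
      _["x"] = final_x, _["converged"] = converged,
      _["oscillating"] = oscillating, _["violation"] = violation,
      _["t_end"] = t, _["mask"] = mask);
  if (record) {
    out["times"] = times;
    out["states"] = states;
    out["rec"] = rec;
  }
  return out;
}
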