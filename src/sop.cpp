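#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Coupled SOP node/link dynamics advanced by classic fixed-step RK4.
//
// State per node: (I, A1, A2); per link: (V+, V-).  Rates are expressed per
// internal time unit tau (one integration step), so the RK4 step size is 1.
// Stimulus on/off flags are held constant within a step.

namespace {

struct Deriv {
  std::vector<double> dI, dA1, dA2, dVp, dVm;
  Deriv(int n_nodes, int n_links)
    : dI(n_nodes), dA1(n_nodes), dA2(n_nodes),
      dVp(n_links), dVm(n_links) {}
};

struct State {
  std::vector<double> I, A1, A2, Vp, Vm;
  State(int n_nodes, int n_links)
    : I(n_nodes, 1.0), A1(n_nodes, 0.0), A2(n_nodes, 0.0),
      Vp(n_links, 0.0), Vm(n_links, 0.0) {}
};

// dy/dt for the full bundle at a fixed activity pattern.
inline void derivs(const State& y, const int* act_step,
                   const double* p1, const double* pd1, const double* pd2,
                   const int* isobj,
                   const int* lsrc, const int* ltgt, int n_links,
                   double lp, double lm, int n_nodes, Deriv& d) {
  // associative promotion probability p2 per object node
  std::vector<double> p2(n_nodes, 0.0);
  for (int l = 0; l < n_links; ++l) {
    p2[ltgt[l]] += y.A1[lsrc[l]] * (y.Vp[l] - y.Vm[l]);
  }
  for (int i = 0; i < n_nodes; ++i) {
    double p2i = isobj[i] ? std::min(1.0, std::max(0.0, p2[i])) : 0.0;
    double p1i = act_step[i] ? p1[i] : 0.0;
    d.dI[i]  = pd2[i] * y.A2[i] - (p1i + p2i) * y.I[i];
    d.dA1[i] = p1i * y.I[i] - pd1[i] * y.A1[i];
    d.dA2[i] = pd1[i] * y.A1[i] + p2i * y.I[i] - pd2[i] * y.A2[i];
  }
  for (int l = 0; l < n_links; ++l) {
    d.dVp[l] = lp * y.A1[lsrc[l]] * y.A1[ltgt[l]];
    d.dVm[l] = lm * y.A1[lsrc[l]] * y.A2[ltgt[l]];
  }
}

inline void axpy(State& out, const State& y, const Deriv& d, double h,
                 int n_nodes, int n_links) {
  for (int i = 0; i < n_nodes; ++i) {
    out.I[i]  = y.I[i]  + h * d.dI[i];
    out.A1[i] = y.A1[i] + h * d.dA1[i];
    out.A2[i] = y.A2[i] + h * d.dA2[i];
  }
  for (int l = 0; l < n_links; ++l) {
    out.Vp[l] = y.Vp[l] + h * d.dVp[l];
    out.Vm[l] = y.Vm[l] + h * d.dVm[l];
  }
}

// One RK4 step (h = 1 tau) with constant activity; returns conservation
// violations detected beyond 1e-9 (clamping doubles as an error detector).
inline long rk4_advance(State& y, const int* act_step,
                        const double* p1, const double* pd1, const double* pd2,
                        const int* isobj, const int* lsrc, const int* ltgt,
                        int n_links, double lp, double lm, int n_nodes,
                        Deriv& k1, Deriv& k2, Deriv& k3, Deriv& k4,
                        State& tmp, int step_index) {
  derivs(y, act_step, p1, pd1, pd2, isobj, lsrc, ltgt, n_links, lp, lm, n_nodes, k1);
  axpy(tmp, y, k1, 0.5, n_nodes, n_links);
  derivs(tmp, act_step, p1, pd1, pd2, isobj, lsrc, ltgt, n_links, lp, lm, n_nodes, k2);
  axpy(tmp, y, k2, 0.5, n_nodes, n_links);
  derivs(tmp, act_step, p1, pd1, pd2, isobj, lsrc, ltgt, n_links, lp, lm, n_nodes, k3);
  axpy(tmp, y, k3, 1.0, n_nodes, n_links);
  derivs(tmp, act_step, p1, pd1, pd2, isobj, lsrc, ltgt, n_links, lp, lm, n_nodes, k4);

  long clamped = 0;
  for (int i = 0; i < n_nodes; ++i) {
    y.I[i]  += (k1.dI[i]  + 2 * k2.dI[i]  + 2 * k3.dI[i]  + k4.dI[i])  / 6.0;
    y.A1[i] += (k1.dA1[i] + 2 * k2.dA1[i] + 2 * k3.dA1[i] + k4.dA1[i]) / 6.0;
    y.A2[i] += (k1.dA2[i] + 2 * k2.dA2[i] + 2 * k3.dA2[i] + k4.dA2[i]) / 6.0;
    if (!std::isfinite(y.I[i]) || !std::isfinite(y.A1[i]) || !std::isfinite(y.A2[i]))
      stop("non-finite state for node index %d at step %d", i + 1, step_index + 1);
    double drift = std::fabs(y.I[i] + y.A1[i] + y.A2[i] - 1.0);
    if (drift > 1e-9 || y.I[i] < -1e-9 || y.A1[i] < -1e-9 || y.A2[i] < -1e-9 ||
        y.I[i] > 1 + 1e-9 || y.A1[i] > 1 + 1e-9 || y.A2[i] > 1 + 1e-9) {
      ++clamped;
      y.I[i]  = std::min(1.0, std::max(0.0, y.I[i]));
      y.A1[i] = std::min(1.0, std::max(0.0, y.A1[i]));
      y.A2[i] = std::min(1.0, std::max(0.0, y.A2[i]));
      double tot = y.I[i] + y.A1[i] + y.A2[i];
      if (tot > 0) { y.I[i] /= tot; y.A1[i] /= tot; y.A2[i] /= tot; }
    }
  }
  for (int l = 0; l < n_links; ++l) {
    y.Vp[l] += (k1.dVp[l] + 2 * k2.dVp[l] + 2 * k3.dVp[l] + k4.dVp[l]) / 6.0;
    y.Vm[l] += (k1.dVm[l] + 2 * k2.dVm[l] + 2 * k3.dVm[l] + k4.dVm[l]) / 6.0;
    if (!std::isfinite(y.Vp[l]) || !std::isfinite(y.Vm[l]))
      stop("non-finite accumulator for link index %d at step %d", l + 1, step_index + 1);
  }
  return clamped;
}

} // namespace

// [[Rcpp::export]]
List cpp_simulate(IntegerMatrix activity, NumericVector p1, NumericVector pd1,
                  NumericVector pd2, IntegerVector is_object,
                  IntegerMatrix links, double l_plus, double l_minus,
                  IntegerVector test_obj, IntegerVector test_start,
                  IntegerVector test_end, bool record) {
  const int n_steps = activity.nrow();
  const int n_nodes = activity.ncol();
  const int n_links = links.nrow();
  const int n_test  = test_obj.size();

  std::vector<int> lsrc(n_links), ltgt(n_links);
  for (int l = 0; l < n_links; ++l) { lsrc[l] = links(l, 0); ltgt[l] = links(l, 1); }

  State y(n_nodes, n_links), tmp(n_nodes, n_links);
  Deriv k1(n_nodes, n_links), k2(n_nodes, n_links),
        k3(n_nodes, n_links), k4(n_nodes, n_links);

  NumericVector node_traj, link_traj;
  if (record) {
    node_traj = NumericVector(Dimension(n_steps + 1, n_nodes, 3));
    link_traj = NumericVector(Dimension(n_steps + 1, std::max(n_links, 1), 2));
  }
  NumericVector peaks(n_test, 0.0);

  const int stride = n_steps + 1;
  auto store = [&](int g) {
    if (record) {
      for (int i = 0; i < n_nodes; ++i) {
        node_traj[g + stride * i]                       = y.I[i];
        node_traj[g + stride * (i + n_nodes)]           = y.A1[i];
        node_traj[g + stride * (i + 2 * n_nodes)]       = y.A2[i];
      }
      int nl = std::max(n_links, 1);
      for (int l = 0; l < n_links; ++l) {
        link_traj[g + stride * l]        = y.Vp[l];
        link_traj[g + stride * (l + nl)] = y.Vm[l];
      }
    }
    for (int j = 0; j < n_test; ++j)
      if (g >= test_start[j] && g <= test_end[j] && y.A1[test_obj[j]] > peaks[j])
        peaks[j] = y.A1[test_obj[j]];
  };

  long n_clamped = 0;
  std::vector<int> act(n_nodes);
  store(0);
  for (int s = 0; s < n_steps; ++s) {
    for (int i = 0; i < n_nodes; ++i) act[i] = activity(s, i);
    n_clamped += rk4_advance(y, act.data(), &p1[0], &pd1[0], &pd2[0],
                             &is_object[0], lsrc.data(), ltgt.data(), n_links,
                             l_plus, l_minus, n_nodes, k1, k2, k3, k4, tmp, s);
    store(s + 1);
  }

  List out = List::create(
    _["peaks"] = peaks,
    _["final_I"] = wrap(y.I), _["final_A1"] = wrap(y.A1), _["final_A2"] = wrap(y.A2),
    _["final_Vp"] = wrap(y.Vp), _["final_Vm"] = wrap(y.Vm),
    _["n_clamped"] = (double) n_clamped);
  if (record) { out["node_traj"] = node_traj; out["link_traj"] = link_traj; }
  return out;
}

// Batch version: one schedule, many parameter points.  Each row of `theta`
// gives (pd1, pd2, L+, L-) applied uniformly to all nodes; p1 stays per node.
// Returns a matrix of peak A1 values (points x test windows).
// [[Rcpp::export]]
NumericMatrix cpp_peak_batch(IntegerMatrix activity, NumericVector p1,
                             IntegerVector is_object, IntegerMatrix links,
                             NumericMatrix theta,
                             IntegerVector test_obj, IntegerVector test_start,
                             IntegerVector test_end) {
  const int n_steps = activity.nrow();
  const int n_nodes = activity.ncol();
  const int n_links = links.nrow();
  const int n_test  = test_obj.size();
  const int n_pts   = theta.nrow();

  std::vector<int> lsrc(n_links), ltgt(n_links);
  for (int l = 0; l < n_links; ++l) { lsrc[l] = links(l, 0); ltgt[l] = links(l, 1); }

  // column-major copy of the activity matrix for fast row access
  std::vector<int> act(n_steps * n_nodes);
  for (int i = 0; i < n_nodes; ++i)
    for (int s = 0; s < n_steps; ++s) act[s * n_nodes + i] = activity(s, i);

  NumericMatrix peaks(n_pts, n_test);
  State y(n_nodes, n_links), tmp(n_nodes, n_links);
  Deriv k1(n_nodes, n_links), k2(n_nodes, n_links),
        k3(n_nodes, n_links), k4(n_nodes, n_links);
  std::vector<double> pd1(n_nodes), pd2(n_nodes);

  for (int p = 0; p < n_pts; ++p) {
    std::fill(pd1.begin(), pd1.end(), theta(p, 0));
    std::fill(pd2.begin(), pd2.end(), theta(p, 1));
    const double lp = theta(p, 2), lm = theta(p, 3);
    std::fill(y.I.begin(),  y.I.end(),  1.0);
    std::fill(y.A1.begin(), y.A1.end(), 0.0);
    std::fill(y.A2.begin(), y.A2.end(), 0.0);
    std::fill(y.Vp.begin(), y.Vp.end(), 0.0);
    std::fill(y.Vm.begin(), y.Vm.end(), 0.0);
    for (int j = 0; j < n_test; ++j) peaks(p, j) = 0.0;

    for (int s = 0; s < n_steps; ++s) {
      rk4_advance(y, act.data() + (size_t) s * n_nodes, &p1[0], pd1.data(),
                  pd2.data(), &is_object[0], lsrc.data(), ltgt.data(), n_links,
                  lp, lm, n_nodes, k1, k2, k3, k4, tmp, s);
      const int g = s + 1;
      for (int j = 0; j < n_test; ++j)
        if (g >= test_start[j] && g <= test_end[j] &&
            y.A1[test_obj[j]] > peaks(p, j))
          peaks(p, j) = y.A1[test_obj[j]];
    }
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return peaks;
}
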