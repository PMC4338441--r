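#include <Rcpp.h>
using namespace Rcpp;

// Elastically coupled motor-team simulator.
//
// N heterodimers share a massless tail node; every dimer is attached to the
// node by an equal spring (star topology), so force balance on the node puts
// it at the mean of the bound head positions. Positions are in nm, forces in
// pN, times in s. Positive displacement is toward the microtubule minus end.

namespace {

// linear force-velocity: full speed unloaded, zero at stall, clamped so
// assisting force never speeds a motor past its intrinsic velocity
inline double fv(double f_spring, double nu, double f_stall,
                 bool force_dependent) {
  if (!force_dependent) return nu;
  double load = f_spring < 0.0 ? -f_spring : 0.0;  // opposing component only
  double v = nu * (1.0 - load / f_stall);
  if (v < 0.0) v = 0.0;
  if (v > nu) v = nu;
  return v;
}

// capped Bell-type detachment: k_off0 * exp(|f|/F_detach), saturating at
// k_off_max
inline double koff(double fmag, double k_off0, double k_off_max,
                   double f_detach, bool force_dependent) {
  if (!force_dependent) return k_off0;
  double k = k_off0 * std::exp(fmag / f_detach);
  return k > k_off_max ? k_off_max : k;
}

struct RunResult {
  double run_length, run_time, velocity;
  bool censored;
};

// One run of the fixed-step Euler/Bernoulli scheme. Records (optionally)
// the node trajectory and bound count at `stride` steps, and per-dimer
// bound/position states when `keep_states` is set (for invariant tests).
RunResult one_run(int n, double v_mean, double v_sd, double f_stall,
                  double k_on, double k_off0, double k_off_max,
                  double k_stiff, double f_detach, double dt,
                  bool force_dependent, bool all_bound, double max_time,
                  int stride, bool keep_traj, bool keep_states,
                  std::vector<double> *t_out, std::vector<double> *x_out,
                  std::vector<int> *nb_out,
                  std::vector<double> *state_x, std::vector<int> *state_b) {
  std::vector<double> x(n, 0.0), nu(n);
  std::vector<int> bound(n, 0);
  for (int i = 0; i < n; ++i) {
    double v;
    do {
      v = R::rnorm(v_mean, v_sd);
    } while (v < 0.0);  // truncated at zero, fixed for the whole run
    nu[i] = v;
  }
  if (all_bound) {
    for (int i = 0; i < n; ++i) bound[i] = 1;
  } else {
    bound[0] = 1;  // complexes land with one engaged head, spring relaxed
  }

  double t = 0.0, x_node = 0.0;
  long step = 0;
  bool censored = false;
  // accumulators for the least-squares slope of x_node vs t
  double s_t = 0, s_x = 0, s_tt = 0, s_tx = 0;
  long n_pts = 0;

  auto record = [&](void) {
    s_t += t; s_x += x_node; s_tt += t * t; s_tx += t * x_node; ++n_pts;
    if (keep_traj) {
      t_out->push_back(t);
      x_out->push_back(x_node);
      int nb = 0;
      for (int i = 0; i < n; ++i) nb += bound[i];
      nb_out->push_back(nb);
    }
    if (keep_states) {
      for (int i = 0; i < n; ++i) {
        state_x->push_back(x[i]);
        state_b->push_back(bound[i]);
      }
    }
  };
  record();

  std::vector<double> f(n, 0.0);
  while (true) {
    // node position = mean of bound heads (equal-spring force balance)
    double sum = 0.0;
    int nb = 0;
    for (int i = 0; i < n; ++i)
      if (bound[i]) { sum += x[i]; ++nb; }
    x_node = sum / nb;
    // spring forces and position advance
    double sum_adv = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!bound[i]) continue;
      f[i] = k_stiff * (x_node - x[i]);
      x[i] += fv(f[i], nu[i], f_stall, force_dependent) * dt;
      sum_adv += x[i];
    }
    // node tracks the advanced heads; if every dimer detaches this step,
    // this is the recorded end position of the run
    x_node = sum_adv / nb;
    // unbinding draws
    for (int i = 0; i < n; ++i) {
      if (!bound[i]) continue;
      double fmag = f[i] < 0 ? -f[i] : f[i];
      double p = koff(fmag, k_off0, k_off_max, f_detach, force_dependent) * dt;
      if (R::unif_rand() < p) bound[i] = 0;
    }
    int nb2 = 0;
    double sum2 = 0.0;
    for (int i = 0; i < n; ++i)
      if (bound[i]) { sum2 += x[i]; ++nb2; }
    t += dt;
    ++step;
    if (nb2 == 0) {  // full detachment ends the run
      record();
      break;
    }
    x_node = sum2 / nb2;
    // rebinding at the node, spring relaxed
    double p_on = k_on * dt;
    if (p_on > 0) {
      for (int i = 0; i < n; ++i) {
        if (!bound[i] && R::unif_rand() < p_on) {
          bound[i] = 1;
          x[i] = x_node;
        }
      }
    }
    if (step % stride == 0) record();
    if (t >= max_time) {
      censored = true;
      if (step % stride != 0) record();
      break;
    }
  }

  RunResult r;
  r.run_time = t;
  r.run_length = x_node;  // started at 0
  double denom = n_pts * s_tt - s_t * s_t;
  r.velocity = denom > 0 ? (n_pts * s_tx - s_t * s_x) / denom : 0.0;
  r.censored = censored;
  return r;
}

}  // namespace

// [[Rcpp::export]]
List simulate_run_cpp(int n_dimers, double v_mean, double v_sd,
                      double f_stall, double k_on, double k_off0,
                      double k_off_max, double k_stiff, double f_detach,
                      double dt, bool force_dependent, bool all_bound,
                      double max_time, int record_stride, bool keep_states) {
  std::vector<double> t, x, sx;
  std::vector<int> nb, sb;
  RunResult r = one_run(n_dimers, v_mean, v_sd, f_stall, k_on, k_off0,
                        k_off_max, k_stiff, f_detach, dt, force_dependent,
                        all_bound, max_time, record_stride, true, keep_states,
                        &t, &x, &nb, &sx, &sb);
  List out = List::create(
      _["time_s"] = wrap(t), _["x_node_nm"] = wrap(x),
      _["n_bound"] = wrap(nb), _["run_length_nm"] = r.run_length,
      _["run_time_s"] = r.run_time, _["velocity_nm_s"] = r.velocity,
      _["censored"] = r.censored);
  if (keep_states) {
    out["state_x"] = wrap(sx);
    out["state_bound"] = wrap(sb);
  }
  return out;
}

// [[Rcpp::export]]
DataFrame simulate_runs_cpp(int n_runs, int n_dimers, double v_mean,
                            double v_sd, double f_stall, double k_on,
                            double k_off0, double k_off_max, double k_stiff,
                            double f_detach, double dt, bool force_dependent,
                            bool all_bound, double max_time) {
  NumericVector rl(n_runs), rt(n_runs), v(n_runs);
  LogicalVector cen(n_runs);
  for (int i = 0; i < n_runs; ++i) {
    RunResult r = one_run(n_dimers, v_mean, v_sd, f_stall, k_on, k_off0,
                          k_off_max, k_stiff, f_detach, dt, force_dependent,
                          all_bound, max_time, 1000000000, false, false,
                          nullptr, nullptr, nullptr, nullptr, nullptr);
    rl[i] = r.run_length;
    rt[i] = r.run_time;
    v[i] = r.velocity;
    cen[i] = r.censored;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["run_length_nm"] = rl, _["run_time_s"] = rt,
                           _["velocity_nm_s"] = v, _["censored"] = cen);
}
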