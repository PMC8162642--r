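#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double ramp_pos(double x, double a, double b) {
  if (b > a) {
    double s = (x - a) / (b - a);
    return s <= 0.0 ? 0.0 : (s >= 1.0 ? 1.0 : s);
  }
  return x >= a ? 1.0 : 0.0;
}

// Continuous-time (Gillespie) simulation of RNAP molecules stepping along a
// 1D lattice of `lattice` bases with hard-core exclusion over a `footprint`.
// Loading places a molecule at base 1 when the first `footprint` sites are
// clear; each molecule carries its own exponential stepping rate (bases/min)
// drawn from a Gamma distribution with mean `mean_rate` and CV `rate_cv`.
// Blocked attempts advance time but not state (exact thinning of the
// exponential clocks).  Molecules stepping off base `lattice` terminate and
// their signal is removed instantly.  Uses R's RNG, so results are
// reproducible under set.seed().
// After stepping off the gene end a molecule's finished transcript remains
// tethered (full signal in both channels) for the deterministic cleavage
// wait `tau_cleave` minutes, then disappears instantly.
// [[Rcpp::export]]
List tasep_gillespie(int lattice, int footprint, double init_rate,
                     double mean_rate, double rate_cv, double duration,
                     double tau_cleave, NumericVector sample_times,
                     double ms2_a, double ms2_b, double pp7_a, double pp7_b,
                     double alpha) {
  if (footprint > lattice) stop("footprint exceeds lattice length");
  if (footprint < 1) stop("footprint must be >= 1");
  std::vector<double> pos, rate, t_load, t_exit, velocity;
  std::vector<int> exited;
  size_t first_active = 0;            // molecules ahead have lower index
  double t = 0.0, min_gap = R_PosInf;
  const double shape = (rate_cv > 0.0) ? 1.0 / (rate_cv * rate_cv) : 0.0;
  const int n_snap = sample_times.size();
  int si = 0;
  NumericVector snap_ms2(n_snap), snap_pp7(n_snap), snap_n(n_snap);
  std::vector<double> traj_t, traj_pos;
  std::vector<int> traj_id;

  auto take_snapshots_until = [&](double t_next) {
    while (si < n_snap && sample_times[si] < t_next) {
      const double ts = sample_times[si];
      double sm = 0.0, sp = 0.0;
      int n_on = 0;
      for (size_t i = first_active; i < pos.size(); ++i) {
        sm += ramp_pos(pos[i], ms2_a, ms2_b);
        sp += ramp_pos(pos[i], pp7_a, pp7_b);
        ++n_on;
        traj_t.push_back(ts);
        traj_id.push_back((int)i + 1);
        traj_pos.push_back(pos[i]);
      }
      // finished transcripts awaiting cleavage: full signal in both channels
      for (size_t i = 0; i < first_active; ++i) {
        if (t_exit[i] <= ts && ts < t_exit[i] + tau_cleave) {
          sm += 1.0;
          sp += 1.0;
          ++n_on;
        }
      }
      snap_ms2[si] = alpha * sm;
      snap_pp7[si] = sp;
      snap_n[si] = n_on;
      ++si;
    }
  };

  while (t < duration) {
    double total = init_rate;
    for (size_t i = first_active; i < pos.size(); ++i) total += rate[i];
    if (total <= 0.0) break;
    double t_next = t + R::rexp(1.0 / total);
    take_snapshots_until(std::min(t_next, duration));
    t = t_next;
    if (t >= duration) break;
    double u = R::runif(0.0, total);
    if (u < init_rate) {
      // loading attempt: needs the first `footprint` sites clear
      bool clear = pos.empty() || first_active == pos.size() ||
                   pos.back() - 1.0 >= (double)footprint;
      if (clear) {
        pos.push_back(1.0);
        rate.push_back(rate_cv > 0.0
                           ? R::rgamma(shape, mean_rate / shape)
                           : mean_rate);
        t_load.push_back(t);
        t_exit.push_back(NA_REAL);
        velocity.push_back(NA_REAL);
        exited.push_back(0);
        if (!pos.empty() && pos.size() >= 2) {
          size_t i = pos.size() - 1;
          if (i > first_active) {
            double gap = pos[i - 1] - pos[i];
            if (gap < min_gap) min_gap = gap;
          }
        }
      }
    } else {
      // stepping attempt
      double acc = init_rate;
      size_t i = first_active;
      for (; i < pos.size(); ++i) {
        acc += rate[i];
        if (u < acc) break;
      }
      if (i < pos.size()) {
        bool front = (i == first_active);
        if (front) {
          pos[i] += 1.0;
          if (pos[i] > (double)lattice) {   // stepped off the end: terminate
            t_exit[i] = t;
            velocity[i] = (double)lattice / (t - t_load[i]);
            exited[i] = 1;
            ++first_active;
          }
        } else if (pos[i - 1] - (pos[i] + 1.0) >= (double)footprint) {
          pos[i] += 1.0;
          double gap = pos[i - 1] - pos[i];
          if (gap < min_gap) min_gap = gap;
        }
      }
    }
  }
  take_snapshots_until(R_PosInf);

  return List::create(
      _["ms2"] = snap_ms2, _["pp7"] = snap_pp7, _["n_on_gene"] = snap_n,
      _["load_time"] = wrap(t_load), _["exit_time"] = wrap(t_exit),
      _["velocity"] = wrap(velocity), _["step_rate"] = wrap(rate),
      _["exited"] = wrap(exited), _["min_gap"] = min_gap,
      _["traj_time"] = wrap(traj_t), _["traj_id"] = wrap(traj_id),
      _["traj_pos"] = wrap(traj_pos));
}
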