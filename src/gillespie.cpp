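// Continuous-time Gillespie simulation of asynchronous Boolean networks.
// Rules arrive as postfix bytecode compiled in R: opcode k > 0 pushes the
// value of node k (1-based); -1 NOT, -2 AND, -3 OR, -4 literal 0, -5 literal 1.

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <random>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline bool eval_rule(const std::vector<int>& code,
                             const std::vector<uint8_t>& state) {
  bool stack[64];
  int top = -1;
  for (size_t k = 0; k < code.size(); ++k) {
    int op = code[k];
    if (op > 0) {
      stack[++top] = state[op - 1] != 0;
    } else if (op == -1) {
      stack[top] = !stack[top];
    } else if (op == -2) {
      stack[top - 1] = stack[top - 1] && stack[top];
      --top;
    } else if (op == -3) {
      stack[top - 1] = stack[top - 1] || stack[top];
      --top;
    } else if (op == -4) {
      stack[++top] = false;
    } else {  // -5
      stack[++top] = true;
    }
  }
  return stack[0];
}

// spread the occupancy of an interval [a, b) over the time-bin grid
static inline void add_occupancy(double a, double b, double bin_width,
                                 int n_bins, std::vector<double>& bin_frac) {
  if (b <= a) return;
  int j0 = (int)(a / bin_width);
  int j1 = (int)(b / bin_width);
  if (j0 >= n_bins) j0 = n_bins - 1;
  if (j1 >= n_bins) j1 = n_bins - 1;
  for (int j = j0; j <= j1; ++j) {
    double lo = j * bin_width, hi = lo + bin_width;
    double ov = std::min(b, hi) - std::max(a, lo);
    if (ov > 0) bin_frac[j] += ov / bin_width;
  }
}

// [[Rcpp::export(name = ".simulate_ensemble_cpp")]]
List simulate_ensemble_cpp(List rule_codes, NumericVector k_up,
                           NumericVector k_down, NumericVector istate,
                           int n_traj, double max_time, int n_bins, int seed,
                           bool record_states) {
  const int n = rule_codes.size();
  if (n > 62) stop("engine supports at most 62 nodes");
  std::vector<std::vector<int>> codes(n);
  for (int i = 0; i < n; ++i)
    codes[i] = as<std::vector<int>>(rule_codes[i]);

  const double bin_width = max_time / n_bins;
  // per-node per-bin running sums of trajectory occupancy (and squares, for SE)
  std::vector<double> occ_sum((size_t)n_bins * n, 0.0),
      occ_sumsq((size_t)n_bins * n, 0.0);
  // sparse per-bin model-state occupancy
  std::vector<std::map<uint64_t, double>> state_occ;
  if (record_states) state_occ.resize(n_bins);

  std::vector<uint8_t> state(n);
  std::vector<double> rates(n);
  std::vector<int> enabled(n);
  std::vector<double> traj_occ;          // per-trajectory bins x nodes buffer
  std::vector<double> bin_frac(n_bins);  // scratch for state occupancy

  for (int tr = 0; tr < n_traj; ++tr) {
    uint64_t s = splitmix64(((uint64_t)(uint32_t)seed << 32) ^ (uint64_t)tr);
    std::mt19937_64 rng(s);
    std::uniform_real_distribution<double> unif(0.0, 1.0);

    for (int i = 0; i < n; ++i) state[i] = unif(rng) < istate[i] ? 1 : 0;

    traj_occ.assign((size_t)n_bins * n, 0.0);
    double t = 0.0;
    while (t < max_time) {
      int n_en = 0;
      double total = 0.0;
      for (int i = 0; i < n; ++i) {
        bool target = eval_rule(codes[i], state);
        double r = 0.0;
        if (!state[i] && target) r = k_up[i];
        else if (state[i] && !target) r = k_down[i];
        if (r > 0) {
          enabled[n_en] = i;
          rates[n_en] = r;
          total += r;
          ++n_en;
        }
      }
      double t_next;
      if (n_en == 0) {
        t_next = max_time;  // absorbed: state constant to the horizon
      } else {
        double u = unif(rng);
        if (u <= 0.0) u = 1e-300;
        t_next = t - std::log(u) / total;
      }
      double t_stop = std::min(t_next, max_time);
      // occupancy of the current state over [t, t_stop)
      if (t_stop > t) {
        int j0 = (int)(t / bin_width), j1 = (int)(t_stop / bin_width);
        if (j0 >= n_bins) j0 = n_bins - 1;
        if (j1 >= n_bins) j1 = n_bins - 1;
        for (int j = j0; j <= j1; ++j) {
          double lo = j * bin_width, hi = lo + bin_width;
          double ov = std::min(t_stop, hi) - std::max(t, lo);
          if (ov <= 0) continue;
          double frac = ov / bin_width;
          for (int i = 0; i < n; ++i)
            if (state[i]) traj_occ[(size_t)j * n + i] += frac;
        }
        if (record_states) {
          uint64_t key = 0;
          for (int i = 0; i < n; ++i)
            if (state[i]) key |= (uint64_t)1 << i;
          std::fill(bin_frac.begin(), bin_frac.end(), 0.0);
          add_occupancy(t, t_stop, bin_width, n_bins, bin_frac);
          for (int j = 0; j < n_bins; ++j)
            if (bin_frac[j] > 0) state_occ[j][key] += bin_frac[j];
        }
      }
      if (n_en == 0 || t_next >= max_time) break;
      // pick the transition proportionally to its rate
      double r = unif(rng) * total, acc = 0.0;
      int pick = enabled[n_en - 1];
      for (int e = 0; e < n_en; ++e) {
        acc += rates[e];
        if (r <= acc) {
          pick = enabled[e];
          break;
        }
      }
      state[pick] ^= 1;
      t = t_next;
    }
    for (size_t k = 0; k < traj_occ.size(); ++k) {
      occ_sum[k] += traj_occ[k];
      occ_sumsq[k] += traj_occ[k] * traj_occ[k];
    }
  }

  NumericMatrix prob(n_bins, n), se(n_bins, n);
  for (int j = 0; j < n_bins; ++j) {
    for (int i = 0; i < n; ++i) {
      double m = occ_sum[(size_t)j * n + i] / n_traj;
      prob(j, i) = m;
      if (n_traj > 1) {
        double v = (occ_sumsq[(size_t)j * n + i] - (double)n_traj * m * m) /
                   (n_traj - 1);
        se(j, i) = v > 0 ? std::sqrt(v / n_traj) : 0.0;
      } else {
        se(j, i) = NA_REAL;
      }
    }
  }

  List out = List::create(_["prob"] = prob, _["se"] = se);
  if (record_states) {
    size_t total_entries = 0;
    for (int j = 0; j < n_bins; ++j) total_entries += state_occ[j].size();
    IntegerVector sb(total_entries);
    NumericVector skey(total_entries), sprob(total_entries);
    size_t k = 0;
    for (int j = 0; j < n_bins; ++j) {
      for (std::map<uint64_t, double>::const_iterator it = state_occ[j].begin();
           it != state_occ[j].end(); ++it, ++k) {
        sb[k] = j + 1;
        skey[k] = (double)it->first;  // exact for n <= 52
        sprob[k] = it->second / n_traj;
      }
    }
    out["state_bin"] = sb;
    out["state_key"] = skey;
    out["state_prob"] = sprob;
  }
  return out;
}
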