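#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Numerically stable logistic 1/(1+exp(-x)).
static inline double sigmoid(double x) {
  if (x >= 0.0) {
    return 1.0 / (1.0 + std::exp(-x));
  } else {
    double e = std::exp(x);
    return e / (1.0 + e);
  }
}

// Asynchronous Fermi-rule dynamics on a fixed graph.
//
// adj / adj_ptr: flattened 0-based adjacency lists in CSR layout
//   (neighbours of node i are adj[adj_ptr[i] .. adj_ptr[i+1]-1]).
// spin0: initial choices as spins (+1 = A, -1 = B).
// delta_o: per-node net preference for A (used when schedule is empty).
// schedule: per-sweep shared net preference; length 0 means "use delta_o",
//   length >= horizon means all nodes share schedule[t] during sweep t.
// subpop: 0-based subpopulation index per node (for recording).
// One sweep = n single-agent updates; recording happens at sweep
// granularity (initial state plus every record_every-th completed sweep
// plus the final sweep). quiet_sweeps > 0 enables early stopping after
// that many consecutive flip-free sweeps.
// [[Rcpp::export]]
List run_abm_cpp(IntegerVector adj, IntegerVector adj_ptr,
                 IntegerVector spin0, NumericVector delta_o,
                 NumericVector w, double beta,
                 NumericVector schedule, int horizon, int record_every,
                 int quiet_sweeps, IntegerVector subpop, int n_subpop) {
  const int n = spin0.size();
  const bool dynamic = schedule.size() > 0;
  if (dynamic && schedule.size() < horizon)
    stop("schedule shorter than horizon");

  std::vector<int> spin(spin0.begin(), spin0.end());
  std::vector<int> flips_node(n, 0);
  std::vector<int> sub_n(n_subpop, 0), sub_a(n_subpop, 0);
  int n_a = 0;
  for (int i = 0; i < n; ++i) {
    sub_n[subpop[i]] += 1;
    if (spin[i] > 0) { n_a += 1; sub_a[subpop[i]] += 1; }
  }
  // aligned-count bookkeeping for the static case (sign(delta_o) fixed)
  int n_signed = 0, n_aligned = 0;
  if (!dynamic) {
    for (int i = 0; i < n; ++i) {
      if (delta_o[i] != 0.0) {
        n_signed += 1;
        if ((delta_o[i] > 0.0) == (spin[i] > 0)) n_aligned += 1;
      }
    }
  }

  std::vector<int> rec_sweep;
  std::vector<double> rec_delta, rec_frac, rec_aligned;
  std::vector<int> rec_flips;
  std::vector<double> rec_sub; // row-major: record x subpop

  double cur_delta = dynamic ? schedule[0] : NA_REAL;
  auto record = [&](int sweep, int flips_in_interval) {
    rec_sweep.push_back(sweep);
    rec_delta.push_back(cur_delta);
    rec_frac.push_back((double)n_a / n);
    rec_flips.push_back(flips_in_interval);
    if (dynamic) {
      double fa = (double)n_a / n;
      rec_aligned.push_back(cur_delta > 0 ? fa : (cur_delta < 0 ? 1.0 - fa : NA_REAL));
    } else {
      rec_aligned.push_back(n_signed > 0 ? (double)n_aligned / n_signed : NA_REAL);
    }
    for (int s = 0; s < n_subpop; ++s)
      rec_sub.push_back(sub_n[s] > 0 ? (double)sub_a[s] / sub_n[s] : NA_REAL);
  };
  record(0, 0);

  RNGScope scope;
  int quiet = 0, sweeps_run = 0, interval_flips = 0;
  bool equilibrium = false;
  for (int t = 0; t < horizon; ++t) {
    if (dynamic) cur_delta = schedule[t];
    int sweep_flips = 0;
    for (int step = 0; step < n; ++step) {
      int i = (int)(unif_rand() * n);
      if (i == n) i = n - 1;
      int ssum = 0;
      for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) ssum += spin[adj[e]];
      double d_i = dynamic ? cur_delta : delta_o[i];
      double du = d_i + w[i] * (double)ssum;
      double p_a = sigmoid(beta * du);
      int new_spin = (unif_rand() < p_a) ? 1 : -1;
      if (new_spin != spin[i]) {
        if (!dynamic && delta_o[i] != 0.0) {
          bool was = (delta_o[i] > 0.0) == (spin[i] > 0);
          n_aligned += was ? -1 : 1;
        }
        n_a += new_spin;
        sub_a[subpop[i]] += new_spin;
        spin[i] = new_spin;
        flips_node[i] += 1;
        sweep_flips += 1;
      }
    }
    sweeps_run = t + 1;
    interval_flips += sweep_flips;
    quiet = (sweep_flips == 0) ? quiet + 1 : 0;
    bool last = (t == horizon - 1);
    bool stop_now = (quiet_sweeps > 0 && quiet >= quiet_sweeps);
    if ((t + 1) % record_every == 0 || last || stop_now) {
      record(t + 1, interval_flips);
      interval_flips = 0;
    }
    if (stop_now) { equilibrium = true; break; }
  }

  NumericMatrix sub_mat(rec_sweep.size(), n_subpop);
  for (size_t r = 0; r < rec_sweep.size(); ++r)
    for (int s = 0; s < n_subpop; ++s)
      sub_mat(r, s) = rec_sub[r * n_subpop + s];

  return List::create(
      _["sweep"] = wrap(rec_sweep), _["delta_o"] = wrap(rec_delta),
      _["frac_A"] = wrap(rec_frac), _["frac_aligned"] = wrap(rec_aligned),
      _["flips"] = wrap(rec_flips), _["frac_A_sub"] = sub_mat,
      _["final_spin"] = wrap(spin), _["flips_per_node"] = wrap(flips_node),
      _["equilibrium"] = equilibrium, _["sweeps_run"] = sweeps_run);
}

static inline double corr_from_sum(double S, int n_anti, int n, double mean_d,
                                   double sd_d) {
  double p = (double)n_anti / n;
  if (sd_d <= 0.0 || n_anti == 0 || n_anti == n) return 0.0;
  double cov = S / n - mean_d * p;
  return cov / (sd_d * std::sqrt(p * (1.0 - p)));
}

// Greedy attribute-swap loop: starting from a given anticonformist
// placement, repeatedly pick one anticonformist and one other node at
// random and exchange their attributes iff doing so does not increase the
// distance of the degree-type Pearson correlation from the target.
// Returns the placement, the achieved correlation, and the trace of
// |achieved - target| after each accepted swap.
// [[Rcpp::export]]
List swap_to_corr_cpp(NumericVector degree, LogicalVector anti_init,
                      double target, double tol, int max_iters) {
  const int n = degree.size();
  std::vector<int> anti_ids, conf_ids;
  double S = 0.0, mean_d = 0.0, m2 = 0.0;
  for (int i = 0; i < n; ++i) mean_d += degree[i];
  mean_d /= n;
  for (int i = 0; i < n; ++i) {
    double d = degree[i] - mean_d;
    m2 += d * d;
    if (anti_init[i]) { anti_ids.push_back(i); S += degree[i]; }
    else conf_ids.push_back(i);
  }
  double sd_d = std::sqrt(m2 / n);
  int n_anti = anti_ids.size();
  std::vector<double> trace;
  double cur = corr_from_sum(S, n_anti, n, mean_d, sd_d);
  double dist = std::fabs(cur - target);
  trace.push_back(dist);

  RNGScope scope;
  int iters = 0;
  if (n_anti > 0 && n_anti < n && sd_d > 0.0) {
    while (dist > tol && iters < max_iters) {
      ++iters;
      int ia = (int)(unif_rand() * n_anti); if (ia == n_anti) --ia;
      int ic = (int)(unif_rand() * (n - n_anti)); if (ic == n - n_anti) --ic;
      double S_new = S - degree[anti_ids[ia]] + degree[conf_ids[ic]];
      double cand = corr_from_sum(S_new, n_anti, n, mean_d, sd_d);
      double cand_dist = std::fabs(cand - target);
      if (cand_dist <= dist) {
        std::swap(anti_ids[ia], conf_ids[ic]);
        S = S_new; cur = cand; dist = cand_dist;
        trace.push_back(dist);
      }
    }
  }
  LogicalVector out(n, false);
  for (int id : anti_ids) out[id] = true;
  return List::create(_["anti"] = out, _["achieved"] = cur,
                      _["iters"] = iters, _["converged"] = dist <= tol,
                      _["trace"] = wrap(trace));
}

// Degree-preserving two-edge rewiring (Xulvi-Brunet & Sokolov scheme).
// mode: +1 assortative (pair the two highest-degree and the two
// lowest-degree endpoints), -1 disassortative (pair highest with lowest),
// 0 neutral (random re-pairing). Proposals creating self-loops or
// duplicate edges are rejected; degrees are invariant by construction.
// [[Rcpp::export]]
IntegerMatrix rewire_edges_cpp(IntegerMatrix edges, int n, int mode,
                               int steps) {
  const int m = edges.nrow();
  std::vector<int> from(m), to(m);
  std::vector<double> deg(n, 0.0);
  std::unordered_set<long long> eset;
  auto key = [n](int a, int b) -> long long {
    if (a > b) std::swap(a, b);
    return (long long)a * n + b;
  };
  for (int e = 0; e < m; ++e) {
    from[e] = edges(e, 0); to[e] = edges(e, 1);
    deg[from[e]] += 1; deg[to[e]] += 1;
    eset.insert(key(from[e], to[e]));
  }
  if (m < 2) return edges;

  RNGScope scope;
  for (int s = 0; s < steps; ++s) {
    int e1 = (int)(unif_rand() * m); if (e1 == m) --e1;
    int e2 = (int)(unif_rand() * m); if (e2 == m) --e2;
    if (e1 == e2) continue;
    int v[4] = {from[e1], to[e1], from[e2], to[e2]};
    bool distinct = true;
    for (int a = 0; a < 4 && distinct; ++a)
      for (int b = a + 1; b < 4; ++b)
        if (v[a] == v[b]) { distinct = false; break; }
    if (!distinct) continue;

    int p1a, p1b, p2a, p2b;
    if (mode == 0) {
      // random alternative pairing of the four endpoints
      if (unif_rand() < 0.5) { p1a = v[0]; p1b = v[2]; p2a = v[1]; p2b = v[3]; }
      else                   { p1a = v[0]; p1b = v[3]; p2a = v[1]; p2b = v[2]; }
    } else {
      int idx[4] = {0, 1, 2, 3};
      // sort endpoints by degree (ties by node id for determinism)
      std::sort(idx, idx + 4, [&](int a, int b) {
        if (deg[v[a]] != deg[v[b]]) return deg[v[a]] < deg[v[b]];
        return v[a] < v[b];
      });
      if (mode > 0) { // low with low, high with high
        p1a = v[idx[0]]; p1b = v[idx[1]]; p2a = v[idx[2]]; p2b = v[idx[3]];
      } else {        // lowest with highest, middle pair together
        p1a = v[idx[0]]; p1b = v[idx[3]]; p2a = v[idx[1]]; p2b = v[idx[2]];
      }
    }
    long long k1 = key(p1a, p1b), k2 = key(p2a, p2b);
    long long o1 = key(from[e1], to[e1]), o2 = key(from[e2], to[e2]);
    if (k1 == o1 && k2 == o2) continue;
    if (k1 == o2 && k2 == o1) continue;
    if ((k1 != o1 && k1 != o2 && eset.count(k1)) ||
        (k2 != o1 && k2 != o2 && eset.count(k2)) || k1 == k2)
      continue;
    eset.erase(o1); eset.erase(o2);
    eset.insert(k1); eset.insert(k2);
    from[e1] = p1a; to[e1] = p1b;
    from[e2] = p2a; to[e2] = p2b;
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) { out(e, 0) = from[e]; out(e, 1) = to[e]; }
  return out;
}
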