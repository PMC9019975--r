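#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// Two-sided stability optimizer.
//
// The score of a partition mc over the graph's assigned nodes V is
//   score = (1 / 2|V|) * sum_v [ log(stable_in(v)) + log(stable_out(v)) ]
// with stable = pstable / punif, pstable the weighted fraction of a node's
// in-/out-edges that stay inside its metacell and punif = |M_mc(v)| / |V|.
// log(pstable) is floored at `floor_log` so one-sided or disconnected
// membership is strongly penalized instead of -Inf.
//
// Hill climbing over single-node moves, swept in seeded random order. At
// annealing level lambda a move of node v is accepted iff
//   delta(sum of terms) + lambda_v * delta(v's own stability terms) > 0,
// where lambda_v = lambda for nodes in the active set and 0 otherwise.
// Levels with lambda > 0 run at most `max_sweeps_pos` sweeps (the criterion
// is not a potential function there); lambda = 0 runs to convergence.
//
// Nodes with assign == 0 are excluded (outliers): they never move and their
// edges are ignored. assign is 1-based metacell ids.

struct Graph {
  int n;
  // CSR out: for node v, edges [op[v], op[v+1]) -> (oi, ox)
  std::vector<int> op, oi;
  std::vector<double> ox;
  std::vector<int> ip, ii;
  std::vector<double> ix;
};

class Optimizer {
 public:
  Graph g;
  std::vector<int> assign;     // 1-based, 0 = excluded
  std::vector<char> active;    // lambda applies
  int n_mc;
  int V;                       // number of assigned nodes
  std::vector<int> size;       // per metacell node count (index 0 unused)
  std::vector<double> tot_out, tot_in, same_out, same_in;
  double floor_log;
  double logV;

  double flog(double num, double den) const {
    if (den <= 0 || num <= 0) return floor_log;
    return std::max(std::log(num / den), floor_log);
  }
  // size-term contribution of a metacell of c nodes: -2 * c * log(c / V)
  double size_term(int c) const {
    if (c <= 0) return 0.0;
    return -2.0 * c * (std::log((double)c) - logV);
  }

  void init() {
    int n = g.n;
    V = 0;
    n_mc = 0;
    for (int v = 0; v < n; ++v) {
      if (assign[v] > 0) ++V;
      n_mc = std::max(n_mc, assign[v]);
    }
    logV = std::log(std::max(V, 1));
    size.assign(n_mc + 1, 0);
    tot_out.assign(n, 0.0);
    tot_in.assign(n, 0.0);
    same_out.assign(n, 0.0);
    same_in.assign(n, 0.0);
    for (int v = 0; v < n; ++v)
      if (assign[v] > 0) ++size[assign[v]];
    for (int v = 0; v < n; ++v) {
      if (assign[v] == 0) continue;
      for (int k = g.op[v]; k < g.op[v + 1]; ++k) {
        int u = g.oi[k];
        if (assign[u] == 0) continue;
        tot_out[v] += g.ox[k];
        if (assign[u] == assign[v]) same_out[v] += g.ox[k];
      }
      for (int k = g.ip[v]; k < g.ip[v + 1]; ++k) {
        int u = g.ii[k];
        if (assign[u] == 0) continue;
        tot_in[v] += g.ix[k];
        if (assign[u] == assign[v]) same_in[v] += g.ix[k];
      }
    }
  }

  double total_score() const {
    double s = 0.0;
    for (int v = 0; v < g.n; ++v) {
      if (assign[v] == 0) continue;
      s += flog(same_out[v], tot_out[v]) + flog(same_in[v], tot_in[v]);
    }
    for (int m = 1; m <= n_mc; ++m) s += size_term(size[m]);
    return s / (2.0 * std::max(V, 1));
  }

  // one sweep at a given lambda; returns number of accepted moves
  int sweep(double lambda, std::mt19937& rng) {
    int n = g.n;
    std::vector<int> order;
    order.reserve(V);
    for (int v = 0; v < n; ++v)
      if (assign[v] > 0) order.push_back(v);
    std::shuffle(order.begin(), order.end(), rng);
    int moves = 0;
    // scratch: per-metacell accumulated weights and per-metacell buckets of
    // v's edges (so each candidate evaluation only touches its own bucket)
    std::vector<double> w_out_to(n_mc + 1, 0.0), w_in_from(n_mc + 1, 0.0);
    std::vector<double> gain_to(n_mc + 1, 0.0);
    std::vector<int> touched;
    for (int v : order) {
      int A = assign[v];
      touched.clear();
      // single pass over v's edges: accumulate per-metacell weights and the
      // neighbour-term gain of joining each metacell
      for (int k = g.op[v]; k < g.op[v + 1]; ++k) {
        int u = g.oi[k], m = assign[u];
        if (m == 0 || u == v) continue;
        if (w_out_to[m] == 0.0 && w_in_from[m] == 0.0) touched.push_back(m);
        w_out_to[m] += g.ox[k];
        gain_to[m] += flog(same_in[u] + g.ox[k], tot_in[u]) -
                      flog(same_in[u], tot_in[u]);
      }
      for (int k = g.ip[v]; k < g.ip[v + 1]; ++k) {
        int u = g.ii[k], m = assign[u];
        if (m == 0 || u == v) continue;
        if (w_out_to[m] == 0.0 && w_in_from[m] == 0.0) touched.push_back(m);
        w_in_from[m] += g.ix[k];
        gain_to[m] += flog(same_out[u] + g.ix[k], tot_out[u]) -
                      flog(same_out[u], tot_out[u]);
      }
      // neighbour-term loss from leaving A (candidate independent)
      double loss_A = 0.0;
      for (int k = g.op[v]; k < g.op[v + 1]; ++k) {
        int u = g.oi[k];
        if (u == v || assign[u] != A) continue;
        loss_A += flog(same_in[u] - g.ox[k], tot_in[u]) -
                  flog(same_in[u], tot_in[u]);
      }
      for (int k = g.ip[v]; k < g.ip[v + 1]; ++k) {
        int u = g.ii[k];
        if (u == v || assign[u] != A) continue;
        loss_A += flog(same_out[u] - g.ix[k], tot_out[u]) -
                  flog(same_out[u], tot_out[u]);
      }
      int a = size[A];
      double term_v_A = flog(same_out[v], tot_out[v]) +
                        flog(same_in[v], tot_in[v]);
      double lam = active[v] ? lambda : 0.0;
      double best_gain = 0.0;
      int best_B = -1;
      double best_crit = 0.0;
      for (int B : touched) {
        if (B == A) continue;
        int b = size[B];
        double d_size = size_term(a - 1) + size_term(b + 1) -
                        size_term(a) - size_term(b);
        double term_v_B = flog(w_out_to[B], tot_out[v]) +
                          flog(w_in_from[B], tot_in[v]);
        double delta = d_size + (term_v_B - term_v_A) + loss_A + gain_to[B];
        // v's own stability incl. punif, for the annealing term
        double self_A = term_v_A - 2.0 * (std::log((double)a) - logV);
        double self_B = term_v_B - 2.0 * (std::log((double)(b + 1)) - logV);
        double crit = delta + lam * (self_B - self_A);
        if (crit > best_crit + 1e-12) {
          best_crit = crit;
          best_gain = delta;
          best_B = B;
        }
      }
      if (best_B > 0 && best_crit > 1e-10) {
        apply_move(v, A, best_B, w_out_to, w_in_from);
        (void)best_gain;
        ++moves;
      }
      for (int m : touched) {
        w_out_to[m] = 0.0;
        w_in_from[m] = 0.0;
        gain_to[m] = 0.0;
      }
    }
    return moves;
  }

  void apply_move(int v, int A, int B, const std::vector<double>& w_out_to,
                  const std::vector<double>& w_in_from) {
    for (int k = g.op[v]; k < g.op[v + 1]; ++k) {
      int u = g.oi[k];
      if (u == v) continue;
      if (assign[u] == A) same_in[u] -= g.ox[k];
      else if (assign[u] == B) same_in[u] += g.ox[k];
    }
    for (int k = g.ip[v]; k < g.ip[v + 1]; ++k) {
      int u = g.ii[k];
      if (u == v) continue;
      if (assign[u] == A) same_out[u] -= g.ix[k];
      else if (assign[u] == B) same_out[u] += g.ix[k];
    }
    assign[v] = B;
    --size[A];
    ++size[B];
    same_out[v] = w_out_to[B];
    same_in[v] = w_in_from[B];
  }
};

static Graph build_graph(int n, IntegerVector op, IntegerVector oi,
                         NumericVector ox, IntegerVector ip, IntegerVector ii,
                         NumericVector ix) {
  Graph g;
  g.n = n;
  g.op.assign(op.begin(), op.end());
  g.oi.assign(oi.begin(), oi.end());
  g.ox.assign(ox.begin(), ox.end());
  g.ip.assign(ip.begin(), ip.end());
  g.ii.assign(ii.begin(), ii.end());
  g.ix.assign(ix.begin(), ix.end());
  return g;
}

// [[Rcpp::export]]
List cpp_optimize_partition(int n, IntegerVector op, IntegerVector oi,
                            NumericVector ox, IntegerVector ip,
                            IntegerVector ii, NumericVector ix,
                            IntegerVector assign0, LogicalVector active,
                            NumericVector lambda_schedule, int max_sweeps_pos,
                            int seed, double floor_log) {
  Optimizer opt;
  opt.g = build_graph(n, op, oi, ox, ip, ii, ix);
  opt.assign.assign(assign0.begin(), assign0.end());
  opt.active.assign(n, 0);
  for (int v = 0; v < n; ++v) opt.active[v] = active[v] ? 1 : 0;
  opt.floor_log = floor_log;
  opt.init();
  std::mt19937 rng(seed);
  for (double lambda : lambda_schedule) {
    int sweeps = 0;
    for (;;) {
      int moves = opt.sweep(lambda, rng);
      ++sweeps;
      if (moves == 0) break;
      if (lambda > 0 && sweeps >= max_sweeps_pos) break;
      if (lambda == 0 && sweeps > 10000) break;  // safety valve
    }
  }
  return List::create(_["assign"] = wrap(opt.assign),
                      _["score"] = opt.total_score());
}
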