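// Multi-restart greedy minimization of the two-level map equation on an
// undirected weighted network (Louvain-style local moves + module
// aggregation, repeated with base-level fine-tuning until converged).
// Flow model: node visit rate = strength / (2W); module exit rate =
// boundary weight / (2W). All code lengths in bits.
//
// Uses R's RNG (unif_rand) so results are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>

using namespace Rcpp;

namespace {

struct Graph {
  int n;
  // adjacency: both directions of every edge, flow-unit weights
  std::vector<std::vector<std::pair<int, double> > > adj;
  std::vector<double> p;  // visit rates (sum to 1 at base level)
};

inline double plogp(double x) {
  return x > 1e-300 ? x * std::log2(x) : 0.0;
}

double codelength(const Graph& g, const std::vector<int>& mod, int nmod) {
  std::vector<double> q(nmod, 0.0), S(nmod, 0.0);
  for (int i = 0; i < g.n; ++i) {
    S[mod[i]] += g.p[i];
    for (size_t k = 0; k < g.adj[i].size(); ++k) {
      if (mod[g.adj[i][k].first] != mod[i]) q[mod[i]] += g.adj[i][k].second;
    }
  }
  double sq = 0.0, tq = 0.0, tqs = 0.0, tp = 0.0;
  for (int m = 0; m < nmod; ++m) {
    sq += q[m];
    tq += plogp(q[m]);
    tqs += plogp(q[m] + S[m]);
  }
  for (int i = 0; i < g.n; ++i) tp += plogp(g.p[i]);
  return plogp(sq) - 2.0 * tq + tqs - tp;
}

int renumber(std::vector<int>& mod) {
  std::vector<int> newid(mod.size(), -1);
  int next = 0;
  for (size_t i = 0; i < mod.size(); ++i) {
    if (newid[mod[i]] < 0) newid[mod[i]] = next++;
    mod[i] = newid[mod[i]];
  }
  return next;
}

void shuffle_order(std::vector<int>& order) {
  for (int i = (int)order.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(order[i], order[j]);
  }
}

// Greedy node moves until a full sweep makes no improving move.
// mod holds module ids 0..nmod-1 on entry (gaps allowed after renumber).
bool local_moves(const Graph& g, std::vector<int>& mod, int nmod) {
  std::vector<double> q(nmod, 0.0), S(nmod, 0.0);
  double sumq = 0.0;
  for (int i = 0; i < g.n; ++i) {
    S[mod[i]] += g.p[i];
    for (size_t k = 0; k < g.adj[i].size(); ++k) {
      if (mod[g.adj[i][k].first] != mod[i]) q[mod[i]] += g.adj[i][k].second;
    }
  }
  for (int m = 0; m < nmod; ++m) sumq += q[m];

  std::vector<double> wtomod(nmod, 0.0);
  std::vector<int> touched;
  std::vector<int> order(g.n);
  for (int i = 0; i < g.n; ++i) order[i] = i;

  bool any = false;
  for (int sweep = 0; sweep < 200; ++sweep) {
    shuffle_order(order);
    bool moved = false;
    for (int oi = 0; oi < g.n; ++oi) {
      int i = order[oi];
      int A = mod[i];
      double ki = 0.0;
      touched.clear();
      for (size_t k = 0; k < g.adj[i].size(); ++k) {
        int j = g.adj[i][k].first;
        double w = g.adj[i][k].second;
        ki += w;
        int m = mod[j];
        if (wtomod[m] == 0.0) touched.push_back(m);
        wtomod[m] += w;
      }
      double wiA = wtomod[A];
      double qA_new = q[A] - ki + 2.0 * wiA;
      double SA_new = S[A] - g.p[i];
      double baseA = -2.0 * plogp(q[A]) + plogp(q[A] + S[A]);
      double newA = -2.0 * plogp(qA_new) + plogp(qA_new + SA_new);

      int bestB = -1;
      double bestDelta = -1e-10;
      for (size_t t = 0; t < touched.size(); ++t) {
        int B = touched[t];
        if (B == A) continue;
        double wiB = wtomod[B];
        double qB_new = q[B] + ki - 2.0 * wiB;
        double SB_new = S[B] + g.p[i];
        double sumq_new = sumq + (qA_new - q[A]) + (qB_new - q[B]);
        double delta = plogp(sumq_new) - plogp(sumq)
          + newA - baseA
          - 2.0 * plogp(qB_new) + plogp(qB_new + SB_new)
          + 2.0 * plogp(q[B]) - plogp(q[B] + S[B]);
        if (delta < bestDelta) {
          bestDelta = delta;
          bestB = B;
        }
      }
      if (bestB >= 0) {
        double wiB = wtomod[bestB];
        double qB_new = q[bestB] + ki - 2.0 * wiB;
        sumq += (qA_new - q[A]) + (qB_new - q[bestB]);
        q[A] = qA_new;
        S[A] = SA_new;
        q[bestB] = qB_new;
        S[bestB] += g.p[i];
        mod[i] = bestB;
        moved = true;
        any = true;
      }
      for (size_t t = 0; t < touched.size(); ++t) wtomod[touched[t]] = 0.0;
    }
    if (!moved) break;
  }
  return any;
}

Graph aggregate(const Graph& g, const std::vector<int>& mod, int nmod) {
  Graph h;
  h.n = nmod;
  h.p.assign(nmod, 0.0);
  h.adj.assign(nmod, std::vector<std::pair<int, double> >());
  for (int i = 0; i < g.n; ++i) h.p[mod[i]] += g.p[i];
  std::vector<std::map<int, double> > acc(nmod);
  for (int i = 0; i < g.n; ++i) {
    for (size_t k = 0; k < g.adj[i].size(); ++k) {
      int j = g.adj[i][k].first;
      if (j <= i) continue;  // each undirected edge once
      int a = mod[i], b = mod[j];
      if (a == b) continue;  // internal weight never crosses again
      double w = g.adj[i][k].second;
      if (a < b) acc[a][b] += w; else acc[b][a] += w;
    }
  }
  for (int a = 0; a < nmod; ++a) {
    for (std::map<int, double>::const_iterator it = acc[a].begin();
         it != acc[a].end(); ++it) {
      h.adj[a].push_back(std::make_pair(it->first, it->second));
      h.adj[it->first].push_back(std::make_pair(a, it->second));
    }
  }
  return h;
}

// One full search pass: local moves at base level from the current
// assignment, then repeated aggregation with moves at each level.
void search_pass(const Graph& base, std::vector<int>& orig) {
  int nmod = renumber(orig);
  local_moves(base, orig, nmod);
  nmod = renumber(orig);
  if (nmod == base.n) return;

  Graph g = aggregate(base, orig, nmod);
  std::vector<int> sup = orig;  // original node -> current supernode
  while (true) {
    std::vector<int> smod(g.n);
    for (int i = 0; i < g.n; ++i) smod[i] = i;
    local_moves(g, smod, g.n);
    int nm = renumber(smod);
    if (nm == g.n) break;
    for (int i = 0; i < base.n; ++i) sup[i] = smod[sup[i]];
    g = aggregate(g, smod, nm);
  }
  orig = sup;
  renumber(orig);
}

}  // namespace

// [[Rcpp::export]]
List infomap_core(int n, IntegerVector from, IntegerVector to,
                  NumericVector weight, int n_trials) {
  if (n < 1) stop("network must have at least one node");
  if (n_trials < 1) stop("n_trials must be >= 1");

  double total = 0.0;
  for (int k = 0; k < weight.size(); ++k) total += weight[k];
  if (total <= 0) stop("total link weight must be positive");

  Graph base;
  base.n = n;
  base.adj.assign(n, std::vector<std::pair<int, double> >());
  base.p.assign(n, 0.0);
  for (int k = 0; k < from.size(); ++k) {
    int i = from[k] - 1, j = to[k] - 1;
    if (i < 0 || i >= n || j < 0 || j >= n) stop("edge endpoint out of range");
    double wf = weight[k] / (2.0 * total);
    base.adj[i].push_back(std::make_pair(j, wf));
    base.adj[j].push_back(std::make_pair(i, wf));
    base.p[i] += wf;
    base.p[j] += wf;
  }

  std::vector<int> best_mod;
  double best_L = R_PosInf;

  for (int trial = 0; trial < n_trials; ++trial) {
    std::vector<int> orig(n);
    for (int i = 0; i < n; ++i) orig[i] = i;
    double L = codelength(base, orig, n);
    for (int pass = 0; pass < 50; ++pass) {
      std::vector<int> prev = orig;
      search_pass(base, orig);
      int nm = renumber(orig);
      double Lnew = codelength(base, orig, nm);
      if (Lnew < L - 1e-10) {
        L = Lnew;
      } else {
        orig = prev;
        break;
      }
    }
    int nm = renumber(orig);
    L = codelength(base, orig, nm);
    if (L < best_L - 1e-12) {
      best_L = L;
      best_mod = orig;
    } else if (L < best_L + 1e-12 && !best_mod.empty()) {
      // deterministic tie-break: lexicographically smallest canonical labels
      for (size_t i = 0; i < orig.size(); ++i) {
        if (orig[i] < best_mod[i]) { best_mod = orig; break; }
        if (orig[i] > best_mod[i]) break;
      }
    }
  }

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = best_mod[i] + 1;
  return List::create(_["modules"] = out, _["codelength"] = best_L);
}
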