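// Structure MCMC over Bayesian-network DAGs with BDeu scoring.
// Hot path of the package: everything here operates on 0-based integer
// matrices (subjects x variables) with per-variable arities.  The R level
// keeps an independent reference implementation of the score and of the
// structural features; this file is validated against it in the tests.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <random>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// BDeu family score
// ---------------------------------------------------------------------------

static double bdeu_family(const IntegerMatrix &data, int child,
                          const std::vector<int> &parents,
                          const IntegerVector &arity, double ess) {
  const int n = data.nrow();
  const int r = arity[child];
  long q = 1;
  for (int p : parents) q *= arity[p];
  std::vector<int> counts(static_cast<size_t>(q) * r, 0);
  for (int i = 0; i < n; ++i) {
    long idx = 0, stride = 1;
    for (int p : parents) {
      idx += static_cast<long>(data(i, p)) * stride;
      stride *= arity[p];
    }
    counts[static_cast<size_t>(idx) * r + data(i, child)]++;
  }
  const double aj = ess / static_cast<double>(q);
  const double ajk = ess / (static_cast<double>(q) * r);
  double s = 0.0;
  for (long j = 0; j < q; ++j) {
    int Nj = 0;
    for (int k = 0; k < r; ++k) {
      const int Njk = counts[static_cast<size_t>(j) * r + k];
      if (Njk > 0) {
        Nj += Njk;
        s += std::lgamma(ajk + Njk) - std::lgamma(ajk);
      }
    }
    if (Nj > 0) s += std::lgamma(aj) - std::lgamma(aj + Nj);
  }
  return s;
}

// [[Rcpp::export]]
double cpp_bdeu_family_score(IntegerMatrix data, int child,
                             IntegerVector parents, IntegerVector arity,
                             double ess) {
  std::vector<int> ps(parents.begin(), parents.end());
  return bdeu_family(data, child, ps, arity, ess);
}

// ---------------------------------------------------------------------------
// DAG enumeration (exact-posterior oracle support, small n only)
// ---------------------------------------------------------------------------

static bool masks_acyclic(const std::vector<int> &mask, int n) {
  // peel nodes whose parents are all already removed
  int removed = 0;
  std::vector<bool> gone(n, false);
  bool progress = true;
  while (progress) {
    progress = false;
    for (int v = 0; v < n; ++v) {
      if (gone[v]) continue;
      int m = mask[v];
      bool free_node = true;
      for (int u = 0; u < n; ++u)
        if ((m >> u) & 1 && !gone[u]) { free_node = false; break; }
      if (free_node) {
        gone[v] = true;
        ++removed;
        progress = true;
      }
    }
  }
  return removed == n;
}

// [[Rcpp::export]]
IntegerMatrix cpp_enumerate_dags(int n, int max_parents) {
  if (n < 1 || n > 5) stop("DAG enumeration supported for 1..5 nodes only");
  // candidate parent masks per node
  std::vector<std::vector<int>> cand(n);
  for (int v = 0; v < n; ++v)
    for (int m = 0; m < (1 << n); ++m) {
      if ((m >> v) & 1) continue;
      int pc = 0;
      for (int u = 0; u < n; ++u) pc += (m >> u) & 1;
      if (pc <= max_parents) cand[v].push_back(m);
    }
  std::vector<std::vector<int>> out;
  std::vector<int> mask(n, 0), pos(n, 0);
  // odometer over candidate lists
  long total = 1;
  for (int v = 0; v < n; ++v) total *= static_cast<long>(cand[v].size());
  for (long t = 0; t < total; ++t) {
    long rem = t;
    for (int v = 0; v < n; ++v) {
      mask[v] = cand[v][rem % cand[v].size()];
      rem /= cand[v].size();
    }
    if (masks_acyclic(mask, n)) out.push_back(mask);
  }
  IntegerMatrix res(static_cast<int>(out.size()), n);
  for (size_t i = 0; i < out.size(); ++i)
    for (int v = 0; v < n; ++v) res(static_cast<int>(i), v) = out[i][v];
  return res;
}

// ---------------------------------------------------------------------------
// Structure MCMC (add / delete / reverse moves, uniform over valid moves)
// ---------------------------------------------------------------------------

struct Move {
  int type; // 0 add, 1 delete, 2 reverse (u->v becomes v->u)
  int u, v;
};

class DagState {
public:
  int n, maxp;
  std::vector<std::vector<bool>> adj; // adj[u][v]: edge u -> v
  std::vector<int> npar;
  int nedges = 0;

  explicit DagState(int n_, int maxp_)
      : n(n_), maxp(maxp_), adj(n_, std::vector<bool>(n_, false)),
        npar(n_, 0) {}

  std::vector<int> parents(int v) const {
    std::vector<int> out;
    for (int u = 0; u < n; ++u)
      if (adj[u][v]) out.push_back(u);
    return out;
  }

  // is there a directed path from a to b (length >= 1)?
  bool path(int a, int b) const {
    std::vector<bool> seen(n, false);
    std::vector<int> stack{a};
    while (!stack.empty()) {
      int x = stack.back();
      stack.pop_back();
      for (int y = 0; y < n; ++y)
        if (adj[x][y] && !seen[y]) {
          if (y == b) return true;
          seen[y] = true;
          stack.push_back(y);
        }
    }
    return false;
  }

  void enumerate_moves(std::vector<Move> &out) const {
    out.clear();
    for (int u = 0; u < n; ++u)
      for (int v = 0; v < n; ++v) {
        if (u == v) continue;
        if (adj[u][v]) {
          out.push_back({1, u, v}); // delete
          // reverse: u->v becomes v->u; u gains a parent
          if (npar[u] < maxp) {
            // acyclic iff no other directed path u ~> v
            const_cast<DagState *>(this)->adj[u][v] = false;
            bool ok = !path(u, v);
            const_cast<DagState *>(this)->adj[u][v] = true;
            if (ok) out.push_back({2, u, v});
          }
        } else if (!adj[v][u] && npar[v] < maxp && !path(v, u)) {
          out.push_back({0, u, v}); // add
        }
      }
  }

  void apply(const Move &m) {
    if (m.type == 0) {
      adj[m.u][m.v] = true;
      npar[m.v]++;
      nedges++;
    } else if (m.type == 1) {
      adj[m.u][m.v] = false;
      npar[m.v]--;
      nedges--;
    } else {
      adj[m.u][m.v] = false;
      adj[m.v][m.u] = true;
      npar[m.v]--;
      npar[m.u]++;
    }
  }

  void revert(const Move &m) {
    Move inv = m;
    if (m.type == 0) inv.type = 1;
    else if (m.type == 1) inv.type = 0;
    else { inv.u = m.v; inv.v = m.u; }
    apply(inv);
  }

  // ancestor-or-self bitmasks: anc[x] has bit z set iff z == x or z ~> x
  void ancestors(std::vector<std::vector<uint64_t>> &anc) const {
    const int blocks = (n + 63) / 64;
    anc.assign(n, std::vector<uint64_t>(blocks, 0));
    for (int x = 0; x < n; ++x) anc[x][x / 64] |= (uint64_t(1) << (x % 64));
    // iterate to fixed point: anc[v] |= anc[u] for every edge u->v
    bool changed = true;
    while (changed) {
      changed = false;
      for (int u = 0; u < n; ++u)
        for (int v = 0; v < n; ++v)
          if (adj[u][v])
            for (int b = 0; b < blocks; ++b) {
              uint64_t nw = anc[v][b] | anc[u][b];
              if (nw != anc[v][b]) {
                anc[v][b] = nw;
                changed = true;
              }
            }
    }
  }
};

struct ScoreCache {
  std::unordered_map<std::string, double> map;

  static std::string key(int child, const std::vector<int> &parents) {
    std::string k;
    k.reserve(parents.size() + 1);
    k.push_back(static_cast<char>(child));
    for (int p : parents) k.push_back(static_cast<char>(p));
    return k;
  }

  double get(const IntegerMatrix &data, const IntegerVector &arity, double ess,
             int child, const std::vector<int> &parents) {
    std::string k = key(child, parents);
    auto it = map.find(k);
    if (it != map.end()) return it->second;
    double s = bdeu_family(data, child, parents, arity, ess);
    map.emplace(std::move(k), s);
    return s;
  }
};

// [[Rcpp::export]]
List cpp_structure_mcmc(IntegerMatrix data, IntegerVector arity, double ess,
                        int max_parents, double kappa, long iterations,
                        long burn_in, int thinning, double seed,
                        bool hill_climb_init = true) {
  const int n = data.ncol();
  if (n > 255) stop("at most 255 variables supported");
  DagState st(n, max_parents);
  ScoreCache cache;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  double log_score = 0.0;
  for (int v = 0; v < n; ++v)
    log_score += cache.get(data, arity, ess, v, {});

  if (hill_climb_init) {
    // Greedy ascent to the dominant mode before sampling: at large n the
    // structure posterior is sharply peaked and a random-walk burn-in
    // starting from the empty graph can trap in a far-off local mode.
    // Initialization does not alter the stationary distribution.
    std::vector<Move> moves;
    for (long step = 0; step < 10L * n * n; ++step) {
      st.enumerate_moves(moves);
      double best = 0.0;
      int best_i = -1;
      for (size_t k = 0; k < moves.size(); ++k) {
        const Move &m = moves[k];
        const int c1 = m.v, c2 = (m.type == 2) ? m.u : -1;
        double delta =
            -cache.get(data, arity, ess, c1, st.parents(c1));
        if (c2 >= 0) delta -= cache.get(data, arity, ess, c2, st.parents(c2));
        const int edges_before = st.nedges;
        st.apply(m);
        delta += cache.get(data, arity, ess, c1, st.parents(c1));
        if (c2 >= 0) delta += cache.get(data, arity, ess, c2, st.parents(c2));
        delta -= kappa * (st.nedges - edges_before);
        st.revert(m);
        if (delta > best + 1e-12) {
          best = delta;
          best_i = static_cast<int>(k);
        }
      }
      if (best_i < 0) break;
      st.apply(moves[best_i]);
      log_score += best;
    }
  }

  NumericMatrix edge_cnt(n, n), assoc_cnt(n, n);
  long n_samples = 0, accepted = 0;
  std::vector<Move> moves, cand_moves;
  std::vector<std::vector<uint64_t>> anc;
  const int blocks = (n + 63) / 64;

  for (long it = 0; it < iterations; ++it) {
    st.enumerate_moves(moves);
    if (!moves.empty()) {
      const size_t pick =
          std::min(moves.size() - 1,
                   static_cast<size_t>(unif(rng) * moves.size()));
      const Move m = moves[pick];
      // delta score: families whose parent set changes
      double delta = 0.0;
      const int c1 = m.v, c2 = (m.type == 2) ? m.u : -1;
      const double old1 = cache.get(data, arity, ess, c1, st.parents(c1));
      double old2 = 0.0;
      if (c2 >= 0) old2 = cache.get(data, arity, ess, c2, st.parents(c2));
      const int edges_before = st.nedges;
      st.apply(m);
      delta += cache.get(data, arity, ess, c1, st.parents(c1)) - old1;
      if (c2 >= 0)
        delta += cache.get(data, arity, ess, c2, st.parents(c2)) - old2;
      delta -= kappa * (st.nedges - edges_before); // per-edge prior penalty
      st.enumerate_moves(cand_moves);
      const double log_hastings =
          std::log(static_cast<double>(moves.size())) -
          std::log(static_cast<double>(
              cand_moves.empty() ? 1 : cand_moves.size()));
      if (std::log(unif(rng)) < delta + log_hastings) {
        log_score += delta;
        ++accepted;
      } else {
        st.revert(m);
      }
    }
    if (it >= burn_in && (it - burn_in) % thinning == 0) {
      ++n_samples;
      st.ancestors(anc);
      for (int x = 0; x < n; ++x)
        for (int y = x + 1; y < n; ++y) {
          if (st.adj[x][y] || st.adj[y][x]) {
            edge_cnt(x, y) += 1.0;
          }
          bool connected = false;
          for (int b = 0; b < blocks && !connected; ++b)
            if (anc[x][b] & anc[y][b]) connected = true;
          if (connected) assoc_cnt(x, y) += 1.0;
        }
    }
  }

  NumericMatrix edge(n, n), assoc(n, n);
  if (n_samples > 0)
    for (int x = 0; x < n; ++x)
      for (int y = x + 1; y < n; ++y) {
        edge(x, y) = edge(y, x) = edge_cnt(x, y) / n_samples;
        assoc(x, y) = assoc(y, x) = assoc_cnt(x, y) / n_samples;
      }
  return List::create(_["edge"] = edge, _["association"] = assoc,
                      _["n_samples"] = static_cast<double>(n_samples),
                      _["acceptance_rate"] =
                          iterations > 0
                              ? static_cast<double>(accepted) / iterations
                              : 0.0,
                      _["final_log_score"] = log_score);
}
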