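// Louvain-style optimizer for multilayer modularity on temporal networks.
// Node-layer pairs are flattened into supernodes; intralayer edges carry the
// layer adjacency weights and interlayer identity edges carry the coupling
// omega between the same bead in consecutive layers (the standard multilayer
// formulation where the quality matrix is B = A - gamma * null + omega * C).
// The null model is handled implicitly through per-layer strengths so that
// aggregation never materializes a dense matrix.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Graph {
  int M;                                            // number of supernodes
  std::vector<std::vector<std::pair<int,double> > > adj;  // plain edges
  std::vector<double> selfw;                        // internal (collapsed) weight
  std::vector<std::vector<std::pair<int,double> > > lstr; // (layer, strength)
};

typedef long long ll;

struct MoveResult {
  bool any_move;
  std::vector<int> trace_u, trace_from, trace_to;
  std::vector<double> trace_gain;
};

// one Louvain move phase; labels modified in place
MoveResult move_phase(const Graph& g, std::vector<int>& lab,
                      const std::vector<double>& lt, double gamma,
                      std::mt19937_64& rng, bool keep_trace) {
  MoveResult res; res.any_move = false;
  int M = g.M;
  std::unordered_map<ll,double> K;       // (community, layer) -> strength
  std::vector<int> csize(2 * M + 1, 0);
  int nlab = 0;
  for (int u = 0; u < M; ++u) nlab = std::max(nlab, lab[u] + 1);
  for (int u = 0; u < M; ++u) {
    csize[lab[u]]++;
    for (size_t a = 0; a < g.lstr[u].size(); ++a)
      K[(ll)lab[u] * 1000000 + g.lstr[u][a].first] += g.lstr[u][a].second;
  }
  std::vector<int> freelab;
  for (int c = 0; c < nlab; ++c) if (csize[c] == 0) freelab.push_back(c);

  std::vector<int> order(M);
  for (int u = 0; u < M; ++u) order[u] = u;
  std::unordered_map<int,double> wc;

  bool improved = true;
  while (improved) {
    improved = false;
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < M; ++oi) {
      int u = order[oi];
      int c = lab[u];
      // detach u
      csize[c]--;
      for (size_t a = 0; a < g.lstr[u].size(); ++a)
        K[(ll)c * 1000000 + g.lstr[u][a].first] -= g.lstr[u][a].second;
      wc.clear();
      for (size_t a = 0; a < g.adj[u].size(); ++a)
        wc[lab[g.adj[u][a].first]] += g.adj[u][a].second;

      // gain of placing u into community d (up to the global 2/2mu factor)
      auto gain = [&](int d) {
        double w = 0.0;
        std::unordered_map<int,double>::const_iterator it = wc.find(d);
        if (it != wc.end()) w = it->second;
        double pen = 0.0;
        for (size_t a = 0; a < g.lstr[u].size(); ++a) {
          int l = g.lstr[u][a].first;
          if (lt[l] <= 0.0) continue;
          std::unordered_map<ll,double>::const_iterator kt =
            K.find((ll)d * 1000000 + l);
          if (kt != K.end()) pen += g.lstr[u][a].second * kt->second / lt[l];
        }
        return w - gamma * pen;
      };

      double g_stay = gain(c);
      int best = c; double g_best = g_stay;
      for (std::unordered_map<int,double>::iterator it = wc.begin();
           it != wc.end(); ++it) {
        int d = it->first;
        if (d == c) continue;
        double gd = gain(d);
        if (gd > g_best + 1e-12 ||
            (gd > g_best - 1e-12 && best != c && d < best)) {
          best = d; g_best = gd;
        }
      }
      // option of a fresh singleton community (gain 0)
      if (csize[c] > 0 && 0.0 > g_best + 1e-12) {
        int d;
        if (!freelab.empty()) { d = freelab.back(); freelab.pop_back(); }
        else { d = nlab++; }
        best = d; g_best = 0.0;
      }

      if (best != c) {
        res.any_move = true; improved = true;
        if (keep_trace) {
          res.trace_u.push_back(u);
          res.trace_from.push_back(c);
          res.trace_to.push_back(best);
          res.trace_gain.push_back(g_best - g_stay);
        }
        if (csize[c] == 0) freelab.push_back(c);
      }
      lab[u] = best;
      csize[best]++;
      for (size_t a = 0; a < g.lstr[u].size(); ++a)
        K[(ll)best * 1000000 + g.lstr[u][a].first] += g.lstr[u][a].second;
    }
  }
  return res;
}

// exact Q numerator on a graph given labels:
// 2 * sum_{edges in same community} w + 2 * selfw
//   - gamma * sum_l (1/lt[l]) * sum_c K_cl^2       (lt[l] = 2 m_l)
double q_numerator(const Graph& g, const std::vector<int>& lab,
                   const std::vector<double>& lt, double gamma) {
  double num = 0.0;
  for (int u = 0; u < g.M; ++u) {
    num += 2.0 * g.selfw[u];
    for (size_t a = 0; a < g.adj[u].size(); ++a) {
      int v = g.adj[u][a].first;
      if (v > u && lab[v] == lab[u]) num += 2.0 * g.adj[u][a].second;
    }
  }
  std::unordered_map<ll,double> K;
  for (int u = 0; u < g.M; ++u)
    for (size_t a = 0; a < g.lstr[u].size(); ++a)
      K[(ll)lab[u] * 1000000 + g.lstr[u][a].first] += g.lstr[u][a].second;
  for (std::unordered_map<ll,double>::iterator it = K.begin(); it != K.end();
       ++it) {
    int l = (int)(it->first % 1000000);
    if (lt[l] > 0.0) num -= gamma * it->second * it->second / lt[l];
  }
  return num;
}

Graph aggregate(const Graph& g, const std::vector<int>& lab, int ncomm) {
  Graph h;
  h.M = ncomm;
  h.adj.assign(ncomm, std::vector<std::pair<int,double> >());
  h.selfw.assign(ncomm, 0.0);
  h.lstr.assign(ncomm, std::vector<std::pair<int,double> >());
  std::vector<std::unordered_map<int,double> > eh(ncomm), sh(ncomm);
  for (int u = 0; u < g.M; ++u) {
    int cu = lab[u];
    h.selfw[cu] += g.selfw[u];
    for (size_t a = 0; a < g.lstr[u].size(); ++a)
      sh[cu][g.lstr[u][a].first] += g.lstr[u][a].second;
    for (size_t a = 0; a < g.adj[u].size(); ++a) {
      int v = g.adj[u][a].first;
      if (v <= u) continue;
      int cv = lab[v];
      if (cu == cv) h.selfw[cu] += g.adj[u][a].second;
      else {
        eh[cu][cv] += g.adj[u][a].second;
        eh[cv][cu] += g.adj[u][a].second;
      }
    }
  }
  for (int c = 0; c < ncomm; ++c) {
    for (std::unordered_map<int,double>::iterator it = eh[c].begin();
         it != eh[c].end(); ++it)
      h.adj[c].push_back(std::make_pair(it->first, it->second));
    for (std::unordered_map<int,double>::iterator it = sh[c].begin();
         it != sh[c].end(); ++it)
      h.lstr[c].push_back(std::make_pair(it->first, it->second));
  }
  return h;
}

int relabel(std::vector<int>& lab) {
  std::unordered_map<int,int> map;
  int next = 0;
  for (size_t u = 0; u < lab.size(); ++u) {
    std::unordered_map<int,int>::iterator it = map.find(lab[u]);
    if (it == map.end()) { map[lab[u]] = next; lab[u] = next++; }
    else lab[u] = it->second;
  }
  return next;
}

Graph build_level0(const IntegerVector& ei, const IntegerVector& ej,
                   const IntegerVector& es, const NumericVector& ew,
                   int N, int T, double omega,
                   std::vector<double>& lt) {
  Graph g;
  g.M = N * T;
  g.adj.assign(g.M, std::vector<std::pair<int,double> >());
  g.selfw.assign(g.M, 0.0);
  g.lstr.assign(g.M, std::vector<std::pair<int,double> >());
  std::vector<double> k((size_t)N * T, 0.0);
  lt.assign(T, 0.0);
  for (int e = 0; e < ei.size(); ++e) {
    int s = es[e] - 1;
    int u = (ei[e] - 1) + N * s, v = (ej[e] - 1) + N * s;
    double w = ew[e];
    g.adj[u].push_back(std::make_pair(v, w));
    g.adj[v].push_back(std::make_pair(u, w));
    k[u] += w; k[v] += w;
    lt[s] += 2.0 * w;
  }
  if (omega > 0.0) {
    for (int s = 0; s + 1 < T; ++s)
      for (int i = 0; i < N; ++i) {
        int u = i + N * s, v = i + N * (s + 1);
        g.adj[u].push_back(std::make_pair(v, omega));
        g.adj[v].push_back(std::make_pair(u, omega));
      }
  }
  for (int u = 0; u < g.M; ++u)
    if (k[u] > 0.0)
      g.lstr[u].push_back(std::make_pair(u / N, k[u]));
  return g;
}

double two_mu(const std::vector<double>& lt, int N, int T, double omega) {
  double s = 0.0;
  for (size_t l = 0; l < lt.size(); ++l) s += lt[l];
  s += 2.0 * omega * (double)N * (T - 1);
  return s;
}

} // namespace

// one full multi-level pass starting from the given labels
static void louvain_pass(const Graph& g0, const std::vector<double>& lt,
                         double gamma, std::mt19937_64& rng,
                         std::vector<int>& full_lab) {
  int ncomm0 = relabel(full_lab);
  Graph g = aggregate(g0, full_lab, ncomm0);
  std::vector<int> lab(g.M);
  for (int u = 0; u < g.M; ++u) lab[u] = u;
  for (int level = 0; level < 100; ++level) {
    MoveResult mr = move_phase(g, lab, lt, gamma, rng, false);
    int ncomm = relabel(lab);
    for (size_t u = 0; u < full_lab.size(); ++u)
      full_lab[u] = lab[full_lab[u]];
    if (!mr.any_move || ncomm == g.M) break;
    g = aggregate(g, lab, ncomm);
    lab.assign(g.M, 0);
    for (int u = 0; u < g.M; ++u) lab[u] = u;
  }
}

// [[Rcpp::export]]
List cpp_multilayer_louvain(IntegerVector ei, IntegerVector ej,
                            IntegerVector es, NumericVector ew, int N, int T,
                            double gamma, double omega, int seed) {
  std::vector<double> lt;
  Graph g0 = build_level0(ei, ej, es, ew, N, T, omega, lt);
  std::mt19937_64 rng((uint64_t)seed);
  double tm = two_mu(lt, N, T, omega);

  std::vector<int> full_lab(g0.M);
  for (int u = 0; u < g0.M; ++u) full_lab[u] = u;

  // iterate full passes, each refining the previous labels at the finest
  // level, until Q stops improving
  double Q = -1e300;
  for (int it = 0; it < 30; ++it) {
    louvain_pass(g0, lt, gamma, rng, full_lab);
    double q = tm > 0 ? q_numerator(g0, full_lab, lt, gamma) / tm : 0.0;
    if (q <= Q + 1e-12) { Q = q; break; }
    Q = q;
  }

  relabel(full_lab);

  IntegerMatrix labels(N, T);
  for (int s = 0; s < T; ++s)
    for (int i = 0; i < N; ++i)
      labels(i, s) = full_lab[i + N * s] + 1;
  return List::create(_["labels"] = labels, _["Q"] = Q);
}

// single move phase from given labels, with a move trace (for validating
// that incremental gains match full re-evaluation of Q)
// [[Rcpp::export]]
List cpp_move_phase(IntegerVector ei, IntegerVector ej, IntegerVector es,
                    NumericVector ew, int N, int T, double gamma,
                    double omega, int seed, IntegerMatrix init_labels) {
  std::vector<double> lt;
  Graph g0 = build_level0(ei, ej, es, ew, N, T, omega, lt);
  std::mt19937_64 rng((uint64_t)seed);
  std::vector<int> lab(g0.M);
  for (int s = 0; s < T; ++s)
    for (int i = 0; i < N; ++i)
      lab[i + N * s] = init_labels(i, s) - 1;
  double tm = two_mu(lt, N, T, omega);
  double q0 = tm > 0 ? q_numerator(g0, lab, lt, gamma) / tm : 0.0;
  MoveResult mr = move_phase(g0, lab, lt, gamma, rng, true);
  double q1 = tm > 0 ? q_numerator(g0, lab, lt, gamma) / tm : 0.0;
  IntegerMatrix labels(N, T);
  for (int s = 0; s < T; ++s)
    for (int i = 0; i < N; ++i)
      labels(i, s) = lab[i + N * s] + 1;
  int nm = (int)mr.trace_u.size();
  IntegerVector tu(nm), tf(nm), tt(nm);
  NumericVector tg(nm);
  for (int k = 0; k < nm; ++k) {
    tu[k] = mr.trace_u[k] + 1; tf[k] = mr.trace_from[k] + 1;
    tt[k] = mr.trace_to[k] + 1;
    tg[k] = tm > 0 ? 2.0 * mr.trace_gain[k] / tm : 0.0;
  }
  return List::create(_["labels"] = labels, _["Q_before"] = q0,
                      _["Q_after"] = q1,
                      _["moves"] = List::create(_["node"] = tu,
                                                _["from"] = tf, _["to"] = tt,
                                                _["dQ"] = tg));
}
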