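#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Character states are bitmasks; a missing state is the full mask, so it never
// forces a union (equivalent to excluding it from the parsimony count).

// Fitch count on a rooted binary tree given as an ape-style postorder edge
// matrix (1-based node ids; tips 1..ntip).  states: ntip x nchar bitmasks.
// [[Rcpp::export(name = ".fitch_count")]]
double fitch_count_tree(IntegerMatrix edge, int ntip,
                        IntegerMatrix states, NumericVector weights) {
  const int nchar = states.ncol();
  const int nnode_tot = max(edge) ;
  std::vector<int> set((size_t)nnode_tot * nchar, 0);
  std::vector<double> changes(nchar, 0.0);
  for (int t = 0; t < ntip; ++t)
    for (int c = 0; c < nchar; ++c)
      set[(size_t)t * nchar + c] = states(t, c);
  for (int e = 0; e < edge.nrow(); ++e) {
    int p = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    for (int c = 0; c < nchar; ++c) {
      int sc = set[(size_t)ch * nchar + c];
      int &sp = set[(size_t)p * nchar + c];
      if (sp == 0) sp = sc;
      else {
        int inter = sp & sc;
        if (inter) sp = inter;
        else { sp |= sc; changes[c] += 1.0; }
      }
    }
  }
  double total = 0.0;
  for (int c = 0; c < nchar; ++c) total += changes[c] * weights[c];
  return total;
}

// ---- unrooted tree search over taxon-addition space ------------------------
//
// Internal representation during search: tips are 0..ntax-1 (rows of
// `states`), internal nodes ntax, ntax+1, ...  All internal nodes have degree
// 3, so rooting on the edge incident to tip 0 gives a binary rooted tree and
// Fitch is exact.

struct SearchCtx {
  int ntax, nchar;
  const int *states;            // ntax x nchar, row-major by tip
  const double *weights;
  std::vector<int> eu, ev;      // edge endpoints, length grows to 2*ntax-3
  int nedge;
  // scratch
  std::vector<int> adj;         // adjacency (node -> up to 3 neighbours)
  std::vector<int> deg, order, parent, fset;
  double best;
  std::vector<int> best_eu, best_ev;
  long long n_scored;
  bool bound;                   // branch-and-bound pruning on partial trees
  // lower-bound bookkeeping: a character that varies in the full taxon
  // set but is still constant among the placed taxa must cost at least
  // one more step when the remaining taxa are added
  std::vector<int> npres, nabs; // placed-taxon state counts per character
  std::vector<char> overall_var;
  double future_lb;

  double char_future(int c) const {
    return (overall_var[c] && (npres[c] == 0 || nabs[c] == 0))
               ? weights[c] : 0.0;
  }
  void place_taxon(int t, int dir) {  // dir = +1 add, -1 remove
    for (int c = 0; c < nchar; ++c) {
      int s = states[(size_t)t * nchar + c];
      if (s != 1 && s != 2) continue;
      future_lb -= char_future(c);
      if (s == 2) npres[c] += dir; else nabs[c] += dir;
      future_lb += char_future(c);
    }
  }
};

static double score_current(SearchCtx &S) {
  int maxnode = 0;
  for (int e = 0; e < S.nedge; ++e)
    maxnode = std::max(maxnode, std::max(S.eu[e], S.ev[e]));
  int nn = maxnode + 1;
  S.adj.assign((size_t)nn * 3, -1);
  S.deg.assign(nn, 0);
  for (int e = 0; e < S.nedge; ++e) {
    int a = S.eu[e], b = S.ev[e];
    S.adj[(size_t)a * 3 + S.deg[a]++] = b;
    S.adj[(size_t)b * 3 + S.deg[b]++] = a;
  }
  // iterative DFS from tip 0 (its single neighbour acts as root child)
  S.parent.assign(nn, -2);
  S.order.clear(); S.order.reserve(nn);
  std::vector<int> stack; stack.push_back(0); S.parent[0] = -1;
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    S.order.push_back(u);
    for (int k = 0; k < S.deg[u]; ++k) {
      int v = S.adj[(size_t)u * 3 + k];
      if (v != S.parent[u]) { S.parent[v] = u; stack.push_back(v); }
    }
  }
  // postorder = reverse of preorder; sequential Fitch combine into parents
  const int nchar = S.nchar;
  S.fset.assign((size_t)nn * nchar, 0);
  for (int u : S.order) {
    if (u < S.ntax)
      for (int c = 0; c < nchar; ++c)
        S.fset[(size_t)u * nchar + c] = S.states[(size_t)u * nchar + c];
  }
  std::vector<double> changes(nchar, 0.0);
  for (int idx = (int)S.order.size() - 1; idx >= 0; --idx) {
    int u = S.order[idx], p = S.parent[u];
    if (p < 0) continue;
    for (int c = 0; c < nchar; ++c) {
      int sc = S.fset[(size_t)u * nchar + c];
      int &sp = S.fset[(size_t)p * nchar + c];
      if (sp == 0) sp = sc;
      else {
        int inter = sp & sc;
        if (inter) sp = inter;
        else { sp |= sc; changes[c] += 1.0; }
      }
    }
  }
  double total = 0.0;
  for (int c = 0; c < nchar; ++c) total += changes[c] * S.weights[c];
  return total;
}

static void search_rec(SearchCtx &S, int next_taxon) {
  if (next_taxon == S.ntax) {
    double sc = score_current(S);
    ++S.n_scored;
    if (sc < S.best) {
      S.best = sc;
      S.best_eu.assign(S.eu.begin(), S.eu.begin() + S.nedge);
      S.best_ev.assign(S.ev.begin(), S.ev.begin() + S.nedge);
    }
    return;
  }
  if (S.bound) {
    // partial length plus the future cost of characters not yet
    // variable among the placed taxa is a valid lower bound
    double sc = score_current(S) + S.future_lb;
    if (sc >= S.best) return;
  }
  int newnode = S.ntax + (next_taxon - 2);  // internal node id for this level
  int ne = S.nedge;
  S.place_taxon(next_taxon, +1);
  for (int e = 0; e < ne; ++e) {
    int u = S.eu[e], v = S.ev[e];
    // split edge e: (u,w) replaces it, add (w,v) and (w,t)
    S.eu[e] = u; S.ev[e] = newnode;
    S.eu[ne] = newnode; S.ev[ne] = v;
    S.eu[ne + 1] = newnode; S.ev[ne + 1] = next_taxon;
    S.nedge = ne + 2;
    search_rec(S, next_taxon + 1);
    S.nedge = ne;
    S.eu[e] = u; S.ev[e] = v;
  }
  S.place_taxon(next_taxon, -1);
}

static List run_search(IntegerMatrix states, NumericVector weights, bool bound,
                       double upper) {
  int ntax = states.nrow(), nchar = states.ncol();
  if (ntax < 2) stop("need at least 2 taxa");
  SearchCtx S;
  S.ntax = ntax; S.nchar = nchar;
  std::vector<int> st((size_t)ntax * nchar);
  for (int i = 0; i < ntax; ++i)
    for (int c = 0; c < nchar; ++c) st[(size_t)i * nchar + c] = states(i, c);
  S.states = st.data();
  std::vector<double> w(weights.begin(), weights.end());
  S.weights = w.data();
  int maxedge = 2 * ntax - 3 + 2;
  S.eu.assign(maxedge, -1); S.ev.assign(maxedge, -1);
  S.best = upper; S.n_scored = 0; S.bound = bound;
  S.npres.assign(nchar, 0); S.nabs.assign(nchar, 0);
  S.overall_var.assign(nchar, 0);
  for (int c = 0; c < nchar; ++c) {
    bool p = false, a = false;
    for (int t = 0; t < ntax; ++t) {
      int st_ = S.states[(size_t)t * nchar + c];
      if (st_ == 2) p = true; else if (st_ == 1) a = true;
    }
    S.overall_var[c] = (p && a);
  }
  // with no taxa placed every globally variable character is still
  // pending, so the bound starts at the full variable-character total
  S.future_lb = 0.0;
  for (int c = 0; c < nchar; ++c) S.future_lb += S.char_future(c);
  if (ntax == 2) {
    S.eu[0] = 0; S.ev[0] = 1; S.nedge = 1;
    double sc = score_current(S);
    return List::create(_["score"] = sc,
                        _["edge_u"] = IntegerVector::create(0),
                        _["edge_v"] = IntegerVector::create(1),
                        _["n_scored"] = 1.0);
  }
  if (ntax == 3) {
    S.eu[0] = 0; S.ev[0] = ntax; S.eu[1] = 1; S.ev[1] = ntax;
    S.eu[2] = 2; S.ev[2] = ntax; S.nedge = 3;
    // rooted-on-tip-0 view is binary; score directly
    double sc = score_current(S);
    return List::create(_["score"] = sc,
                        _["edge_u"] = IntegerVector(S.eu.begin(), S.eu.begin() + 3),
                        _["edge_v"] = IntegerVector(S.ev.begin(), S.ev.begin() + 3),
                        _["n_scored"] = 1.0);
  }
  S.eu[0] = 0; S.ev[0] = ntax; S.eu[1] = 1; S.ev[1] = ntax;
  S.eu[2] = 2; S.ev[2] = ntax; S.nedge = 3;
  for (int t = 0; t < 3; ++t) S.place_taxon(t, +1);
  // seed the lower-bound bookkeeping for the initial 3-taxon star
  search_rec(S, 3);
  if (S.best_eu.empty()) stop("no tree beat the supplied upper bound");
  return List::create(_["score"] = S.best,
                      _["edge_u"] = IntegerVector(S.best_eu.begin(), S.best_eu.end()),
                      _["edge_v"] = IntegerVector(S.best_ev.begin(), S.best_ev.end()),
                      _["n_scored"] = (double)S.n_scored);
}

// Exhaustive enumeration of all unrooted topologies (oracle; no pruning).
// [[Rcpp::export(name = ".exhaustive_parsimony")]]
List exhaustive_parsimony(IntegerMatrix states, NumericVector weights) {
  return run_search(states, weights, false, R_PosInf);
}

// Branch-and-bound exact search; `upper` is an initial upper bound
// (e.g. from a heuristic tree), Inf if unknown.
// [[Rcpp::export(name = ".bb_parsimony")]]
List bb_parsimony(IntegerMatrix states, NumericVector weights, double upper) {
  return run_search(states, weights, true, upper + 1e-9);
}
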