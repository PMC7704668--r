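#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include "hky.h"
using namespace Rcpp;

// Bayesian skyline plot MCMC: piecewise-constant coalescent prior over a
// tip-dated genealogy (times in years before present), HKY(+Gamma) sequence
// likelihood, Metropolis-Hastings moves over node times, topology
// (Wilson-Balding regraft + narrow exchange), per-group population sizes
// (N_f x generation time, in years), kappa, Gamma shape and clock rate.

namespace {

struct Chain {
  int ntip, nnode, root;
  std::vector<int> parent, left, right;
  std::vector<double> time;            // node times, YBP
  std::vector<double> theta;           // per-group pop size (years)
  double kappa, alpha, rate;

  // data
  const int *tipcode; int npat;
  std::vector<double> wts, pi;
  std::vector<double> tip_sorted;      // tip times ascending
  std::vector<int> gsize, gcum;        // skyline groups over n-1 coal events
  int ncat;

  // scratch
  std::vector<int> pre, postu;
  std::vector<double> partial, logscale, logLcat, ct;
  std::vector<char> seen;

  void build_order() {
    pre.clear();
    std::vector<int> stack{root};
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      pre.push_back(u);
      if (left[u] >= 0) { stack.push_back(left[u]); stack.push_back(right[u]); }
    }
    postu.assign(pre.rbegin(), pre.rend());
  }

  double gamma_rates(double *r, double *w) const {
    if (ncat <= 1) { r[0] = 1.0; w[0] = 1.0; return 1.0; }
    for (int k = 0; k < ncat; ++k) w[k] = 1.0 / ncat;
    double prev = 0.0;
    for (int k = 0; k < ncat; ++k) {
      double q = (k == ncat - 1)
                     ? R_PosInf
                     : R::qgamma((k + 1.0) / ncat, alpha, 1.0 / alpha, 1, 0);
      double hi = (k == ncat - 1) ? 1.0
                                  : R::pgamma(q, alpha + 1.0, 1.0 / alpha, 1, 0);
      r[k] = ncat * (hi - prev);
      prev = hi;
    }
    return 1.0;
  }

  double seq_loglik() {
    build_order();
    std::vector<double> crate(ncat > 0 ? ncat : 1), cw(ncat > 0 ? ncat : 1);
    int nc = ncat > 1 ? ncat : 1;
    gamma_rates(crate.data(), cw.data());
    HKY mod; mod.set(pi.data(), kappa);
    partial.assign((size_t)nnode * npat * 4, 0.0);
    logLcat.assign((size_t)nc * npat, 0.0);
    double P[16];
    for (int c = 0; c < nc; ++c) {
      logscale.assign(npat, 0.0);
      seen.assign(nnode, 0);
      for (int t = 0; t < ntip; ++t)
        for (int s = 0; s < npat; ++s) {
          int code = tipcode[(size_t)t * npat + s];
          double *pp = &partial[((size_t)t * npat + s) * 4];
          pp[0] = (code & 1) ? 1.0 : 0.0;
          pp[1] = (code & 2) ? 1.0 : 0.0;
          pp[2] = (code & 4) ? 1.0 : 0.0;
          pp[3] = (code & 8) ? 1.0 : 0.0;
        }
      for (int u : postu) {
        if (u == root) continue;
        int pa = parent[u];
        double bl = rate * (time[pa] - time[u]) * crate[c];
        mod.pmat(bl, P);
        if (!seen[pa]) {
          seen[pa] = 1;
          for (int s = 0; s < npat; ++s) {
            double *pp = &partial[((size_t)pa * npat + s) * 4];
            pp[0] = pp[1] = pp[2] = pp[3] = 1.0;
          }
        }
        for (int s = 0; s < npat; ++s) {
          const double *pc = &partial[((size_t)u * npat + s) * 4];
          double *pp = &partial[((size_t)pa * npat + s) * 4];
          for (int i = 0; i < 4; ++i)
            pp[i] *= P[i * 4 + 0] * pc[0] + P[i * 4 + 1] * pc[1] +
                     P[i * 4 + 2] * pc[2] + P[i * 4 + 3] * pc[3];
          double mx = std::max(std::max(pp[0], pp[1]),
                               std::max(pp[2], pp[3]));
          if (mx < 1e-200 && mx > 0) {
            for (int i = 0; i < 4; ++i) pp[i] /= mx;
            logscale[s] += std::log(mx);
          }
        }
      }
      for (int s = 0; s < npat; ++s) {
        const double *pr = &partial[((size_t)root * npat + s) * 4];
        double lik = pi[0] * pr[0] + pi[1] * pr[1] + pi[2] * pr[2] +
                     pi[3] * pr[3];
        logLcat[(size_t)c * npat + s] =
            (lik > 0 ? std::log(lik) : -1e308) + logscale[s];
      }
    }
    double total = 0.0;
    for (int s = 0; s < npat; ++s) {
      double mx = -1e308;
      for (int c = 0; c < nc; ++c)
        mx = std::max(mx, logLcat[(size_t)c * npat + s]);
      double acc = 0.0;
      for (int c = 0; c < nc; ++c)
        acc += cw[c] * std::exp(logLcat[(size_t)c * npat + s] - mx);
      total += wts[s] * (mx + std::log(acc));
    }
    return total;
  }

  // piecewise-constant heterochronous coalescent log density
  double coal_logprior() {
    ct.clear();
    for (int u = ntip; u < nnode; ++u) ct.push_back(time[u]);
    std::sort(ct.begin(), ct.end());
    int nc = (int)ct.size();
    double logp = 0.0;
    size_t is = 0; int ic = 0, k = 0;
    double tcur = tip_sorted[0];
    while (is < tip_sorted.size() && tip_sorted[is] <= tcur) { ++k; ++is; }
    while (ic < nc) {
      int g = gcum_group(ic);
      double th = theta[g];
      double tnext_s = is < tip_sorted.size() ? tip_sorted[is] : R_PosInf;
      double tnext = std::min(tnext_s, ct[ic]);
      logp -= 0.5 * k * (k - 1) * (tnext - tcur) / th;
      tcur = tnext;
      if (tnext_s <= ct[ic]) { ++k; ++is; }
      else {
        logp -= std::log(th);
        --k; ++ic;
        if (k < 1) return -1e308;
      }
    }
    return logp;
  }
  int gcum_group(int coal_index) const {
    for (size_t g = 0; g < gcum.size(); ++g)
      if (coal_index < gcum[g]) return (int)g;
    return (int)gcum.size() - 1;
  }

  bool in_subtree(int j, int i) const {
    while (j >= 0) { if (j == i) return true; j = parent[j]; }
    return false;
  }
  int sibling(int u) const {
    int p = parent[u];
    return left[p] == u ? right[p] : left[p];
  }
};

}  // namespace

// [[Rcpp::export(name = ".skyline_mcmc")]]
List skyline_mcmc(IntegerMatrix tipcode, NumericVector wts, NumericVector pi,
                  NumericVector tip_times, IntegerVector parent0,
                  IntegerVector left0, IntegerVector right0,
                  NumericVector time0, NumericVector theta0, double kappa0,
                  double alpha0, double rate0, IntegerVector group_sizes,
                  int ncat, List priors, NumericVector move_weights,
                  double chain_length, double thin, bool use_data) {
  Chain C;
  C.ntip = tipcode.nrow();
  C.npat = tipcode.ncol();
  C.nnode = 2 * C.ntip - 1;
  C.parent.assign(parent0.begin(), parent0.end());
  C.left.assign(left0.begin(), left0.end());
  C.right.assign(right0.begin(), right0.end());
  C.time.assign(time0.begin(), time0.end());
  C.root = -1;
  for (int u = 0; u < C.nnode; ++u) if (C.parent[u] < 0) C.root = u;
  C.theta.assign(theta0.begin(), theta0.end());
  C.kappa = kappa0; C.alpha = alpha0; C.rate = rate0;
  std::vector<int> tc((size_t)C.ntip * C.npat);
  for (int t = 0; t < C.ntip; ++t)
    for (int s = 0; s < C.npat; ++s) tc[(size_t)t * C.npat + s] = tipcode(t, s);
  C.tipcode = tc.data();
  C.wts.assign(wts.begin(), wts.end());
  C.pi.assign(pi.begin(), pi.end());
  C.tip_sorted.assign(tip_times.begin(), tip_times.end());
  std::sort(C.tip_sorted.begin(), C.tip_sorted.end());
  C.gsize.assign(group_sizes.begin(), group_sizes.end());
  C.gcum.resize(C.gsize.size());
  int acc_ = 0;
  for (size_t g = 0; g < C.gsize.size(); ++g) {
    acc_ += C.gsize[g]; C.gcum[g] = acc_;
  }
  C.ncat = ncat;

  const double th_lo = priors["theta_lo"], th_hi = priors["theta_hi"];
  const double kap_max = priors["kappa_max"];
  const double r_lo = priors["rate_lo"], r_hi = priors["rate_hi"];
  const double alpha_rate = priors["alpha_rate"];
  const int m = (int)C.theta.size();

  auto param_logprior = [&](void) -> double {
    double lp = 0.0;
    for (int g = 0; g < m; ++g) {
      if (C.theta[g] < th_lo || C.theta[g] > th_hi) return -1e308;
      lp -= std::log(C.theta[g]);
    }
    if (C.kappa <= 0 || C.kappa > kap_max) return -1e308;
    if (C.ncat > 1) {
      if (C.alpha <= 0) return -1e308;
      lp -= alpha_rate * C.alpha;
    }
    if (C.rate < r_lo || C.rate > r_hi) return -1e308;
    lp -= std::log(C.rate);
    return lp;
  };

  double cur_like = use_data ? C.seq_loglik() : 0.0;
  double cur_coal = C.coal_logprior();
  double cur_parp = param_logprior();
  if (cur_coal < -1e307 || cur_parp < -1e307)
    stop("invalid initial state (check tip dates, priors and init values)");

  const int NMOVE = 10;
  std::vector<double> mw(move_weights.begin(), move_weights.end());
  double wsum = 0; for (double w : mw) wsum += w;
  std::vector<double> mcum(NMOVE);
  double a = 0;
  for (int i = 0; i < NMOVE; ++i) { a += mw[i] / wsum; mcum[i] = a; }
  std::vector<double> n_prop(NMOVE, 0.0), n_acc(NMOVE, 0.0);

  long long niter = (long long)chain_length;
  int nthin = (int)thin;
  int nsamp = (int)(niter / nthin);
  NumericMatrix out_theta(nsamp, m), out_coal(nsamp, C.ntip - 1);
  NumericVector out_kappa(nsamp), out_alpha(nsamp), out_rate(nsamp),
      out_like(nsamp), out_prior(nsamp);
  int isamp = 0;

  std::vector<int> eligible, cand;
  for (long long it = 1; it <= niter; ++it) {
    double u01 = unif_rand();
    int mv = 0;
    while (mv < NMOVE - 1 && u01 > mcum[mv]) ++mv;
    n_prop[mv] += 1;

    bool need_like = false, need_coal = false, need_parp = false;
    double logH = 0.0;
    // save-state (shallow; restored on reject)
    std::vector<int> sp, sl, sr;
    std::vector<double> stime;
    double skappa = C.kappa, salpha = C.alpha, srate = C.rate;
    std::vector<double> stheta = C.theta;
    bool tree_changed = false;
    bool ok = true;

    switch (mv) {
      case 0: {  // internal non-root node time, uniform in its bracket
        if (C.ntip < 3) { ok = false; break; }
        int u = C.ntip + (int)(unif_rand() * (C.ntip - 1));
        if (u == C.root || u >= C.nnode) { ok = false; break; }
        double lo = std::max(C.time[C.left[u]], C.time[C.right[u]]);
        double hi = C.time[C.parent[u]];
        if (hi <= lo) { ok = false; break; }
        stime = C.time; tree_changed = true;
        C.time[u] = lo + unif_rand() * (hi - lo);
        need_like = use_data; need_coal = true;
        break;
      }
      case 1: {  // root height multiplier on (t_root - max child)
        double mc = std::max(C.time[C.left[C.root]], C.time[C.right[C.root]]);
        double f = std::exp(1.0 * (unif_rand() - 0.5));
        stime = C.time; tree_changed = true;
        C.time[C.root] = mc + (C.time[C.root] - mc) * f;
        logH = std::log(f);
        need_like = use_data; need_coal = true;
        break;
      }
      case 2: {  // narrow exchange: swap node with its uncle
        eligible.clear();
        for (int u = 0; u < C.nnode; ++u)
          if (u != C.root && C.parent[u] >= 0 && C.parent[u] != C.root &&
              C.parent[C.parent[u]] >= 0)
            eligible.push_back(u);
        if (eligible.empty()) { ok = false; break; }
        int aN = eligible[(int)(unif_rand() * eligible.size())];
        int p = C.parent[aN], g = C.parent[p];
        int b = (C.left[g] == p) ? C.right[g] : C.left[g];
        if (C.time[p] <= C.time[b]) { ok = false; break; }
        sp = C.parent; sl = C.left; sr = C.right; tree_changed = true;
        // swap a and b
        if (C.left[p] == aN) C.left[p] = b; else C.right[p] = b;
        if (C.left[g] == b) C.left[g] = aN; else C.right[g] = aN;
        C.parent[aN] = g; C.parent[b] = p;
        need_like = use_data; need_coal = true;
        break;
      }
      case 3: {  // Wilson-Balding subtree regraft
        eligible.clear();
        for (int u = 0; u < C.nnode; ++u)
          if (u != C.root && C.parent[u] >= 0 && C.parent[u] != C.root)
            eligible.push_back(u);
        if (eligible.empty()) { ok = false; break; }
        int i = eligible[(int)(unif_rand() * eligible.size())];
        int p = C.parent[i], g = C.parent[p], s = C.sibling(i);
        // candidates j in the residual tree (p excised, subtree(i) removed)
        cand.clear();
        for (int j = 0; j < C.nnode; ++j) {
          if (j == p || C.in_subtree(j, i)) continue;
          int pj = C.parent[j];
          if (pj == p) pj = g;
          if (pj < 0) continue;  // residual root
          if (C.time[pj] > C.time[i]) cand.push_back(j);
        }
        if (cand.empty()) { ok = false; break; }
        int j = cand[(int)(unif_rand() * cand.size())];
        double range_old = C.time[g] - std::max(C.time[i], C.time[s]);
        sp = C.parent; sl = C.left; sr = C.right; stime = C.time;
        tree_changed = true;
        // excise p: g adopts s
        if (C.left[g] == p) C.left[g] = s; else C.right[g] = s;
        C.parent[s] = g;
        // attach p above j
        int pj = C.parent[j];
        if (C.left[pj] == j) C.left[pj] = p; else C.right[pj] = p;
        C.parent[p] = pj;
        C.left[p] = i; C.right[p] = j; C.parent[j] = p;
        double lo = std::max(C.time[i], C.time[j]);
        double range_new = C.time[pj] - lo;
        C.time[p] = lo + unif_rand() * range_new;
        logH = std::log(range_new) - std::log(range_old);
        need_like = use_data; need_coal = true;
        break;
      }
      case 4: {  // theta scale
        int g = (int)(unif_rand() * m);
        double f = std::exp(1.2 * (unif_rand() - 0.5));
        C.theta[g] *= f;
        logH = std::log(f);
        need_parp = true; need_coal = true;
        break;
      }
      case 5: {  // kappa scale
        double f = std::exp(1.0 * (unif_rand() - 0.5));
        C.kappa *= f; logH = std::log(f);
        need_parp = true; need_like = use_data;
        break;
      }
      case 6: {  // alpha scale
        double f = std::exp(1.4 * (unif_rand() - 0.5));
        C.alpha *= f; logH = std::log(f);
        need_parp = true; need_like = use_data;
        break;
      }
      case 7: {  // clock rate scale
        double f = std::exp(1.0 * (unif_rand() - 0.5));
        C.rate *= f; logH = std::log(f);
        need_parp = true; need_like = use_data;
        break;
      }
      case 8: {  // scale all internal node times
        double f = std::exp(0.4 * (unif_rand() - 0.5));
        stime = C.time; tree_changed = true;
        bool valid = true;
        for (int u = C.ntip; u < C.nnode; ++u) C.time[u] *= f;
        for (int u = C.ntip; u < C.nnode; ++u) {
          if (C.time[u] < C.time[C.left[u]] || C.time[u] < C.time[C.right[u]])
            valid = false;
        }
        if (!valid) { C.time = stime; ok = false; break; }
        logH = (C.ntip - 1) * std::log(f);
        need_like = use_data; need_coal = true;
        break;
      }
      case 9: {  // rate-times tradeoff: r *= f, internal times /= f
        double f = std::exp(0.6 * (unif_rand() - 0.5));
        stime = C.time; srate = C.rate; tree_changed = true;
        bool valid = true;
        for (int u = C.ntip; u < C.nnode; ++u) C.time[u] /= f;
        for (int u = C.ntip; u < C.nnode; ++u) {
          if (C.time[u] < C.time[C.left[u]] || C.time[u] < C.time[C.right[u]])
            valid = false;
        }
        if (!valid) { C.time = stime; ok = false; break; }
        C.rate *= f;
        // Jacobian of (r, t) -> (r f, t/f)
        logH = (2.0 - C.ntip) * std::log(f);
        // branch lengths in substitutions change only via tip times
        need_like = use_data; need_coal = true; need_parp = true;
        break;
      }
    }

    if (!ok) {
      // proposal impossible; count as rejected
    } else {
      double new_like = need_like ? C.seq_loglik() : cur_like;
      double new_coal = need_coal ? C.coal_logprior() : cur_coal;
      double new_parp = need_parp ? param_logprior() : cur_parp;
      double delta = (new_like + new_coal + new_parp) -
                     (cur_like + cur_coal + cur_parp) + logH;
      if (new_coal > -1e307 && new_parp > -1e307 &&
          std::log(unif_rand()) < delta) {
        cur_like = new_like; cur_coal = new_coal; cur_parp = new_parp;
        n_acc[mv] += 1;
      } else {
        // restore
        if (!sp.empty()) { C.parent = sp; C.left = sl; C.right = sr; }
        if (!stime.empty()) C.time = stime;
        C.kappa = skappa; C.alpha = salpha; C.rate = srate;
        C.theta = stheta;
        (void)tree_changed;
      }
    }

    if (it % nthin == 0 && isamp < nsamp) {
      for (int g = 0; g < m; ++g) out_theta(isamp, g) = C.theta[g];
      std::vector<double> ct;
      for (int u = C.ntip; u < C.nnode; ++u) ct.push_back(C.time[u]);
      std::sort(ct.begin(), ct.end());
      for (int k2 = 0; k2 < C.ntip - 1; ++k2) out_coal(isamp, k2) = ct[k2];
      out_kappa[isamp] = C.kappa; out_alpha[isamp] = C.alpha;
      out_rate[isamp] = C.rate; out_like[isamp] = cur_like;
      out_prior[isamp] = cur_coal + cur_parp;
      ++isamp;
    }
    if (it % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc_rate(NMOVE);
  for (int i = 0; i < NMOVE; ++i)
    acc_rate[i] = n_prop[i] > 0 ? n_acc[i] / n_prop[i] : NA_REAL;

  return List::create(
      _["theta"] = out_theta, _["coal_times"] = out_coal,
      _["kappa"] = out_kappa, _["alpha"] = out_alpha, _["rate"] = out_rate,
      _["loglik"] = out_like, _["logprior"] = out_prior,
      _["acceptance"] = acc_rate);
}
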