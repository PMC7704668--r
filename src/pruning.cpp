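#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "hky.h"
using namespace Rcpp;

// Felsenstein pruning log-likelihood under HKY (JC/K80 as special cases via
// pi and kappa) with an arbitrary discrete rate-category mixture.
//
// edge      : ape-style postorder edge matrix (1-based ids, tips 1..ntip)
// elen      : branch lengths (expected substitutions/site), one per edge row
// tipcode   : ntip x npat IUPAC bitmasks (A=1, C=2, G=4, T=8; N = 15)
// wts       : pattern weights (site counts)
// pi        : base frequencies (A, C, G, T)
// rates     : rate of each mixture category (may include 0 for invariant)
// rweights  : mixture weights, summing to 1
// [[Rcpp::export(name = ".pruning_loglik")]]
double pruning_loglik_cpp(IntegerMatrix edge, NumericVector elen, int ntip,
                          IntegerMatrix tipcode, NumericVector wts,
                          NumericVector pi, double kappa,
                          NumericVector rates, NumericVector rweights) {
  const int npat = tipcode.ncol();
  const int nedge = edge.nrow();
  const int ncat = rates.size();
  int nnode = 0;
  for (int e = 0; e < nedge; ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));
  const int root = edge(nedge - 1, 0) - 1;

  HKY mod;
  double p4[4] = {pi[0], pi[1], pi[2], pi[3]};
  mod.set(p4, kappa);

  // per-category per-pattern log-likelihood
  std::vector<double> logLcat((size_t)ncat * npat);
  std::vector<double> partial((size_t)nnode * npat * 4);
  std::vector<double> logscale(npat);
  std::vector<char> seen(nnode);
  double P[16];

  for (int c = 0; c < ncat; ++c) {
    std::fill(partial.begin(), partial.end(), 0.0);
    std::fill(logscale.begin(), logscale.end(), 0.0);
    std::fill(seen.begin(), seen.end(), 0);
    for (int t = 0; t < ntip; ++t)
      for (int s = 0; s < npat; ++s) {
        int code = tipcode(t, s);
        double *pp = &partial[((size_t)t * npat + s) * 4];
        pp[0] = (code & 1) ? 1.0 : 0.0;
        pp[1] = (code & 2) ? 1.0 : 0.0;
        pp[2] = (code & 4) ? 1.0 : 0.0;
        pp[3] = (code & 8) ? 1.0 : 0.0;
      }
    for (int e = 0; e < nedge; ++e) {
      int pa = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      mod.pmat(elen[e] * rates[c], P);
      if (!seen[pa]) {
        seen[pa] = 1;
        for (int s = 0; s < npat; ++s) {
          double *pp = &partial[((size_t)pa * npat + s) * 4];
          pp[0] = pp[1] = pp[2] = pp[3] = 1.0;
        }
      }
      for (int s = 0; s < npat; ++s) {
        const double *pc = &partial[((size_t)ch * npat + s) * 4];
        double *pp = &partial[((size_t)pa * npat + s) * 4];
        for (int i = 0; i < 4; ++i) {
          double sum = P[i * 4 + 0] * pc[0] + P[i * 4 + 1] * pc[1] +
                       P[i * 4 + 2] * pc[2] + P[i * 4 + 3] * pc[3];
          pp[i] *= sum;
        }
        double mx = std::max(std::max(pp[0], pp[1]), std::max(pp[2], pp[3]));
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
    for (int c = 0; c < ncat; ++c)
      mx = std::max(mx, logLcat[(size_t)c * npat + s]);
    double acc = 0.0;
    for (int c = 0; c < ncat; ++c)
      acc += rweights[c] * std::exp(logLcat[(size_t)c * npat + s] - mx);
    total += wts[s] * (mx + std::log(acc));
  }
  return total;
}
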