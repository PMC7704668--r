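#ifndef MITOHAP_HKY_H
#define MITOHAP_HKY_H

#include <cmath>

// HKY transition probabilities, closed form, with Q normalised so that branch
// length t is measured in expected substitutions per site.
// Base order: A=0, C=1, G=2, T=3; purines {A,G}, pyrimidines {C,T}.
struct HKY {
  double pi[4];
  double piR, piY, beta;
  void set(const double *p, double kappa_) {
    kappa = kappa_;
    for (int i = 0; i < 4; ++i) pi[i] = p[i];
    piR = pi[0] + pi[2];
    piY = pi[1] + pi[3];
    beta = 1.0 / (2.0 * kappa * (pi[0] * pi[2] + pi[1] * pi[3]) +
                  2.0 * piR * piY);
  }
  double kappa;
  // P[i*4+j] = P(j | i, t)
  void pmat(double t, double *P) const {
    if (t < 0) t = 0;
    double e2 = std::exp(-beta * t);
    for (int j = 0; j < 4; ++j) {
      double Pi = (j == 0 || j == 2) ? piR : piY;
      double e3 = std::exp(-beta * t * (Pi * kappa + 1.0 - Pi));
      double same = pi[j] + pi[j] * (1.0 / Pi - 1.0) * e2 +
                    ((Pi - pi[j]) / Pi) * e3;
      double within = pi[j] + pi[j] * (1.0 / Pi - 1.0) * e2 -
                      (pi[j] / Pi) * e3;
      double across = pi[j] * (1.0 - e2);
      for (int i = 0; i < 4; ++i) {
        bool ipur = (i == 0 || i == 2), jpur = (j == 0 || j == 2);
        double v;
        if (i == j) v = same;
        else if (ipur == jpur) v = within;
        else v = across;
        P[i * 4 + j] = v;
      }
    }
  }
};

#endif
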