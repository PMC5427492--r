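#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x * log(y) with 0 * log(0) == 0
static inline double xlogy(double x, double y) {
  if (x == 0.0) return 0.0;
  return x * std::log(y);
}

// EM fit of the site genotype-frequency mixture for one site.
//
// Data: per-individual counts of major-allele reads (nM), minor-allele
// reads (nm) and other reads (nE; both error categories share probability
// eps/3 for every genotype, so only their sum matters).  Model: each
// individual's quartet is multinomial given its genotype g in {MM, Mm, mm}
// with read probabilities
//   MM: P(M) = 1 - eps, P(m) = P(e) = eps/3
//   Mm: P(M) = P(m) = 1/2 - eps/3, P(e) = eps/3
//   mm: P(m) = 1 - eps, P(M) = P(e) = eps/3
// and genotypes are iid categorical(gamma).  The M-step for gamma is the
// mean responsibility; the M-step for eps maximises the expected
// complete-data log-likelihood
//   a ln(1 - eps) + B ln(eps/3) + c ln(1/2 - eps/3)
// whose stationary point solves
//   (2B + 2a + 2c) eps^2 - (5B + 3a + 2c) eps + 3B = 0
// (smaller root; the objective is concave in eps, so the root clamped to
// [0, 3/4] is the constrained maximiser).
//
// [[Rcpp::export]]
List gfe_em_fit(NumericVector nM, NumericVector nm, NumericVector nE,
                NumericVector gamma_init, double eps_init,
                double tol = 1e-12, int max_iter = 5000) {
  const int N = nM.size();
  double g1 = gamma_init[0], g2 = gamma_init[1], g3 = gamma_init[2];
  double eps = eps_init;
  double ll = R_NegInf, ll_old = R_NegInf;
  NumericVector r1(N), r2(N), r3(N);
  int iter = 0;
  bool converged = false;

  for (iter = 1; iter <= max_iter; ++iter) {
    // E-step at current (gamma, eps)
    const double lPM1 = std::log(1.0 - eps);
    const double lPe  = std::log(eps / 3.0);
    const double lP2  = std::log(0.5 - eps / 3.0);
    ll = 0.0;
    for (int i = 0; i < N; ++i) {
      const double cM = nM[i], cm = nm[i], cE = nE[i];
      // per-genotype log-likelihoods (0*log(0) handled)
      double l1 = (cM > 0 ? cM * lPM1 : 0.0) +
                  ((cm + cE) > 0 ? (cm + cE) * lPe : 0.0);
      double l2 = ((cM + cm) > 0 ? (cM + cm) * lP2 : 0.0) +
                  (cE > 0 ? cE * lPe : 0.0);
      double l3 = (cm > 0 ? cm * lPM1 : 0.0) +
                  ((cM + cE) > 0 ? (cM + cE) * lPe : 0.0);
      double lmax = std::max(l1, std::max(l2, l3));
      if (!std::isfinite(lmax)) lmax = 0.0;
      double w1 = (g1 > 0 && std::isfinite(l1)) ? g1 * std::exp(l1 - lmax) : 0.0;
      double w2 = (g2 > 0 && std::isfinite(l2)) ? g2 * std::exp(l2 - lmax) : 0.0;
      double w3 = (g3 > 0 && std::isfinite(l3)) ? g3 * std::exp(l3 - lmax) : 0.0;
      double s = w1 + w2 + w3;
      if (s <= 0.0) { // all genotypes impossible: should not happen
        w1 = w2 = w3 = 1.0 / 3.0; s = 1.0;
        ll += R_NegInf;
      } else {
        ll += lmax + std::log(s);
      }
      r1[i] = w1 / s; r2[i] = w2 / s; r3[i] = w3 / s;
    }
    if (std::isfinite(ll) && std::isfinite(ll_old) &&
        std::fabs(ll - ll_old) < tol) {
      converged = true;
      break;
    }
    ll_old = ll;

    // M-step
    double s1 = 0.0, s2 = 0.0, s3 = 0.0;
    double a = 0.0, b = 0.0, c = 0.0;
    for (int i = 0; i < N; ++i) {
      s1 += r1[i]; s2 += r2[i]; s3 += r3[i];
      a += r1[i] * nM[i] + r3[i] * nm[i];
      c += r2[i] * (nM[i] + nm[i]);
      b += r1[i] * (nm[i] + nE[i]) + r3[i] * (nM[i] + nE[i]) + r2[i] * nE[i];
    }
    const double tot = s1 + s2 + s3;
    g1 = s1 / tot; g2 = s2 / tot; g3 = s3 / tot;
    if (b <= 0.0) {
      eps = 0.0;
    } else {
      const double A2 = 2.0 * (b + a + c);
      const double A1 = 5.0 * b + 3.0 * a + 2.0 * c;
      double disc = A1 * A1 - 12.0 * b * A2;
      if (disc < 0.0) disc = 0.0;
      eps = (A1 - std::sqrt(disc)) / (2.0 * A2);
    }
    if (eps < 0.0) eps = 0.0;
    if (eps > 0.75) eps = 0.75;
  }

  // log-likelihood at the final parameters
  {
    const double lPM1 = std::log(1.0 - eps);
    const double lPe  = std::log(eps / 3.0);
    const double lP2  = std::log(0.5 - eps / 3.0);
    ll = 0.0;
    for (int i = 0; i < N; ++i) {
      const double cM = nM[i], cm = nm[i], cE = nE[i];
      double l1 = (cM > 0 ? cM * lPM1 : 0.0) +
                  ((cm + cE) > 0 ? (cm + cE) * lPe : 0.0);
      double l2 = ((cM + cm) > 0 ? (cM + cm) * lP2 : 0.0) +
                  (cE > 0 ? cE * lPe : 0.0);
      double l3 = (cm > 0 ? cm * lPM1 : 0.0) +
                  ((cM + cE) > 0 ? (cM + cE) * lPe : 0.0);
      double lmax = std::max(l1, std::max(l2, l3));
      if (!std::isfinite(lmax)) lmax = 0.0;
      double s = (g1 > 0 && std::isfinite(l1) ? g1 * std::exp(l1 - lmax) : 0.0) +
                 (g2 > 0 && std::isfinite(l2) ? g2 * std::exp(l2 - lmax) : 0.0) +
                 (g3 > 0 && std::isfinite(l3) ? g3 * std::exp(l3 - lmax) : 0.0);
      ll += (s > 0.0) ? (lmax + std::log(s)) : R_NegInf;
    }
  }

  return List::create(_["gamma"] = NumericVector::create(g1, g2, g3),
                      _["eps"] = eps, _["loglik"] = ll,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}
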