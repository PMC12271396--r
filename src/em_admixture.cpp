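#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// One full EM pass for the admixture model: the complete-data formulation
// treats each of a sample's two allele copies at each site as drawn from a
// latent ancestral component. Q (n x K, simplex rows) and P (K x m, allele
// frequencies) are updated simultaneously; the log-likelihood of the
// current parameters is returned so the caller can verify monotonicity and
// convergence. Missing genotypes (NA) contribute nothing.
//
// ll = sum_ij [ log C(2, g_ij) + g_ij log(sum_k q_ik p_kj)
//                               + (2 - g_ij) log(sum_k q_ik (1 - p_kj)) ]

// [[Rcpp::export(name = ".em_admixture_step_cpp")]]
List em_admixture_step_cpp(IntegerMatrix G, NumericMatrix Q, NumericMatrix P,
                           bool updateP = true) {
  const int n = G.nrow(), m = G.ncol(), K = Q.ncol();
  if (Q.nrow() != n || P.ncol() != m || P.nrow() != K)
    stop("dimension mismatch");
  if (K > 8) stop("at most 8 ancestral components are supported");
  const double PMIN = 1e-6, PMAX = 1.0 - 1e-6;
  const double LOG2 = std::log(2.0);

  NumericMatrix Qnew(n, K), Pout(K, m);
  const int *g = G.begin();
  const double *q = Q.begin();       // column-major n x K
  const double *p = P.begin();       // column-major K x m
  double *qn = Qnew.begin();
  double *po = Pout.begin();
  std::vector<double> mi(n, 0.0), pk(K), ak(K);
  double ll = 0.0;

  for (int j = 0; j < m; ++j) {
    const double *pj = p + (size_t)j * K;
    const int *gj = g + (size_t)j * n;
    double pnum[8], pden[8];           // K is small (<= 8 supported)
    for (int kk = 0; kk < K; ++kk) { pnum[kk] = 0.0; pden[kk] = 0.0; }
    for (int i = 0; i < n; ++i) {
      int gij = gj[i];
      if (gij == NA_INTEGER) continue;
      mi[i] += 1.0;
      double denom = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        double v = q[i + (size_t)kk * n] * pj[kk];
        ak[kk] = v;
        denom += v;
      }
      double denom2 = 1.0 - denom;     // rows of Q sum to 1
      if (denom < 1e-300) denom = 1e-300;
      if (denom2 < 1e-300) denom2 = 1e-300;
      ll += gij * std::log(denom) + (2.0 - gij) * std::log(denom2);
      if (gij == 1) ll += LOG2;
      double wAlt = gij / denom, wRef = (2.0 - gij) / denom2;
      for (int kk = 0; kk < K; ++kk) {
        double a = wAlt * ak[kk];
        double b = wRef * (q[i + (size_t)kk * n] - ak[kk]); // q (1 - p)
        qn[i + (size_t)kk * n] += a + b;
        pnum[kk] += a;
        pden[kk] += a + b;
      }
    }
    double *poj = po + (size_t)j * K;
    if (updateP) {
      for (int kk = 0; kk < K; ++kk) {
        double v = (pden[kk] > 0) ? pnum[kk] / pden[kk] : pj[kk];
        if (v < PMIN) v = PMIN;
        if (v > PMAX) v = PMAX;
        poj[kk] = v;
      }
    } else {
      for (int kk = 0; kk < K; ++kk) poj[kk] = pj[kk];
    }
  }

  for (int i = 0; i < n; ++i) {
    if (mi[i] > 0) {
      double rowsum = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        qn[i + (size_t)kk * n] /= (2.0 * mi[i]);
        rowsum += qn[i + (size_t)kk * n];
      }
      for (int kk = 0; kk < K; ++kk) qn[i + (size_t)kk * n] /= rowsum;
    } else {
      for (int kk = 0; kk < K; ++kk)
        qn[i + (size_t)kk * n] = q[i + (size_t)kk * n];
    }
  }
  return List::create(_["Q"] = Qnew, _["P"] = Pout, _["loglik"] = ll);
}
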