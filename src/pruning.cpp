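#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning over weighted site patterns with per-node
// log-scaling and discrete-rate-category averaging.
//
// P holds one K x K transition matrix per (node, category) for the
// branch ABOVE each non-root node, flattened column-major as
// P[((c*nnode) + v)*K*K + j*K + i] = P_c,v(i -> j).
// Tip partials are K x npat per tip: tipp[(t*npat + p)*K + i].
//
// Scaling: when the largest partial at a node falls below 1e-40 the
// column is renormalized and the log factor accumulated, so the result
// is exact up to floating point and never underflows to NaN.

static double peel_core(const IntegerVector &postorder,
                        const IntegerMatrix &children, int root, int ntip,
                        int nnode, int K, int npat, int ncat,
                        const std::vector<double> &P,
                        const NumericVector &tipp, const NumericVector &pi,
                        const NumericVector &weights,
                        const NumericVector &catprob) {
  std::vector<double> partial((size_t)nnode * npat * K);
  std::vector<double> logscale((size_t)nnode * npat);
  std::vector<double> sitell((size_t)npat * ncat);
  const double SCALE_THRESH = 1e-40;

  for (int c = 0; c < ncat; ++c) {
    for (int t = 0; t < ntip; ++t) {
      for (int p = 0; p < npat; ++p) {
        logscale[(size_t)t * npat + p] = 0.0;
        for (int i = 0; i < K; ++i)
          partial[((size_t)t * npat + p) * K + i] =
              tipp[((size_t)t * npat + p) * K + i];
      }
    }
    for (int n = 0; n < postorder.size(); ++n) {
      int v = postorder[n] - 1;
      int c1 = children(v, 0) - 1;
      int c2 = children(v, 1) - 1;
      const double *P1 = &P[(((size_t)c * nnode) + c1) * K * K];
      const double *P2 = &P[(((size_t)c * nnode) + c2) * K * K];
      for (int p = 0; p < npat; ++p) {
        double *out = &partial[((size_t)v * npat + p) * K];
        const double *L1 = &partial[((size_t)c1 * npat + p) * K];
        const double *L2 = &partial[((size_t)c2 * npat + p) * K];
        double mx = 0.0;
        for (int i = 0; i < K; ++i) {
          double s1 = 0.0, s2 = 0.0;
          for (int j = 0; j < K; ++j) {
            s1 += P1[j * K + i] * L1[j];
            s2 += P2[j * K + i] * L2[j];
          }
          out[i] = s1 * s2;
          if (out[i] > mx) mx = out[i];
        }
        double ls = logscale[(size_t)c1 * npat + p] +
                    logscale[(size_t)c2 * npat + p];
        if (mx < SCALE_THRESH && mx > 0.0) {
          for (int i = 0; i < K; ++i) out[i] /= mx;
          ls += std::log(mx);
        }
        logscale[(size_t)v * npat + p] = ls;
      }
    }
    int rv = root - 1;
    for (int p = 0; p < npat; ++p) {
      double s = 0.0;
      for (int i = 0; i < K; ++i)
        s += pi[i] * partial[((size_t)rv * npat + p) * K + i];
      sitell[(size_t)c * npat + p] =
          std::log(s) + logscale[(size_t)rv * npat + p] +
          std::log(catprob[c]);
    }
  }
  double total = 0.0;
  for (int p = 0; p < npat; ++p) {
    double mx = R_NegInf;
    for (int c = 0; c < ncat; ++c)
      if (sitell[(size_t)c * npat + p] > mx) mx = sitell[(size_t)c * npat + p];
    double s = 0.0;
    for (int c = 0; c < ncat; ++c)
      s += std::exp(sitell[(size_t)c * npat + p] - mx);
    total += weights[p] * (mx + std::log(s));
  }
  return total;
}

// [[Rcpp::export]]
double peel_loglik_cpp(IntegerVector postorder, IntegerMatrix children,
                       int root, int ntip, int nnode, int K, int npat,
                       int ncat, NumericVector P, NumericVector tipp,
                       NumericVector pi, NumericVector weights,
                       NumericVector catprob) {
  std::vector<double> Pv(P.begin(), P.end());
  return peel_core(postorder, children, root, ntip, nnode, K, npat, ncat,
                   Pv, tipp, pi, weights, catprob);
}

// Same peel, but transition matrices are built internally from a real
// spectral decomposition: P_v,c[i,j] = sum_k Amat[(i,j),k] exp(lambda_k
// * ts[(c,v)]), rows renormalized.  ts < 0 marks the root (skipped).
// [[Rcpp::export]]
double peel_spectral_cpp(IntegerVector postorder, IntegerMatrix children,
                         int root, int ntip, int nnode, int K, int npat,
                         int ncat, NumericMatrix Amat, NumericVector lambda,
                         NumericVector ts, NumericVector tipp,
                         NumericVector pi, NumericVector weights,
                         NumericVector catprob) {
  const int K2 = K * K;
  std::vector<double> P((size_t)nnode * ncat * K2, 0.0);
  std::vector<double> ek(K);
  for (int s = 0; s < nnode * ncat; ++s) {
    double t = ts[s];
    if (t < 0) continue;
    for (int k = 0; k < K; ++k) ek[k] = std::exp(lambda[k] * t);
    double *Ps = &P[(size_t)s * K2];
    for (int e = 0; e < K2; ++e) {
      double acc = 0.0;
      for (int k = 0; k < K; ++k) acc += Amat(e, k) * ek[k];
      Ps[e] = acc > 0.0 ? acc : 0.0;
    }
    for (int i = 0; i < K; ++i) {      // renormalize rows
      double rs = 0.0;
      for (int j = 0; j < K; ++j) rs += Ps[j * K + i];
      for (int j = 0; j < K; ++j) Ps[j * K + i] /= rs;
    }
  }
  return peel_core(postorder, children, root, ntip, nnode, K, npat, ncat,
                   P, tipp, pi, weights, catprob);
}

// Complex-spectrum variant for non-reversible generators: with
// lambda_k = lr_k + i li_k and projector entries A_k = Ar_k + i Ai_k,
// P(t) = sum_k exp(lr_k t) (Ar_k cos(li_k t) - Ai_k sin(li_k t)).
// [[Rcpp::export]]
double peel_spectral_cplx_cpp(IntegerVector postorder,
                              IntegerMatrix children, int root, int ntip,
                              int nnode, int K, int npat, int ncat,
                              NumericMatrix Ar, NumericMatrix Ai,
                              NumericVector lr, NumericVector li,
                              NumericVector ts, NumericVector tipp,
                              NumericVector pi, NumericVector weights,
                              NumericVector catprob) {
  const int K2 = K * K;
  std::vector<double> P((size_t)nnode * ncat * K2, 0.0);
  std::vector<double> wre(K), wim(K);
  for (int s = 0; s < nnode * ncat; ++s) {
    double t = ts[s];
    if (t < 0) continue;
    for (int k = 0; k < K; ++k) {
      double m = std::exp(lr[k] * t);
      wre[k] = m * std::cos(li[k] * t);
      wim[k] = m * std::sin(li[k] * t);
    }
    double *Ps = &P[(size_t)s * K2];
    for (int e = 0; e < K2; ++e) {
      double acc = 0.0;
      for (int k = 0; k < K; ++k)
        acc += Ar(e, k) * wre[k] - Ai(e, k) * wim[k];
      Ps[e] = acc > 0.0 ? acc : 0.0;
    }
    for (int i = 0; i < K; ++i) {
      double rs = 0.0;
      for (int j = 0; j < K; ++j) rs += Ps[j * K + i];
      for (int j = 0; j < K; ++j) Ps[j * K + i] /= rs;
    }
  }
  return peel_core(postorder, children, root, ntip, nnode, K, npat, ncat,
                   P, tipp, pi, weights, catprob);
}

// Per-node conditional partial likelihoods for ancestral-state sampling
// (single pattern, single category).  Returns an nnode x K matrix of
// scaled partials; scaling factors cancel in the conditional draws.
// [[Rcpp::export]]
NumericMatrix peel_partials_cpp(IntegerVector postorder,
                                IntegerMatrix children, int ntip, int nnode,
                                int K, NumericVector P,
                                NumericMatrix tip_partials) {
  NumericMatrix out(nnode, K);
  for (int t = 0; t < ntip; ++t)
    for (int i = 0; i < K; ++i) out(t, i) = tip_partials(t, i);
  for (int n = 0; n < postorder.size(); ++n) {
    int v = postorder[n] - 1;
    int c1 = children(v, 0) - 1;
    int c2 = children(v, 1) - 1;
    const double *P1 = &P[(size_t)c1 * K * K];
    const double *P2 = &P[(size_t)c2 * K * K];
    double mx = 0.0;
    for (int i = 0; i < K; ++i) {
      double s1 = 0.0, s2 = 0.0;
      for (int j = 0; j < K; ++j) {
        s1 += P1[j * K + i] * out(c1, j);
        s2 += P2[j * K + i] * out(c2, j);
      }
      out(v, i) = s1 * s2;
      if (out(v, i) > mx) mx = out(v, i);
    }
    if (mx > 0.0 && mx < 1e-100)
      for (int i = 0; i < K; ++i) out(v, i) /= mx;
  }
  return out;
}
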