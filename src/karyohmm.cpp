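#include <Rcpp.h>
using namespace Rcpp;

// Transition matrices are polynomials in the per-gap recombination fraction r:
//   P_ij(r) = sum_h N[i,j,h+1] * r^h * (1-r)^(k-h)
// where N counts ordered per-copy switch assignments mapping state i to state j
// and k is the total number of transmitted copies. N is precomputed in R once
// per copy-number hypothesis; here we evaluate P per gap on the fly.

static inline void fill_trans(const double *N, int K, int kp1,
                              double r, double *P) {
  double pw[8];
  for (int h = 0; h < kp1; ++h) {
    double v = 1.0;
    for (int a = 0; a < h; ++a) v *= r;
    for (int a = 0; a < kp1 - 1 - h; ++a) v *= (1.0 - r);
    pw[h] = v;
  }
  for (int j = 0; j < K; ++j)
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int h = 0; h < kp1; ++h) s += N[i + K * (j + K * h)] * pw[h];
      P[i + K * j] = s;
    }
}

// copy emissions into a state-major (K x n) buffer of exp(logE - rowmax),
// recording the per-site max; keeps the recursion cache-friendly
static void prep_emissions(const NumericMatrix &logE, int n, int K,
                           std::vector<double> &Et, std::vector<double> &mx) {
  for (int j = 0; j < K; ++j) {
    const double *col = &logE(0, j);
    for (int t = 0; t < n; ++t) Et[(size_t)t * K + j] = col[t];
  }
  for (int t = 0; t < n; ++t) {
    double m = R_NegInf;
    for (int j = 0; j < K; ++j) m = std::max(m, Et[(size_t)t * K + j]);
    if (!R_finite(m)) m = 0.0;
    mx[t] = m;
    for (int j = 0; j < K; ++j) {
      double &e = Et[(size_t)t * K + j];
      e = std::exp(e - m);
    }
  }
}

// Scaled forward pass. logE: n x K emission log-densities (0 for missing
// observations), N: K*K*(k+1) switch-count array, r: length n-1 recombination
// fractions. Initial distribution uniform over states.
// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(NumericMatrix logE, NumericVector N, NumericVector r) {
  const int n = logE.nrow(), K = logE.ncol();
  const int kp1 = N.size() / (K * K);
  const double *Np = N.begin();
  const double *rp = r.begin();
  std::vector<double> Et((size_t)n * K), mx(n);
  prep_emissions(logE, n, K, Et, mx);

  std::vector<double> a(K), anew(K);
  double P[64];
  double logL = 0.0, c = 0.0;
  for (int j = 0; j < K; ++j) { a[j] = Et[j] / K; c += a[j]; }
  logL += std::log(c) + mx[0];
  for (int j = 0; j < K; ++j) a[j] /= c;

  for (int t = 1; t < n; ++t) {
    fill_trans(Np, K, kp1, rp[t - 1], P);
    const double *et = &Et[(size_t)t * K];
    c = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      const double *pc = P + (size_t)K * j;
      for (int i = 0; i < K; ++i) s += a[i] * pc[i];
      anew[j] = s * et[j];
      c += anew[j];
    }
    logL += std::log(c) + mx[t];
    for (int j = 0; j < K; ++j) a[j] = anew[j] / c;
  }
  return logL;
}

// Forward-backward: returns total log-likelihood and n x K posterior matrix.
// [[Rcpp::export(name = ".hmm_fb_cpp")]]
List hmm_fb_cpp(NumericMatrix logE, NumericVector N, NumericVector r) {
  const int n = logE.nrow(), K = logE.ncol();
  const int kp1 = N.size() / (K * K);
  const double *Np = N.begin();
  const double *rp = r.begin();
  std::vector<double> Et((size_t)n * K), mx(n);
  prep_emissions(logE, n, K, Et, mx);

  std::vector<double> alpha((size_t)n * K), beta((size_t)n * K), sc(n);
  double P[64];
  double logL = 0.0, c = 0.0;

  for (int j = 0; j < K; ++j) { alpha[j] = Et[j] / K; c += alpha[j]; }
  sc[0] = c; logL += std::log(c) + mx[0];
  for (int j = 0; j < K; ++j) alpha[j] /= c;

  for (int t = 1; t < n; ++t) {
    fill_trans(Np, K, kp1, rp[t - 1], P);
    double *at = &alpha[(size_t)t * K];
    const double *ap = &alpha[(size_t)(t - 1) * K];
    const double *et = &Et[(size_t)t * K];
    c = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      const double *pc = P + (size_t)K * j;
      for (int i = 0; i < K; ++i) s += ap[i] * pc[i];
      at[j] = s * et[j];
      c += at[j];
    }
    sc[t] = c; logL += std::log(c) + mx[t];
    for (int j = 0; j < K; ++j) at[j] /= c;
  }

  for (int j = 0; j < K; ++j) beta[(size_t)(n - 1) * K + j] = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    fill_trans(Np, K, kp1, rp[t], P);
    double *bt = &beta[(size_t)t * K];
    const double *bn = &beta[(size_t)(t + 1) * K];
    const double *en = &Et[(size_t)(t + 1) * K];
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += P[i + K * j] * en[j] * bn[j];
      bt[i] = s / sc[t + 1];
    }
  }

  NumericMatrix gamma(n, K);
  for (int t = 0; t < n; ++t) {
    double s = 0.0;
    for (int j = 0; j < K; ++j) {
      double g = alpha[(size_t)t * K + j] * beta[(size_t)t * K + j];
      gamma(t, j) = g; s += g;
    }
    for (int j = 0; j < K; ++j) gamma(t, j) /= s;
  }
  return List::create(_["loglik"] = logL, _["gamma"] = gamma);
}

// Viterbi in log space; ties broken toward the lowest state index.
// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
List hmm_viterbi_cpp(NumericMatrix logE, NumericVector N, NumericVector r) {
  const int n = logE.nrow(), K = logE.ncol();
  const int kp1 = N.size() / (K * K);
  const double *Np = N.begin();
  const double *rp = r.begin();
  std::vector<double> delta((size_t)n * K);
  std::vector<int> psi((size_t)n * K);
  double P[64], logP[64];
  const double log1K = -std::log((double)K);

  for (int j = 0; j < K; ++j) delta[j] = log1K + logE(0, j);
  for (int t = 1; t < n; ++t) {
    fill_trans(Np, K, kp1, rp[t - 1], P);
    for (int q = 0; q < K * K; ++q) logP[q] = std::log(P[q]);
    const double *dp = &delta[(size_t)(t - 1) * K];
    double *dt = &delta[(size_t)t * K];
    int *pt = &psi[(size_t)t * K];
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = dp[i] + logP[i + K * j];
        if (v > best) { best = v; arg = i; }
      }
      dt[j] = best + logE(t, j);
      pt[j] = arg;
    }
  }
  IntegerVector path(n);
  const double *dl = &delta[(size_t)(n - 1) * K];
  double best = R_NegInf; int arg = 0;
  for (int j = 0; j < K; ++j) if (dl[j] > best) { best = dl[j]; arg = j; }
  path[n - 1] = arg;
  for (int t = n - 2; t >= 0; --t)
    path[t] = psi[(size_t)(t + 1) * K + path[t + 1]];
  for (int t = 0; t < n; ++t) path[t] += 1;  // 1-based state indices for R
  return List::create(_["path"] = path, _["logp"] = best);
}
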