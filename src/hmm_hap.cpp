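// Optimized haploid-chain E-step: K x L transposed layout so per-site
// cluster vectors are contiguous; plain loops avoid per-site temporaries.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".hap_estep_cpp")]]
List hap_estep(const arma::imat& X, const arma::mat& alpha,
               const arma::vec& rho, const arma::mat& theta,
               const arma::ivec& pop, int n_pop, bool want_stats) {
  const int L = X.n_rows, N = X.n_cols, K = alpha.n_cols;
  arma::mat at = alpha.t();   // K x L
  arma::mat tt = theta.t();   // K x L
  double loglik = 0.0;
  arma::vec init_occ(K, arma::fill::zeros);
  arma::vec jump_tot(std::max(L - 1, 0), arma::fill::zeros);
  arma::mat jump_dest(K, std::max(L - 1, 0), arma::fill::zeros);
  arma::mat emit_num(K, L, arma::fill::zeros);
  arma::mat emit_den(K, L, arma::fill::zeros);
  arma::cube pop_gamma(K, L, n_pop, arma::fill::zeros);

  arma::mat f(K, L), bm(K, L);
  arma::vec scales(L);
  std::vector<double> ework(K);

  for (int i = 0; i < N; ++i) {
    const int p = pop(i);
    // forward
    {
      const double* a0 = at.colptr(0);
      const double* th = tt.colptr(0);
      double* f0 = f.colptr(0);
      int x = X(0, i);
      double c = 0.0;
      for (int k = 0; k < K; ++k) {
        double e = (x < 0) ? 1.0 : (x == 1 ? th[k] : 1.0 - th[k]);
        f0[k] = a0[k] * e;
        c += f0[k];
      }
      for (int k = 0; k < K; ++k) f0[k] /= c;
      scales(0) = c;
    }
    for (int l = 1; l < L; ++l) {
      const double r = rho(l - 1), omr = 1.0 - r;
      const double* al = at.colptr(l);
      const double* th = tt.colptr(l);
      const double* fp = f.colptr(l - 1);
      double* fl = f.colptr(l);
      int x = X(l, i);
      double c = 0.0;
      for (int k = 0; k < K; ++k) {
        double e = (x < 0) ? 1.0 : (x == 1 ? th[k] : 1.0 - th[k]);
        fl[k] = (omr * fp[k] + r * al[k]) * e;
        c += fl[k];
      }
      for (int k = 0; k < K; ++k) fl[k] /= c;
      scales(l) = c;
    }
    for (int l = 0; l < L; ++l) loglik += std::log(scales(l));
    // backward
    {
      double* bL = bm.colptr(L - 1);
      for (int k = 0; k < K; ++k) bL[k] = 1.0;
    }
    for (int l = L - 2; l >= 0; --l) {
      const double r = rho(l), omr = 1.0 - r;
      const double* al1 = at.colptr(l + 1);
      const double* th1 = tt.colptr(l + 1);
      const double* b1 = bm.colptr(l + 1);
      double* bl = bm.colptr(l);
      const double sc = scales(l + 1);
      int x = X(l + 1, i);
      double dotaG = 0.0;
      for (int k = 0; k < K; ++k) {
        double e = (x < 0) ? 1.0 : (x == 1 ? th1[k] : 1.0 - th1[k]);
        double G = e * b1[k] / sc;
        ework[k] = G;
        dotaG += al1[k] * G;
      }
      for (int k = 0; k < K; ++k) bl[k] = omr * ework[k] + r * dotaG;
      if (want_stats) {
        double* jd = jump_dest.colptr(l);
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          double v = r * al1[k] * ework[k];
          jd[k] += v;
          tot += v;
        }
        jump_tot(l) += tot;
      }
    }
    // gamma accumulation
    double* pg = pop_gamma.slice_memptr(p);
    for (int l = 0; l < L; ++l) {
      const double* fl = f.colptr(l);
      const double* bl = bm.colptr(l);
      double s = 0.0;
      for (int k = 0; k < K; ++k) { ework[k] = fl[k] * bl[k]; s += ework[k]; }
      double* pgl = pg + (size_t)l * K;
      for (int k = 0; k < K; ++k) {
        ework[k] /= s;
        pgl[k] += ework[k];
      }
      if (want_stats) {
        int x = X(l, i);
        if (x >= 0) {
          double* ed = emit_den.colptr(l);
          for (int k = 0; k < K; ++k) ed[k] += ework[k];
          if (x == 1) {
            double* en = emit_num.colptr(l);
            for (int k = 0; k < K; ++k) en[k] += ework[k];
          }
        }
        if (l == 0) for (int k = 0; k < K; ++k) init_occ(k) += ework[k];
      }
    }
  }
  // return in L x K orientation to match the R-side contract
  arma::cube pg_out(L, K, n_pop);
  for (int p = 0; p < n_pop; ++p) pg_out.slice(p) = pop_gamma.slice(p).t();
  return List::create(_["loglik"] = loglik, _["init_occ"] = init_occ,
                      _["jump_tot"] = jump_tot,
                      _["jump_dest"] = jump_dest.t(),
                      _["emit_num"] = emit_num.t(),
                      _["emit_den"] = emit_den.t(),
                      _["pop_gamma"] = pg_out);
}
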