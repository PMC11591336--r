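// Scaled forward-backward recursions and EM expected sufficient statistics
// for the localized haplotype-cluster model: each haplotype is a mosaic of
// K latent clusters with per-interval jump probability rho_l, jump
// destination weights alpha_l, and cluster-specific allele-2 emission
// frequencies theta_lk. Unphased genotypes use the product chain over
// ordered cluster pairs; transitions factorize, so updates stay O(K^2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// genotype emission matrix for a site: g in {0,1,2,-1}
static inline arma::mat dip_emit(int g, const arma::rowvec& th) {
  const int K = th.n_elem;
  arma::mat E(K, K);
  if (g < 0) { E.ones(); return E; }
  arma::vec t1 = th.t(), q1 = 1.0 - th.t();
  if (g == 0) E = q1 * q1.t();
  else if (g == 2) E = t1 * t1.t();
  else E = t1 * q1.t() + q1 * t1.t();
  return E;
}

// [[Rcpp::export(name = ".dip_estep_cpp")]]
List dip_estep(const arma::imat& Gmat, const arma::mat& alpha,
               const arma::vec& rho, const arma::mat& theta,
               const arma::ivec& pop, int n_pop, bool want_stats) {
  const int L = Gmat.n_rows, N = Gmat.n_cols, K = alpha.n_cols;
  double loglik = 0.0;
  arma::vec init_occ(K, arma::fill::zeros);
  arma::vec jump_tot(std::max(L - 1, 0), arma::fill::zeros);
  arma::mat jump_dest(std::max(L - 1, 0), K, arma::fill::zeros);
  arma::mat emit_num(L, K, arma::fill::zeros);
  arma::mat emit_den(L, K, arma::fill::zeros);
  arma::cube pop_gamma(L, K, n_pop, arma::fill::zeros);

  arma::cube F(K, K, L);
  arma::vec scales(L);

  for (int i = 0; i < N; ++i) {
    const int p = pop(i);
    // forward
    arma::vec a0 = alpha.row(0).t();
    arma::mat Fl = (a0 * a0.t()) % dip_emit(Gmat(0, i), theta.row(0));
    double c = arma::accu(Fl);
    Fl /= c; scales(0) = c; F.slice(0) = Fl;
    for (int l = 1; l < L; ++l) {
      double r = rho(l - 1);
      arma::vec ap = alpha.row(l).t();
      arma::vec rs = arma::sum(Fl, 1);        // over chain-2 index
      arma::rowvec cs = arma::sum(Fl, 0);     // over chain-1 index
      arma::mat pred = (1.0 - r) * (1.0 - r) * Fl
        + (1.0 - r) * r * (rs * ap.t())
        + r * (1.0 - r) * (ap * cs)
        + r * r * (ap * ap.t());
      Fl = pred % dip_emit(Gmat(l, i), theta.row(l));
      c = arma::accu(Fl);
      Fl /= c; scales(l) = c; F.slice(l) = Fl;
    }
    loglik += arma::accu(arma::log(scales));
    // backward
    arma::mat B(K, K, arma::fill::ones);
    for (int l = L - 1; l >= 0; --l) {
      arma::mat gamma = F.slice(l) % B;
      gamma /= arma::accu(gamma);
      arma::vec m1 = arma::sum(gamma, 1);
      arma::vec m2 = arma::sum(gamma, 0).t();
      pop_gamma.slice(p).row(l) += (m1 + m2).t();
      if (want_stats) {
        int g = Gmat(l, i);
        if (g >= 0) {
          emit_den.row(l) += (m1 + m2).t();
          if (g == 2) emit_num.row(l) += (m1 + m2).t();
          else if (g == 1) {
            arma::vec t1 = theta.row(l).t(), q1 = 1.0 - t1;
            arma::mat w1 = (t1 * q1.t());
            arma::mat den = w1 + (q1 * t1.t());
            w1 /= den;  // P(chain1 carries allele 2 | het, k1, k2)
            arma::mat A = gamma % w1;
            emit_num.row(l) += (arma::sum(A, 1) +
                                arma::sum(gamma - A, 0).t()).t();
          }
        }
        if (l == 0) init_occ += m1 + m2;
      }
      if (l > 0) {
        double r = rho(l - 1);
        arma::vec ap = alpha.row(l).t();
        arma::mat Gm = dip_emit(Gmat(l, i), theta.row(l)) % B / scales(l);
        arma::vec u = Gm * ap;             // sum over chain-2 dest
        arma::vec v = Gm.t() * ap;         // sum over chain-1 dest
        double w = arma::dot(ap, Gm * ap);
        arma::mat Bprev = (1.0 - r) * (1.0 - r) * Gm;
        Bprev.each_col() += (1.0 - r) * r * u;
        Bprev.each_row() += (r * (1.0 - r) * v).t();
        Bprev += r * r * w;
        if (want_stats) {
          const arma::mat& Fp = F.slice(l - 1);
          arma::vec rs = arma::sum(Fp, 1);
          arma::vec cs = arma::sum(Fp, 0).t();
          arma::vec q2 = (1.0 - r) * cs + r * ap;  // chain-2 predictive
          arma::vec q1 = (1.0 - r) * rs + r * ap;  // chain-1 predictive
          arma::vec jd1 = r * (ap % (Gm * q2));
          arma::vec jd2 = r * (ap % (Gm.t() * q1));
          jump_dest.row(l - 1) += (jd1 + jd2).t();
          jump_tot(l - 1) += arma::accu(jd1) + arma::accu(jd2);
        }
        B = Bprev;
      }
    }
  }
  return List::create(_["loglik"] = loglik, _["init_occ"] = init_occ,
                      _["jump_tot"] = jump_tot, _["jump_dest"] = jump_dest,
                      _["emit_num"] = emit_num, _["emit_den"] = emit_den,
                      _["pop_gamma"] = pop_gamma);
}
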