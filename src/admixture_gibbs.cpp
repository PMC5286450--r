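#include <Rcpp.h>
using namespace Rcpp;

// Gibbs chain for the admixture model: alternates allele-origin assignments
// Z (categorical given Q, P), cluster allele frequencies P (Beta updates),
// and admixture proportions Q (Dirichlet(alpha + origin counts)).
// g: samples x loci alt-allele dosages with NA for missing calls.
// Returns the mean post-burn-in data log-likelihood and the mean Q.
// Uses R's RNG, so set.seed() on the R side makes the chain reproducible.
// [[Rcpp::export]]
List admixture_chain_cpp(IntegerMatrix g, int K, int burn_in, int n_iter,
                         double alpha) {
  const int n = g.nrow(), L = g.ncol();
  NumericMatrix P(K, L), Q(n, K), q_sum(n, K);
  NumericMatrix a_cnt(K, L), r_cnt(K, L), m(n, K);
  std::vector<double> w(K);

  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) P(k, l) = R::rbeta(1.0, 1.0);
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int k = 0; k < K; ++k) { w[k] = R::rgamma(1.0, 1.0); s += w[k]; }
    for (int k = 0; k < K; ++k) Q(i, k) = w[k] / s;
  }

  double ll_sum = 0.0;
  int n_keep = 0;
  for (int sweep = 0; sweep < burn_in + n_iter; ++sweep) {
    std::fill(a_cnt.begin(), a_cnt.end(), 0.0);
    std::fill(r_cnt.begin(), r_cnt.end(), 0.0);
    std::fill(m.begin(), m.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        const int gi = g(i, l);
        if (gi == NA_INTEGER) continue;
        for (int copy = 0; copy < 2; ++copy) {
          const bool alt = copy < gi;
          double tot = 0;
          for (int k = 0; k < K; ++k) {
            w[k] = Q(i, k) * (alt ? P(k, l) : 1.0 - P(k, l));
            tot += w[k];
          }
          double u = R::unif_rand() * tot, c = 0;
          int k = 0;
          for (; k < K - 1; ++k) { c += w[k]; if (u <= c) break; }
          if (alt) a_cnt(k, l) += 1.0; else r_cnt(k, l) += 1.0;
          m(i, k) += 1.0;
        }
      }
    }
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double p = R::rbeta(1.0 + a_cnt(k, l), 1.0 + r_cnt(k, l));
        if (p < 1e-9) p = 1e-9;
        if (p > 1.0 - 1e-9) p = 1.0 - 1e-9;
        P(k, l) = p;
      }
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int k = 0; k < K; ++k) {
        w[k] = R::rgamma(alpha + m(i, k), 1.0);
        s += w[k];
      }
      for (int k = 0; k < K; ++k) Q(i, k) = w[k] / s;
    }
    if (sweep >= burn_in) {
      ++n_keep;
      double ll = 0;
      for (int i = 0; i < n; ++i)
        for (int l = 0; l < L; ++l) {
          const int gi = g(i, l);
          if (gi == NA_INTEGER) continue;
          double f = 0;
          for (int k = 0; k < K; ++k) f += Q(i, k) * P(k, l);
          if (f < 1e-12) f = 1e-12;
          if (f > 1.0 - 1e-12) f = 1.0 - 1e-12;
          ll += gi * std::log(f) + (2 - gi) * std::log1p(-f) +
            (gi == 1 ? M_LN2 : 0.0);
        }
      ll_sum += ll;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) q_sum(i, k) += Q(i, k);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) q_sum(i, k) /= n_keep;
  return List::create(_["loglik"] = ll_sum / n_keep, _["q"] = q_sum);
}
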