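#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exhaustive grid argmax of the binomial psychometric log-likelihood.
//
// Trials are binned by unique stimulus value within each load group:
// s[g][u] (ascending) with counts of positive (c1) and negative (c0)
// responses. The log-likelihood for parameters (mu, lambda, sigma_1, ...,
// sigma_G) is
//   sum_g sum_u c1 * log p(s_u) + c0 * log (1 - p(s_u)),
//   p(s) = lambda/2 + (1 - lambda) * Phi((s - mu) / sigma_g).
// Because the sigma terms separate at fixed (mu, lambda), the maximum over
// all sigmas is the sum of per-group maxima, which makes the search over
// the full grid exact at a fraction of the naive cost. Probabilities are
// clipped to [1e-12, 1 - 1e-12] before the log. Ties resolve to the lowest
// grid index on (mu, lambda, sigma_1, sigma_2), in that order (loops run
// ascending with strict improvement).
//
// Speed: Phi is nondecreasing in s at fixed (mu, sigma), so the cells where
// it underflows to exactly 0.0 form a prefix and those where it saturates
// to exactly 1.0 a suffix of each (mu, sigma) row. Their log terms depend
// on lambda alone (p equals lambda/2 + (1-lambda)*{0,1} bit-for-bit), so
// they collapse to prefix-sum counts times two per-lambda logs; only the
// strictly interior cells pay a log each. The result is bit-identical to
// the naive triple loop.
// [[Rcpp::export]]
List psych_grid_argmax(NumericVector mu_grid, NumericVector lambda_grid,
                       NumericVector sigma_grid, List s_by_load,
                       List c1_by_load, List c0_by_load) {
  const int nm = mu_grid.size(), nl = lambda_grid.size(), ns = sigma_grid.size();
  const int G = s_by_load.size();
  const double eps = 1e-12;
  const size_t ncell = (size_t)nm * ns;

  // Phi tables per group, dims [S_g][nm * ns] with mu fastest, plus the
  // exact-0 prefix end (lo) and exact-1 suffix start (hi) per (mu, sigma)
  // cell and prefix sums of the counts.
  std::vector<NumericVector> sv(G), c1v(G), c0v(G);
  std::vector<std::vector<double>> phi(G);
  std::vector<std::vector<int>> lo(G), hi(G);
  std::vector<std::vector<double>> c1pre(G), c0pre(G);
  for (int g = 0; g < G; ++g) {
    sv[g] = as<NumericVector>(s_by_load[g]);
    c1v[g] = as<NumericVector>(c1_by_load[g]);
    c0v[g] = as<NumericVector>(c0_by_load[g]);
    const int S = sv[g].size();
    for (int u = 1; u < S; ++u) {
      if (sv[g][u] <= sv[g][u - 1]) {
        stop("stimulus bins must be strictly ascending");
      }
    }
    c1pre[g].resize(S + 1, 0.0);
    c0pre[g].resize(S + 1, 0.0);
    for (int u = 0; u < S; ++u) {
      c1pre[g][u + 1] = c1pre[g][u] + c1v[g][u];
      c0pre[g][u + 1] = c0pre[g][u] + c0v[g][u];
    }
    phi[g].resize((size_t)S * ncell);
    lo[g].resize(ncell);
    hi[g].resize(ncell);
    for (int is = 0; is < ns; ++is) {
      const double sig = sigma_grid[is];
      for (int im = 0; im < nm; ++im) {
        const double mu = mu_grid[im];
        const size_t cell = (size_t)is * nm + im;
        const size_t base = cell * S;
        for (int u = 0; u < S; ++u) {
          phi[g][base + u] = R::pnorm((sv[g][u] - mu) / sig, 0.0, 1.0, 1, 0);
        }
        int u0 = 0;
        while (u0 < S && phi[g][base + u0] == 0.0) ++u0;
        int u1 = S;
        while (u1 > u0 && phi[g][base + u1 - 1] == 1.0) --u1;
        lo[g][cell] = u0;
        hi[g][cell] = u1;
      }
    }
  }

  double best_ll = R_NegInf;
  int best_im = 0, best_il = 0;
  std::vector<int> best_is(G, 0);
  std::vector<int> cur_is(G, 0);

  for (int im = 0; im < nm; ++im) {
    for (int il = 0; il < nl; ++il) {
      const double lam = lambda_grid[il];
      const double a = 0.5 * lam, b = 1.0 - lam;
      // log p at exactly Phi = 0 and Phi = 1, clipped like the mid cells
      double p_lo = a, p_hi = a + b;
      if (p_lo < eps) p_lo = eps; else if (p_lo > 1.0 - eps) p_lo = 1.0 - eps;
      if (p_hi < eps) p_hi = eps; else if (p_hi > 1.0 - eps) p_hi = 1.0 - eps;
      const double log_plo = std::log(p_lo), log_1mplo = std::log(1.0 - p_lo);
      const double log_phi1 = std::log(p_hi), log_1mphi1 = std::log(1.0 - p_hi);
      double total = 0.0;
      for (int g = 0; g < G; ++g) {
        const int S = sv[g].size();
        const double c1tot = c1pre[g][S], c0tot = c0pre[g][S];
        double gbest = R_NegInf;
        int gbest_is = 0;
        for (int is = 0; is < ns; ++is) {
          const size_t cell = (size_t)is * nm + im;
          const size_t base = cell * S;
          const int u0 = lo[g][cell], u1 = hi[g][cell];
          // saturated prefix (Phi = 0): p = lambda/2 exactly
          double ll = c1pre[g][u0] * log_plo + c0pre[g][u0] * log_1mplo;
          // saturated suffix (Phi = 1): p = lambda/2 + (1 - lambda) exactly
          ll += (c1tot - c1pre[g][u1]) * log_phi1 +
                (c0tot - c0pre[g][u1]) * log_1mphi1;
          for (int u = u0; u < u1; ++u) {
            double p = a + b * phi[g][base + u];
            if (p < eps) p = eps; else if (p > 1.0 - eps) p = 1.0 - eps;
            const double c1 = c1v[g][u], c0 = c0v[g][u];
            if (c1 > 0) ll += c1 * std::log(p);
            if (c0 > 0) ll += c0 * std::log(1.0 - p);
          }
          if (ll > gbest) { gbest = ll; gbest_is = is; }
        }
        total += gbest;
        cur_is[g] = gbest_is;
      }
      if (total > best_ll) {
        best_ll = total;
        best_im = im;
        best_il = il;
        best_is = cur_is;
      }
    }
  }

  IntegerVector is_out(G);
  for (int g = 0; g < G; ++g) is_out[g] = best_is[g] + 1;  // 1-based for R
  return List::create(_["loglik"] = best_ll, _["i_mu"] = best_im + 1,
                      _["i_lambda"] = best_il + 1, _["i_sigma"] = is_out);
}
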