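#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the Bayesian ridge marker model
//   y = X b + M m + e,  m ~ N(0, I s2m),  e ~ N(0, I s2e)
// with flat priors on b and scaled-inverse-chi-square priors on the two
// variance components. M is the record-level marker matrix (W rows expanded
// to phenotype records). Residual-updating scheme: e always holds
// y - X b - M m for the current state.
//
// Returns thinned post-burn-in draws of b, m, s2m, s2e. When update_var is
// false the variances stay at their initial values (degenerate priors), in
// which case the chain targets the conditional MVN of (b, m) given the
// variances.
// [[Rcpp::export]]
List gibbs_ridge_cpp(NumericVector y, NumericMatrix X, NumericMatrix M,
                     int n_iter, int burnin, int thin,
                     double nu_m, double scale_m,
                     double nu_e, double scale_e,
                     double s2m_init, double s2e_init,
                     bool update_var) {
  const int n = y.size();
  const int nb = X.ncol();
  const int nm = M.ncol();
  if (X.nrow() != n || M.nrow() != n) stop("design row mismatch");
  const int n_keep = (n_iter - burnin) / thin;
  if (n_keep < 1) stop("chain settings retain no samples");

  std::vector<double> b(nb, 0.0), m(nm, 0.0), e(y.begin(), y.end());
  std::vector<double> xtx(nb), mtm(nm);
  for (int j = 0; j < nb; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    if (s <= 0) stop("fixed-effect column with zero sum of squares");
    xtx[j] = s;
  }
  for (int j = 0; j < nm; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += M(i, j) * M(i, j);
    mtm[j] = s;
  }

  double s2m = s2m_init, s2e = s2e_init;
  NumericMatrix b_out(n_keep, nb), m_out(n_keep, nm);
  NumericVector s2m_out(n_keep), s2e_out(n_keep);

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // fixed effects, flat prior
    for (int j = 0; j < nb; ++j) {
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xtx[j] * b[j];
      double mean = rhs / xtx[j];
      double bnew = mean + norm_rand() * std::sqrt(s2e / xtx[j]);
      double diff = bnew - b[j];
      if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] -= X(i, j) * diff;
      b[j] = bnew;
    }
    // marker effects, ridge prior
    double lambda = s2e / s2m;
    for (int j = 0; j < nm; ++j) {
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += M(i, j) * e[i];
      rhs += mtm[j] * m[j];
      double denom = mtm[j] + lambda;
      double mean = rhs / denom;
      double mnew = mean + norm_rand() * std::sqrt(s2e / denom);
      double diff = mnew - m[j];
      if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] -= M(i, j) * diff;
      m[j] = mnew;
    }
    if (update_var) {
      double ssm = 0.0;
      for (int j = 0; j < nm; ++j) ssm += m[j] * m[j];
      s2m = (nu_m * scale_m + ssm) / R::rchisq(nu_m + nm);
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      s2e = (nu_e * scale_e + sse) / R::rchisq(nu_e + n);
    }
    if (it > burnin && (it - burnin) % thin == 0) {
      for (int j = 0; j < nb; ++j) b_out(kept, j) = b[j];
      for (int j = 0; j < nm; ++j) m_out(kept, j) = m[j];
      s2m_out[kept] = s2m;
      s2e_out[kept] = s2e;
      ++kept;
    }
  }
  return List::create(_["b"] = b_out, _["m"] = m_out,
                      _["sigma2_m"] = s2m_out, _["sigma2_e"] = s2e_out);
}
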