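// Gibbs sampler for the five-component colouration animal model:
//   y = X beta + Z_a a + Z_d dam + Z_p pcage + Z_o ocage + e
// with a ~ N(0, A sigma2_A) (pedigree additive relationship matrix A),
// the other random vectors iid Normal, and scaled-inverse-chi-square
// priors (scale V, df nu) on every variance component.
//
// Location effects (beta and all random effects) are drawn as one joint
// Gaussian block from their exact full conditional via the mixed-model
// equations, with A-inverse on the animal block; each variance is then
// drawn from its scaled-inv-chi-square full conditional. All randomness
// comes from R's RNG, so a set.seed() in R fixes the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List gibbs_mcmc_cpp(const arma::vec& y,
                          const arma::mat& X,
                          const arma::uvec& animal_idx, // 1-based into A
                          const arma::uvec& dam_idx,
                          const arma::uvec& pcage_idx,
                          const arma::uvec& ocage_idx,
                          const arma::sp_mat& Ainv,
                          int n_dam, int n_pcage, int n_ocage,
                          double prior_V, double prior_nu,
                          int n_iter, int burnin, int thin,
                          double start_var) {
  const uword n = y.n_elem;
  const uword p = X.n_cols;
  const uword qa = Ainv.n_rows;
  const uword q = p + qa + n_dam + n_pcage + n_ocage;
  const uword o_a = p, o_d = p + qa, o_p = o_d + n_dam, o_o = o_p + n_pcage;

  // sparse design W = [X | Z_a | Z_d | Z_p | Z_o]
  umat locs(2, n * (p + 4));
  vec vals(n * (p + 4));
  uword c = 0;
  for (uword i = 0; i < n; ++i) {
    for (uword j = 0; j < p; ++j) {
      locs(0, c) = i; locs(1, c) = j; vals(c) = X(i, j); ++c;
    }
    locs(0, c) = i; locs(1, c) = o_a + animal_idx(i) - 1; vals(c) = 1.0; ++c;
    locs(0, c) = i; locs(1, c) = o_d + dam_idx(i) - 1;    vals(c) = 1.0; ++c;
    locs(0, c) = i; locs(1, c) = o_p + pcage_idx(i) - 1;  vals(c) = 1.0; ++c;
    locs(0, c) = i; locs(1, c) = o_o + ocage_idx(i) - 1;  vals(c) = 1.0; ++c;
  }
  sp_mat W(locs, vals, n, q);
  mat WtW(W.t() * W);
  vec Wty = vec(W.t() * y);

  double s2A = start_var, s2D = start_var, s2P = start_var,
         s2O = start_var, s2R = start_var;
  const double eps_floor = std::numeric_limits<double>::epsilon();
  int n_floored = 0;

  const int n_keep = (n_iter - burnin) / thin;
  mat beta_draws(n_keep, p);
  mat var_draws(n_keep, 5);
  int keep = 0;

  Rcpp::RNGScope scope;
  mat C(q, q), U(q, q);
  vec theta(q), z(q), rhs(q), mu(q), e(n), a(qa);

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- location block: theta | variances, y ~ N(C^-1 rhs, C^-1)
    C = WtW;          // copy into preallocated storage
    C /= s2R;
    for (sp_mat::const_iterator it = Ainv.begin(); it != Ainv.end(); ++it) {
      C(o_a + it.row(), o_a + it.col()) += (*it) / s2A;
    }
    for (uword j = 0; j < p; ++j) C(j, j) += 1e-10; // effectively flat prior
    for (uword j = o_d; j < o_p; ++j) C(j, j) += 1.0 / s2D;
    for (uword j = o_p; j < o_o; ++j) C(j, j) += 1.0 / s2P;
    for (uword j = o_o; j < q;   ++j) C(j, j) += 1.0 / s2O;

    if (!chol(U, C)) {
      Rcpp::stop("mixed-model equations not positive definite at iteration %d", iter);
    }
    rhs = Wty;
    rhs /= s2R;
    mu = solve(trimatu(U), solve(trimatl(U.t()), rhs));
    for (uword j = 0; j < q; ++j) z(j) = R::norm_rand();
    theta = mu + solve(trimatu(U), z);
    if (!theta.is_finite()) {
      Rcpp::stop("non-finite location draw at iteration %d", iter);
    }

    // --- variance components: scaled-inv-chi-square full conditionals
    a = theta.subvec(o_a, o_d - 1);
    double ssA = dot(a, Ainv * a);
    double ssD = dot(theta.subvec(o_d, o_p - 1), theta.subvec(o_d, o_p - 1));
    double ssP = dot(theta.subvec(o_p, o_o - 1), theta.subvec(o_p, o_o - 1));
    double ssO = dot(theta.subvec(o_o, q - 1), theta.subvec(o_o, q - 1));
    e = y;
    e -= W * theta;
    double ssR = dot(e, e);

    s2A = (prior_nu * prior_V + ssA) / R::rchisq(prior_nu + qa);
    s2D = (prior_nu * prior_V + ssD) / R::rchisq(prior_nu + n_dam);
    s2P = (prior_nu * prior_V + ssP) / R::rchisq(prior_nu + n_pcage);
    s2O = (prior_nu * prior_V + ssO) / R::rchisq(prior_nu + n_ocage);
    s2R = (prior_nu * prior_V + ssR) / R::rchisq(prior_nu + n);

    double* vars[5] = {&s2A, &s2D, &s2P, &s2O, &s2R};
    for (int v = 0; v < 5; ++v) {
      if (!std::isfinite(*vars[v])) {
        Rcpp::stop("non-finite variance draw at iteration %d", iter);
      }
      if (*vars[v] < eps_floor) { *vars[v] = eps_floor; ++n_floored; }
    }

    if (iter > burnin && (iter - burnin) % thin == 0 && keep < n_keep) {
      for (uword j = 0; j < p; ++j) beta_draws(keep, j) = theta(j);
      var_draws(keep, 0) = s2A; var_draws(keep, 1) = s2D;
      var_draws(keep, 2) = s2P; var_draws(keep, 3) = s2O;
      var_draws(keep, 4) = s2R;
      ++keep;
    }
    if (iter % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(Rcpp::Named("beta") = beta_draws,
                            Rcpp::Named("variances") = var_draws,
                            Rcpp::Named("n_floored") = n_floored);
}
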