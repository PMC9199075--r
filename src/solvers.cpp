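// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Sparse-regression inner loops. All solvers operate on an already
// standardized (and, for the hard-thresholding family, spectral-norm
// rescaled) system; wrappers in R/solvers.R own the conventions.

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Cyclical coordinate descent for 0.5*||y - X b||^2 + lam * sum(pen_k |b_k|).
// pen_k = 1/W_k for the randomized variant (all 1 for plain LASSO).
// [[Rcpp::export]]
Rcpp::List cpp_cd_lasso(const arma::mat& X, const arma::vec& y, double lam,
                        const arma::vec& pen, arma::vec beta, int max_iter,
                        double tol) {
  const uword p = X.n_cols;
  vec cn(p);
  for (uword k = 0; k < p; ++k) cn(k) = dot(X.col(k), X.col(k));
  vec r = y - X * beta;
  bool converged = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    double delta = 0.0;
    for (uword k = 0; k < p; ++k) {
      if (cn(k) <= 0.0) continue;
      const double bk = beta(k);
      const double z = dot(X.col(k), r) + cn(k) * bk;
      const double bn = soft(z, lam * pen(k)) / cn(k);
      if (bn != bk) {
        r += X.col(k) * (bk - bn);
        beta(k) = bn;
        delta = std::max(delta, std::fabs(bn - bk));
      }
    }
    if (delta < tol) { converged = true; break; }
  }
  return Rcpp::List::create(Rcpp::_["beta"] = beta,
                            Rcpp::_["converged"] = converged,
                            Rcpp::_["iter"] = it + 1);
}

// [[Rcpp::export]]
arma::mat cpp_lasso_path(const arma::mat& X, const arma::vec& y,
                         const arma::vec& lambdas, const arma::vec& pen,
                         int max_iter, double tol) {
  const uword p = X.n_cols, M = lambdas.n_elem;
  mat out(p, M, fill::zeros);
  vec beta(p, fill::zeros);
  for (uword m = 0; m < M; ++m) {
    Rcpp::List fit = cpp_cd_lasso(X, y, lambdas(m), pen, beta, max_iter, tol);
    beta = Rcpp::as<vec>(fit["beta"]);
    out.col(m) = beta;
  }
  return out;
}

static inline void hard_threshold(vec& b, double lam) {
  for (uword i = 0; i < b.n_elem; ++i)
    if (std::fabs(b(i)) <= lam) b(i) = 0.0;
}

// Ridge-stabilized least-squares solution used to initialize the
// hard-thresholding iterations: the debias-consistent starting point. A tiny
// ridge (1e-8 of the mean Gram diagonal) keeps it defined for n < p.
// [[Rcpp::export]]
arma::vec cpp_ridge_init(const arma::mat& X, const arma::vec& y) {
  const uword p = X.n_cols;
  mat G = X.t() * X;
  const double reg = 1e-8 * trace(G) / (double)p;
  G.diag() += reg;
  vec beta;
  if (!solve(beta, G, X.t() * y, solve_opts::likely_sympd + solve_opts::no_approx))
    beta = pinv(G) * (X.t() * y);
  return beta;
}

// Plain iterative hard thresholding: b <- H_lam(b + X'(y - X b)).
// Requires ||X||_2 < 1 for the descent guarantee (caller rescales).
// [[Rcpp::export]]
Rcpp::List cpp_iht(const arma::mat& X, const arma::vec& y, double lam,
                   arma::vec beta, int max_iter, double tol, double cmon) {
  vec r = y - X * beta;
  double rss = dot(r, r);
  bool converged = false, monitor_stop = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    vec bn = beta + X.t() * r;
    hard_threshold(bn, lam);
    vec rn = y - X * bn;
    const double rssn = dot(rn, rn);
    const double change = norm(bn - beta, "inf");
    if (change < tol) { beta = bn; converged = true; break; }
    if (rssn >= (1.0 - cmon) * rss) { monitor_stop = true; break; }
    beta = bn; r = rn; rss = rssn;
  }
  return Rcpp::List::create(Rcpp::_["beta"] = beta,
                            Rcpp::_["converged"] = converged,
                            Rcpp::_["monitor_stop"] = monitor_stop,
                            Rcpp::_["iter"] = it + 1);
}

// IHT with debiasing: after each thresholding step, refine the
// coefficients restricted to the current support, either by exact
// restricted least squares (HTP-style, used with the LS initialization) or
// by gradient descent with step 1/||X_S||_2^2 (the classical variant,
// optionally stopped at the loose bound ||y - X b||^2 <= lam |S|).
// The whole iteration runs in Gram form: with G = X'X, c = X'y and
// yty = y'y all gradients and residual norms are O(p^2) per step.
static Rcpp::List iht_d_gram(const mat& G, const vec& c, double yty,
                             double lam, vec beta, int max_iter, double tol,
                             int debias_max, double cmon, bool use_bound,
                             double debias_tol, bool exact_debias) {
  const uword p = G.n_cols;
  auto rss_of = [&](const vec& b, const vec& Gb) {
    return yty - 2.0 * dot(b, c) + dot(b, Gb);
  };
  vec Gbeta = G * beta;
  double rss = rss_of(beta, Gbeta);
  bool converged = false, monitor_stop = false;
  uvec prev_supp = find(beta != 0.0);
  double step = 0.0;
  uvec step_supp;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    vec bn = beta + c - Gbeta;
    hard_threshold(bn, lam);
    uvec S = find(bn != 0.0);
    if (S.n_elem == 0) {
      beta.zeros();
      converged = true;
      break;
    }
    mat Gs = G.submat(S, S);
    vec cs = c(S);
    vec bs = bn(S);
    if (exact_debias) {
      Gs.diag() += 1e-12 * (trace(Gs) / (double)S.n_elem + 1.0);
      bs = solve(Gs, cs, solve_opts::likely_sympd);
    } else {
      if (step_supp.n_elem != S.n_elem || any(step_supp != S)) {
        step = 1.0 / eig_sym(Gs).max();   // 1 / ||X_S||_2^2
        step_supp = S;
      }
      const double bound = lam * (double)S.n_elem;
      const double gtol = debias_tol * lam;   // threshold-relative tolerance
      for (int d = 0; d < debias_max; ++d) {
        const vec Gb = Gs * bs;
        if (use_bound && yty - 2.0 * dot(bs, cs) + dot(bs, Gb) <= bound)
          break;
        const vec g = cs - Gb;
        if (norm(g, "inf") < gtol) break;
        bs += step * g;
      }
    }
    vec bnew(p, fill::zeros);
    bnew(S) = bs;
    const double change = norm(bnew - beta, "inf");
    vec Gbnew = G * bnew;
    const double rssn = rss_of(bnew, Gbnew);
    const bool same_supp = (S.n_elem == prev_supp.n_elem) &&
      (S.n_elem == 0 || all(S == prev_supp));
    if (same_supp && change < tol) { beta = bnew; converged = true; break; }
    if (rssn >= (1.0 - cmon) * rss && same_supp) {
      beta = bnew;
      monitor_stop = true;
      break;
    }
    beta = bnew;
    Gbeta = Gbnew;
    rss = rssn;
    prev_supp = S;
  }
  return Rcpp::List::create(Rcpp::_["beta"] = beta,
                            Rcpp::_["converged"] = converged,
                            Rcpp::_["monitor_stop"] = monitor_stop,
                            Rcpp::_["iter"] = it + 1);
}

// [[Rcpp::export]]
Rcpp::List cpp_iht_d(const arma::mat& X, const arma::vec& y, double lam,
                     arma::vec beta, int max_iter, double tol, int debias_max,
                     double cmon, bool use_bound, double debias_tol,
                     bool exact_debias) {
  return iht_d_gram(X.t() * X, X.t() * y, dot(y, y), lam, beta, max_iter,
                    tol, debias_max, cmon, use_bound, debias_tol,
                    exact_debias);
}

// Paths over a descending lambda grid. Every lambda restarts from the same
// initial point (zeros or the ridge-stabilized LS solution): warm starts
// from a neighbouring lambda can lock the non-convex iterations into a
// support found there.
// [[Rcpp::export]]
arma::mat cpp_iht_path(const arma::mat& X, const arma::vec& y,
                       const arma::vec& lambdas, int max_iter, double tol,
                       double cmon, bool ls_init) {
  const uword p = X.n_cols, M = lambdas.n_elem;
  mat out(p, M, fill::zeros);
  const vec b0 = ls_init ? cpp_ridge_init(X, y) : vec(p, fill::zeros);
  for (uword m = 0; m < M; ++m) {
    Rcpp::List fit = cpp_iht(X, y, lambdas(m), b0, max_iter, tol, cmon);
    out.col(m) = Rcpp::as<vec>(fit["beta"]);
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_iht_d_path(const arma::mat& X, const arma::vec& y,
                         const arma::vec& lambdas, int max_iter, double tol,
                         int debias_max, double cmon, bool use_bound,
                         double debias_tol, bool ls_init, bool exact_debias) {
  const uword p = X.n_cols, M = lambdas.n_elem;
  mat out(p, M, fill::zeros);
  const mat G = X.t() * X;
  const vec c = X.t() * y;
  const double yty = dot(y, y);
  const vec b0 = ls_init ? cpp_ridge_init(X, y) : vec(p, fill::zeros);
  for (uword m = 0; m < M; ++m) {
    Rcpp::List fit = iht_d_gram(G, c, yty, lambdas(m), b0, max_iter, tol,
                                debias_max, cmon, use_bound, debias_tol,
                                exact_debias);
    out.col(m) = Rcpp::as<vec>(fit["beta"]);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_spec_norm(const arma::mat& X) {
  return norm(X, 2);
}

// Full stability-selection inner loop for the hard-thresholding family:
// for each of the B row-subsamples (columns of `rows`, 1-based indices),
// standardize the sub-design (centre, unit mean square; response centred),
// jointly rescale by the spectral norm times (1 + delta), run the IHT(-d)
// path cold-started per lambda, and accumulate per-(lambda, component)
// selection counts.
// [[Rcpp::export]]
arma::mat cpp_stability_counts(const arma::mat& X, const arma::vec& y,
                               const arma::umat& rows,
                               const arma::vec& lambdas, bool debias,
                               int max_iter, double tol, int debias_max,
                               double cmon, bool use_bound, double debias_tol,
                               double delta, bool ls_init, bool exact_debias) {
  const uword p = X.n_cols, M = lambdas.n_elem, B = rows.n_cols;
  mat counts(M, p, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    uvec idx = rows.col(b) - 1;
    mat Xs = X.rows(idx);
    vec ys = y(idx);
    rowvec mu = mean(Xs, 0);
    Xs.each_row() -= mu;
    rowvec sc = sqrt(mean(square(Xs), 0));
    // a column that is constant within this subsample carries no signal;
    // neutralise it (zero column) rather than aborting the whole sweep
    for (uword j = 0; j < p; ++j) if (sc(j) < 1e-12) sc(j) = 1.0;
    Xs.each_row() /= sc;
    ys -= mean(ys);
    // spectral norm via the Gram matrix (exact, p x p eigenproblem)
    vec eig = eig_sym(Xs.t() * Xs);
    const double s = 1.0 / (std::sqrt(eig.max()) * (1.0 + delta));
    Xs *= s;
    ys *= s;
    const vec b0 = ls_init ? cpp_ridge_init(Xs, ys) : vec(p, fill::zeros);
    const mat Gsub = Xs.t() * Xs;
    const vec csub = Xs.t() * ys;
    const double yty = dot(ys, ys);
    for (uword k = 0; k < M; ++k) {
      Rcpp::List fit = debias
        ? iht_d_gram(Gsub, csub, yty, lambdas(k), b0, max_iter, tol,
                     debias_max, cmon, use_bound, debias_tol, exact_debias)
        : cpp_iht(Xs, ys, lambdas(k), b0, max_iter, tol, cmon);
      vec beta = Rcpp::as<vec>(fit["beta"]);
      for (uword j = 0; j < p; ++j)
        if (beta(j) != 0.0) counts(k, j) += 1.0;
    }
  }
  return counts;
}
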