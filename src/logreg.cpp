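// L2-regularized logistic regression via damped Newton iterations, plus the
// inner cross-validation grid search used by the nested CV. The objective is
//   f(w, b) = mean_i log(1 + exp(-s_i (x_i' w + b))) + lambda/2 * ||w||^2
// with s_i in {-1, +1}; the intercept is unpenalized.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double obj_value(const mat& X, const vec& s, double lambda,
                        const vec& w, double b) {
  vec m = s % (X * w + b);
  double f = 0.0;
  for (uword i = 0; i < m.n_elem; ++i) {
    double mi = m(i);
    f += (mi > 0) ? std::log1p(std::exp(-mi)) : (-mi + std::log1p(std::exp(mi)));
  }
  return f / m.n_elem + 0.5 * lambda * dot(w, w);
}

// y must be 0/1. Returns convergence info through the output arguments.
static void newton_fit(const mat& X, const vec& y, double lambda, double tol,
                       int maxit, vec& w, double& b, int& iters,
                       double& gnorm, bool& conv) {
  const uword n = X.n_rows, d = X.n_cols;
  w.zeros(d);
  b = 0.0;
  vec s = 2.0 * y - 1.0;
  conv = false;
  double fcur = obj_value(X, s, lambda, w, b);
  for (iters = 0; iters < maxit; ++iters) {
    vec z = X * w + b;
    vec p = 1.0 / (1.0 + exp(-z));
    vec r = (p - y) / n;
    vec gw = X.t() * r + lambda * w;
    double gb = accu(r);
    gnorm = std::max(norm(gw, "inf"), std::fabs(gb));
    if (gnorm < tol) { conv = true; return; }
    vec sw = p % (1.0 - p) / n;
    mat Xs = X.each_col() % sw;
    mat H(d + 1, d + 1);
    H.submat(0, 0, d - 1, d - 1) = X.t() * Xs + lambda * eye(d, d);
    vec hx = sum(Xs, 0).t();
    H.submat(0, d, d - 1, d) = hx;
    H.submat(d, 0, d, d - 1) = hx.t();
    H(d, d) = accu(sw);
    H.diag() += 1e-12;
    vec g(d + 1);
    g.head(d) = gw;
    g(d) = gb;
    vec step;
    if (!solve(step, H, g, solve_opts::likely_sympd + solve_opts::no_approx))
      step = pinv(H) * g;
    // damped update: halve until the objective decreases
    double t = 1.0;
    for (int ls = 0; ls < 30; ++ls) {
      vec wn = w - t * step.head(d);
      double bn = b - t * step(d);
      double fn = obj_value(X, s, lambda, wn, bn);
      if (fn <= fcur + 1e-14) { w = wn; b = bn; fcur = fn; break; }
      t *= 0.5;
    }
  }
  vec z = X * w + b;
  vec p = 1.0 / (1.0 + exp(-z));
  vec r = (p - y) / n;
  gnorm = std::max(norm(X.t() * r + lambda * w, "inf"),
                   std::fabs(accu(r)));
  conv = gnorm < tol;
}

// [[Rcpp::export(name = ".lrFitCpp")]]
Rcpp::List lrFitCpp(const arma::mat& X, const arma::vec& y, double lambda,
                    double tol = 1e-7, int maxit = 1000) {
  vec w;
  double b, gnorm;
  int iters;
  bool conv;
  newton_fit(X, y, lambda, tol, maxit, w, b, iters, gnorm, conv);
  return Rcpp::List::create(Rcpp::Named("w") = w, Rcpp::Named("b") = b,
                            Rcpp::Named("iterations") = iters,
                            Rcpp::Named("gradNorm") = gnorm,
                            Rcpp::Named("converged") = conv);
}

// Inner CV: for each lambda, k-fold CV accuracy on (X, y) with the given
// fold assignment (1-based fold ids). X is assumed already normalized with
// the outer-training statistics.
// [[Rcpp::export(name = ".lrCvAccCpp")]]
arma::vec lrCvAccCpp(const arma::mat& X, const arma::vec& y,
                     const arma::ivec& foldId, const arma::vec& lambdas,
                     double tol = 1e-7, int maxit = 200) {
  const int k = foldId.max();
  vec acc(lambdas.n_elem, fill::zeros);
  for (int f = 1; f <= k; ++f) {
    uvec te = find(foldId == f);
    uvec tr = find(foldId != f);
    mat Xtr = X.rows(tr), Xte = X.rows(te);
    vec ytr = y.elem(tr), yte = y.elem(te);
    for (uword li = 0; li < lambdas.n_elem; ++li) {
      vec w;
      double b, gnorm;
      int iters;
      bool conv;
      newton_fit(Xtr, ytr, lambdas(li), tol, maxit, w, b, iters, gnorm, conv);
      vec pred = Xte * w + b;
      acc(li) += accu((pred > 0) == (yte > 0.5));
    }
  }
  return acc / X.n_rows;
}
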