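#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Wrap a list of numeric matrices as arma views without copying.
static std::vector<arma::mat> view_list(List Xs) {
  std::vector<arma::mat> out;
  out.reserve(Xs.size());
  for (R_xlen_t i = 0; i < Xs.size(); ++i) {
    NumericMatrix m = Xs[i];
    out.emplace_back(m.begin(), m.nrow(), m.ncol(), false, true);
  }
  return out;
}

static std::vector<arma::vec> view_vec_list(List ys) {
  std::vector<arma::vec> out;
  out.reserve(ys.size());
  for (R_xlen_t i = 0; i < ys.size(); ++i) {
    NumericVector v = ys[i];
    out.emplace_back(v.begin(), v.size(), false, true);
  }
  return out;
}

// Largest eigenvalue of the aggregated per-group Gram matrix
// sum_i (X_g^i)' X_g^i.  Groups are contiguous column blocks given by
// 0-based starts and sizes.  The group spectral norm ||X_g||_2 is the
// square root of the returned value.
// [[Rcpp::export]]
arma::vec cpp_group_lipschitz(List Xs, IntegerVector gstart, IntegerVector gsize) {
  std::vector<arma::mat> X = view_list(Xs);
  const int G = gstart.size();
  arma::vec L(G, arma::fill::zeros);
  for (int g = 0; g < G; ++g) {
    const int s = gstart[g], k = gsize[g];
    arma::mat gram(k, k, arma::fill::zeros);
    for (size_t i = 0; i < X.size(); ++i) {
      const arma::mat blk = X[i].cols(s, s + k - 1);
      gram += blk.t() * blk;
    }
    arma::vec ev;
    arma::eig_sym(ev, arma::symmatu(gram));
    L[g] = ev.max();
  }
  return L;
}

// One federated BCD solve at a fixed lambda.  Residuals r_i = X_i beta - y_i
// are maintained per site; each group update aggregates per-site partial
// gradients (X_g^i)' r_i in ascending site order, applies the group
// soft-threshold step with the blockwise Lipschitz constant, and pushes the
// coefficient change back into every site's residual.  Only p_g-length
// aggregates cross site boundaries.
// [[Rcpp::export]]
List cpp_bcd_solve(List Xs, List ys, arma::vec beta,
                   IntegerVector gstart, IntegerVector gsize,
                   arma::vec wg, arma::vec L,
                   IntegerVector active,
                   double lambda, double tol, int max_epochs) {
  std::vector<arma::mat> X = view_list(Xs);
  std::vector<arma::vec> y = view_vec_list(ys);
  const size_t I = X.size();
  const int G = gstart.size();

  // residuals from the warm start
  std::vector<arma::vec> r(I);
  for (size_t i = 0; i < I; ++i) r[i] = -y[i];
  for (int g = 0; g < G; ++g) {
    const int s = gstart[g], k = gsize[g];
    const arma::vec bg = beta.subvec(s, s + k - 1);
    if (arma::any(bg != 0.0)) {
      for (size_t i = 0; i < I; ++i) r[i] += X[i].cols(s, s + k - 1) * bg;
    }
  }

  auto objective = [&]() -> double {
    double quad = 0.0;
    for (size_t i = 0; i < I; ++i) quad += arma::dot(r[i], r[i]);
    double pen = 0.0;
    for (int g = 0; g < G; ++g) {
      const int s = gstart[g], k = gsize[g];
      pen += wg[g] * arma::norm(beta.subvec(s, s + k - 1), 2);
    }
    return 0.5 * quad + lambda * pen;
  };

  double obj_prev = objective();
  std::vector<double> trace;
  trace.push_back(obj_prev);
  long long updates = 0;
  int epochs = 0;
  bool converged = false;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    for (int a = 0; a < active.size(); ++a) {
      const int g = active[a];
      const int s = gstart[g], k = gsize[g];
      ++updates;
      if (L[g] <= 0.0) continue;  // all-zero columns: beta_g stays as is
      arma::vec grad(k, arma::fill::zeros);
      for (size_t i = 0; i < I; ++i)
        grad += X[i].cols(s, s + k - 1).t() * r[i];
      arma::vec bg = beta.subvec(s, s + k - 1);
      arma::vec z = bg - grad / L[g];
      const double nz = arma::norm(z, 2);
      const double t = lambda * wg[g] / L[g];
      arma::vec bnew(k, arma::fill::zeros);
      if (nz > t && nz > 0.0) bnew = z * (1.0 - t / nz);
      arma::vec delta = bnew - bg;
      if (arma::any(delta != 0.0)) {
        for (size_t i = 0; i < I; ++i)
          r[i] += X[i].cols(s, s + k - 1) * delta;
        beta.subvec(s, s + k - 1) = bnew;
      }
    }
    epochs = epoch;
    const double obj = objective();
    trace.push_back(obj);
    if (!std::isfinite(obj))
      stop("objective diverged (non-finite) at epoch %d", epoch);
    const double denom = std::max(std::abs(obj_prev), 1e-300);
    if (std::abs(obj_prev - obj) / denom < tol) { converged = true; obj_prev = obj; break; }
    obj_prev = obj;
  }

  return List::create(
    _["beta"] = beta,
    _["objective"] = obj_prev,
    _["epochs_run"] = epochs,
    _["converged"] = converged,
    _["n_updates"] = (double)updates,
    _["trace"] = trace);
}
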