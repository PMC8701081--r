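// HALS solver for the NMF objective 0.5 * ||R - W H||_F^2 with W, H >= 0.
// Each column of W (row of H) is updated by exact nonnegative least squares
// given the others, so the objective is non-increasing across sweeps.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double frob_objective(const mat& R, const mat& W, const mat& H) {
  return 0.5 * accu(square(R - W * H));
}

// [[Rcpp::export]]
Rcpp::List cpp_nmf_hals(const arma::mat& R,
                        arma::mat W,
                        arma::mat H,
                        int max_iter,
                        double tol) {
  const uword k = W.n_cols;
  const double eps = 1e-16;

  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  double obj = frob_objective(R, W, H);
  trace.push_back(obj);

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    // Update H: for each topic j, exact NNLS in row H(j,.)
    mat WtW = W.t() * W;          // k x k
    mat WtR = W.t() * R;          // k x m
    for (uword j = 0; j < k; ++j) {
      double d = WtW(j, j);
      if (d < eps) continue;      // dead topic, leave untouched
      rowvec h = H.row(j) + (WtR.row(j) - WtW.row(j) * H) / d;
      H.row(j) = clamp(h, 0.0, datum::inf);
    }

    // Update W: for each topic j, exact NNLS in column W(.,j)
    mat HHt = H * H.t();          // k x k
    mat RHt = R * H.t();          // n x k
    for (uword j = 0; j < k; ++j) {
      double d = HHt(j, j);
      if (d < eps) continue;
      vec w = W.col(j) + (RHt.col(j) - W * HHt.col(j)) / d;
      W.col(j) = clamp(w, 0.0, datum::inf);
    }

    double obj_new = frob_objective(R, W, H);
    trace.push_back(obj_new);
    double denom = std::max(obj, 1e-12);
    if ((obj - obj_new) / denom < tol) {
      obj = obj_new;
      converged = true;
      break;
    }
    obj = obj_new;
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("objective") = obj,
    Rcpp::Named("objective_trace") = trace,
    Rcpp::Named("n_iter") = std::min(iter, max_iter),
    Rcpp::Named("converged") = converged);
}
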