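#include <Rcpp.h>
using namespace Rcpp;

// Coordinate-descent non-negative least squares on a sparse (CSC) system:
// minimize ||A w - b||^2 + lambda ||w||^2 subject to w >= 0.
// A is m x m with column j stored in Ai/Ax over [Ap[j], Ap[j+1]).
//
// Full sweeps over all coordinates alternate with repeated sweeps over the
// active set (coordinates that moved in the last full sweep); convergence is
// declared only when a full sweep moves no coordinate by more than tol, so
// the stationarity check always covers every coordinate. max_sweeps counts
// both full and active-set sweeps.
// [[Rcpp::export]]
List nnls_cd_sparse(IntegerVector Ai, IntegerVector Ap, NumericVector Ax,
                    int m, NumericVector b, double lambda, double tol,
                    int max_sweeps, NumericVector w0) {
  std::vector<double> w(m, 1.0);
  if (w0.size() == m) {
    for (int j = 0; j < m; ++j) w[j] = w0[j];
  }
  std::vector<double> r(m);
  for (int i = 0; i < m; ++i) r[i] = b[i];
  for (int j = 0; j < m; ++j) {
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) r[Ai[k]] -= Ax[k] * w[j];
  }
  std::vector<double> ss(m, 0.0);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) s += Ax[k] * Ax[k];
    ss[j] = s;
  }
  std::vector<int> active;
  active.reserve(m);

  auto update_one = [&](int j) -> double {
    double g = 0.0;
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) g += Ax[k] * r[Ai[k]];
    double delta = (g - lambda * w[j]) / (ss[j] + lambda);
    double wn = w[j] + delta;
    if (wn < 0.0) wn = 0.0;
    delta = wn - w[j];
    if (delta != 0.0) {
      for (int k = Ap[j]; k < Ap[j + 1]; ++k) r[Ai[k]] -= Ax[k] * delta;
      w[j] = wn;
    }
    return std::abs(delta);
  };

  bool converged = false;
  int sweep = 0;
  while (sweep < max_sweeps) {
    // full sweep: update everything and rebuild the active set
    ++sweep;
    active.clear();
    double maxd = 0.0;
    for (int j = 0; j < m; ++j) {
      double ad = update_one(j);
      if (ad > maxd) maxd = ad;
      if (ad > tol) active.push_back(j);
    }
    if (maxd < tol) {
      converged = true;
      break;
    }
    // inner sweeps over the active set until it is internally converged
    while (sweep < max_sweeps && !active.empty()) {
      ++sweep;
      double amaxd = 0.0;
      for (size_t t = 0; t < active.size(); ++t) {
        double ad = update_one(active[t]);
        if (ad > amaxd) amaxd = ad;
      }
      if (amaxd < tol) break;
    }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["converged"] = converged, _["sweeps"] = sweep);
}
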