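#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularised L1-loss (hinge) linear
// SVM (Hsieh et al., ICML 2008), with the shrinking heuristic and the
// PGmax - PGmin stopping rule of liblinear. The bias is handled
// liblinear-style by augmenting each sample with a constant feature, so it
// is (weakly) regularised. Coordinates are visited in a randomly permuted
// order per pass; the permutation comes from an internal fixed-seed
// xorshift generator, so the solver is fully deterministic and independent
// of R's RNG state. The primal weight vector at the dual optimum is
// unique, so visiting order affects speed only.
//
// X: n x d training matrix, y: +/-1 labels, C: per-sample cost
// (class weighting folds in here). alpha0 optionally warm-starts the dual
// variables (clamped into [0, C]); nested training windows make the
// previous window's solution an excellent start. Returns a list with the
// (d+1)-vector (w, b) and the dual variables.
// [[Rcpp::export]]
List svm_dcd_fit(NumericMatrix X, NumericVector y, NumericVector C,
                 int max_passes = 1000, double tol = 1e-3,
                 Nullable<NumericVector> alpha0 = R_NilValue) {
  const int n = X.nrow(), d = X.ncol();
  // row-contiguous copy (R matrices are column-major; the inner loops
  // walk one sample's features)
  std::vector<double> Xr((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int f = 0; f < d; ++f) Xr[(size_t)i * d + f] = X(i, f);
  std::vector<double> w(d + 1, 0.0), alpha(n, 0.0), qii(n);
  if (alpha0.isNotNull()) {
    NumericVector a0(alpha0);
    for (int i = 0; i < n; ++i) {
      double a = a0[i];
      if (a < 0.0) a = 0.0;
      if (a > C[i]) a = C[i];
      alpha[i] = a;
      if (a != 0.0) {
        const double *xi = &Xr[(size_t)i * d];
        double delta = a * y[i];
        for (int f = 0; f < d; ++f) w[f] += delta * xi[f];
        w[d] += delta;
      }
    }
  }
  std::vector<int> index(n);
  for (int i = 0; i < n; ++i) {
    index[i] = i;
    double s = 1.0;                       // bias feature
    const double *xi = &Xr[(size_t)i * d];
    for (int f = 0; f < d; ++f) s += xi[f] * xi[f];
    qii[i] = s;
  }
  uint64_t rng = 88172645463325252ull;    // xorshift64 state, fixed seed
  int active = n;
  double pgmax_old = R_PosInf, pgmin_old = R_NegInf;
  for (int pass = 0; pass < max_passes; ++pass) {
    double pgmax = R_NegInf, pgmin = R_PosInf;
    for (int i = active - 1; i > 0; --i) {  // Fisher-Yates over active set
      rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
      std::swap(index[i], index[rng % (uint64_t)(i + 1)]);
    }
    for (int t = 0; t < active; ++t) {
      int i = index[t];
      const double *xi = &Xr[(size_t)i * d];
      double wx = w[d];
      for (int f = 0; f < d; ++f) wx += w[f] * xi[f];
      double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0) {
        if (G > pgmax_old) {                // shrink
          std::swap(index[t], index[--active]);
          --t;
          continue;
        }
        if (G > 0.0) PG = 0.0;
      } else if (alpha[i] >= C[i]) {
        if (G < pgmin_old) {                // shrink
          std::swap(index[t], index[--active]);
          --t;
          continue;
        }
        if (G < 0.0) PG = 0.0;
      }
      if (PG > pgmax) pgmax = PG;
      if (PG < pgmin) pgmin = PG;
      if (std::fabs(PG) > 1e-12) {
        double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C[i]) a_new = C[i];
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0) {
          for (int f = 0; f < d; ++f) w[f] += delta * xi[f];
          w[d] += delta;
        }
      }
    }
    if (pgmax - pgmin <= tol) {
      if (active == n) break;
      active = n;                           // unshrink and take a full pass
      pgmax_old = R_PosInf; pgmin_old = R_NegInf;
      continue;
    }
    pgmax_old = (pgmax <= 0.0) ? R_PosInf : pgmax;
    pgmin_old = (pgmin >= 0.0) ? R_NegInf : pgmin;
  }
  NumericVector wout(d + 1), aout(n);
  for (int f = 0; f <= d; ++f) wout[f] = w[f];
  for (int i = 0; i < n; ++i) aout[i] = alpha[i];
  return List::create(Named("w") = wout, Named("alpha") = aout);
}
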