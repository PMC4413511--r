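#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Pairwise squared Euclidean distances between rows of A and rows of B.
// [[Rcpp::export]]
NumericMatrix sqdist_cpp(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow(), p = A.ncol();
  if (B.ncol() != p) stop("column mismatch");
  NumericMatrix D(na, nb);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int t = 0; t < p; ++t) {
        double d = A(i, t) - B(j, t);
        s += d * d;
      }
      D(i, j) = s;
    }
  }
  return D;
}

// C-SVC dual solved by SMO with first-order (maximal violating pair)
// working-set selection, in the style of LIBSVM:
//   min 0.5 a'Qa - e'a  s.t. 0 <= a_i <= C, y'a = 0,  Q_ij = y_i y_j K_ij
// K is the RBF kernel exp(-gamma * d2) built from the precomputed squared
// distance matrix d2 so grid search can reuse one d2 across (C, gamma).
// [[Rcpp::export]]
List smo_train_cpp(NumericMatrix d2, IntegerVector y, double C, double gamma,
                   double eps = 1e-3, int max_iter = 100000) {
  int n = d2.nrow();
  if (d2.ncol() != n || y.size() != n) stop("dimension mismatch");
  if (C <= 0 || gamma <= 0) stop("C and gamma must be positive");

  std::vector<double> K(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      K[static_cast<size_t>(i) * n + j] = std::exp(-gamma * d2(i, j));

  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G = Qa - e
  const double TAU = 1e-12;
  int iter = 0;

  for (; iter < max_iter; ++iter) {
    // select i: max -y_t G_t over I_up; j: min -y_t G_t over I_low
    int i = -1, j = -1;
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;

    const double Kii = K[static_cast<size_t>(i) * n + i];
    const double Kjj = K[static_cast<size_t>(j) * n + j];
    const double Kij = K[static_cast<size_t>(i) * n + j];
    double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
      double quad = Kii + Kjj + 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    if (dai == 0.0 && daj == 0.0) break;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * y[i] * K[static_cast<size_t>(i) * n + t] * dai +
              y[t] * y[j] * K[static_cast<size_t>(j) * n + t] * daj;
    }
  }

  // bias: average of -y_t G_t over free vectors, else midpoint of bounds
  double bsum = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 0 && alpha[t] < C) { bsum += -y[t] * G[t]; ++nfree; }
  }
  double b;
  if (nfree > 0) {
    b = bsum / nfree;
  } else {
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > gmax) gmax = v;
      if (low && v < gmin) gmin = v;
    }
    b = (gmax + gmin) / 2.0;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter);
}
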