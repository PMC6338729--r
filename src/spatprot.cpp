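#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Radial basis function kernel K(x, y) = exp(-sigma * ||x - y||^2).
// Convention matches the printed sigma of the classification protocol
// (kernlab's rbfdot), NOT libsvm's "gamma = 1/(2 sigma^2)" variant.
// [[Rcpp::export]]
NumericMatrix cpp_rbf_kernel(NumericMatrix X, NumericMatrix Y, double sigma) {
  const int n = X.nrow(), m = Y.nrow(), d = X.ncol();
  if (Y.ncol() != d) stop("dimension mismatch between X and Y");
  NumericMatrix K(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int t = 0; t < d; ++t) {
        const double diff = X(i, t) - Y(j, t);
        s += diff * diff;
      }
      K(i, j) = std::exp(-sigma * s);
    }
  }
  return K;
}

// C-SVC dual solved by SMO with maximal-violating-pair working-set
// selection.  K is the kernel matrix over the training points, y in
// {-1, +1}.  Returns alpha, the intercept b (decision value is
// sum_s alpha_s y_s K(x, s) + b), and the number of iterations.
// [[Rcpp::export]]
List cpp_smo_train(NumericMatrix K, IntegerVector y, double C,
                   double tol = 1e-3, int max_iter = 100000) {
  const int n = K.nrow();
  if (y.size() != n || K.ncol() != n) stop("kernel/label size mismatch");
  std::vector<double> alpha(n, 0.0);
  // gradient of 0.5 a'Qa - e'a with Q_ts = y_t y_s K_ts; at a = 0 it is -e
  std::vector<double> grad(n, -1.0);
  int iter = 0;
  double m_up = 0.0, m_low = 0.0;
  bool converged = false;
  for (iter = 0; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    m_up = -std::numeric_limits<double>::infinity();
    m_low = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * grad[t];
      const bool in_up  = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      const bool in_low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      if (in_up && v > m_up)  { m_up = v;  i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < tol) { converged = true; break; }
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 0) eta = 1e-12;
    double d = (m_up - m_low) / eta;
    // box constraints; the equality y'a = 0 is preserved by construction
    double d_max = (y[i] == 1) ? (C - alpha[i]) : alpha[i];
    double d_max2 = (y[j] == 1) ? alpha[j] : (C - alpha[j]);
    if (d_max2 < d_max) d_max = d_max2;
    if (d > d_max) d = d_max;
    alpha[i] += y[i] * d;
    alpha[j] -= y[j] * d;
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * d * (K(t, i) - K(t, j));
  }
  // intercept from free support vectors; midpoint rule as fallback
  double b = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) {
      b += -y[t] * grad[t];
      ++nfree;
    }
  }
  if (nfree > 0) b /= nfree; else b = (m_up + m_low) / 2.0;
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = converged);
}

// Pairwise coupling of one-vs-one class probabilities (Wu & Lin 2004,
// their second method).  rpair is n_query x n_pair with entries
// r_ij = P(class i | i or j); iIdx/jIdx give the (0-based) class index
// of each pair column.  Returns n_query x k class probabilities.
// [[Rcpp::export]]
NumericMatrix cpp_couple_probs(NumericMatrix rpair, IntegerVector iIdx,
                               IntegerVector jIdx, int k,
                               int max_iter = 200, double eps = 1e-10) {
  const int nq = rpair.nrow(), np = rpair.ncol();
  NumericMatrix P(nq, k);
  std::vector<std::vector<double> > r(k, std::vector<double>(k, 0.0));
  std::vector<std::vector<double> > Q(k, std::vector<double>(k, 0.0));
  std::vector<double> p(k), Qp(k);
  for (int q = 0; q < nq; ++q) {
    for (int c = 0; c < np; ++c) {
      const int i = iIdx[c], j = jIdx[c];
      double rij = rpair(q, c);
      if (rij < 1e-12) rij = 1e-12;
      if (rij > 1.0 - 1e-12) rij = 1.0 - 1e-12;
      r[i][j] = rij;
      r[j][i] = 1.0 - rij;
    }
    for (int i = 0; i < k; ++i) {
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        if (j == i) continue;
        Q[i][j] = -r[j][i] * r[i][j];
        s += r[j][i] * r[j][i];
      }
      Q[i][i] = s;
      p[i] = 1.0 / k;
    }
    for (int it = 0; it < max_iter; ++it) {
      double pQp = 0.0;
      for (int i = 0; i < k; ++i) {
        double s = 0.0;
        for (int j = 0; j < k; ++j) s += Q[i][j] * p[j];
        Qp[i] = s;
        pQp += p[i] * s;
      }
      double maxdev = 0.0;
      for (int i = 0; i < k; ++i)
        maxdev = std::max(maxdev, std::fabs(Qp[i] - pQp));
      if (maxdev < eps) break;
      for (int t = 0; t < k; ++t) {
        double sum = 0.0;
        double pQp2 = 0.0;
        for (int j = 0; j < k; ++j) {
          if (j != t) sum += Q[t][j] * p[j];
        }
        // one Gauss-Seidel style update of p_t followed by renormalisation
        for (int i = 0; i < k; ++i) {
          double s = 0.0;
          for (int j = 0; j < k; ++j) s += Q[i][j] * p[j];
          pQp2 += p[i] * s;
        }
        p[t] = (-sum + pQp2) / Q[t][t];
        if (p[t] < 0) p[t] = 0;
        double tot = 0.0;
        for (int i = 0; i < k; ++i) tot += p[i];
        for (int i = 0; i < k; ++i) p[i] /= tot;
      }
    }
    for (int i = 0; i < k; ++i) P(q, i) = p[i];
  }
  return P;
}

// Null overlap counts for the selection-bias-corrected category test.
// Draws `ndraws` sets of `size` items without replacement from a
// universe of length(w) items with inclusion probability proportional
// to w (Efraimidis-Spirakis exponential keys, R RNG), and returns the
// overlap of each draw with each category (list of 0-based index
// vectors) as an ndraws x ncat integer matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_null_overlaps(NumericVector w, int size, int ndraws,
                                List members) {
  const int n = w.size();
  const int ncat = members.size();
  if (size < 0 || size > n) stop("invalid draw size");
  std::vector<std::vector<int> > cats(ncat);
  for (int c = 0; c < ncat; ++c) {
    IntegerVector m = members[c];
    cats[c].assign(m.begin(), m.end());
    for (size_t t = 0; t < cats[c].size(); ++t)
      if (cats[c][t] < 0 || cats[c][t] >= n) stop("member index out of range");
  }
  IntegerMatrix out(ndraws, ncat);
  std::vector<double> key(n);
  std::vector<int> idx(n);
  std::vector<char> sel(n);
  RNGScope scope;
  for (int d = 0; d < ndraws; ++d) {
    for (int t = 0; t < n; ++t) {
      key[t] = ::exp_rand() / w[t];
      idx[t] = t;
    }
    std::nth_element(idx.begin(), idx.begin() + size, idx.end(),
                     [&key](int a, int b) { return key[a] < key[b]; });
    std::fill(sel.begin(), sel.end(), 0);
    for (int t = 0; t < size; ++t) sel[idx[t]] = 1;
    for (int c = 0; c < ncat; ++c) {
      int ov = 0;
      for (size_t t = 0; t < cats[c].size(); ++t) ov += sel[cats[c][t]];
      out(d, c) = ov;
    }
  }
  return out;
}

// One weighted sample without replacement (indices, 1-based), used by
// the generic weighted-draw utility.
// [[Rcpp::export]]
IntegerVector cpp_weighted_sample(NumericVector w, int size) {
  const int n = w.size();
  if (size < 0 || size > n) stop("invalid draw size");
  std::vector<double> key(n);
  std::vector<int> idx(n);
  RNGScope scope;
  for (int t = 0; t < n; ++t) {
    key[t] = ::exp_rand() / w[t];
    idx[t] = t;
  }
  std::nth_element(idx.begin(), idx.begin() + size, idx.end(),
                   [&key](int a, int b) { return key[a] < key[b]; });
  IntegerVector out(size);
  for (int t = 0; t < size; ++t) out[t] = idx[t] + 1;
  return out;
}
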