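#include <Rcpp.h>
using namespace Rcpp;

// Boosted decision stumps on a dense feature matrix. The stump search
// re-scans every feature with a presorted order each round, so training is
// exactly deterministic for fixed inputs. Returned matrix: one row per
// learner with columns (feature 1-based; 0 = constant stump), threshold,
// left response (x <= t), right response, split gain.

static void presort(const NumericMatrix &X, std::vector<std::vector<int>> &ord) {
  const int n = X.nrow(), p = X.ncol();
  ord.assign(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    std::vector<int> &o = ord[j];
    for (int i = 0; i < n; ++i) o[i] = i;
    const double *col = &X(0, j);
    std::stable_sort(o.begin(), o.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }
}

// Best weighted least-squares stump for response z with weights w.
// Returns gain relative to the constant fit; responses are weighted means.
struct Stump { int feature; double threshold, left, right, gain; };

static Stump best_ls_stump(const NumericMatrix &X,
                           const std::vector<std::vector<int>> &ord,
                           const std::vector<double> &w,
                           const std::vector<double> &z) {
  const int n = X.nrow(), p = X.ncol();
  double W = 0.0, WZ = 0.0;
  for (int i = 0; i < n; ++i) { W += w[i]; WZ += w[i] * z[i]; }
  const double base = (W > 0) ? WZ * WZ / W : 0.0;
  Stump best = {0, NA_REAL, WZ / std::max(W, 1e-300),
                WZ / std::max(W, 1e-300), 0.0};
  for (int j = 0; j < p; ++j) {
    const double *col = &X(0, j);
    const std::vector<int> &o = ord[j];
    double wl = 0.0, wzl = 0.0;
    for (int r = 0; r < n - 1; ++r) {
      const int i = o[r];
      wl += w[i]; wzl += w[i] * z[i];
      const double x0 = col[o[r]], x1 = col[o[r + 1]];
      if (x1 <= x0) continue;  // no split between equal values
      const double wr = W - wl, wzr = WZ - wzl;
      if (wl < 1e-300 || wr < 1e-300) continue;
      const double gain = wzl * wzl / wl + wzr * wzr / wr - base;
      if (gain > best.gain) {
        best.feature = j + 1;
        best.threshold = 0.5 * (x0 + x1);
        best.left = wzl / wl;
        best.right = wzr / wr;
        best.gain = gain;
      }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".logitboost_train_cpp")]]
NumericMatrix logitboost_train_cpp(NumericMatrix X, IntegerVector y,
                                   NumericVector w0, int n_learners,
                                   double learning_rate,
                                   double z_max, double p_min) {
  const int n = X.nrow();
  std::vector<std::vector<int>> ord;
  presort(X, ord);
  std::vector<double> F(n, 0.0), w(n), z(n);
  NumericMatrix stumps(n_learners, 5);
  for (int m = 0; m < n_learners; ++m) {
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-2.0 * F[i]));
      if (p < p_min) p = p_min; else if (p > 1.0 - p_min) p = 1.0 - p_min;
      const double pq = p * (1.0 - p);
      w[i] = w0[i] * pq;
      double zi = (y[i] - p) / pq;
      if (zi > z_max) zi = z_max; else if (zi < -z_max) zi = -z_max;
      z[i] = zi;
    }
    const Stump s = best_ls_stump(X, ord, w, z);
    stumps(m, 0) = s.feature;
    stumps(m, 1) = s.threshold;
    stumps(m, 2) = s.left;
    stumps(m, 3) = s.right;
    stumps(m, 4) = s.gain;
    if (s.feature == 0) {
      for (int i = 0; i < n; ++i) F[i] += learning_rate * s.left;
    } else {
      const double *col = &X(0, s.feature - 1);
      for (int i = 0; i < n; ++i)
        F[i] += learning_rate * (col[i] <= s.threshold ? s.left : s.right);
    }
  }
  return stumps;
}

// AdaBoost.M1 with classification stumps; responses already include the
// learner weight alpha so that score = sum(learning_rate * response).
// [[Rcpp::export(name = ".adaboostm1_train_cpp")]]
NumericMatrix adaboostm1_train_cpp(NumericMatrix X, IntegerVector y,
                                   NumericVector w0, int n_learners,
                                   double learning_rate) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<std::vector<int>> ord;
  presort(X, ord);
  std::vector<double> d(n);
  double wsum = 0.0;
  for (int i = 0; i < n; ++i) wsum += w0[i];
  for (int i = 0; i < n; ++i) d[i] = w0[i] / wsum;
  std::vector<int> ypm(n);
  for (int i = 0; i < n; ++i) ypm[i] = y[i] == 1 ? 1 : -1;
  NumericMatrix stumps(n_learners, 5);
  for (int m = 0; m < n_learners; ++m) {
    // find stump (feature, threshold, left class) minimizing weighted error
    double best_err = R_PosInf, best_thr = NA_REAL;
    int best_j = 0, best_pol = 1;
    double Dpos = 0.0;
    for (int i = 0; i < n; ++i) if (ypm[i] == 1) Dpos += d[i];
    const double Dtot = std::accumulate(d.begin(), d.end(), 0.0);
    for (int j = 0; j < p; ++j) {
      const double *col = &X(0, j);
      const std::vector<int> &o = ord[j];
      double posl = 0.0, dl = 0.0;
      for (int r = 0; r < n - 1; ++r) {
        const int i = o[r];
        dl += d[i];
        if (ypm[i] == 1) posl += d[i];
        const double x0 = col[o[r]], x1 = col[o[r + 1]];
        if (x1 <= x0) continue;
        // left = +1: errors are negatives left + positives right
        const double err_pos = (dl - posl) + (Dpos - posl);
        const double err_neg = Dtot - err_pos;
        if (err_pos < best_err) {
          best_err = err_pos; best_j = j + 1;
          best_thr = 0.5 * (x0 + x1); best_pol = 1;
        }
        if (err_neg < best_err) {
          best_err = err_neg; best_j = j + 1;
          best_thr = 0.5 * (x0 + x1); best_pol = -1;
        }
      }
    }
    if (best_j == 0) { // all features constant: stop with zero stumps
      stumps(m, 0) = 0; stumps(m, 1) = NA_REAL;
      stumps(m, 2) = 0; stumps(m, 3) = 0; stumps(m, 4) = 0;
      continue;
    }
    double eps = best_err / Dtot;
    if (eps < 1e-10) eps = 1e-10;
    if (eps > 1.0 - 1e-10) eps = 1.0 - 1e-10;
    const double alpha = 0.5 * std::log((1.0 - eps) / eps);
    stumps(m, 0) = best_j;
    stumps(m, 1) = best_thr;
    stumps(m, 2) = alpha * best_pol;
    stumps(m, 3) = -alpha * best_pol;
    stumps(m, 4) = Dtot - 2.0 * best_err > 0 ? Dtot - 2.0 * best_err : 0.0;
    const double *col = &X(0, best_j - 1);
    double dnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      const int h = (col[i] <= best_thr ? best_pol : -best_pol);
      d[i] *= std::exp(-learning_rate * alpha * h * ypm[i]);
      dnorm += d[i];
    }
    for (int i = 0; i < n; ++i) d[i] /= dnorm;
  }
  return stumps;
}
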