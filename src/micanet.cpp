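#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Random-forest regression importance (GENIE3-style total variance reduction)
// ---------------------------------------------------------------------------

namespace {

struct ForestCtx {
  const double* X;   // column-major n x p
  const double* y;
  int n;
  int p;
  int mtry;
  int min_split;
  std::vector<double> importance;
  std::vector<int> varpool;
  std::vector<std::pair<double, double> > xy;  // scratch: (x, y) per node
};

void grow_node(ForestCtx& ctx, std::vector<int>& idx) {
  const int n = (int)idx.size();
  if (n < ctx.min_split) return;
  double s = 0.0, ss = 0.0;
  for (int i : idx) { const double v = ctx.y[i]; s += v; ss += v * v; }
  const double ss_parent = ss - s * s / n;  // sum of squares about the mean
  if (ss_parent <= 1e-12) return;

  // partial Fisher-Yates draw of mtry candidate variables via R's RNG
  std::vector<int>& pool = ctx.varpool;
  for (int i = 0; i < ctx.mtry; ++i) {
    int j = i + (int)(unif_rand() * (ctx.p - i));
    if (j >= ctx.p) j = ctx.p - 1;
    std::swap(pool[i], pool[j]);
  }

  double best_gain = 0.0, best_thr = 0.0;
  int best_var = -1;
  std::vector<std::pair<double, double> >& xy = ctx.xy;
  for (int vi = 0; vi < ctx.mtry; ++vi) {
    const int v = pool[vi];
    const double* xcol = ctx.X + (size_t)v * ctx.n;
    xy.resize(n);
    for (int k = 0; k < n; ++k) {
      const int i = idx[k];
      xy[k].first = xcol[i];
      xy[k].second = ctx.y[i];
    }
    std::sort(xy.begin(), xy.end());
    double sl = 0.0, ssl = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      const double yk = xy[k].second;
      sl += yk; ssl += yk * yk;
      if (xy[k].first == xy[k + 1].first) continue;  // no split between equal x
      const int nl = k + 1, nr = n - nl;
      const double sr = s - sl, ssr = ss - ssl;
      const double gain = ss_parent - (ssl - sl * sl / nl) - (ssr - sr * sr / nr);
      if (gain > best_gain) {
        best_gain = gain;
        best_var = v;
        best_thr = (xy[k].first + xy[k + 1].first) / 2.0;
      }
    }
  }
  if (best_var < 0) return;
  ctx.importance[best_var] += best_gain;

  const double* xbest = ctx.X + (size_t)best_var * ctx.n;
  std::vector<int> left, right;
  left.reserve(n); right.reserve(n);
  for (int i : idx) {
    if (xbest[i] <= best_thr) left.push_back(i);
    else right.push_back(i);
  }
  if (left.empty() || right.empty()) return;
  grow_node(ctx, left);
  grow_node(ctx, right);
}

}  // namespace

// Total variance-reduction importance of each predictor column of X for the
// response y, averaged over `ntrees` trees grown on bootstrap resamples.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector rf_importance_cpp(NumericMatrix X, NumericVector y,
                                int ntrees, int mtry, int min_split,
                                bool bootstrap) {
  const int n = X.nrow(), p = X.ncol();
  ForestCtx ctx;
  ctx.X = X.begin();
  ctx.y = y.begin();
  ctx.n = n;
  ctx.p = p;
  ctx.mtry = std::max(1, std::min(mtry, p));
  ctx.min_split = std::max(2, min_split);
  ctx.importance.assign(p, 0.0);
  ctx.varpool.resize(p);
  for (int j = 0; j < p; ++j) ctx.varpool[j] = j;
  RNGScope scope;
  for (int t = 0; t < ntrees; ++t) {
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int j = (int)(unif_rand() * n);
        idx[i] = j >= n ? n - 1 : j;
      }
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    grow_node(ctx, idx);
  }
  NumericVector out(p);
  for (int j = 0; j < p; ++j) out[j] = ctx.importance[j] / ntrees;
  return out;
}

// ---------------------------------------------------------------------------
// L0L2 coordinate descent with hard thresholding
// ---------------------------------------------------------------------------

// Minimises 0.5 * ||y - X b||^2 + gamma * ||b||_0 + lambda * ||b||_2^2
// by cyclic coordinate descent. For coordinate j with column norm s_j and
// full partial residual correlation c_j, the stationary value is
// b_j = c_j / (s_j + 2 lambda); it is kept iff the objective gain
// c_j^2 / (2 (s_j + 2 lambda)) exceeds gamma, else b_j = 0.
// [[Rcpp::export]]
List l0l2_cd_cpp(NumericMatrix X, NumericVector y, double gamma, double lambda,
                 NumericVector b_init, int max_iter, double tol) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector b = clone(b_init);
  std::vector<double> s(p);
  for (int j = 0; j < p; ++j) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += X(i, j) * X(i, j);
    s[j] = acc;
  }
  // residual r = y - X b
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) {
    double acc = y[i];
    for (int j = 0; j < p; ++j)
      if (b[j] != 0.0) acc -= X(i, j) * b[j];
    r[i] = acc;
  }
  // objective 0.5*||r||^2 + gamma*||b||_0 + lambda*||b||^2; every exact
  // coordinate update is non-increasing, so stop on relative objective stall
  // (coefficient-wise stopping can cycle under the hard threshold).
  auto objective = [&]() {
    double rss = 0.0, l2 = 0.0;
    int l0 = 0;
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    for (int j = 0; j < p; ++j)
      if (b[j] != 0.0) { ++l0; l2 += b[j] * b[j]; }
    return 0.5 * rss + gamma * l0 + lambda * l2;
  };
  bool converged = false;
  int it = 0;
  double obj_prev = objective();
  for (; it < max_iter; ++it) {
    bool moved = false;
    for (int j = 0; j < p; ++j) {
      if (s[j] <= 0.0) { b[j] = 0.0; continue; }
      double c = 0.0;
      for (int i = 0; i < n; ++i) c += X(i, j) * r[i];
      c += s[j] * b[j];
      const double denom = s[j] + 2.0 * lambda;
      const double gain = c * c / (2.0 * denom);
      const double b_new = (gain > gamma) ? c / denom : 0.0;
      const double delta = b_new - b[j];
      if (delta != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * delta;
        b[j] = b_new;
        moved = true;
      }
    }
    const double obj = objective();
    if (!moved || obj_prev - obj < tol * (1.0 + obj)) {
      converged = true; ++it; break;
    }
    obj_prev = obj;
  }
  return List::create(_["b"] = b, _["converged"] = converged,
                      _["iterations"] = it);
}
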