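// Core tree/forest engine.
//
// Criteria codes: 1 = least squares (SSE), 2 = Gini (binary 0/1 response,
// node score n*p*(1-p), identical to SSE for a 0/1 response), 3 =
// zero-truncated Poisson log-likelihood (responses >= 1, maximized).
//
// All randomness flows through std::mt19937_64 streams seeded via
// splitmix64 from (forest seed, tree index); raw engine output is consumed
// directly (modulo reduction) so results are bit-reproducible across
// platforms, independent of R's RNG.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

static const double MU_MIN = 1e-8;

// ---------------------------------------------------------------- RNG ----

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t tree_seed(uint64_t forest_seed, uint64_t index) {
  return splitmix64(splitmix64(forest_seed) ^ splitmix64(index + 1));
}

// uniform integer in [0, n), slight modulo bias is irrelevant here
static inline size_t rng_below(std::mt19937_64 &rng, size_t n) {
  return static_cast<size_t>(rng() % n);
}

// draw k of 0..(p-1) without replacement (partial Fisher-Yates), ascending
static std::vector<int> sample_features(std::mt19937_64 &rng, int p, int k) {
  std::vector<int> pool(p);
  for (int i = 0; i < p; ++i) pool[i] = i;
  std::vector<int> out(k);
  for (int i = 0; i < k; ++i) {
    size_t j = i + rng_below(rng, p - i);
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
  std::sort(out.begin(), out.end());
  return out;
}

// ---------------------------------------------------------------- ZTP ----

// Solve mean = mu / (1 - exp(-mu)) for mu; safeguarded Newton.
static double ztp_mu_from_mean(double target) {
  if (!(target > 1.0 + 1e-8)) return MU_MIN;
  double lo = 1e-12, hi = 2.0 * std::max(target, 2.0);
  double mu = (target > 10.0) ? target : 2.0 * (target - 1.0);
  if (mu <= lo || mu >= hi) mu = 0.5 * (lo + hi);
  for (int it = 0; it < 200; ++it) {
    double em = -std::expm1(-mu);  // 1 - e^{-mu}
    double m = mu / em;
    double f = m - target;
    if (std::fabs(f) < 1e-11) return mu;
    if (f > 0.0) hi = mu; else lo = mu;
    double dm = (em - mu * std::exp(-mu)) / (em * em);
    double mu_new = mu - f / dm;
    if (!(mu_new > lo && mu_new < hi)) mu_new = 0.5 * (lo + hi);
    mu = mu_new;
  }
  return mu;
}

// [[Rcpp::export]]
NumericVector cpp_ztp_mu_from_mean(NumericVector target) {
  NumericVector out(target.size());
  for (R_xlen_t i = 0; i < target.size(); ++i)
    out[i] = ztp_mu_from_mean(target[i]);
  return out;
}

// partial ZTP log-likelihood (the sum log(y!) term, constant in mu, is
// dropped; it cancels between a parent node and the union of its children)
static inline double ztp_ll_partial(double n, double S, double mu) {
  return -n * std::log(-std::expm1(-mu)) + S * std::log(mu) - n * mu;
}

// ------------------------------------------------------- split search ----

struct SplitResult {
  bool found;
  int feature;      // 0-based
  double threshold;
  double obj;       // children objective (lower is better)
};

// objective of one child from sufficient stats; for LS/GINI uses (n, S, S2),
// for ZTP uses (n, S) with a fresh per-child mu-hat
static inline double child_obj(int crit, double n, double S, double S2) {
  if (crit == 3) {
    double mu = ztp_mu_from_mean(S / n);
    return -ztp_ll_partial(n, S, mu);
  }
  return S2 - S * S / n;  // SSE; equals n*p*(1-p) for 0/1 responses
}

// Search all admissible (feature, threshold) pairs over `cand` (ascending),
// row subset `rows`. Candidate thresholds are midpoints between consecutive
// distinct sorted feature values. A candidate replaces the incumbent only
// when it improves by more than a relative tolerance tied to the parent
// score (and the first accepted candidate must beat the parent by the same
// margin). This keeps the (lowest feature, lowest threshold) tie-break
// robust to float accumulation order — exact-tie partitions, e.g. from
// bootstrap-duplicated rows, resolve identically in an independent
// enumeration oracle applying the same rule.
static SplitResult best_split_impl(const NumericMatrix &X,
                                   const NumericVector &y,
                                   const std::vector<int> &rows,
                                   const std::vector<int> &cand,
                                   int nodesize, int crit) {
  SplitResult best;
  best.found = false;
  const int n = static_cast<int>(rows.size());
  if (n < 2 * nodesize) return best;

  std::vector<double> xv(n), yv(n);
  std::vector<int> ord(n);

  double ptotS = 0, ptotQ = 0;
  for (int i = 0; i < n; ++i) {
    double yi = y[rows[i]];
    ptotS += yi; ptotQ += yi * yi;
  }
  const double parent = child_obj(crit, n, ptotS, ptotQ);
  const double eps = 1e-9 * (std::fabs(parent) + 1.0);
  best.obj = parent;

  for (size_t c = 0; c < cand.size(); ++c) {
    const int j = cand[c];
    bool binary = true;
    for (int i = 0; i < n; ++i) {
      xv[i] = X(rows[i], j);
      yv[i] = y[rows[i]];
      if (binary && xv[i] != 0.0 && xv[i] != 1.0) binary = false;
    }

    if (binary) {
      // single candidate threshold 0.5
      double n0 = 0, S0 = 0, Q0 = 0, n1 = 0, S1 = 0, Q1 = 0;
      for (int i = 0; i < n; ++i) {
        if (xv[i] == 0.0) { n0 += 1; S0 += yv[i]; Q0 += yv[i] * yv[i]; }
        else              { n1 += 1; S1 += yv[i]; Q1 += yv[i] * yv[i]; }
      }
      if (n0 >= nodesize && n1 >= nodesize) {
        double obj = child_obj(crit, n0, S0, Q0) + child_obj(crit, n1, S1, Q1);
        if (obj < best.obj - eps) {
          best.found = true; best.feature = j; best.threshold = 0.5;
          best.obj = obj;
        }
      }
      continue;
    }

    for (int i = 0; i < n; ++i) ord[i] = i;
    // stable sort so tied x keep row order: accumulation order is
    // reproducible by an independent (stable-order) enumeration oracle
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return xv[a] < xv[b]; });

    double totS = 0, totQ = 0;
    for (int i = 0; i < n; ++i) { totS += yv[i]; totQ += yv[i] * yv[i]; }

    double nl = 0, Sl = 0, Ql = 0;
    for (int i = 0; i < n - 1; ++i) {
      const double yi = yv[ord[i]];
      nl += 1; Sl += yi; Ql += yi * yi;
      const double xlo = xv[ord[i]], xhi = xv[ord[i + 1]];
      if (xlo == xhi) continue;
      if (nl < nodesize || (n - nl) < nodesize) continue;
      double thr = 0.5 * (xlo + xhi);
      if (thr >= xhi) thr = xlo;  // rounding guard: keep the same partition
      double obj = child_obj(crit, nl, Sl, Ql) +
                   child_obj(crit, n - nl, totS - Sl, totQ - Ql);
      if (obj < best.obj - eps) {
        best.found = true; best.feature = j; best.threshold = thr;
        best.obj = obj;
      }
    }
  }

  return best;
}

// [[Rcpp::export]]
SEXP cpp_best_split(NumericMatrix X, NumericVector y, IntegerVector rows,
                    IntegerVector cand, int nodesize, int crit) {
  std::vector<int> r(rows.begin(), rows.end());
  std::vector<int> cf(cand.begin(), cand.end());
  SplitResult s = best_split_impl(X, y, r, cf, nodesize, crit);
  if (!s.found) return R_NilValue;
  double totS = 0, totQ = 0;
  for (size_t i = 0; i < r.size(); ++i) {
    double yi = y[r[i]]; totS += yi; totQ += yi * yi;
  }
  double parent = child_obj(crit, (double)r.size(), totS, totQ);
  return List::create(_["feature"] = s.feature + 1,
                      _["threshold"] = s.threshold,
                      _["gain"] = parent - s.obj);
}

// ------------------------------------------------------------- trees -----

struct TreeBuf {
  std::vector<int> feature;     // 1-based, -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right; // 1-based node ids, 0 = none
  std::vector<double> value;
  std::vector<int> n;
};

static double leaf_value(const NumericVector &y, const std::vector<int> &rows,
                         int crit) {
  double S = 0;
  for (size_t i = 0; i < rows.size(); ++i) S += y[rows[i]];
  double mean = S / rows.size();
  if (crit == 3) return ztp_mu_from_mean(mean);
  return mean;  // LS mean; GINI class-1 proportion
}

static int grow_node(const NumericMatrix &X, const NumericVector &y,
                     std::vector<int> &rows, int depth, int mtry,
                     int nodesize, int max_depth, int crit,
                     std::mt19937_64 &rng, TreeBuf &tb) {
  const int id = static_cast<int>(tb.feature.size());
  tb.feature.push_back(-1);
  tb.threshold.push_back(NA_REAL);
  tb.left.push_back(0);
  tb.right.push_back(0);
  tb.value.push_back(0.0);
  tb.n.push_back(static_cast<int>(rows.size()));

  const int n = static_cast<int>(rows.size());
  bool pure = true;
  for (int i = 1; i < n && pure; ++i)
    if (y[rows[i]] != y[rows[0]]) pure = false;

  if (n >= 2 * nodesize && depth < max_depth && !pure) {
    std::vector<int> cand = sample_features(rng, X.ncol(), mtry);
    SplitResult s = best_split_impl(X, y, rows, cand, nodesize, crit);
    if (s.found) {
      std::vector<int> lrows, rrows;
      for (int i = 0; i < n; ++i) {
        if (X(rows[i], s.feature) <= s.threshold) lrows.push_back(rows[i]);
        else rrows.push_back(rows[i]);
      }
      tb.feature[id] = s.feature + 1;
      tb.threshold[id] = s.threshold;
      int lid = grow_node(X, y, lrows, depth + 1, mtry, nodesize, max_depth,
                          crit, rng, tb);
      int rid = grow_node(X, y, rrows, depth + 1, mtry, nodesize, max_depth,
                          crit, rng, tb);
      tb.left[id] = lid + 1;
      tb.right[id] = rid + 1;
      return id;
    }
  }
  tb.value[id] = leaf_value(y, rows, crit);
  return id;
}

static List tree_to_list(const TreeBuf &tb) {
  return List::create(_["feature"] = IntegerVector(tb.feature.begin(), tb.feature.end()),
                      _["threshold"] = NumericVector(tb.threshold.begin(), tb.threshold.end()),
                      _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
                      _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
                      _["value"] = NumericVector(tb.value.begin(), tb.value.end()),
                      _["n"] = IntegerVector(tb.n.begin(), tb.n.end()));
}

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, NumericVector y, int crit, int mtry,
                   int nodesize, int max_depth, double seed) {
  std::mt19937_64 rng(tree_seed(static_cast<uint64_t>(seed), 0));
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  TreeBuf tb;
  grow_node(X, y, rows, 0, mtry, nodesize, max_depth, crit, rng, tb);
  return tree_to_list(tb);
}

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericVector y, int crit, int mtry,
                     int nodesize, int max_depth, int ntree, double seed,
                     bool bootstrap, bool keep_inbag) {
  const int n = X.nrow();
  List trees(ntree);
  IntegerMatrix inbag;
  if (keep_inbag) inbag = IntegerMatrix(n, ntree);
  for (int b = 0; b < ntree; ++b) {
    std::mt19937_64 rng(tree_seed(static_cast<uint64_t>(seed), b));
    std::vector<int> rows(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) rows[i] = static_cast<int>(rng_below(rng, n));
      std::sort(rows.begin(), rows.end());
    } else {
      for (int i = 0; i < n; ++i) rows[i] = i;
    }
    if (keep_inbag)
      for (int i = 0; i < n; ++i) inbag(rows[i], b) += 1;
    TreeBuf tb;
    grow_node(X, y, rows, 0, mtry, nodesize, max_depth, crit, rng, tb);
    trees[b] = tree_to_list(tb);
  }
  if (keep_inbag) return List::create(_["trees"] = trees, _["inbag"] = inbag);
  return List::create(_["trees"] = trees);
}

// ---------------------------------------------------------- prediction ---

// predict one row; if swap_col >= 0, feature swap_col reads swap_val instead
static inline double predict_row_fast(const int *feature, const double *threshold,
                                      const int *left, const int *right,
                                      const double *value,
                                      const NumericMatrix &X, int i,
                                      int swap_col, double swap_val) {
  int node = 0;
  while (feature[node] != -1) {
    int j = feature[node] - 1;
    double x = (j == swap_col) ? swap_val : X(i, j);
    node = (x <= threshold[node]) ? left[node] - 1 : right[node] - 1;
  }
  return value[node];
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector value = tree["value"];
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    out[i] = predict_row_fast(feature.begin(), threshold.begin(), left.begin(),
                              right.begin(), value.begin(), X, i, -1, 0.0);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_forest_trees(List trees, NumericMatrix X) {
  const int B = trees.size();
  NumericMatrix out(X.nrow(), B);
  for (int b = 0; b < B; ++b) {
    List tree = trees[b];
    IntegerVector feature = tree["feature"];
    NumericVector threshold = tree["threshold"];
    IntegerVector left = tree["left"], right = tree["right"];
    NumericVector value = tree["value"];
    for (int i = 0; i < X.nrow(); ++i)
      out(i, b) = predict_row_fast(feature.begin(), threshold.begin(),
                                   left.begin(), right.begin(), value.begin(),
                                   X, i, -1, 0.0);
  }
  return out;
}

// ------------------------------------------------------------- VIM -------

// Per-tree, per-predictor prediction-error differences on a test set.
// pe_type: 0 = mean squared error, 1 = misclassification rate at 0.5.
// Returns a B x p matrix of PE(permuted) - PE(original).
// Permutations come from a per-tree seeded stream; n_perm permutations per
// predictor are averaged.
// [[Rcpp::export]]
NumericMatrix cpp_forest_vim(List trees, NumericMatrix X, NumericVector y,
                             int pe_type, int n_perm, double seed) {
  const int B = trees.size(), n = X.nrow(), p = X.ncol();
  NumericMatrix D(B, p);
  std::vector<int> perm(n);
  for (int b = 0; b < B; ++b) {
    List tree = trees[b];
    IntegerVector feature = tree["feature"];
    NumericVector threshold = tree["threshold"];
    IntegerVector left = tree["left"], right = tree["right"];
    NumericVector value = tree["value"];
    const int *fe = feature.begin(); const double *th = threshold.begin();
    const int *le = left.begin(); const int *ri = right.begin();
    const double *va = value.begin();

    double pe0 = 0.0;
    for (int i = 0; i < n; ++i) {
      double pr = predict_row_fast(fe, th, le, ri, va, X, i, -1, 0.0);
      if (pe_type == 1) pe0 += ((pr > 0.5 ? 1.0 : 0.0) != y[i]);
      else { double d = pr - y[i]; pe0 += d * d; }
    }
    pe0 /= n;

    // features never used in this tree have exactly zero difference
    std::vector<bool> used(p, false);
    for (R_xlen_t k = 0; k < feature.size(); ++k)
      if (feature[k] != -1) used[feature[k] - 1] = true;

    std::mt19937_64 rng(tree_seed(static_cast<uint64_t>(seed) ^ 0xA5A5A5A5ULL, b));
    for (int j = 0; j < p; ++j) {
      if (!used[j]) { D(b, j) = 0.0; continue; }
      double acc = 0.0;
      for (int rep = 0; rep < n_perm; ++rep) {
        for (int i = 0; i < n; ++i) perm[i] = i;
        for (int i = n - 1; i > 0; --i) {
          size_t k = rng_below(rng, i + 1);
          std::swap(perm[i], perm[k]);
        }
        double pe = 0.0;
        for (int i = 0; i < n; ++i) {
          double pr = predict_row_fast(fe, th, le, ri, va, X, i, j,
                                       X(perm[i], j));
          if (pe_type == 1) pe += ((pr > 0.5 ? 1.0 : 0.0) != y[i]);
          else { double d = pr - y[i]; pe += d * d; }
        }
        acc += pe / n - pe0;
      }
      D(b, j) = acc / n_perm;
    }
  }
  return D;
}
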