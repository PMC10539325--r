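// Exact path-dependent TreeSHAP for gradient-boosted binary trees, in
// double precision. Follows the published polynomial-time algorithm: a
// path of (feature, zero-fraction, one-fraction, weight) elements is
// extended down each tree and unwound to read off per-feature Shapley
// contributions at the leaves. Expectations are cover-weighted, i.e.
// conditioned on the training-data split proportions.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathElem {
  int d;       // feature index of the split that created this element
  double z;    // fraction of "zero" (feature hidden) paths that flow down
  double o;    // fraction of "one" (feature observed) paths (0 or 1)
  double w;    // permutation weight
};

static void extend_path(std::vector<PathElem>& m, double pz, double po,
                        int pi) {
  int l = (int) m.size();
  PathElem e; e.d = pi; e.z = pz; e.o = po; e.w = (l == 0) ? 1.0 : 0.0;
  m.push_back(e);
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / (double)(l + 1);
    m[i].w = pz * m[i].w * (l - i) / (double)(l + 1);
  }
}

static void unwind_path(std::vector<PathElem>& m, int i) {
  int l = (int) m.size() - 1;
  double n = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (m[i].o != 0.0) {
      double t = m[j].w;
      m[j].w = n * (l + 1) / ((j + 1) * m[i].o);
      n = t - m[j].w * m[i].z * (l - j) / (double)(l + 1);
    } else {
      m[j].w = m[j].w * (l + 1) / (m[i].z * (l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    m[j].d = m[j + 1].d; m[j].z = m[j + 1].z; m[j].o = m[j + 1].o;
  }
  m.pop_back();
}

static double unwound_sum(const std::vector<PathElem>& m, int i) {
  int l = (int) m.size() - 1;
  double total = 0.0, n = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (m[i].o != 0.0) {
      double t = n * (l + 1) / ((j + 1) * m[i].o);
      total += t;
      n = m[j].w - t * m[i].z * (l - j) / (double)(l + 1);
    } else {
      total += m[j].w * (l + 1) / (m[i].z * (l - j));
    }
  }
  return total;
}

struct TreeArrays {
  const IntegerVector& feature;   // -1 for leaf
  const NumericVector& split;
  const IntegerVector& yes;
  const IntegerVector& no;
  const IntegerVector& missing;
  const NumericVector& value;
  const NumericVector& cover;
};

static void recurse(const TreeArrays& T, const NumericVector& x,
                    NumericVector& phi, int j, std::vector<PathElem> m,
                    double pz, double po, int pi) {
  extend_path(m, pz, po, pi);
  if (T.feature[j] < 0) {                       // leaf
    for (int i = 1; i < (int) m.size(); ++i) {
      phi[m[i].d] += unwound_sum(m, i) * (m[i].o - m[i].z) * T.value[j];
    }
    return;
  }
  int f = T.feature[j];
  double xv = x[f];
  int hot, cold;
  if (NumericVector::is_na(xv)) hot = T.missing[j];
  else hot = ((float) xv < (float) T.split[j]) ? T.yes[j] : T.no[j];
  cold = (hot == T.yes[j]) ? T.no[j] : T.yes[j];
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int) m.size(); ++i) {
    if (m[i].d == f) { k = i; break; }
  }
  if (k >= 0) {
    iz = m[k].z; io = m[k].o;
    unwind_path(m, k);
  }
  recurse(T, x, phi, hot, m, iz * T.cover[hot] / T.cover[j], io, f);
  recurse(T, x, phi, cold, m, iz * T.cover[cold] / T.cover[j], 0.0, f);
}

static double tree_expectation(const TreeArrays& T, int j) {
  if (T.feature[j] < 0) return T.value[j];
  return (T.cover[T.yes[j]] * tree_expectation(T, T.yes[j]) +
          T.cover[T.no[j]] * tree_expectation(T, T.no[j])) / T.cover[j];
}

// [[Rcpp::export]]
NumericMatrix treeshap_cpp(NumericMatrix x, IntegerVector feature,
                           NumericVector split, IntegerVector yes,
                           IntegerVector no, IntegerVector missing,
                           NumericVector value, NumericVector cover,
                           IntegerVector roots) {
  int n = x.nrow(), p = x.ncol(), ntree = roots.size();
  TreeArrays T = {feature, split, yes, no, missing, value, cover};
  double bias = 0.0;
  for (int t = 0; t < ntree; ++t) bias += tree_expectation(T, roots[t]);
  NumericMatrix out(n, p + 1);
  for (int r = 0; r < n; ++r) {
    NumericVector xi = x(r, _);
    NumericVector phi(p);
    for (int t = 0; t < ntree; ++t) {
      std::vector<PathElem> m;
      recurse(T, xi, phi, roots[t], m, 1.0, 1.0, -1);
    }
    for (int c = 0; c < p; ++c) out(r, c) = phi[c];
    out(r, p) = bias;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector tree_margin_cpp(NumericMatrix x, IntegerVector feature,
                              NumericVector split, IntegerVector yes,
                              IntegerVector no, IntegerVector missing,
                              NumericVector value, IntegerVector roots) {
  int n = x.nrow(), ntree = roots.size();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    double tot = 0.0;
    for (int t = 0; t < ntree; ++t) {
      int j = roots[t];
      while (feature[j] >= 0) {
        double xv = x(r, feature[j]);
        if (NumericVector::is_na(xv)) j = missing[j];
        else j = ((float) xv < (float) split[j]) ? yes[j] : no[j];
      }
      tot += value[j];
    }
    out[r] = tot;
  }
  return out;
}
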