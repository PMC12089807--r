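// Exact path-dependent TreeSHAP for binary trees with numeric splits
// (x <= threshold goes left). Node weights ("covers") are the counts of a
// reference dataset routed through each tree; conditional expectations for
// features absent from a coalition average the two branches by cover.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  const int *left, *right, *feature;
  const double *thr, *value, *cover;
};

// Unique-feature path state of the recursion: feature index d, zero/one
// fractions z/o, and the permutation weights w.
struct PathState {
  std::vector<int> d;
  std::vector<double> z, o, w;
};

void extend(PathState &m, double pz, double po, int pi) {
  int l = static_cast<int>(m.d.size());
  m.d.push_back(pi);
  m.z.push_back(pz);
  m.o.push_back(po);
  m.w.push_back(l == 0 ? 1.0 : 0.0);
  for (int i = l - 1; i >= 0; --i) {
    m.w[i + 1] += po * m.w[i] * (i + 1) / static_cast<double>(l + 1);
    m.w[i] = pz * m.w[i] * (l - i) / static_cast<double>(l + 1);
  }
}

void unwind(PathState &m, int i) {
  int l = static_cast<int>(m.d.size()) - 1;
  double one = m.o[i], zero = m.z[i];
  double next = m.w[l];
  if (one != 0) {
    for (int j = l - 1; j >= 0; --j) {
      double tmp = m.w[j];
      m.w[j] = next * (l + 1) / static_cast<double>((j + 1) * one);
      next = tmp - m.w[j] * zero * (l - j) / static_cast<double>(l + 1);
    }
  } else {
    for (int j = l - 1; j >= 0; --j)
      m.w[j] = m.w[j] * (l + 1) / (zero * (l - j));
  }
  for (int j = i; j < l; ++j) {
    m.d[j] = m.d[j + 1];
    m.z[j] = m.z[j + 1];
    m.o[j] = m.o[j + 1];
  }
  m.d.pop_back(); m.z.pop_back(); m.o.pop_back(); m.w.pop_back();
}

double unwound_sum(const PathState &m, int i) {
  int l = static_cast<int>(m.d.size()) - 1;
  double one = m.o[i], zero = m.z[i];
  double next = m.w[l], total = 0.0;
  if (one != 0) {
    for (int j = l - 1; j >= 0; --j) {
      double tmp = next / static_cast<double>((j + 1) * one);
      total += tmp;
      next = m.w[j] - tmp * zero * (l - j);
    }
  } else {
    for (int j = l - 1; j >= 0; --j)
      total += m.w[j] / (zero * (l - j));
  }
  return total * (l + 1);
}

void recurse(const Tree &tr, const double *x, double *phi, PathState m,
             int node, double pz, double po, int pi) {
  extend(m, pz, po, pi);
  int f = tr.feature[node];
  if (f < 0) {  // leaf
    int l = static_cast<int>(m.d.size()) - 1;
    for (int i = 1; i <= l; ++i) {
      double w = unwound_sum(m, i);
      phi[m.d[i]] += w * (m.o[i] - m.z[i]) * tr.value[node];
    }
    return;
  }
  int lc = tr.left[node], rc = tr.right[node];
  int hot = (x[f] <= tr.thr[node]) ? lc : rc;
  int cold = (hot == lc) ? rc : lc;
  double iz = 1.0, io = 1.0;
  int l = static_cast<int>(m.d.size()) - 1;
  int k = -1;
  for (int i = 1; i <= l; ++i)
    if (m.d[i] == f) { k = i; break; }
  if (k >= 0) {
    iz = m.z[k];
    io = m.o[k];
    unwind(m, k);
  }
  double cov = tr.cover[node];
  recurse(tr, x, phi, m, hot, iz * tr.cover[hot] / cov, io, f);
  recurse(tr, x, phi, m, cold, iz * tr.cover[cold] / cov, 0.0, f);
}

}  // namespace

// [[Rcpp::export]]
List treeshap_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol(), T = trees.size();
  NumericMatrix phi(n, p);
  double base = 0.0;
  std::vector<double> xrow(p), ph(p);
  for (int t = 0; t < T; ++t) {
    List tl = trees[t];
    IntegerVector left = tl["left"], right = tl["right"],
                  feature = tl["feature"];
    NumericVector thr = tl["threshold"], val = tl["value"],
                  cov = tl["cover"];
    Tree tr{left.begin(), right.begin(), feature.begin(),
            thr.begin(), val.begin(), cov.begin()};
    const int nn = left.size();
    double ev = 0.0;
    for (int j = 0; j < nn; ++j)
      if (feature[j] < 0) ev += cov[j] / cov[0] * val[j];
    base += ev / T;
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
      std::fill(ph.begin(), ph.end(), 0.0);
      PathState m;
      recurse(tr, xrow.data(), ph.data(), m, 0, 1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += ph[j] / T;
    }
    if (t % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}

// Count how many rows of X reach each node of a tree.
// [[Rcpp::export]]
NumericVector tree_cover_cpp(IntegerVector left, IntegerVector right,
                             IntegerVector feature, NumericVector threshold,
                             NumericMatrix X) {
  const int nn = left.size(), n = X.nrow();
  NumericVector cover(nn);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    for (;;) {
      cover[node] += 1.0;
      int f = feature[node];
      if (f < 0) break;
      node = (X(i, f) <= threshold[node]) ? left[node] : right[node];
    }
  }
  return cover;
}
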