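#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Portable deterministic RNG (splitmix64 seeding, xorshift64* stream),
// independent of the standard library's implementation-defined
// distributions so fits are bit-identical across platforms.
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) {
    s = seed + 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x106689D45497FDB5ULL;
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int below(int n) {  // uniform in [0, n), unbiased by rejection
    uint64_t lim = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
    uint64_t x;
    do { x = next(); } while (x >= lim);
    return (int)(x % (uint64_t)n);
  }
};

// An ensemble is stored flat: per-node arrays concatenated over trees plus
// a tree_start offset vector; left/right are local (within-tree) indices.
struct Forest {
  std::vector<int> feature;  // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> value;
  std::vector<int> tree_start;

  void begin_tree() { tree_start.push_back((int)feature.size()); }
  int n_trees() const { return (int)tree_start.size(); }
  int tree_size(int t) const {
    const int end = (t + 1 < n_trees()) ? tree_start[t + 1]
                                        : (int)feature.size();
    return end - tree_start[t];
  }
  double predict_tree(int t, const double* xrow, int nrow_stride) const {
    const int off = tree_start[t];
    int nd = 0;
    while (feature[off + nd] >= 0) {
      const double v = xrow[(size_t)feature[off + nd] * nrow_stride];
      nd = (v <= thr[off + nd]) ? left[off + nd] : right[off + nd];
    }
    return value[off + nd];
  }
  List to_list() const {
    return List::create(
        _["feature"] = IntegerVector(feature.begin(), feature.end()),
        _["thr"] = NumericVector(thr.begin(), thr.end()),
        _["left"] = IntegerVector(left.begin(), left.end()),
        _["right"] = IntegerVector(right.begin(), right.end()),
        _["value"] = NumericVector(value.begin(), value.end()),
        _["tree_start"] = IntegerVector(tree_start.begin(),
                                        tree_start.end()));
  }
  static Forest from_list(List fl) {
    Forest fo;
    IntegerVector f = fl["feature"], l = fl["left"], r = fl["right"],
                  ts = fl["tree_start"];
    NumericVector t = fl["thr"], v = fl["value"];
    fo.feature.assign(f.begin(), f.end());
    fo.thr.assign(t.begin(), t.end());
    fo.left.assign(l.begin(), l.end());
    fo.right.assign(r.begin(), r.end());
    fo.value.assign(v.begin(), v.end());
    fo.tree_start.assign(ts.begin(), ts.end());
    return fo;
  }
};

// Quantile-binned feature codes (histogram split finding). Bin b of feature
// f covers values in (edge[b-1], edge[b]]; edges are actual data values, so
// a split "x <= edge[b]" routes training rows exactly as their codes do.
struct BinnedX {
  int n, p, B;
  std::vector<uint8_t> code;                // row-major: code[i*p + f]
  std::vector<std::vector<double> > edges;  // per feature, ascending
};

static const int MAX_BINS = 64;

static BinnedX bin_features(const NumericMatrix& X) {
  const int n = X.nrow(), p = X.ncol();
  BinnedX bx;
  bx.n = n; bx.p = p; bx.B = 0;
  bx.code.assign((size_t)n * p, 0);
  bx.edges.resize(p);
  std::vector<double> col(n);
  for (int f = 0; f < p; ++f) {
    for (int i = 0; i < n; ++i) col[i] = X(i, f);
    std::vector<double> sorted = col;
    std::sort(sorted.begin(), sorted.end());
    std::vector<double>& ed = bx.edges[f];
    std::vector<double> uniq = sorted;
    uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
    if ((int)uniq.size() <= MAX_BINS) {
      ed = uniq;
    } else {
      ed.reserve(MAX_BINS);
      for (int b = 1; b <= MAX_BINS; ++b) {
        size_t k = (size_t)((double)b * n / MAX_BINS) - 1;
        if (k >= (size_t)n) k = n - 1;
        ed.push_back(sorted[k]);
      }
      ed.erase(std::unique(ed.begin(), ed.end()), ed.end());
      ed.back() = uniq.back();
    }
    const int nb = (int)ed.size();
    if (nb > bx.B) bx.B = nb;
    for (int i = 0; i < n; ++i) {
      int b = (int)(std::lower_bound(ed.begin(), ed.end(), col[i]) -
                    ed.begin());
      if (b >= nb) b = nb - 1;
      bx.code[(size_t)i * p + f] = (uint8_t)b;
    }
  }
  if (bx.B == 0) bx.B = 1;
  return bx;
}

// Level-wise histogram tree grower for the second-order objective
// sum_i [g_i f(x_i) + 1/2 h_i f(x_i)^2] + 1/2 lambda sum_leaf w^2.
// g/h instantiate the learners: GBT (logistic grad/hess), random forest
// (g = -w y, h = w: leaf = weighted mean y, gain = weighted variance
// reduction, i.e. Gini for 0/1 y), LogitBoost stumps (g = -w z, h = w:
// weighted least squares). Feature subsampling (mtry) is drawn per node.
// Appends one tree to `fo`; predictions on training rows are returned by
// adding leaf values into `train_pred` (scaled by `pred_scale`).
static void grow_tree(const BinnedX& bx,
                      const std::vector<double>& g,
                      const std::vector<double>& h,
                      const std::vector<int>& node_of_init,
                      int max_depth, double lambda, double min_child_weight,
                      int min_node, int mtry, XRng* rng, double leaf_scale,
                      Forest& fo, std::vector<double>& importance,
                      std::vector<double>* train_pred) {
  const int n = bx.n, p = bx.p, B = bx.B;
  fo.begin_tree();
  const int off = fo.tree_start.back();
  std::vector<int> node_of = node_of_init;  // -1 = excluded

  double G0 = 0.0, H0 = 0.0; int C0 = 0;
  for (int i = 0; i < n; ++i)
    if (node_of[i] == 0) { G0 += g[i]; H0 += h[i]; ++C0; }
  fo.feature.push_back(-1); fo.thr.push_back(0.0);
  fo.left.push_back(-1); fo.right.push_back(-1);
  fo.value.push_back((H0 + lambda > 0 ? -G0 / (H0 + lambda) : 0.0) *
                     leaf_scale);

  std::vector<int> level_nodes(1, 0);  // local node ids
  std::vector<double> Gn(1, G0), Hn(1, H0);
  std::vector<int> Cn(1, C0);
  std::vector<double> hg, hh;
  std::vector<int> hc;

  for (int depth = 0; depth < max_depth && !level_nodes.empty(); ++depth) {
    const int m = (int)level_nodes.size();
    const int n_local = (int)fo.feature.size() - off;
    std::vector<int> loc(n_local, -1);
    for (int j = 0; j < m; ++j) loc[level_nodes[j]] = j;

    std::vector<char> allowed((size_t)m * p, 1);
    if (mtry < p && rng != nullptr) {
      std::fill(allowed.begin(), allowed.end(), 0);
      std::vector<int> feats(p);
      for (int j = 0; j < m; ++j) {
        for (int f = 0; f < p; ++f) feats[f] = f;
        for (int t = 0; t < mtry; ++t) {
          int r = t + rng->below(p - t);
          std::swap(feats[t], feats[r]);
          allowed[(size_t)j * p + feats[t]] = 1;
        }
      }
    }

    // one sequential pass accumulates node x feature x bin histograms
    const size_t stride_j = (size_t)p * B;
    hg.assign((size_t)m * stride_j, 0.0);
    hh.assign((size_t)m * stride_j, 0.0);
    hc.assign((size_t)m * stride_j, 0);
    for (int i = 0; i < n; ++i) {
      const int nd = node_of[i];
      if (nd < 0) continue;
      const int j = loc[nd];
      if (j < 0) continue;
      const double gi = g[i], hi = h[i];
      const uint8_t* ci = &bx.code[(size_t)i * p];
      double* hgj = &hg[(size_t)j * stride_j];
      double* hhj = &hh[(size_t)j * stride_j];
      int* hcj = &hc[(size_t)j * stride_j];
      for (int f = 0; f < p; ++f) {
        const size_t o = (size_t)f * B + ci[f];
        hgj[o] += gi; hhj[o] += hi; hcj[o] += 1;
      }
    }

    // best split per node (features ascending, bins ascending: ties go to
    // the first candidate, deterministically)
    std::vector<double> best_gain(m, 0.0), best_thr(m, 0.0);
    std::vector<int> best_feat(m, -1);
    for (int j = 0; j < m; ++j) {
      const double Gt = Gn[j], Ht = Hn[j];
      const int Ct = Cn[j];
      const double parent_score = Gt * Gt / (Ht + lambda);
      for (int f = 0; f < p; ++f) {
        if (!allowed[(size_t)j * p + f]) continue;
        const int nb = (int)bx.edges[f].size();
        const double* hgj = &hg[(size_t)j * stride_j + (size_t)f * B];
        const double* hhj = &hh[(size_t)j * stride_j + (size_t)f * B];
        const int* hcj = &hc[(size_t)j * stride_j + (size_t)f * B];
        double GL = 0.0, HL = 0.0; int CL = 0;
        for (int b = 0; b < nb - 1; ++b) {
          GL += hgj[b]; HL += hhj[b]; CL += hcj[b];
          if (CL == 0) continue;
          const int CR = Ct - CL;
          if (CR == 0) break;
          const double HR = Ht - HL, GR = Gt - GL;
          if (HL < min_child_weight || HR < min_child_weight ||
              CL < min_node || CR < min_node) continue;
          const double gain = 0.5 * (GL * GL / (HL + lambda) +
                                     GR * GR / (HR + lambda) -
                                     parent_score);
          if (gain > best_gain[j] + 1e-12) {
            best_gain[j] = gain;
            best_feat[j] = f;
            best_thr[j] = bx.edges[f][b];
          }
        }
      }
    }

    std::vector<int> next_nodes;
    std::vector<double> Gn2, Hn2;
    std::vector<int> Cn2;
    for (int j = 0; j < m; ++j) {
      const int nd = level_nodes[j];
      if (best_feat[j] < 0) continue;
      const int li = (int)fo.feature.size() - off, ri = li + 1;
      fo.feature[off + nd] = best_feat[j];
      fo.thr[off + nd] = best_thr[j];
      fo.left[off + nd] = li; fo.right[off + nd] = ri;
      importance[best_feat[j]] += best_gain[j];
      for (int c = 0; c < 2; ++c) {
        fo.feature.push_back(-1); fo.thr.push_back(0.0);
        fo.left.push_back(-1); fo.right.push_back(-1);
        fo.value.push_back(0.0);
      }
      next_nodes.push_back(li); next_nodes.push_back(ri);
      Gn2.push_back(0.0); Gn2.push_back(0.0);
      Hn2.push_back(0.0); Hn2.push_back(0.0);
      Cn2.push_back(0); Cn2.push_back(0);
    }
    if (next_nodes.empty()) break;

    // route rows to children (bin-code routing == value routing)
    std::vector<int> locnew((int)fo.feature.size() - off, -1);
    for (int j = 0; j < (int)next_nodes.size(); ++j)
      locnew[next_nodes[j]] = j;
    for (int i = 0; i < n; ++i) {
      const int nd = node_of[i];
      if (nd < 0 || fo.feature[off + nd] < 0) continue;
      const int f = fo.feature[off + nd];
      const double xv = bx.edges[f][bx.code[(size_t)i * p + f]];
      const int child = (xv <= fo.thr[off + nd]) ? fo.left[off + nd]
                                                 : fo.right[off + nd];
      node_of[i] = child;
      const int j = locnew[child];
      Gn2[j] += g[i]; Hn2[j] += h[i]; Cn2[j] += 1;
    }
    for (int j = 0; j < (int)next_nodes.size(); ++j) {
      const int nd = next_nodes[j];
      fo.value[off + nd] =
          (Hn2[j] + lambda > 0 ? -Gn2[j] / (Hn2[j] + lambda) : 0.0) *
          leaf_scale;
    }
    level_nodes.swap(next_nodes);
    Gn.swap(Gn2); Hn.swap(Hn2); Cn.swap(Cn2);
  }

  if (train_pred != nullptr) {
    // add this tree's leaf values to the running training-score vector
    for (int i = 0; i < n; ++i) {
      if (node_of_init[i] < 0) continue;
      int nd = 0;
      while (fo.feature[off + nd] >= 0) {
        const int f = fo.feature[off + nd];
        const double xv = bx.edges[f][bx.code[(size_t)i * p + f]];
        nd = (xv <= fo.thr[off + nd]) ? fo.left[off + nd]
                                      : fo.right[off + nd];
      }
      (*train_pred)[i] += fo.value[off + nd];
    }
  }
}

// [[Rcpp::export]]
List cpp_gbt_fit(NumericMatrix X, NumericVector y, int nrounds, double eta,
                 int max_depth, double lambda, double min_child_weight) {
  const int n = X.nrow(), p = X.ncol();
  BinnedX bx = bin_features(X);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  const double base = std::log(ybar / (1.0 - ybar));
  std::vector<double> F(n, base), g(n), h(n);
  std::vector<int> node0(n, 0);
  std::vector<double> importance(p, 0.0);
  Forest fo;
  for (int r = 0; r < nrounds; ++r) {
    for (int i = 0; i < n; ++i) {
      const double pr = 1.0 / (1.0 + std::exp(-F[i]));
      g[i] = pr - y[i];
      h[i] = std::max(pr * (1.0 - pr), 1e-6);
    }
    grow_tree(bx, g, h, node0, max_depth, lambda, min_child_weight, 1, p,
              nullptr, eta, fo, importance, &F);
  }
  List out = fo.to_list();
  out["base"] = base;
  out["importance"] = NumericVector(importance.begin(), importance.end());
  return out;
}

// Probabilities from the first k trees for each checkpoint in `nrounds`
// (ascending): the first k trees of a boosted fit are exactly the k-round
// fit, so one fit serves a whole nrounds grid.
// [[Rcpp::export]]
NumericMatrix cpp_gbt_predict_multi(List model, NumericMatrix X,
                                    IntegerVector nrounds) {
  Forest fo = Forest::from_list(model);
  const double base = as<double>(model["base"]);
  const int n = X.nrow(), k = nrounds.size();
  NumericMatrix out(n, k);
  for (int i = 0; i < n; ++i) {
    const double* xrow = &X(i, 0);
    double F = base;
    int t = 0;
    for (int c = 0; c < k; ++c) {
      const int upto = std::min(nrounds[c], fo.n_trees());
      for (; t < upto; ++t) F += fo.predict_tree(t, xrow, n);
      out(i, c) = 1.0 / (1.0 + std::exp(-F));
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gbt_predict(List model, NumericMatrix X) {
  Forest fo = Forest::from_list(model);
  const double base = as<double>(model["base"]);
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double* xrow = &X(i, 0);
    double F = base;
    for (int t = 0; t < fo.n_trees(); ++t)
      F += fo.predict_tree(t, xrow, n);
    out[i] = 1.0 / (1.0 + std::exp(-F));
  }
  return out;
}

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int max_depth, int min_node, double seed) {
  const int n = X.nrow(), p = X.ncol();
  BinnedX bx = bin_features(X);
  XRng rng((uint64_t)seed);
  std::vector<double> importance(p, 0.0);
  Forest fo;
  std::vector<double> g(n), h(n);
  std::vector<int> node0(n), w(n);
  for (int t = 0; t < ntree; ++t) {
    std::fill(w.begin(), w.end(), 0);
    for (int i = 0; i < n; ++i) w[rng.below(n)] += 1;  // bootstrap
    for (int i = 0; i < n; ++i) {
      node0[i] = w[i] > 0 ? 0 : -1;
      g[i] = -(double)w[i] * y[i];
      h[i] = (double)w[i];
    }
    grow_tree(bx, g, h, node0, max_depth, 0.0, 1e-9, min_node, mtry, &rng,
              1.0, fo, importance, nullptr);
  }
  List out = fo.to_list();
  out["ntree"] = ntree;
  out["importance"] = NumericVector(importance.begin(), importance.end());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List model, NumericMatrix X) {
  Forest fo = Forest::from_list(model);
  const int n = X.nrow();
  const double m = (double)fo.n_trees();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double* xrow = &X(i, 0);
    double s = 0.0;
    for (int t = 0; t < fo.n_trees(); ++t)
      s += fo.predict_tree(t, xrow, n);
    out[i] = std::min(std::max(s / m, 0.0), 1.0);
  }
  return out;
}

// Classic two-class LogitBoost (additive logistic regression) with depth-1
// regression stumps fitted to the working response by weighted least
// squares; p = 1 / (1 + exp(-2 F)).
// [[Rcpp::export]]
List cpp_logitboost_fit(NumericMatrix X, NumericVector y, int niter) {
  const int n = X.nrow(), p = X.ncol();
  const double zmax = 4.0;
  BinnedX bx = bin_features(X);
  std::vector<double> F(n, 0.0), g(n), h(n);
  std::vector<int> node0(n, 0);
  std::vector<double> importance(p, 0.0);
  Forest fo;
  for (int r = 0; r < niter; ++r) {
    for (int i = 0; i < n; ++i) {
      const double pr = 1.0 / (1.0 + std::exp(-2.0 * F[i]));
      double wgt = std::max(pr * (1.0 - pr), 1e-6);
      double z = (y[i] - pr) / wgt;
      if (z > zmax) z = zmax;
      if (z < -zmax) z = -zmax;
      g[i] = -wgt * z;
      h[i] = wgt;
    }
    grow_tree(bx, g, h, node0, 1, 0.0, 1e-9, 1, p, nullptr, 0.5, fo,
              importance, &F);
  }
  List out = fo.to_list();
  out["importance"] = NumericVector(importance.begin(), importance.end());
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_logitboost_predict_multi(List model, NumericMatrix X,
                                           IntegerVector niter) {
  Forest fo = Forest::from_list(model);
  const int n = X.nrow(), k = niter.size();
  NumericMatrix out(n, k);
  for (int i = 0; i < n; ++i) {
    const double* xrow = &X(i, 0);
    double F = 0.0;
    int t = 0;
    for (int c = 0; c < k; ++c) {
      const int upto = std::min(niter[c], fo.n_trees());
      for (; t < upto; ++t) F += fo.predict_tree(t, xrow, n);
      out(i, c) = 1.0 / (1.0 + std::exp(-2.0 * F));
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_logitboost_predict(List model, NumericMatrix X) {
  Forest fo = Forest::from_list(model);
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double* xrow = &X(i, 0);
    double F = 0.0;
    for (int t = 0; t < fo.n_trees(); ++t)
      F += fo.predict_tree(t, xrow, n);
    out[i] = 1.0 / (1.0 + std::exp(-2.0 * F));
  }
  return out;
}
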