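// Stochastic gradient boosting with logistic loss.
//
// Trees are grown level-wise by greedy least-squares splits on the
// pseudo-residuals g = y - p; leaf values are a single Newton step
// sum(g) / sum(p(1-p)) over the in-bag rows of the leaf.  Split
// candidates are midpoints of consecutive distinct sorted feature
// values; ties in gain are broken toward the lowest feature index and
// the lowest threshold (features and thresholds are scanned in
// ascending order and a strictly larger gain is required to replace
// the incumbent).  Features with few distinct values (Likert
// categories) are accumulated into per-value histograms, which is
// exact and fast; continuous features fall back to a presorted scan.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

constexpr int MAX_BINS = 64;
constexpr double MIN_GAIN = 1e-10;

struct Tree {
  // feature = -1 marks a leaf
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;
  int new_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

inline double sigmoid(double f) { return 1.0 / (1.0 + std::exp(-f)); }

// overflow-safe logistic loss: y ln(1+e^-f) + (1-y) ln(1+e^f)
inline double logloss1(double y, double f) {
  double z = (2.0 * y - 1.0) * f;
  if (z > 0) return std::log1p(std::exp(-z));
  return -z + std::log1p(std::exp(z));
}

inline double route(const Tree& tr, int n, int r, const double* X) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    double x = X[(size_t)tr.feature[node] * n + r];
    node = (x <= tr.threshold[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.value[node];
}

// Per-fit preprocessed feature representation.  Binned features share one
// row-major code matrix so a level's histograms fill in a single sweep
// over the in-bag rows.
struct FitData {
  int n = 0, p = 0;
  const double* X = nullptr;
  std::vector<char> binned;                     // per feature
  std::vector<int> bin_feats;                   // indices of binned features
  std::vector<int> bin_idx;                     // feature -> binned index
  std::vector<int> bin_off;                     // histogram offset per binned
  int total_bins = 0;
  std::vector<uint8_t> codes_rm;                // n x n_binned, row-major
  std::vector<std::vector<double>> binvals;     // binned: sorted uniques
  std::vector<std::vector<int>> sortidx;        // exact: sorted row order
  std::vector<std::vector<double>> xsort;       // exact: sorted values
};

void preprocess(const double* X, int n, int p, FitData& fd) {
  fd.n = n;
  fd.p = p;
  fd.X = X;
  fd.binned.assign(p, 0);
  fd.bin_feats.clear();
  fd.bin_idx.assign(p, -1);
  fd.bin_off.clear();
  fd.total_bins = 0;
  fd.binvals.assign(p, {});
  fd.sortidx.assign(p, {});
  fd.xsort.assign(p, {});
  std::vector<double> vals;
  std::vector<std::vector<uint8_t>> codes(p);
  for (int f = 0; f < p; ++f) {
    const double* col = X + (size_t)f * n;
    vals.assign(col, col + n);
    std::sort(vals.begin(), vals.end());
    vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
    if ((int)vals.size() <= MAX_BINS) {
      fd.binned[f] = 1;
      fd.binvals[f] = vals;
      fd.bin_idx[f] = (int)fd.bin_feats.size();
      fd.bin_feats.push_back(f);
      fd.bin_off.push_back(fd.total_bins);
      fd.total_bins += (int)vals.size();
      codes[f].resize(n);
      for (int i = 0; i < n; ++i) {
        codes[f][i] = (uint8_t)(std::lower_bound(vals.begin(), vals.end(),
                                                 col[i]) -
                                vals.begin());
      }
    } else {
      std::vector<int>& si = fd.sortidx[f];
      si.resize(n);
      for (int i = 0; i < n; ++i) si[i] = i;
      std::stable_sort(si.begin(), si.end(),
                       [col](int a, int b) { return col[a] < col[b]; });
      fd.xsort[f].resize(n);
      for (int i = 0; i < n; ++i) fd.xsort[f][i] = col[si[i]];
    }
  }
  int nb_feats = (int)fd.bin_feats.size();
  fd.codes_rm.resize((size_t)n * nb_feats);
  for (int bf = 0; bf < nb_feats; ++bf) {
    const std::vector<uint8_t>& code = codes[fd.bin_feats[bf]];
    for (int i = 0; i < n; ++i) {
      fd.codes_rm[(size_t)i * nb_feats + bf] = code[i];
    }
  }
}

// scratch buffers reused across trees to avoid per-tree allocation
struct Workspace {
  std::vector<double> sumG, sumH;
  std::vector<int> cnt;
  std::vector<double> best_gain, best_thr, accS, lastV;
  std::vector<float> binS, prevS;
  std::vector<int> best_f, accN, parent;
  std::vector<int32_t> binN, prevN;
  std::vector<char> is_sweep;
};

// Grow one regression tree on the in-bag rows.  nid: per-row node id
// (0 for in-bag, -1 for out-of-bag on entry); on exit each in-bag row's
// nid is its leaf node.
Tree grow_tree(const FitData& fd, const std::vector<double>& g,
               const std::vector<double>& h, std::vector<int>& nid,
               const std::vector<int>& inbag, int max_depth, int min_leaf,
               Workspace& ws) {
  Tree tr;
  tr.new_node();
  int n = fd.n, p = fd.p;

  std::vector<double>& sumG = ws.sumG;
  std::vector<double>& sumH = ws.sumH;
  std::vector<int>& cnt = ws.cnt;
  sumG.assign(1, 0.0);
  sumH.assign(1, 0.0);
  cnt.assign(1, 0);
  for (int r : inbag) {
    sumG[0] += g[r];
    sumH[0] += h[r];
    cnt[0]++;
  }

  int level_start = 0, level_end = 1;
  int prev_start = 0;
  std::vector<float>& binS = ws.binS;
  std::vector<int32_t>& binN = ws.binN;
  std::vector<int>& parent = ws.parent;
  parent.assign(1, -1);
  for (int level = 0; level < max_depth && level_start < level_end;
       ++level) {
    int n_active = level_end - level_start;
    std::vector<double>& best_gain = ws.best_gain;
    std::vector<int>& best_f = ws.best_f;
    std::vector<double>& best_thr = ws.best_thr;
    best_gain.assign(n_active, MIN_GAIN);
    best_f.assign(n_active, -1);
    best_thr.assign(n_active, 0.0);

    std::vector<double>& accS = ws.accS;
    std::vector<int>& accN = ws.accN;
    std::vector<double>& lastV = ws.lastV;
    accS.resize(n_active);
    accN.resize(n_active);
    lastV.resize(n_active);

    // Fill per-node histograms of every binned feature.  At the root the
    // sweep covers all in-bag rows; deeper down only each parent's smaller
    // child is swept and the sibling is derived as parent minus child.
    int nbf = (int)fd.bin_feats.size();
    if (nbf > 0) {
      binS.assign((size_t)n_active * fd.total_bins, 0.0f);
      binN.assign((size_t)n_active * fd.total_bins, 0);
      std::vector<char>& is_sweep = ws.is_sweep;
      is_sweep.assign(n_active, 1);
      if (level > 0) {
        for (int a = 0; a < n_active; ++a) {
          int node = level_start + a;
          int par = parent[node];
          int sib = (tr.left[par] == node) ? tr.right[par] : tr.left[par];
          // sweep the smaller child; ties sweep the left child
          if (cnt[node] > cnt[sib] ||
              (cnt[node] == cnt[sib] && node == tr.right[par])) {
            is_sweep[a] = 0;
          }
        }
      }
      const uint8_t* codes = fd.codes_rm.data();
      const int* off = fd.bin_off.data();
      for (int r : inbag) {
        int node = nid[r];
        if (node < level_start || !is_sweep[node - level_start]) continue;
        size_t base = (size_t)(node - level_start) * fd.total_bins;
        const uint8_t* row = codes + (size_t)r * nbf;
        float gr = (float)g[r];
        float* S = binS.data() + base;
        int32_t* N = binN.data() + base;
        for (int bf = 0; bf < nbf; ++bf) {
          int at = off[bf] + row[bf];
          S[at] += gr;
          N[at]++;
        }
      }
      if (level > 0) {
        for (int a = 0; a < n_active; ++a) {
          if (is_sweep[a]) continue;
          int node = level_start + a;
          int par = parent[node];
          int sib = (tr.left[par] == node) ? tr.right[par] : tr.left[par];
          const float* pS = ws.prevS.data() +
                            (size_t)(par - prev_start) * fd.total_bins;
          const int32_t* pN = ws.prevN.data() +
                              (size_t)(par - prev_start) * fd.total_bins;
          const float* sS = binS.data() +
                            (size_t)(sib - level_start) * fd.total_bins;
          const int32_t* sN = binN.data() +
                              (size_t)(sib - level_start) * fd.total_bins;
          float* S = binS.data() + (size_t)a * fd.total_bins;
          int32_t* N = binN.data() + (size_t)a * fd.total_bins;
          for (int b = 0; b < fd.total_bins; ++b) {
            S[b] = pS[b] - sS[b];
            N[b] = pN[b] - sN[b];
          }
        }
      }
    }

    for (int f = 0; f < p; ++f) {
      if (fd.binned[f]) {
        int nb = (int)fd.binvals[f].size();
        if (nb < 2) continue;
        int foff = fd.bin_off[fd.bin_idx[f]];
        const double* vals = fd.binvals[f].data();
        for (int a = 0; a < n_active; ++a) {
          int node = level_start + a;
          if (cnt[node] < 2 * min_leaf) continue;
          const float* S = binS.data() + (size_t)a * fd.total_bins + foff;
          const int32_t* N = binN.data() + (size_t)a * fd.total_bins + foff;
          double sL = 0.0;
          int nL = 0, last = -1;
          double base = sumG[node] * sumG[node] / cnt[node];
          for (int b = 0; b < nb; ++b) {
            if (N[b] == 0) continue;
            if (last >= 0) {
              int nR = cnt[node] - nL;
              if (nL >= min_leaf && nR >= min_leaf) {
                double sR = sumG[node] - sL;
                double gain = sL * sL / nL + sR * sR / nR - base;
                if (gain > best_gain[a]) {
                  best_gain[a] = gain;
                  best_f[a] = f;
                  best_thr[a] = 0.5 * (vals[last] + vals[b]);
                }
              }
            }
            sL += S[b];
            nL += N[b];
            last = b;
          }
        }
      } else {
        std::fill(accS.begin(), accS.end(), 0.0);
        std::fill(accN.begin(), accN.end(), 0);
        const std::vector<int>& si = fd.sortidx[f];
        const std::vector<double>& xv = fd.xsort[f];
        for (int i = 0; i < n; ++i) {
          int r = si[i];
          int node = nid[r];
          if (node < level_start) continue;
          int a = node - level_start;
          double x = xv[i];
          if (accN[a] > 0 && x > lastV[a]) {
            int nL = accN[a];
            int nR = cnt[node] - nL;
            if (nL >= min_leaf && nR >= min_leaf) {
              double sL = accS[a], sR = sumG[node] - sL;
              double gain = sL * sL / nL + sR * sR / nR -
                            sumG[node] * sumG[node] / cnt[node];
              if (gain > best_gain[a]) {
                best_gain[a] = gain;
                best_f[a] = f;
                best_thr[a] = 0.5 * (lastV[a] + x);
              }
            }
          }
          accS[a] += g[r];
          accN[a]++;
          lastV[a] = x;
        }
      }
    }

    int child_start = (int)tr.feature.size();
    for (int a = 0; a < n_active; ++a) {
      int node = level_start + a;
      if (best_f[a] >= 0) {
        int L = tr.new_node();
        int R = tr.new_node();
        tr.feature[node] = best_f[a];
        tr.threshold[node] = best_thr[a];
        tr.left[node] = L;
        tr.right[node] = R;
        sumG.resize(tr.feature.size(), 0.0);
        sumH.resize(tr.feature.size(), 0.0);
        cnt.resize(tr.feature.size(), 0);
        parent.resize(tr.feature.size(), -1);
        parent[L] = node;
        parent[R] = node;
      } else {
        tr.value[node] = sumG[node] / std::max(sumH[node], 1e-12);
      }
    }
    int child_end = (int)tr.feature.size();

    for (int r : inbag) {
      int node = nid[r];
      if (node < level_start || node >= level_end) continue;
      if (tr.feature[node] >= 0) {
        double x = fd.X[(size_t)tr.feature[node] * n + r];
        int child = (x <= tr.threshold[node]) ? tr.left[node] : tr.right[node];
        nid[r] = child;
        sumG[child] += g[r];
        sumH[child] += h[r];
        cnt[child]++;
      }
    }
    if (nbf > 0) {
      ws.prevS.swap(binS);
      ws.prevN.swap(binN);
    }
    prev_start = level_start;
    level_start = child_start;
    level_end = child_end;
  }

  for (int node = level_start; node < level_end; ++node)
    tr.value[node] = sumG[node] / std::max(sumH[node], 1e-12);

  return tr;
}

NumericMatrix tree_to_matrix(const Tree& tr) {
  int k = (int)tr.feature.size();
  NumericMatrix M(k, 5);
  for (int i = 0; i < k; ++i) {
    M(i, 0) = tr.feature[i] >= 0 ? tr.feature[i] + 1 : -1;  // 1-based
    M(i, 1) = tr.threshold[i];
    M(i, 2) = tr.left[i] >= 0 ? tr.left[i] + 1 : -1;
    M(i, 3) = tr.right[i] >= 0 ? tr.right[i] + 1 : -1;
    M(i, 4) = tr.value[i];
  }
  colnames(M) = CharacterVector::create("feature", "threshold", "left",
                                        "right", "value");
  return M;
}

Tree tree_from_matrix(const NumericMatrix& M) {
  Tree tr;
  int k = M.nrow();
  tr.feature.resize(k);
  tr.threshold.resize(k);
  tr.left.resize(k);
  tr.right.resize(k);
  tr.value.resize(k);
  for (int i = 0; i < k; ++i) {
    tr.feature[i] = M(i, 0) > 0 ? (int)M(i, 0) - 1 : -1;
    tr.threshold[i] = M(i, 1);
    tr.left[i] = M(i, 2) > 0 ? (int)M(i, 2) - 1 : -1;
    tr.right[i] = M(i, 3) > 0 ? (int)M(i, 3) - 1 : -1;
    tr.value[i] = M(i, 4);
  }
  return tr;
}

}  // namespace

// [[Rcpp::export]]
List fit_gbm_cpp(NumericMatrix X, NumericVector y, int n_trees, int depth,
                 int min_leaf, double shrinkage, double bag_fraction, int seed,
                 NumericMatrix Xval, NumericVector yval,
                 bool keep_trees = true) {
  int n = X.nrow(), p = X.ncol();
  int nval = Xval.nrow();
  const double* Xp = REAL(X);
  const double* Xvp = nval > 0 ? REAL(Xval) : nullptr;

  FitData fd;
  preprocess(Xp, n, p, fd);

  double pbar = 0.0;
  for (int i = 0; i < n; ++i) pbar += y[i];
  pbar /= n;
  pbar = std::min(1.0 - 1e-6, std::max(1e-6, pbar));
  double F0 = std::log(pbar / (1.0 - pbar));

  std::vector<double> F(n, F0), Fval(nval, F0);
  std::vector<double> g(n), h(n);
  std::vector<int> nid(n);

  std::mt19937 rng((unsigned)seed);
  int n_bag = (bag_fraction >= 1.0) ? n : (int)std::floor(bag_fraction * n);
  if (n_bag < 2) n_bag = std::min(2, n);
  std::vector<int> perm(n);
  std::vector<int> inbag_all(n);
  for (int i = 0; i < n; ++i) inbag_all[i] = i;

  NumericVector train_loss(keep_trees ? n_trees : 0);
  NumericVector val_loss(nval > 0 ? n_trees : 0);
  List trees(keep_trees ? n_trees : 0);
  Workspace ws;
  std::vector<int> inbag;
  inbag.reserve(n);

  for (int m = 0; m < n_trees; ++m) {
    if (n_bag >= n) {
      inbag = inbag_all;
    } else {
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = 0; i < n_bag; ++i) {
        std::uniform_int_distribution<int> U(i, n - 1);
        std::swap(perm[i], perm[U(rng)]);
      }
      inbag.assign(perm.begin(), perm.begin() + n_bag);
    }
    std::fill(nid.begin(), nid.end(), -1);
    for (int r : inbag) {
      nid[r] = 0;
      double pi = sigmoid(F[r]);  // gradients needed on in-bag rows only
      g[r] = y[r] - pi;
      h[r] = pi * (1.0 - pi);
    }

    Tree tr = grow_tree(fd, g, h, nid, inbag, depth, min_leaf, ws);

    // in-bag rows already know their leaf; only out-of-bag rows route
    for (int r : inbag) F[r] += shrinkage * tr.value[nid[r]];
    if (n_bag < n) {
      for (int i = 0; i < n; ++i) {
        if (nid[i] < 0) F[i] += shrinkage * route(tr, n, i, Xp);
      }
    }
    if (keep_trees) {
      double tl = 0.0;
      for (int i = 0; i < n; ++i) tl += logloss1(y[i], F[i]);
      train_loss[m] = tl / n;
      trees[m] = tree_to_matrix(tr);
    }
    if (nval > 0) {
      double vl = 0.0;
      for (int i = 0; i < nval; ++i) {
        Fval[i] += shrinkage * route(tr, nval, i, Xvp);
        vl += logloss1(yval[i], Fval[i]);
      }
      val_loss[m] = vl / nval;
    }
  }

  return List::create(_["f0"] = F0, _["trees"] = trees,
                      _["train_loss"] = train_loss, _["val_loss"] = val_loss);
}

// [[Rcpp::export]]
NumericVector predict_gbm_cpp(double f0, List trees, double shrinkage,
                              NumericMatrix X, int n_use) {
  int n = X.nrow();
  const double* Xp = REAL(X);
  NumericVector out(n, f0);
  int M = std::min((int)trees.size(), n_use);
  for (int m = 0; m < M; ++m) {
    Tree tr = tree_from_matrix(as<NumericMatrix>(trees[m]));
    for (int i = 0; i < n; ++i) out[i] += shrinkage * route(tr, n, i, Xp);
  }
  return out;
}

// Single regression tree on (g, h) targets; all rows in-bag.
// [[Rcpp::export]]
NumericMatrix fit_tree_cpp(NumericMatrix X, NumericVector g, NumericVector h,
                           int depth, int min_leaf) {
  int n = X.nrow(), p = X.ncol();
  FitData fd;
  preprocess(REAL(X), n, p, fd);
  std::vector<double> gv(g.begin(), g.end()), hv(h.begin(), h.end());
  std::vector<int> nid(n, 0), inbag(n);
  for (int i = 0; i < n; ++i) inbag[i] = i;
  Workspace ws;
  Tree tr = grow_tree(fd, gv, hv, nid, inbag, depth, min_leaf, ws);
  return tree_to_matrix(tr);
}
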