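// Boosted regression trees for a Bernoulli response, fitted by
// forward-stagewise gradient boosting with best-first regression trees.
// Tree complexity is the exact number of splits per tree; leaf values are
// Newton steps on the Bernoulli deviance, shrunk by the learning rate.
// All randomness (bagging) comes from R's RNG so fits are reproducible
// under set.seed().
//
// Continuous split search never sorts inside a leaf: each variable's
// global sort order is computed once per fit and filtered by leaf
// membership, so one candidate scan is O(n) rather than O(n log n).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double EPS_IMPROVE = 1e-12;
static const double MAX_LEAF_STEP = 10.0; // cap on the Newton step per leaf

struct Node {
  int var = -1;           // split variable (0-based); -1 => leaf
  double thr = 0.0;       // continuous threshold (go left if x <= thr)
  uint64_t mask = 0;      // categorical: level bit set => go left
  uint64_t seen = 0;      // categorical: levels present when the node split
  int defdir = 0;         // unseen level: 0 => left, 1 => right
  int left = -1, right = -1;
  double value = 0.0;     // leaf contribution, already shrunk
  double improve = 0.0;   // squared-error improvement of the split
};

struct Tree {
  std::vector<Node> nodes;
};

static inline double inv_logit(double f) { return 1.0 / (1.0 + std::exp(-f)); }

struct SplitCand {
  bool ok = false;
  double improve = 0.0;
  int var = -1;
  double thr = 0.0;
  uint64_t mask = 0, seen = 0;
  int defdir = 0;
};

class Fitter {
public:
  const double* X;    // column-major n x p
  int n, p;
  const int* iscat;
  const int* ncat;
  const double* y;
  int tc, minobs;
  double lr, bag_frac;

  std::vector<std::vector<int>> order;  // per continuous var: rows by x
  std::vector<double> resid, hess;
  std::vector<uint8_t> inleaf;          // leaf membership scratch
  std::vector<int> buf_rows;            // scratch: leaf rows in x-order
  std::vector<int> bag_scratch;

  Fitter(const double* X_, int n_, int p_, const int* iscat_,
         const int* ncat_, const double* y_, int tc_, double lr_,
         double bag_frac_, int minobs_)
      : X(X_), n(n_), p(p_), iscat(iscat_), ncat(ncat_), y(y_), tc(tc_),
        minobs(minobs_), lr(lr_), bag_frac(bag_frac_),
        resid(n_), hess(n_), inleaf(n_, 0), buf_rows(n_) {
    order.resize(p);
    for (int j = 0; j < p; ++j) {
      if (iscat[j]) continue;
      order[j].resize(n);
      for (int i = 0; i < n; ++i) order[j][i] = i;
      const double* col = X + static_cast<size_t>(j) * n;
      std::sort(order[j].begin(), order[j].end(),
                [col](int a, int b) { return col[a] < col[b]; });
    }
  }

  // sample m distinct rows from pool via partial Fisher-Yates (R RNG)
  const std::vector<int>& sample_rows(const std::vector<int>& pool, int m) {
    bag_scratch = pool;
    const int np = static_cast<int>(bag_scratch.size());
    if (m > np) m = np;
    for (int i = 0; i < m; ++i) {
      int j = i + static_cast<int>(unif_rand() * (np - i));
      if (j >= np) j = np - 1;
      std::swap(bag_scratch[i], bag_scratch[j]);
    }
    bag_scratch.resize(m);
    return bag_scratch;
  }

  SplitCand best_split(const std::vector<int>& rows) {
    SplitCand best;
    const int nl = static_cast<int>(rows.size());
    if (nl < 2 * minobs) return best;

    double S = 0.0;
    for (int r : rows) {
      S += resid[r];
      inleaf[r] = 1;
    }
    const double base = S * S / nl;

    for (int j = 0; j < p; ++j) {
      const double* col = X + static_cast<size_t>(j) * n;
      if (!iscat[j]) {
        // leaf rows in ascending x order, via the global order
        int m = 0;
        for (int r : order[j])
          if (inleaf[r]) buf_rows[m++] = r;
        double SL = 0.0;
        for (int i = 0; i < m - 1; ++i) {
          SL += resid[buf_rows[i]];
          const int nL = i + 1, nR = m - nL;
          if (nL < minobs || nR < minobs) continue;
          const double xlo = col[buf_rows[i]], xhi = col[buf_rows[i + 1]];
          if (xhi <= xlo) continue; // tied x, no cut here
          const double SR = S - SL;
          const double imp = SL * SL / nL + SR * SR / nR - base;
          if (imp > EPS_IMPROVE && imp > best.improve) {
            best.ok = true;
            best.improve = imp;
            best.var = j;
            best.thr = 0.5 * (xlo + xhi);
            best.mask = best.seen = 0;
            best.defdir = 0;
          }
        }
      } else {
        const int L = ncat[j];
        int cnt[64];
        double sum[64];
        for (int c = 0; c < L; ++c) { cnt[c] = 0; sum[c] = 0.0; }
        for (int r : rows) {
          const int c = static_cast<int>(col[r]);
          cnt[c] += 1;
          sum[c] += resid[r];
        }
        int lev[64], nlev = 0;
        for (int c = 0; c < L; ++c) if (cnt[c] > 0) lev[nlev++] = c;
        if (nlev < 2) continue;
        std::sort(lev, lev + nlev, [&](int a, int b) {
          return sum[a] / cnt[a] < sum[b] / cnt[b];
        });
        uint64_t seen = 0;
        for (int q = 0; q < nlev; ++q) seen |= (1ull << lev[q]);
        double SL = 0.0;
        int nL = 0;
        uint64_t mask = 0;
        for (int q = 0; q + 1 < nlev; ++q) {
          SL += sum[lev[q]];
          nL += cnt[lev[q]];
          mask |= (1ull << lev[q]);
          const int nR = nl - nL;
          if (nL < minobs || nR < minobs) continue;
          const double SR = S - SL;
          const double imp = SL * SL / nL + SR * SR / nR - base;
          if (imp > EPS_IMPROVE && imp > best.improve) {
            best.ok = true;
            best.improve = imp;
            best.var = j;
            best.thr = 0.0;
            best.mask = mask;
            best.seen = seen;
            best.defdir = (nL >= nR) ? 0 : 1;
          }
        }
      }
    }
    for (int r : rows) inleaf[r] = 0;
    return best;
  }

  bool go_left(const Node& nd, int row) const {
    const double x = X[static_cast<size_t>(nd.var) * n + row];
    if (!iscat[nd.var]) return x <= nd.thr;
    const int c = static_cast<int>(x);
    if (c < 0 || c >= 64 || !((nd.seen >> c) & 1ull)) return nd.defdir == 0;
    return (nd.mask >> c) & 1ull;
  }

  double tree_value(const Tree& t, int row) const {
    int ni = 0;
    while (t.nodes[ni].var != -1)
      ni = go_left(t.nodes[ni], row) ? t.nodes[ni].left : t.nodes[ni].right;
    return t.nodes[ni].value;
  }

  Tree grow_tree(const std::vector<int>& bag) {
    Tree t;
    t.nodes.push_back(Node());
    std::vector<std::vector<int>> noderows;
    noderows.push_back(bag);
    std::vector<SplitCand> cand(1);
    std::vector<uint8_t> fresh(1, 1);

    for (int s = 0; s < tc; ++s) {
      int bestLeaf = -1;
      for (size_t ni = 0; ni < t.nodes.size(); ++ni) {
        if (t.nodes[ni].var != -1) continue;
        if (fresh[ni]) { // candidate splits are stable within one tree
          cand[ni] = best_split(noderows[ni]);
          fresh[ni] = 0;
        }
        if (cand[ni].ok &&
            (bestLeaf < 0 || cand[ni].improve > cand[bestLeaf].improve))
          bestLeaf = static_cast<int>(ni);
      }
      if (bestLeaf < 0) break;

      const SplitCand& c = cand[bestLeaf];
      Node& nd = t.nodes[bestLeaf];
      nd.var = c.var;
      nd.thr = c.thr;
      nd.mask = c.mask;
      nd.seen = c.seen;
      nd.defdir = c.defdir;
      nd.improve = c.improve;

      std::vector<int> lrows, rrows;
      lrows.reserve(noderows[bestLeaf].size());
      rrows.reserve(noderows[bestLeaf].size());
      for (int r : noderows[bestLeaf]) {
        if (go_left(t.nodes[bestLeaf], r)) lrows.push_back(r);
        else rrows.push_back(r);
      }
      t.nodes[bestLeaf].left = static_cast<int>(t.nodes.size());
      t.nodes.push_back(Node());
      noderows.push_back(std::move(lrows));
      t.nodes[bestLeaf].right = static_cast<int>(t.nodes.size());
      t.nodes.push_back(Node());
      noderows.push_back(std::move(rrows));
      cand.resize(t.nodes.size());
      fresh.resize(t.nodes.size(), 1);
    }

    // Newton leaf values: sum(residual) / sum(p(1-p)), shrunk by lr
    for (size_t ni = 0; ni < t.nodes.size(); ++ni) {
      if (t.nodes[ni].var != -1) continue;
      double num = 0.0, den = 0.0;
      for (int r : noderows[ni]) {
        num += resid[r];
        den += hess[r];
      }
      double v = num / std::max(den, 1e-12);
      if (v > MAX_LEAF_STEP) v = MAX_LEAF_STEP;
      if (v < -MAX_LEAF_STEP) v = -MAX_LEAF_STEP;
      t.nodes[ni].value = lr * v;
    }
    return t;
  }

  // add `count` boosted trees; update F in place on score_rows
  void boost(std::vector<Tree>& trees, const std::vector<int>& train,
             const std::vector<int>& score_rows, std::vector<double>& F,
             int count) {
    const int bag_n = std::max(
        2 * minobs,
        static_cast<int>(std::floor(bag_frac * train.size())));
    for (int k = 0; k < count; ++k) {
      for (int r : train) {
        const double pr = inv_logit(F[r]);
        resid[r] = y[r] - pr;
        hess[r] = std::max(pr * (1.0 - pr), 1e-12);
      }
      const std::vector<int>& bag = sample_rows(train, bag_n);
      Tree t = grow_tree(bag);
      for (int r : score_rows) F[r] += tree_value(t, r);
      trees.push_back(std::move(t));
    }
  }
};

static double mean_bernoulli_deviance(const double* y,
                                      const std::vector<int>& rows,
                                      const std::vector<double>& F) {
  double d = 0.0;
  for (int r : rows) {
    double p = inv_logit(F[r]);
    if (p < 1e-12) p = 1e-12;
    if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
    d += y[r] * std::log(p) + (1.0 - y[r]) * std::log(1.0 - p);
  }
  return -2.0 * d / rows.size();
}

static NumericMatrix serialize_tree(const Tree& t) {
  const int m = static_cast<int>(t.nodes.size());
  NumericMatrix out(m, 9);
  for (int i = 0; i < m; ++i) {
    const Node& nd = t.nodes[i];
    out(i, 0) = nd.var;
    out(i, 1) = nd.thr;
    out(i, 2) = static_cast<double>(nd.mask);
    out(i, 3) = static_cast<double>(nd.seen);
    out(i, 4) = nd.defdir;
    out(i, 5) = nd.left;
    out(i, 6) = nd.right;
    out(i, 7) = nd.value;
    out(i, 8) = nd.improve;
  }
  colnames(out) = CharacterVector::create("var", "thr", "mask", "seen",
                                          "defdir", "left", "right",
                                          "value", "improve");
  return out;
}

static Tree deserialize_tree(const NumericMatrix& m) {
  Tree t;
  const int nn = m.nrow();
  t.nodes.resize(nn);
  for (int i = 0; i < nn; ++i) {
    Node& nd = t.nodes[i];
    nd.var = static_cast<int>(m(i, 0));
    nd.thr = m(i, 1);
    nd.mask = static_cast<uint64_t>(m(i, 2));
    nd.seen = static_cast<uint64_t>(m(i, 3));
    nd.defdir = static_cast<int>(m(i, 4));
    nd.left = static_cast<int>(m(i, 5));
    nd.right = static_cast<int>(m(i, 6));
    nd.value = m(i, 7);
    nd.improve = m(i, 8);
  }
  return t;
}

// [[Rcpp::export]]
List brt_fit_cpp(NumericMatrix X, IntegerVector iscat, IntegerVector ncat,
                 NumericVector y, IntegerVector fold,
                 int tc, double lr, double bag_frac, int step_size,
                 int max_trees, int patience, int minobs) {
  const int n = X.nrow();
  int k = 0;
  for (int i = 0; i < n; ++i) k = std::max(k, fold[i]);

  Fitter fit(REAL(X), n, X.ncol(), INTEGER(iscat), INTEGER(ncat), REAL(y),
             tc, lr, bag_frac, minobs);

  std::vector<std::vector<int>> train(k), held(k);
  for (int i = 0; i < n; ++i)
    for (int f = 0; f < k; ++f)
      (fold[i] == f + 1 ? held[f] : train[f]).push_back(i);

  std::vector<std::vector<double>> F(k, std::vector<double>(n, 0.0));
  std::vector<std::vector<Tree>> fold_trees(k);
  std::vector<int> all_rows(n);
  for (int i = 0; i < n; ++i) all_rows[i] = i;

  for (int f = 0; f < k; ++f) {
    double ybar = 0.0;
    for (int r : train[f]) ybar += y[r];
    ybar /= train[f].size();
    ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
    const double f0 = std::log(ybar / (1.0 - ybar));
    for (int i = 0; i < n; ++i) F[f][i] = f0;
  }

  std::vector<double> cv_curve;
  std::vector<std::vector<double>> oof_by_stage; // out-of-fold F per stage
  int best_stage = -1;
  double best_dev = R_PosInf;
  bool diverged = false;
  const int max_stages = std::max(1, max_trees / step_size);

  for (int s = 0; s < max_stages; ++s) {
    double dev_sum = 0.0;
    std::vector<double> oof(n, 0.0);
    for (int f = 0; f < k; ++f) {
      fit.boost(fold_trees[f], train[f], all_rows, F[f], step_size);
      dev_sum += mean_bernoulli_deviance(REAL(y), held[f], F[f]);
      for (int r : held[f]) oof[r] = F[f][r];
    }
    const double dev = dev_sum / k;
    cv_curve.push_back(dev);
    oof_by_stage.push_back(std::move(oof));
    if (!R_finite(dev)) { diverged = true; break; }
    if (dev < best_dev - 1e-12) {
      best_dev = dev;
      best_stage = s;
    } else if (best_stage >= 0 && s - best_stage >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  if (best_stage < 0)
    stop("cross-validated deviance never reached a finite minimum "
         "(learning rate too large?)");

  const int n_trees = (best_stage + 1) * step_size;

  NumericVector oof_prob(n);
  for (int i = 0; i < n; ++i)
    oof_prob[i] = inv_logit(oof_by_stage[best_stage][i]);

  // final model on all rows
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  const double intercept = std::log(ybar / (1.0 - ybar));
  std::vector<double> Ffull(n, intercept);
  std::vector<Tree> final_trees;
  fit.boost(final_trees, all_rows, all_rows, Ffull, n_trees);

  NumericVector fitted(n);
  for (int i = 0; i < n; ++i) fitted[i] = inv_logit(Ffull[i]);

  const double null_dev = mean_bernoulli_deviance(
      REAL(y), all_rows, std::vector<double>(n, intercept));

  NumericVector infl(X.ncol());
  for (const Tree& t : final_trees)
    for (const Node& nd : t.nodes)
      if (nd.var >= 0) infl[nd.var] += nd.improve;

  List trees_out(final_trees.size());
  for (size_t i = 0; i < final_trees.size(); ++i)
    trees_out[i] = serialize_tree(final_trees[i]);

  return List::create(
      _["intercept"] = intercept,
      _["trees"] = trees_out,
      _["n_trees"] = n_trees,
      _["cv_curve"] = NumericVector(cv_curve.begin(), cv_curve.end()),
      _["cv_deviance"] = best_dev,
      _["null_deviance"] = null_dev,
      _["oof_prob"] = oof_prob,
      _["fitted"] = fitted,
      _["split_improvement"] = infl,
      _["diverged"] = diverged);
}

// [[Rcpp::export]]
NumericVector brt_predict_cpp(List trees, double intercept,
                              NumericMatrix X, IntegerVector iscat,
                              int n_trees) {
  const int n = X.nrow();
  const double* xp = REAL(X);
  const int* ic = INTEGER(iscat);
  const int total = trees.size();
  const int use = (n_trees < 0 || n_trees > total) ? total : n_trees;
  std::vector<Tree> tr(use);
  for (int i = 0; i < use; ++i)
    tr[i] = deserialize_tree(as<NumericMatrix>(trees[i]));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double f = intercept;
    for (int j = 0; j < use; ++j) {
      const Tree& t = tr[j];
      int ni = 0;
      while (t.nodes[ni].var != -1) {
        const Node& nd = t.nodes[ni];
        const double x = xp[static_cast<size_t>(nd.var) * n + i];
        bool left;
        if (!ic[nd.var]) {
          left = x <= nd.thr;
        } else {
          const int c = static_cast<int>(x);
          if (c < 0 || c >= 64 || !((nd.seen >> c) & 1ull))
            left = nd.defdir == 0;
          else
            left = (nd.mask >> c) & 1ull;
        }
        ni = left ? nd.left : nd.right;
      }
      f += t.nodes[ni].value;
    }
    out[i] = inv_logit(f);
  }
  return out;
}
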