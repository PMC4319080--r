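// Bagged survival trees with two-sample log-rank split finding, restricted to a
// fixed horizon (event times are integer days in 1..horizon; censoring only at or
// before the horizon). Leaves carry the empirical within-horizon event fraction,
// so a forest score is a posterior event probability, not a hazard.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct NodeRec {
  int feat;      // 1-based feature index, 0 for leaf
  double thr;    // split threshold (go left if x <= thr)
  int left;      // 1-based row index of child, 0 for leaf
  int right;
  double value;  // leaf: event fraction; internal: node event fraction too
  int n;
};

struct Problem {
  const double *X;  // column-major n x p
  int n, p;
  const int *day;   // 1..horizon
  const int *ev;    // 0/1
  int horizon;
  int max_depth;
  int min_leaf;
  int split_rule;   // 0 = log-rank, 1 = gini (classification mode)
  int max_thresholds;
};

// Two-sample log-rank chi-square for membership vector inA over rows.
// dA/cA etc are scratch histograms of size horizon+1, zeroed on entry and exit.
double logrank_from_hist(std::vector<int> &dA, std::vector<int> &cA,
                         std::vector<int> &dB, std::vector<int> &cB,
                         int nA, int nB, int horizon) {
  double O = 0.0, E = 0.0, V = 0.0;
  double ya = nA, yb = nB;
  for (int t = 1; t <= horizon; ++t) {
    int d = dA[t] + dB[t];
    double y = ya + yb;
    if (d > 0 && y > 1.0) {
      O += dA[t];
      E += d * ya / y;
      V += d * (ya / y) * (yb / y) * (y - d) / (y - 1.0);
    }
    ya -= dA[t] + cA[t];
    yb -= dB[t] + cB[t];
    if (ya + yb <= 0) break;
  }
  if (V <= 0.0) return 0.0;
  double diff = O - E;
  return diff * diff / V;
}

class TreeGrower {
 public:
  TreeGrower(const Problem &pb) : pb_(pb),
      dA_(pb.horizon + 1, 0), cA_(pb.horizon + 1, 0),
      dB_(pb.horizon + 1, 0), cB_(pb.horizon + 1, 0) {}

  std::vector<NodeRec> grow(std::vector<int> &rows) {
    nodes_.clear();
    build(rows, 0);
    return nodes_;
  }

 private:
  const Problem &pb_;
  std::vector<NodeRec> nodes_;
  std::vector<int> dA_, cA_, dB_, cB_;

  double node_value(const std::vector<int> &rows) const {
    double s = 0.0;
    for (int r : rows) s += pb_.ev[r];
    return rows.empty() ? 0.0 : s / rows.size();
  }

  // Split quality of x[f] <= thr over rows; -1 if invalid (child below min_leaf).
  double split_score(const std::vector<int> &rows, int f, double thr) {
    const double *col = pb_.X + (size_t)f * pb_.n;
    int nA = 0, nB = 0;
    if (pb_.split_rule == 0) {
      for (int r : rows) {
        if (col[r] <= thr) {
          ++nA;
          if (pb_.ev[r]) ++dA_[pb_.day[r]]; else ++cA_[pb_.day[r]];
        } else {
          ++nB;
          if (pb_.ev[r]) ++dB_[pb_.day[r]]; else ++cB_[pb_.day[r]];
        }
      }
      double stat = -1.0;
      if (nA >= pb_.min_leaf && nB >= pb_.min_leaf)
        stat = logrank_from_hist(dA_, cA_, dB_, cB_, nA, nB, pb_.horizon);
      // zero scratch (only touched days)
      for (int r : rows) {
        int t = pb_.day[r];
        dA_[t] = cA_[t] = dB_[t] = cB_[t] = 0;
      }
      return stat;
    }
    // gini mode on the event indicator: weighted impurity decrease
    int eA = 0, eB = 0;
    for (int r : rows) {
      if (col[r] <= thr) { ++nA; eA += pb_.ev[r]; }
      else               { ++nB; eB += pb_.ev[r]; }
    }
    if (nA < pb_.min_leaf || nB < pb_.min_leaf) return -1.0;
    int n = nA + nB, e = eA + eB;
    auto gini = [](int cnt, int pos) {
      if (cnt == 0) return 0.0;
      double q = (double)pos / cnt;
      return 2.0 * q * (1.0 - q);
    };
    double before = n * gini(n, e);
    double after = nA * gini(nA, eA) + nB * gini(nB, eB);
    return before - after;
  }

  int build(std::vector<int> &rows, int depth) {
    NodeRec nd;
    nd.feat = 0; nd.thr = 0.0; nd.left = 0; nd.right = 0;
    nd.value = node_value(rows);
    nd.n = (int)rows.size();
    int self = (int)nodes_.size();
    nodes_.push_back(nd);

    if (depth >= pb_.max_depth || (int)rows.size() < 2 * pb_.min_leaf)
      return self;

    // pure node: nothing to separate
    bool any0 = false, any1 = false;
    for (int r : rows) { if (pb_.ev[r]) any1 = true; else any0 = true; }

    double best = 0.0;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<double> vals;
    vals.reserve(rows.size());
    for (int f = 0; f < pb_.p; ++f) {
      const double *col = pb_.X + (size_t)f * pb_.n;
      vals.clear();
      for (int r : rows) vals.push_back(col[r]);
      std::sort(vals.begin(), vals.end());
      vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
      int nu = (int)vals.size();
      if (nu < 2) continue;
      int ncand = std::min(nu - 1, pb_.max_thresholds);
      for (int j = 0; j < ncand; ++j) {
        // evenly spaced picks over the nu-1 gaps; all gaps when few
        int g = (ncand == nu - 1) ? j : (int)((double)(j + 1) * (nu - 1) / (ncand + 1));
        if (g > nu - 2) g = nu - 2;
        double thr = 0.5 * (vals[g] + vals[g + 1]);
        double sc = split_score(rows, f, thr);
        if (sc > best + 1e-12) { best = sc; best_f = f; best_thr = thr; }
      }
      // gini mode cannot improve on a pure node; log-rank can still separate times,
      // but a pure-censored node has no events to order
      (void)any0; (void)any1;
    }
    if (best_f < 0 || best <= 0.0) return self;

    std::vector<int> lrows, rrows;
    const double *col = pb_.X + (size_t)best_f * pb_.n;
    for (int r : rows) {
      if (col[r] <= best_thr) lrows.push_back(r); else rrows.push_back(r);
    }
    if ((int)lrows.size() < pb_.min_leaf || (int)rrows.size() < pb_.min_leaf)
      return self;

    int li = build(lrows, depth + 1);
    int ri = build(rrows, depth + 1);
    nodes_[self].feat = best_f + 1;
    nodes_[self].thr = best_thr;
    nodes_[self].left = li + 1;   // 1-based for the R side
    nodes_[self].right = ri + 1;
    return self;
  }
};

NumericMatrix pack_tree(const std::vector<NodeRec> &nodes) {
  NumericMatrix m((int)nodes.size(), 6);
  colnames(m) = CharacterVector::create("feat", "thr", "left", "right", "value", "n");
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feat;
    m(i, 1) = nodes[i].thr;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
    m(i, 5) = nodes[i].n;
  }
  return m;
}

}  // namespace

// [[Rcpp::export]]
List fit_forest_cpp(NumericMatrix X, IntegerVector day, IntegerVector event,
                    int horizon, int n_trees, int max_depth, int min_leaf,
                    double boot_frac, int split_rule, int seed,
                    int max_thresholds = 15) {
  int n = X.nrow();
  Problem pb;
  pb.X = REAL(X); pb.n = n; pb.p = X.ncol();
  pb.day = INTEGER(day); pb.ev = INTEGER(event);
  pb.horizon = horizon; pb.max_depth = max_depth; pb.min_leaf = min_leaf;
  pb.split_rule = split_rule; pb.max_thresholds = max_thresholds;

  std::mt19937 rng((unsigned)seed);
  int m = std::max(1, (int)std::lround(boot_frac * n));
  std::uniform_int_distribution<int> pick(0, n - 1);

  List out(n_trees);
  TreeGrower grower(pb);
  std::vector<int> rows(m);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < m; ++i) rows[i] = pick(rng);  // bootstrap with replacement
    std::vector<NodeRec> nodes = grower.grow(rows);
    out[t] = pack_tree(nodes);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X) {
  int n = X.nrow();
  NumericVector out(n, 0.0);
  int T = trees.size();
  for (int t = 0; t < T; ++t) {
    NumericMatrix tr = trees[t];
    int max_steps = tr.nrow() + 1;  // guards against malformed documents
    for (int i = 0; i < n; ++i) {
      int node = 0, steps = 0;
      while ((int)tr(node, 0) > 0) {
        if (++steps > max_steps) stop("malformed tree: traversal cycle");
        int f = (int)tr(node, 0) - 1;
        node = (X(i, f) <= tr(node, 1)) ? (int)tr(node, 2) - 1
                                        : (int)tr(node, 3) - 1;
      }
      out[i] += tr(node, 4);
    }
  }
  if (T > 0) for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// Two-sample log-rank chi-square on (day, event) with group in {0,1}; exposed for
// cross-checking the split criterion against survival::survdiff.
// [[Rcpp::export]]
double logrank_stat_cpp(IntegerVector day, IntegerVector event,
                        IntegerVector group, int horizon) {
  std::vector<int> dA(horizon + 1, 0), cA(horizon + 1, 0),
      dB(horizon + 1, 0), cB(horizon + 1, 0);
  int nA = 0, nB = 0;
  for (int i = 0; i < day.size(); ++i) {
    if (group[i] == 0) {
      ++nA;
      if (event[i]) ++dA[day[i]]; else ++cA[day[i]];
    } else {
      ++nB;
      if (event[i]) ++dB[day[i]]; else ++cB[day[i]];
    }
  }
  return logrank_from_hist(dA, cA, dB, cB, nA, nB, horizon);
}
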