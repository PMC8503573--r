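// Greedy depth-limited regression tree growing for the gradient-boosting
// core, plus node assignment for prediction. Trees are grown on pseudo-
// residuals with squared-error improvement; categorical predictors use
// exhaustive subset search up to 10 observed codes and the mean-ordering
// scan above that. All tie-breaks are deterministic: node creation order,
// then predictor order, then ascending threshold / subset enumeration order.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct NodeRows {
  std::vector<int> rows;  // 0-based row indices of X
};

struct BestSplit {
  double improvement = 0.0;
  int node = -1, var = -1;
  double thr = NA_REAL;
  std::vector<double> catLeft, catRight;
  std::vector<int> leftRows, rightRows;
  bool found = false;
};

// Scan a continuous predictor within one node. Rows must carry x and z.
void scanContinuous(const std::vector<double>& x, const std::vector<double>& z,
                    const std::vector<int>& rows, int minObs,
                    double& bestImp, double& bestThr,
                    std::vector<int>& bestL, std::vector<int>& bestR) {
  const int n = rows.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return x[rows[a]] < x[rows[b]];
  });
  double S = 0.0;
  for (int i = 0; i < n; ++i) S += z[rows[i]];
  double base = S * S / n;
  double SL = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    SL += z[rows[ord[i]]];
    double xl = x[rows[ord[i]]], xr = x[rows[ord[i + 1]]];
    if (xr <= xl) continue;  // only split between distinct values
    int nL = i + 1, nR = n - nL;
    if (nL < minObs || nR < minObs) continue;
    double SR = S - SL;
    double imp = SL * SL / nL + SR * SR / nR - base;
    if (imp > bestImp) {
      bestImp = imp;
      bestThr = (xl + xr) / 2.0;
      bestL.clear(); bestR.clear();
      for (int j = 0; j < n; ++j)
        (j <= i ? bestL : bestR).push_back(rows[ord[j]]);
    }
  }
}

// Scan a categorical predictor within one node.
void scanCategorical(const std::vector<double>& x, const std::vector<double>& z,
                     const std::vector<int>& rows, int minObs,
                     double& bestImp,
                     std::vector<double>& bestCatL, std::vector<double>& bestCatR,
                     std::vector<int>& bestL, std::vector<int>& bestR) {
  const int n = rows.size();
  // aggregate per code (codes kept sorted ascending for determinism)
  std::vector<double> codes;
  std::vector<double> csum;
  std::vector<int> ccnt;
  for (int i = 0; i < n; ++i) {
    double c = x[rows[i]];
    size_t pos = std::lower_bound(codes.begin(), codes.end(), c) - codes.begin();
    if (pos == codes.size() || codes[pos] != c) {
      codes.insert(codes.begin() + pos, c);
      csum.insert(csum.begin() + pos, 0.0);
      ccnt.insert(ccnt.begin() + pos, 0);
    }
    csum[pos] += z[rows[i]];
    ccnt[pos] += 1;
  }
  const int k = codes.size();
  if (k < 2) return;
  double S = 0.0;
  int N = n;
  for (int j = 0; j < k; ++j) S += csum[j];
  double base = S * S / N;

  auto tryPartition = [&](const std::vector<bool>& inLeft) {
    double SL = 0.0; int nL = 0;
    for (int j = 0; j < k; ++j) if (inLeft[j]) { SL += csum[j]; nL += ccnt[j]; }
    int nR = N - nL;
    if (nL < minObs || nR < minObs) return;
    double SR = S - SL;
    double imp = SL * SL / nL + SR * SR / nR - base;
    if (imp > bestImp) {
      bestImp = imp;
      bestCatL.clear(); bestCatR.clear();
      for (int j = 0; j < k; ++j)
        (inLeft[j] ? bestCatL : bestCatR).push_back(codes[j]);
      bestL.clear(); bestR.clear();
      for (int i = 0; i < n; ++i) {
        double c = x[rows[i]];
        bool lf = std::binary_search(bestCatL.begin(), bestCatL.end(), c);
        (lf ? bestL : bestR).push_back(rows[i]);
      }
    }
  };

  if (k <= 10) {
    // exhaustive subsets; fix code 0 to the left half to avoid mirrors
    for (unsigned mask = 1; mask < (1u << (k - 1)); ++mask) {
      std::vector<bool> inLeft(k, false);
      inLeft[0] = true;
      for (int j = 1; j < k; ++j)
        if (mask & (1u << (j - 1))) inLeft[j] = true;
      if ((int)std::count(inLeft.begin(), inLeft.end(), true) == k) continue;
      tryPartition(inLeft);
    }
  } else {
    // order codes by in-node mean residual, split as if continuous
    std::vector<int> ord(k);
    for (int j = 0; j < k; ++j) ord[j] = j;
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      return csum[a] / ccnt[a] < csum[b] / ccnt[b];
    });
    for (int cut = 1; cut < k; ++cut) {
      std::vector<bool> inLeft(k, false);
      for (int j = 0; j < cut; ++j) inLeft[ord[j]] = true;
      tryPartition(inLeft);
    }
  }
}

}  // namespace

// Grow one depth-limited tree on in-bag rows. X: n x p numeric (categorical
// columns hold codes); z: pseudo-residuals; inbag: 0-based row indices.
// Returns flat node arrays (1-based child links, 0 = none) and the leaf node
// id (1-based) of each in-bag row.
// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, LogicalVector isCat, NumericVector z,
                   IntegerVector inbag, int maxSplits, int minObs) {
  const int p = X.ncol();
  std::vector<std::vector<double> > cols(p);
  for (int j = 0; j < p; ++j)
    cols[j].assign(X.column(j).begin(), X.column(j).end());
  std::vector<double> zz(z.begin(), z.end());

  std::vector<int> var(1, -1), left(1, -1), right(1, -1), nNode;
  std::vector<double> thr(1, NA_REAL), improvement(1, 0.0);
  std::vector<std::vector<double> > catL(1), catR(1);
  std::vector<NodeRows> nodeRows(1);
  nodeRows[0].rows.assign(inbag.begin(), inbag.end());
  nNode.push_back(nodeRows[0].rows.size());
  std::vector<int> leaves(1, 0);  // creation order

  for (int s = 0; s < maxSplits; ++s) {
    BestSplit best;
    for (size_t li = 0; li < leaves.size(); ++li) {
      int nd = leaves[li];
      const std::vector<int>& rows = nodeRows[nd].rows;
      if ((int)rows.size() < 2 * minObs) continue;
      for (int j = 0; j < p; ++j) {
        double imp = best.improvement;
        double thrj = NA_REAL;
        std::vector<double> cl, cr;
        std::vector<int> lr, rr;
        if (isCat[j])
          scanCategorical(cols[j], zz, rows, minObs, imp, cl, cr, lr, rr);
        else
          scanContinuous(cols[j], zz, rows, minObs, imp, thrj, lr, rr);
        if (imp > best.improvement) {
          best.improvement = imp;
          best.node = nd; best.var = j; best.thr = thrj;
          best.catLeft = cl; best.catRight = cr;
          best.leftRows = lr; best.rightRows = rr;
          best.found = true;
        }
      }
    }
    if (!best.found || best.improvement <= 1e-12) break;
    int li = var.size(), ri = li + 1;
    var.push_back(-1); var.push_back(-1);
    thr.push_back(NA_REAL); thr.push_back(NA_REAL);
    left.push_back(-1); left.push_back(-1);
    right.push_back(-1); right.push_back(-1);
    improvement.push_back(0.0); improvement.push_back(0.0);
    catL.push_back(std::vector<double>()); catL.push_back(std::vector<double>());
    catR.push_back(std::vector<double>()); catR.push_back(std::vector<double>());
    nodeRows.push_back(NodeRows()); nodeRows.push_back(NodeRows());
    nodeRows[li].rows = best.leftRows;
    nodeRows[ri].rows = best.rightRows;
    nNode.push_back(best.leftRows.size());
    nNode.push_back(best.rightRows.size());
    var[best.node] = best.var;
    thr[best.node] = best.thr;
    catL[best.node] = best.catLeft;
    catR[best.node] = best.catRight;
    left[best.node] = li;
    right[best.node] = ri;
    improvement[best.node] = best.improvement;
    leaves.erase(std::find(leaves.begin(), leaves.end(), best.node));
    leaves.push_back(li);
    leaves.push_back(ri);
  }

  // leaf node id per in-bag row
  IntegerVector inbagNode(inbag.size());
  {
    std::vector<int> rowLeaf(X.nrow(), -1);
    for (size_t nd = 0; nd < nodeRows.size(); ++nd)
      if (var[nd] == -1)
        for (int r : nodeRows[nd].rows) rowLeaf[r] = nd;
    for (int i = 0; i < inbag.size(); ++i)
      inbagNode[i] = rowLeaf[inbag[i]] + 1;
  }

  int nn = var.size();
  IntegerVector varOut(nn), leftOut(nn), rightOut(nn), nOut(nn);
  NumericVector thrOut(nn), impOut(nn);
  List catLOut(nn), catROut(nn);
  for (int i = 0; i < nn; ++i) {
    varOut[i] = var[i] + 1;               // 0 = leaf
    leftOut[i] = left[i] + 1;             // 0 = none
    rightOut[i] = right[i] + 1;
    thrOut[i] = thr[i];
    impOut[i] = improvement[i];
    nOut[i] = nNode[i];
    catLOut[i] = NumericVector(catL[i].begin(), catL[i].end());
    catROut[i] = NumericVector(catR[i].begin(), catR[i].end());
  }
  return List::create(
    _["var"] = varOut, _["thr"] = thrOut, _["catLeft"] = catLOut,
    _["catRight"] = catROut, _["left"] = leftOut, _["right"] = rightOut,
    _["improvement"] = impOut, _["n"] = nOut, _["inbagNode"] = inbagNode);
}

// Assign each row of X to a leaf node of a grown tree. Unseen categorical
// codes are routed to the child with more training rows (ties to the left)
// and counted.
// [[Rcpp::export]]
List cpp_tree_assign(NumericMatrix X, IntegerVector var, NumericVector thr,
                     List catLeft, List catRight, IntegerVector left,
                     IntegerVector right, IntegerVector nNode) {
  const int n = X.nrow();
  IntegerVector node(n);
  int unseen = 0;
  for (int i = 0; i < n; ++i) {
    int nd = 0;
    while (var[nd] != 0) {
      int j = var[nd] - 1;
      double x = X(i, j);
      bool goLeft;
      NumericVector cl = catLeft[nd];
      if (cl.size() == 0 && !NumericVector::is_na(thr[nd])) {
        goLeft = x < thr[nd];
      } else {
        NumericVector cr = catRight[nd];
        bool inL = std::binary_search(cl.begin(), cl.end(), x);
        bool inR = std::binary_search(cr.begin(), cr.end(), x);
        if (inL) goLeft = true;
        else if (inR) goLeft = false;
        else {
          ++unseen;
          goLeft = nNode[left[nd] - 1] >= nNode[right[nd] - 1];
        }
      }
      nd = (goLeft ? left[nd] : right[nd]) - 1;
    }
    node[i] = nd + 1;
  }
  return List::create(_["node"] = node, _["unseen"] = unseen);
}
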