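#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <climits>

using namespace Rcpp;

// Minimum-cost path forest over a (H, W, T) pixel grid.
//
// Nodes are linearly indexed as idx = r + H * (c + W * t), matching the
// memory layout of an R array with dim c(H, W, T).
//
// Path cost is either the maximum arc weight along the path (max-arc) or the
// sum of arc weights (additive); arc weight is |I(p) - I(q)|, multiplied by
// temporalScale for arcs that cross frames. Seed nodes are frozen (never
// relaxed), so every seed keeps its own label. Ties are resolved
// deterministically: each node takes the smallest seed entry order among
// seeds that reach it along a path whose every prefix cost equals the node
// cost map ("tight" optimal paths), realized by ordering the queue on the
// lexicographic tuple (cost, seed order) and relaxing on strict lex
// improvement; the queue is additionally FIFO on insertion so the pop order
// is fully deterministic.

struct QEntry {
  double cost;
  int ord;
  long long ctr;
  int node;
};

struct QCmp {
  bool operator()(const QEntry &a, const QEntry &b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    if (a.ord != b.ord) return a.ord > b.ord;
    return a.ctr > b.ctr;
  }
};

// [[Rcpp::export(name = ".ift_forest_cpp")]]
List ift_forest_cpp(NumericVector values, int H, int W, int T,
                    IntegerVector seedNode, IntegerVector seedLabel,
                    int inPlane, bool temporal, double temporalScale,
                    bool additive, double handicap) {
  const R_xlen_t N = (R_xlen_t)H * W * T;
  if ((R_xlen_t)values.size() != N)
    stop("values length does not match H*W*T");
  if (N > INT_MAX)
    stop("grid too large: more than 2^31-1 nodes");

  std::vector<double> cost(N, R_PosInf);
  std::vector<int> ord(N, INT_MAX);
  std::vector<int> lab(N, NA_INTEGER);
  std::vector<int> pred(N, -1);
  std::vector<int> root(N, -1);
  std::vector<char> done(N, 0);

  std::vector<char> isSeed(N, 0);
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  long long ctr = 0;

  for (int i = 0; i < seedNode.size(); ++i) {
    int s = seedNode[i];
    if (s < 0 || s >= N) stop("seed node index out of range");
    isSeed[s] = 1;
    if (handicap < cost[s] || (handicap == cost[s] && i < ord[s])) {
      cost[s] = handicap;
      ord[s] = i;
      lab[s] = seedLabel[i];
      pred[s] = -1;
      root[s] = s;
      pq.push(QEntry{handicap, i, ctr++, s});
    }
  }

  // neighbour offsets: (dt, dr, dc)
  std::vector<int> odt, odr, odc;
  std::vector<double> oscale;
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  for (int k = 0; k < 4; ++k) {
    odt.push_back(0); odr.push_back(dr4[k]); odc.push_back(dc4[k]);
    oscale.push_back(1.0);
  }
  if (inPlane == 8) {
    const int drd[4] = {-1, -1, 1, 1};
    const int dcd[4] = {-1, 1, -1, 1};
    for (int k = 0; k < 4; ++k) {
      odt.push_back(0); odr.push_back(drd[k]); odc.push_back(dcd[k]);
      oscale.push_back(1.0);
    }
  }
  if (temporal && T > 1) {
    odt.push_back(-1); odr.push_back(0); odc.push_back(0);
    oscale.push_back(temporalScale);
    odt.push_back(1); odr.push_back(0); odc.push_back(0);
    oscale.push_back(temporalScale);
  }
  const int nOff = (int)odt.size();
  const R_xlen_t frameSize = (R_xlen_t)H * W;

  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    const int p = e.node;
    if (done[p] || e.cost != cost[p] || e.ord != ord[p]) continue;
    done[p] = 1;

    const int t = (int)(p / frameSize);
    const int rem = (int)(p % frameSize);
    const int c = rem / H;
    const int r = rem % H;
    const double vp = values[p];
    const double cp = cost[p];
    const int op = ord[p];

    for (int k = 0; k < nOff; ++k) {
      const int rq = r + odr[k];
      const int cq = c + odc[k];
      const int tq = t + odt[k];
      if (rq < 0 || rq >= H || cq < 0 || cq >= W || tq < 0 || tq >= T)
        continue;
      const R_xlen_t q = rq + (R_xlen_t)H * (cq + (R_xlen_t)W * tq);
      if (done[q] || isSeed[q]) continue;  // seeds keep their own label
      const double w = std::fabs(vp - values[q]) * oscale[k];
      const double cand = additive ? cp + w : (cp > w ? cp : w);
      if (cand < cost[q] || (cand == cost[q] && op < ord[q])) {
        cost[q] = cand;
        ord[q] = op;
        lab[q] = lab[p];
        pred[q] = p;
        root[q] = root[p];
        pq.push(QEntry{cand, op, ctr++, (int)q});
      }
    }
  }

  IntegerVector outLab(N), outPred(N), outRoot(N), outOrd(N);
  NumericVector outCost(N);
  for (R_xlen_t i = 0; i < N; ++i) {
    outLab[i] = lab[i];
    outPred[i] = pred[i];
    outRoot[i] = root[i];
    outOrd[i] = ord[i];
    outCost[i] = cost[i];
  }
  return List::create(_["label"] = outLab, _["cost"] = outCost,
                      _["pred"] = outPred, _["root"] = outRoot,
                      _["ord"] = outOrd);
}
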