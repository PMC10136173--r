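#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Arc weight f(g) = alpha * exp(beta * (255 - g)) + gamma, g = mean of the
// two incident magnitudes; diagonal arcs scaled by diagFactor.  Optional
// prior multiplies by the mean of the two incident mask values.
static inline double arc_w(double gi, double gj, bool diag,
                           double alpha, double beta, double gamma,
                           double diagFactor,
                           const double *prior, int i, int j) {
  double g = 0.5 * (gi + gj);
  double w = alpha * std::exp(beta * (255.0 - g)) + gamma;
  if (diag) w *= diagFactor;
  if (prior) w *= 0.5 * (prior[i] + prior[j]);
  return w;
}

// Dijkstra on the implicit 8-connected pixel graph of an edge map.
// start/end are 1-based (row, col).  Ties in the priority queue are broken
// by the smaller row-major (column-major storage, but the key is the linear
// index) node index; predecessors are updated only on strict improvement,
// so the returned node sequence is deterministic.
// [[Rcpp::export(name = ".cg_dijkstra")]]
List cg_dijkstra(NumericMatrix mag, IntegerVector start, IntegerVector end,
                 double alpha, double beta, double gamma, double diagFactor,
                 Nullable<NumericMatrix> prior = R_NilValue) {
  const int H = mag.nrow(), W = mag.ncol();
  const int N = H * W;
  const int r0 = start[0] - 1, c0 = start[1] - 1;
  const int r1 = end[0] - 1, c1 = end[1] - 1;
  if (r0 < 0 || r0 >= H || c0 < 0 || c0 >= W ||
      r1 < 0 || r1 >= H || c1 < 0 || c1 >= W)
    stop("endpoint outside image bounds");

  const double *pr = NULL;
  NumericMatrix pm;
  if (prior.isNotNull()) {
    pm = NumericMatrix(prior);
    if (pm.nrow() != H || pm.ncol() != W) stop("prior mask shape mismatch");
    pr = &pm[0];
  }
  const double *m = &mag[0];

  const int s = c0 * H + r0, t = c1 * H + r1;
  if (s == t) {
    IntegerMatrix nodes(1, 2);
    nodes(0, 0) = start[0]; nodes(0, 1) = start[1];
    return List::create(_["nodes"] = nodes, _["cost"] = 0.0);
  }

  std::vector<double> dist(N, std::numeric_limits<double>::infinity());
  std::vector<int> pred(N, -1);
  std::vector<char> done(N, 0);

  typedef std::pair<double, int> QE;  // (dist, row-major node index)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[s] = 0.0;
  pq.push(QE(0.0, r0 * W + c0));

  static const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = (top.second % W) * H + top.second / W;
    if (done[u]) continue;
    done[u] = 1;
    if (u == t) break;
    int ur = u % H, uc = u / H;
    double du = dist[u];
    for (int k = 0; k < 8; ++k) {
      int vr = ur + dr[k], vc = uc + dc[k];
      if (vr < 0 || vr >= H || vc < 0 || vc >= W) continue;
      int v = vc * H + vr;
      if (done[v]) continue;
      bool diag = (dr[k] != 0 && dc[k] != 0);
      double w = arc_w(m[u], m[v], diag, alpha, beta, gamma, diagFactor,
                       pr, u, v);
      double nd = du + w;
      if (nd < dist[v]) {  // strict improvement only
        dist[v] = nd;
        pred[v] = u;
        pq.push(QE(nd, vr * W + vc));
      }
    }
  }

  if (!std::isfinite(dist[t])) stop("end point unreachable");

  std::vector<int> rev;
  for (int v = t; v != -1; v = pred[v]) rev.push_back(v);
  int n = (int)rev.size();
  IntegerMatrix nodes(n, 2);
  for (int i = 0; i < n; ++i) {
    int v = rev[n - 1 - i];
    nodes(i, 0) = v % H + 1;
    nodes(i, 1) = v / H + 1;
  }
  return List::create(_["nodes"] = nodes, _["cost"] = dist[t]);
}
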