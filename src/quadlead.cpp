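// Anisotropic eikonal solver on tetrahedral meshes and a ray-casting
// wall-thickness kernel.
//
// The eikonal solver approximates the viscosity solution of
//   sqrt(grad(T)' V grad(T)) = 1,  T = onset at sources,
// with V the per-element squared-velocity tensor. It is a label-correcting
// fast-iterative scheme: each node is repeatedly updated from its incident
// tetrahedra by minimizing the arrival time over the opposite face
// (face / edge / vertex characteristic cases, each solved in closed form in
// the travel-time metric M = V^{-1}).

#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

static inline double qf(const double M[9], const double e[3]) {
  return e[0] * (M[0] * e[0] + M[1] * e[1] + M[2] * e[2]) +
         e[1] * (M[3] * e[0] + M[4] * e[1] + M[5] * e[2]) +
         e[2] * (M[6] * e[0] + M[7] * e[1] + M[8] * e[2]);
}

static inline double bil(const double M[9], const double a[3], const double b[3]) {
  return a[0] * (M[0] * b[0] + M[1] * b[1] + M[2] * b[2]) +
         a[1] * (M[3] * b[0] + M[4] * b[1] + M[5] * b[2]) +
         a[2] * (M[6] * b[0] + M[7] * b[1] + M[8] * b[2]);
}

// invert a 3x3 (row-major); returns false if near-singular
static bool inv3(const double A[9], double Ai[9]) {
  double d = A[0] * (A[4] * A[8] - A[5] * A[7]) -
             A[1] * (A[3] * A[8] - A[5] * A[6]) +
             A[2] * (A[3] * A[7] - A[4] * A[6]);
  if (std::fabs(d) < 1e-300) return false;
  double id = 1.0 / d;
  Ai[0] = (A[4] * A[8] - A[5] * A[7]) * id;
  Ai[1] = (A[2] * A[7] - A[1] * A[8]) * id;
  Ai[2] = (A[1] * A[5] - A[2] * A[4]) * id;
  Ai[3] = (A[5] * A[6] - A[3] * A[8]) * id;
  Ai[4] = (A[0] * A[8] - A[2] * A[6]) * id;
  Ai[5] = (A[2] * A[3] - A[0] * A[5]) * id;
  Ai[6] = (A[3] * A[7] - A[4] * A[6]) * id;
  Ai[7] = (A[1] * A[6] - A[0] * A[7]) * id;
  Ai[8] = (A[0] * A[4] - A[1] * A[3]) * id;
  return true;
}

// arrival-time update at xd from a face with vertices x[0..2], times T[0..2]
static double local_update(const double x[3][3], const double T[3],
                           const double xd[3], const double M[9]) {
  double best = INF;
  // vertex characteristics
  for (int i = 0; i < 3; ++i) {
    if (!std::isfinite(T[i])) continue;
    double e[3] = {xd[0] - x[i][0], xd[1] - x[i][1], xd[2] - x[i][2]};
    double q = qf(M, e);
    if (q >= 0) {
      double cand = T[i] + std::sqrt(q);
      if (cand < best) best = cand;
    }
  }
  // edge characteristics
  for (int i = 0; i < 3; ++i) {
    int j = (i + 1) % 3;
    if (!std::isfinite(T[i]) || !std::isfinite(T[j])) continue;
    double E[3] = {x[i][0] - x[j][0], x[i][1] - x[j][1], x[i][2] - x[j][2]};
    double e0[3] = {xd[0] - x[j][0], xd[1] - x[j][1], xd[2] - x[j][2]};
    double t = T[i] - T[j];
    double a = qf(M, E);
    if (a <= 1e-300) continue;
    double c0 = bil(M, E, e0);
    double e00 = qf(M, e0);
    double lam0 = c0 / a, mu = t / a;
    double K = e00 - lam0 * c0;
    double den = 1.0 - t * mu;
    if (K < 0 || den <= 1e-14) continue;
    double s = std::sqrt(K / den);
    double lam = lam0 - s * mu;
    if (lam < -1e-12 || lam > 1 + 1e-12) continue;
    double cand = T[j] + lam * t + s;
    if (cand < best) best = cand;
  }
  // face characteristic
  if (std::isfinite(T[0]) && std::isfinite(T[1]) && std::isfinite(T[2])) {
    double E1[3] = {x[0][0] - x[2][0], x[0][1] - x[2][1], x[0][2] - x[2][2]};
    double E2[3] = {x[1][0] - x[2][0], x[1][1] - x[2][1], x[1][2] - x[2][2]};
    double e0[3] = {xd[0] - x[2][0], xd[1] - x[2][1], xd[2] - x[2][2]};
    double t1 = T[0] - T[2], t2 = T[1] - T[2];
    double A11 = qf(M, E1), A22 = qf(M, E2), A12 = bil(M, E1, E2);
    double det = A11 * A22 - A12 * A12;
    if (det > 1e-300) {
      double c1 = bil(M, E1, e0), c2 = bil(M, E2, e0);
      double l01 = (A22 * c1 - A12 * c2) / det;
      double l02 = (A11 * c2 - A12 * c1) / det;
      double m1 = (A22 * t1 - A12 * t2) / det;
      double m2 = (A11 * t2 - A12 * t1) / det;
      double K = qf(M, e0) - (l01 * c1 + l02 * c2);
      double den = 1.0 - (t1 * m1 + t2 * m2);
      if (K >= 0 && den > 1e-14) {
        double s = std::sqrt(K / den);
        double l1 = l01 - s * m1, l2 = l02 - s * m2;
        if (l1 > -1e-12 && l2 > -1e-12 && l1 + l2 < 1 + 1e-12) {
          double cand = T[2] + l1 * t1 + l2 * t2 + s;
          if (cand < best) best = cand;
        }
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector eikonal_solve_cpp(NumericMatrix nodes, IntegerMatrix tets,
                                NumericMatrix V, LogicalVector active,
                                IntegerVector src, NumericVector onset,
                                double tol) {
  const int n = nodes.nrow(), m = tets.nrow();
  // per-element metric M = V^{-1}
  std::vector<double> Mv((size_t)m * 9);
  for (int e = 0; e < m; ++e) {
    if (!active[e]) continue;
    double A[9], Ai[9];
    for (int k = 0; k < 9; ++k) A[k] = V(e, k);
    if (!inv3(A, Ai)) stop("singular velocity tensor in element %d", e + 1);
    for (int k = 0; k < 9; ++k) Mv[(size_t)e * 9 + k] = Ai[k];
  }
  // node -> active tets (CSR)
  std::vector<int> cnt(n + 1, 0);
  for (int e = 0; e < m; ++e) {
    if (!active[e]) continue;
    for (int k = 0; k < 4; ++k) cnt[tets(e, k) + 1]++;
  }
  for (int i = 0; i < n; ++i) cnt[i + 1] += cnt[i];
  std::vector<int> adj(cnt[n]);
  {
    std::vector<int> fill(cnt.begin(), cnt.end() - 1);
    for (int e = 0; e < m; ++e) {
      if (!active[e]) continue;
      for (int k = 0; k < 4; ++k) adj[fill[tets(e, k)]++] = e;
    }
  }
  std::vector<double> T(n, INF);
  std::vector<char> fixed_(n, 0), inq(n, 0);
  for (int s = 0; s < src.size(); ++s) {
    int u = src[s];
    if (u < 0 || u >= n) stop("source node out of range");
    if (onset[s] < T[u]) T[u] = onset[s];
    fixed_[u] = 1;
  }
  std::deque<int> q;
  // seed with neighbours of the sources
  for (int s = 0; s < src.size(); ++s) {
    int u = src[s];
    for (int a = cnt[u]; a < cnt[u + 1]; ++a) {
      int e = adj[a];
      for (int k = 0; k < 4; ++k) {
        int w = tets(e, k);
        if (!fixed_[w] && !inq[w]) { inq[w] = 1; q.push_back(w); }
      }
    }
  }
  long pops = 0;
  const long pop_limit = 2000L * (long)n + 1000L;
  double xf[3][3], Tf[3], xd[3];
  while (!q.empty()) {
    if (++pops > pop_limit) stop("eikonal solver failed to converge");
    int u = q.front(); q.pop_front();
    inq[u] = 0;
    double old = T[u], best = old;
    for (int a = cnt[u]; a < cnt[u + 1]; ++a) {
      int e = adj[a];
      int idx = 0;
      bool any_finite = false;
      for (int k = 0; k < 4; ++k) {
        int w = tets(e, k);
        if (w == u) continue;
        xf[idx][0] = nodes(w, 0); xf[idx][1] = nodes(w, 1); xf[idx][2] = nodes(w, 2);
        Tf[idx] = T[w];
        if (std::isfinite(T[w])) any_finite = true;
        ++idx;
      }
      if (!any_finite || idx != 3) continue;
      xd[0] = nodes(u, 0); xd[1] = nodes(u, 1); xd[2] = nodes(u, 2);
      double cand = local_update(xf, Tf, xd, &Mv[(size_t)e * 9]);
      if (cand < best) best = cand;
    }
    if (best < old - tol) {
      T[u] = best;
      for (int a = cnt[u]; a < cnt[u + 1]; ++a) {
        int e = adj[a];
        for (int k = 0; k < 4; ++k) {
          int w = tets(e, k);
          if (w != u && !fixed_[w] && !inq[w]) { inq[w] = 1; q.push_back(w); }
        }
      }
    }
  }
  return NumericVector(T.begin(), T.end());
}

static inline double dot3(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static double pt_seg_d2(const double p[3], const double a[3], const double b[3]) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double t = dot3(ab, ap);
  double denom = dot3(ab, ab);
  if (denom > 0) t /= denom; else t = 0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  double d[3] = {ap[0] - t * ab[0], ap[1] - t * ab[1], ap[2] - t * ab[2]};
  return dot3(d, d);
}

// squared distance from a point to a triangle
static double pt_tri_d2(const double p[3], const double a[3],
                        const double b[3], const double c[3]) {
  double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double a11 = dot3(e1, e1), a22 = dot3(e2, e2), a12 = dot3(e1, e2);
  double b1 = dot3(e1, ap), b2 = dot3(e2, ap);
  double det = a11 * a22 - a12 * a12;
  if (det > 1e-300) {
    double u = (a22 * b1 - a12 * b2) / det;
    double v = (a11 * b2 - a12 * b1) / det;
    if (u >= 0 && v >= 0 && u + v <= 1) {
      double d[3] = {ap[0] - u * e1[0] - v * e2[0],
                     ap[1] - u * e1[1] - v * e2[1],
                     ap[2] - u * e1[2] - v * e2[2]};
      return dot3(d, d);
    }
  }
  double d2 = pt_seg_d2(p, a, b);
  double t2 = pt_seg_d2(p, b, c);
  if (t2 < d2) d2 = t2;
  t2 = pt_seg_d2(p, a, c);
  if (t2 < d2) d2 = t2;
  return d2;
}

// minimum distance from each point to a triangulated surface
// [[Rcpp::export]]
NumericVector surface_distance_cpp(NumericMatrix points, NumericMatrix nodes,
                                   IntegerMatrix tris) {
  const int n = points.nrow(), nt = tris.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double best = INF;
    for (int k = 0; k < nt; ++k) {
      double a[3] = {nodes(tris(k, 0), 0), nodes(tris(k, 0), 1), nodes(tris(k, 0), 2)};
      double b[3] = {nodes(tris(k, 1), 0), nodes(tris(k, 1), 1), nodes(tris(k, 1), 2)};
      double c[3] = {nodes(tris(k, 2), 0), nodes(tris(k, 2), 1), nodes(tris(k, 2), 2)};
      double d2 = pt_tri_d2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
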