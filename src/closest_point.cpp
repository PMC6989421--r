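#include <Rcpp.h>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p. Ericson, Real-Time Collision
// Detection, ch. 5.1.5. Also reports barycentric coordinates of the foot.
static inline void cp_triangle(const double *p, const double *a,
                               const double *b, const double *c,
                               double *out, double *bary) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {  // vertex a
    for (int k = 0; k < 3; ++k) out[k] = a[k];
    bary[0] = 1.0; bary[1] = 0.0; bary[2] = 0.0;
    return;
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {  // vertex b
    for (int k = 0; k < 3; ++k) out[k] = b[k];
    bary[0] = 0.0; bary[1] = 1.0; bary[2] = 0.0;
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {  // edge ab
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    bary[0] = 1.0 - v; bary[1] = v; bary[2] = 0.0;
    return;
  }
  double cp_[3];
  for (int k = 0; k < 3; ++k) cp_[k] = p[k] - c[k];
  double d5 = ab[0] * cp_[0] + ab[1] * cp_[1] + ab[2] * cp_[2];
  double d6 = ac[0] * cp_[0] + ac[1] * cp_[1] + ac[2] * cp_[2];
  if (d6 >= 0.0 && d5 <= d6) {  // vertex c
    for (int k = 0; k < 3; ++k) out[k] = c[k];
    bary[0] = 0.0; bary[1] = 0.0; bary[2] = 1.0;
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {  // edge ac
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    bary[0] = 1.0 - w; bary[1] = 0.0; bary[2] = w;
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {  // edge bc
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    bary[0] = 0.0; bary[1] = 1.0 - w; bary[2] = w;
    return;
  }
  double denom = 1.0 / (va + vb + vc);  // interior
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
  bary[0] = 1.0 - v - w; bary[1] = v; bary[2] = w;
}

//' @title Closest points on a triangle mesh (internal kernel)
//' @description For each query point, exhaustively scans all triangles and
//'   returns the globally closest surface point, the (1-based) index of the
//'   face attaining it, the distance, and barycentric coordinates of the foot
//'   point. Ties are broken towards the lowest face index.
//' @param queries numeric matrix M x 3
//' @param vertices numeric matrix N x 3
//' @param faces integer matrix F x 3, 1-based vertex indices
//' @return list(points, face, distance, bary)
//' @keywords internal
// [[Rcpp::export(name = ".closest_points_cpp")]]
List closest_points_cpp(NumericMatrix queries, NumericMatrix vertices,
                        IntegerMatrix faces) {
  const int M = queries.nrow(), F = faces.nrow();
  if (F < 1) stop("mesh has no faces");
  NumericMatrix pts(M, 3), bary(M, 3);
  IntegerVector face(M);
  NumericVector dist(M);
  std::vector<double> V(vertices.nrow() * 3);
  for (int i = 0; i < vertices.nrow(); ++i)
    for (int k = 0; k < 3; ++k) V[3 * i + k] = vertices(i, k);
  std::vector<int> Fv(F * 3);
  for (int f = 0; f < F; ++f)
    for (int k = 0; k < 3; ++k) Fv[3 * f + k] = faces(f, k) - 1;

  for (int i = 0; i < M; ++i) {
    double p[3] = {queries(i, 0), queries(i, 1), queries(i, 2)};
    double best = R_PosInf, bestpt[3] = {0, 0, 0}, bestb[3] = {0, 0, 0};
    int bestf = -1;
    for (int f = 0; f < F; ++f) {
      const double *a = &V[3 * Fv[3 * f]];
      const double *b = &V[3 * Fv[3 * f + 1]];
      const double *c = &V[3 * Fv[3 * f + 2]];
      double q[3], bc[3];
      cp_triangle(p, a, b, c, q, bc);
      double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        bestf = f;
        for (int k = 0; k < 3; ++k) { bestpt[k] = q[k]; bestb[k] = bc[k]; }
      }
    }
    for (int k = 0; k < 3; ++k) { pts(i, k) = bestpt[k]; bary(i, k) = bestb[k]; }
    face[i] = bestf + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["points"] = pts, _["face"] = face,
                      _["distance"] = dist, _["bary"] = bary);
}

//' @title Pairwise Euclidean distance matrix (internal kernel)
//' @param a numeric matrix N x 3
//' @param b numeric matrix M x 3
//' @return numeric matrix N x M of distances
//' @keywords internal
// [[Rcpp::export(name = ".cross_dist_cpp")]]
NumericMatrix cross_dist_cpp(NumericMatrix a, NumericMatrix b) {
  const int N = a.nrow(), M = b.nrow();
  NumericMatrix out(N, M);
  for (int i = 0; i < N; ++i) {
    double x = a(i, 0), y = a(i, 1), z = a(i, 2);
    for (int j = 0; j < M; ++j) {
      double dx = x - b(j, 0), dy = y - b(j, 1), dz = z - b(j, 2);
      out(i, j) = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  return out;
}
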