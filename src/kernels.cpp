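#include <Rcpp.h>
using namespace Rcpp;

// Lattice codes: 0 = empty, 1..n = population index. The grid is stored
// column-major (an R matrix, height rows x width cols); linear site indices
// follow R's column-major order so an R-side reference stepper can mirror
// the random draw sequence exactly.
//
// Draw protocol per elementary contact update:
//   u1 -> focal site; if the focal site is empty nothing more is drawn;
//   u2 -> von Neumann neighbor (0 up, 1 down, 2 left, 3 right; toroidal);
//   if a kill edge focal -| neighbor exists: u3, kill iff u3 < p_kill;
//   else if the neighbor is empty:           u3, copy iff u3 < p_rep.
// One sweep = height*width contact updates, then a demographic pass over
// sites in column-major order: for each occupied site draw u_m (maturation,
// applied if an outgoing edge exists) then u_d (spontaneous death of the
// post-maturation state).

static inline int torus(int i, int n) { return (i % n + n) % n; }

// [[Rcpp::export]]
List ca_run_cpp(IntegerMatrix grid, int sweeps,
                IntegerMatrix kill_edge, NumericMatrix kill_prob,
                NumericVector rep_prob, NumericVector mat_prob,
                IntegerVector mat_target, NumericVector death_prob) {
  int H = grid.nrow(), W = grid.ncol();
  int N = H * W;
  int npop = rep_prob.size();
  IntegerMatrix g = clone(grid);
  IntegerMatrix counts(sweeps, npop);

  for (int s = 0; s < sweeps; ++s) {
    for (int k = 0; k < N; ++k) {
      int site = (int)(unif_rand() * N);
      if (site >= N) site = N - 1;
      int focal = g[site];
      if (focal == 0) continue;
      int r = site % H, c = site / H;
      int dir = (int)(unif_rand() * 4);
      if (dir >= 4) dir = 3;
      int nr = r, nc = c;
      if (dir == 0) nr = torus(r - 1, H);
      else if (dir == 1) nr = torus(r + 1, H);
      else if (dir == 2) nc = torus(c - 1, W);
      else nc = torus(c + 1, W);
      int nsite = nc * H + nr;
      int nb = g[nsite];
      if (nb > 0 && kill_edge(focal - 1, nb - 1) == 1) {
        if (unif_rand() < kill_prob(focal - 1, nb - 1)) g[nsite] = 0;
      } else if (nb == 0) {
        if (unif_rand() < rep_prob[focal - 1]) g[nsite] = focal;
      }
    }
    for (int site = 0; site < N; ++site) {
      int st = g[site];
      if (st == 0) continue;
      double um = unif_rand();
      if (mat_target[st - 1] > 0 && um < mat_prob[st - 1]) {
        st = mat_target[st - 1];
        g[site] = st;
      }
      double ud = unif_rand();
      if (ud < death_prob[st - 1]) g[site] = 0;
    }
    for (int site = 0; site < N; ++site)
      if (g[site] > 0) counts(s, g[site] - 1)++;
  }
  return List::create(Named("grid") = g, Named("counts") = counts);
}

static inline double pt_seg_dist(double px, double py, double ax, double ay,
                                 double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy;
  double t = 0.0;
  if (L2 > 0) {
    t = ((px - ax) * dx + (py - ay) * dy) / L2;
    if (t < 0) t = 0;
    if (t > 1) t = 1;
  }
  double qx = ax + t * dx - px, qy = ay + t * dy - py;
  return std::sqrt(qx * qx + qy * qy);
}

static inline double cross2(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

static bool segs_intersect(double ax, double ay, double bx, double by,
                           double cx, double cy, double dx, double dy) {
  double d1 = cross2(cx, cy, dx, dy, ax, ay);
  double d2 = cross2(cx, cy, dx, dy, bx, by);
  double d3 = cross2(ax, ay, bx, by, cx, cy);
  double d4 = cross2(ax, ay, bx, by, dx, dy);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return true;
  return false;
}

// Minimum distance between two segments [p0,p1], [q0,q1] in R^d
// (Eberly's constrained quadratic minimization, valid in any dimension).
static double seg_seg_dist_nd(const double *p0, const double *p1,
                              const double *q0, const double *q1, int d) {
  std::vector<double> u(d), v(d), w(d);
  double a = 0, b = 0, c = 0, dd = 0, e = 0;
  for (int k = 0; k < d; ++k) {
    u[k] = p1[k] - p0[k];
    v[k] = q1[k] - q0[k];
    w[k] = p0[k] - q0[k];
    a += u[k] * u[k];
    b += u[k] * v[k];
    c += v[k] * v[k];
    dd += u[k] * w[k];
    e += v[k] * w[k];
  }
  double D = a * c - b * b;
  double sN, sD = D, tN, tD = D;
  const double tiny = 1e-30;
  if (D < tiny) { sN = 0.0; sD = 1.0; tN = e; tD = c > tiny ? c : 1.0; }
  else {
    sN = b * e - c * dd;
    tN = a * e - b * dd;
    if (sN < 0) { sN = 0; tN = e; tD = c > tiny ? c : 1.0; }
    else if (sN > sD) { sN = sD; tN = e + b; tD = c > tiny ? c : 1.0; }
  }
  if (tN < 0) {
    tN = 0;
    if (-dd < 0) sN = 0;
    else if (-dd > a) sN = sD;
    else { sN = -dd; sD = a > tiny ? a : 1.0; }
  } else if (tN > tD) {
    tN = tD;
    if ((-dd + b) < 0) sN = 0;
    else if ((-dd + b) > a) sN = sD;
    else { sN = -dd + b; sD = a > tiny ? a : 1.0; }
  }
  double sc = (std::abs(sN) < tiny) ? 0.0 : sN / sD;
  double tc = (std::abs(tN) < tiny) ? 0.0 : tN / tD;
  double dist2 = 0;
  for (int k = 0; k < d; ++k) {
    double diff = w[k] + sc * u[k] - tc * v[k];
    dist2 += diff * diff;
  }
  return std::sqrt(dist2);
}

// Minimum distance between non-adjacent segments of the polyline whose
// vertices are the rows of `pts` (T x d); segments shorter than `eps` are
// degenerate and skipped.
// [[Rcpp::export]]
double min_segment_separation_nd_cpp(NumericMatrix pts, double eps = 1e-15) {
  int T = pts.nrow(), d = pts.ncol();
  int m = T - 1;
  std::vector<double> P(T * d);
  for (int i = 0; i < T; ++i)
    for (int k = 0; k < d; ++k) P[i * d + k] = pts(i, k);
  std::vector<double> len(m);
  for (int i = 0; i < m; ++i) {
    double L = 0;
    for (int k = 0; k < d; ++k) {
      double dx = P[(i + 1) * d + k] - P[i * d + k];
      L += dx * dx;
    }
    len[i] = std::sqrt(L);
  }
  double best = R_PosInf;
  for (int i = 0; i < m; ++i) {
    if (len[i] < eps) continue;
    for (int j = i + 2; j < m; ++j) {
      if (len[j] < eps) continue;
      double dist = seg_seg_dist_nd(&P[i * d], &P[(i + 1) * d],
                                    &P[j * d], &P[(j + 1) * d], d);
      if (dist < best) best = dist;
      if (best == 0.0) return 0.0;
    }
  }
  if (!R_FINITE(best)) return NA_REAL;
  return best;
}

// Minimum distance between non-adjacent segments of the polyline
// (x[i], y[i]) -> (x[i+1], y[i+1]); segments shorter than `eps` are
// treated as degenerate and skipped.
// [[Rcpp::export]]
double min_segment_separation_cpp(NumericVector x, NumericVector y,
                                  double eps = 1e-15) {
  int m = x.size() - 1;
  double best = R_PosInf;
  for (int i = 0; i < m; ++i) {
    double li = std::hypot(x[i + 1] - x[i], y[i + 1] - y[i]);
    if (li < eps) continue;
    for (int j = i + 2; j < m; ++j) {
      double lj = std::hypot(x[j + 1] - x[j], y[j + 1] - y[j]);
      if (lj < eps) continue;
      if (segs_intersect(x[i], y[i], x[i + 1], y[i + 1],
                         x[j], y[j], x[j + 1], y[j + 1]))
        return 0.0;
      double d = pt_seg_dist(x[j], y[j], x[i], y[i], x[i + 1], y[i + 1]);
      d = std::min(d, pt_seg_dist(x[j + 1], y[j + 1],
                                  x[i], y[i], x[i + 1], y[i + 1]));
      d = std::min(d, pt_seg_dist(x[i], y[i], x[j], y[j], x[j + 1], y[j + 1]));
      d = std::min(d, pt_seg_dist(x[i + 1], y[i + 1],
                                  x[j], y[j], x[j + 1], y[j + 1]));
      if (d < best) best = d;
    }
  }
  if (!R_FINITE(best)) return NA_REAL;
  return best;
}
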