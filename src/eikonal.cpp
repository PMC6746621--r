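// Anisotropic eikonal solver on tetrahedral meshes.
//
// Label-correcting fast-iterative scheme: a min-heap orders tentative
// arrival times; popping a node triggers local updates of every neighbour
// through every shared (non-blocked) element, and improved nodes are
// re-inserted.  Unlike plain fast marching this tolerates the causality
// violations that anisotropic metrics induce on lattice tetrahedra, at the
// cost of occasional re-expansion.
//
// Per-element metric: travel time along direction d is sqrt(d' M d) with
//   M = f f'/vl^2 + (I - f f')/vt^2,   vt = ratio * vl,
// f the unit fiber direction, vl the longitudinal speed in mm/ms (= m/s).
// vl <= 0 encodes complete block: the element transmits nothing.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Metric {
  double f[3];   // unit fiber
  double st;     // 1/vt^2
  double dsl;    // 1/vl^2 - 1/vt^2
  // x' M y = st * (x.y) + dsl * (f.x)(f.y)
  inline double dot(const double* x, const double* y) const {
    double xy = x[0]*y[0] + x[1]*y[1] + x[2]*y[2];
    double fx = f[0]*x[0] + f[1]*x[1] + f[2]*x[2];
    double fy = f[0]*y[0] + f[1]*y[1] + f[2]*y[2];
    return st * xy + dsl * fx * fy;
  }
  inline double norm(const double* x) const {
    double q = dot(x, x);
    return q > 0.0 ? std::sqrt(q) : 0.0;
  }
};

// objective of the 3-point (face) update at barycentric (a,b)
static inline double face_obj(const Metric& M, double t1, double d2, double d3,
                              const double* d0, const double* u, const double* w,
                              double a, double b) {
  double r[3] = { d0[0] - a*u[0] - b*w[0],
                  d0[1] - a*u[1] - b*w[1],
                  d0[2] - a*u[2] - b*w[2] };
  return t1 + a*d2 + b*d3 + M.norm(r);
}

// two-point (edge) update: min over alpha in [0,1] of
//   (1-a) t1 + a t2 + || d0 - a u ||_M
static double edge_update(const Metric& M, double t1, double t2,
                          const double* d0, const double* u) {
  double A = M.dot(u, u), B = M.dot(u, d0), C = M.dot(d0, d0);
  double D = t2 - t1;
  double best = INF;
  // endpoints
  {
    double s0 = C > 0 ? std::sqrt(C) : 0.0;
    double r1[3] = { d0[0]-u[0], d0[1]-u[1], d0[2]-u[2] };
    best = std::min(t1 + s0, t2 + M.norm(r1));
  }
  // Candidate interior minimizers; spurious or duplicate candidates are
  // harmless because the true objective is re-evaluated at each.
  double cand[3]; int nc = 0;
  if (A > 1e-300) cand[nc++] = B / A;  // M-orthogonal projection (exact for D = 0)
  // stationary points of the squared condition
  // (B - a A)^2 = D^2 (C - 2 a B + a^2 A).  Analytically
  // disc = 4 D^2 (A - D^2)(A C - B^2) >= 0, but the expanded form can round
  // negative near ties (D ~ 0): clamp instead of branching on the sign.
  double a2 = A * (A - D*D);
  double a1 = -2.0 * B * (A - D*D);
  double a0 = B*B - D*D*C;
  if (std::fabs(a2) > 1e-300) {
    double sq = std::sqrt(std::max(0.0, a1*a1 - 4.0*a2*a0));
    cand[nc++] = (-a1 - sq) / (2.0 * a2);
    cand[nc++] = (-a1 + sq) / (2.0 * a2);
  }
  for (int k = 0; k < nc; ++k) {
    double a = cand[k];
    if (a > 0.0 && a < 1.0) {
      double r[3] = { d0[0]-a*u[0], d0[1]-a*u[1], d0[2]-a*u[2] };
      double val = t1 + a*D + M.norm(r);
      if (val < best) best = val;
    }
  }
  return best;
}

// three-point (face) update with known times t1,t2,t3 at x1,x2,x3,
// target at xj; d0 = xj-x1, u = x2-x1, w = x3-x1
static double face_update(const Metric& M, double t1, double t2, double t3,
                          const double* d0, const double* u, const double* w) {
  double d2 = t2 - t1, d3 = t3 - t1;
  double Auu = M.dot(u,u), Auw = M.dot(u,w), Aww = M.dot(w,w);
  double Bu = M.dot(u,d0), Bw = M.dot(w,d0), C = M.dot(d0,d0);
  double det = Auu*Aww - Auw*Auw;
  double best = INF;
  if (std::fabs(det) > 1e-300) {
    // stationarity: G [a;b] = [Bu;Bw] - s [d2;d3]
    double p0a = ( Aww*Bu - Auw*Bw) / det;
    double p0b = (-Auw*Bu + Auu*Bw) / det;
    double p1a = ( Aww*d2 - Auw*d3) / det;
    double p1b = (-Auw*d2 + Auu*d3) / det;
    double num = std::max(0.0, C - (p0a*Bu + p0b*Bw));  // = r'Mr at the projection
    double den = 1.0 - (p1a*d2 + p1b*d3);
    if (den > 0.0) {
      double s = std::sqrt(num / den);
      double a = p0a - s*p1a, b = p0b - s*p1b;
      if (a >= 0.0 && b >= 0.0 && a + b <= 1.0) {
        double val = face_obj(M, t1, d2, d3, d0, u, w, a, b);
        if (val < best) best = val;
      }
    }
    // M-orthogonal projection onto the face (exact stationary point when
    // d2 = d3 = 0); cheap extra candidate, robust at ties
    if (p0a >= 0.0 && p0b >= 0.0 && p0a + p0b <= 1.0) {
      double val = face_obj(M, t1, d2, d3, d0, u, w, p0a, p0b);
      if (val < best) best = val;
    }
  }
  return best;
}

// barycentric inside test for a tet, with a small absolute tolerance
static bool point_in_tet(const double* p, const double* a, const double* b,
                         const double* c, const double* d) {
  double m[3][3], rhs[3];
  for (int k = 0; k < 3; ++k) {
    m[k][0] = b[k]-a[k]; m[k][1] = c[k]-a[k]; m[k][2] = d[k]-a[k];
    rhs[k] = p[k]-a[k];
  }
  double det = m[0][0]*(m[1][1]*m[2][2]-m[1][2]*m[2][1])
             - m[0][1]*(m[1][0]*m[2][2]-m[1][2]*m[2][0])
             + m[0][2]*(m[1][0]*m[2][1]-m[1][1]*m[2][0]);
  if (std::fabs(det) < 1e-300) return false;
  double l1 = (rhs[0]*(m[1][1]*m[2][2]-m[1][2]*m[2][1])
             - m[0][1]*(rhs[1]*m[2][2]-m[1][2]*rhs[2])
             + m[0][2]*(rhs[1]*m[2][1]-m[1][1]*rhs[2])) / det;
  double l2 = (m[0][0]*(rhs[1]*m[2][2]-m[1][2]*rhs[2])
             - rhs[0]*(m[1][0]*m[2][2]-m[1][2]*m[2][0])
             + m[0][2]*(m[1][0]*rhs[2]-rhs[1]*m[2][0])) / det;
  double l3 = (m[0][0]*(m[1][1]*rhs[2]-rhs[1]*m[2][1])
             - m[0][1]*(m[1][0]*rhs[2]-rhs[1]*m[2][0])
             + rhs[0]*(m[1][0]*m[2][1]-m[1][1]*m[2][0])) / det;
  const double tol = 1e-9;
  return l1 >= -tol && l2 >= -tol && l3 >= -tol && (l1+l2+l3) <= 1.0 + tol;
}

// [[Rcpp::export(name = ".eikonal_solve_cpp")]]
NumericVector eikonal_solve_cpp(const NumericMatrix& nodes,
                                const IntegerMatrix& elems,   // 0-based, m x 4
                                const NumericMatrix& fibers,  // m x 3 unit
                                const NumericVector& cv_long, // m, mm/ms
                                double anisotropy_ratio,
                                const IntegerVector& stim,    // 0-based
                                double onset,
                                double init_radius) {         // <0 => auto
  const int n = nodes.nrow(), m = elems.nrow();
  if (elems.ncol() != 4) stop("elements must be tetrahedra (4 columns)");
  if (fibers.nrow() != m || cv_long.size() != m)
    stop("fibers/cv_long size must match element count");
  if (anisotropy_ratio <= 0.0 || anisotropy_ratio > 1.0)
    stop("anisotropy_ratio must be in (0, 1]");

  std::vector<Metric> met(m);
  std::vector<bool> blocked(m);
  for (int e = 0; e < m; ++e) {
    double vl = cv_long[e];
    blocked[e] = !(vl > 0.0);
    if (!blocked[e]) {
      double vt = anisotropy_ratio * vl;
      met[e].f[0] = fibers(e,0); met[e].f[1] = fibers(e,1); met[e].f[2] = fibers(e,2);
      double nf = std::sqrt(met[e].f[0]*met[e].f[0] + met[e].f[1]*met[e].f[1] +
                            met[e].f[2]*met[e].f[2]);
      if (std::fabs(nf - 1.0) > 1e-6) stop("fiber directions must be unit vectors");
      met[e].st = 1.0/(vt*vt);
      met[e].dsl = 1.0/(vl*vl) - met[e].st;
    }
  }

  // node -> incident non-blocked elements (CSR)
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) {
    if (blocked[e]) continue;
    for (int k = 0; k < 4; ++k) {
      int v = elems(e,k);
      if (v < 0 || v >= n) stop("element references invalid node index");
      ++deg[v];
    }
  }
  std::vector<int> ptr(n+1, 0);
  for (int v = 0; v < n; ++v) ptr[v+1] = ptr[v] + deg[v];
  std::vector<int> inc(ptr[n]);
  {
    std::vector<int> fill(ptr.begin(), ptr.end()-1);
    for (int e = 0; e < m; ++e) {
      if (blocked[e]) continue;
      for (int k = 0; k < 4; ++k) inc[fill[elems(e,k)]++] = e;
    }
  }

  std::vector<double> t(n, INF);
  typedef std::pair<double,int> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
  bool any_live = false;
  for (int i = 0; i < stim.size(); ++i) {
    int v = stim[i];
    if (v < 0 || v >= n) stop("stimulus node index out of range");
    t[v] = onset;
    pq.push(QN(onset, v));
    if (deg[v] > 0) any_live = true;
  }
  if (stim.size() == 0) stop("stimulus node set is empty");
  if (!any_live) stop("all stimulus nodes lie inside blocked tissue");

  // --- exact-ball source initialization -------------------------------
  // First-order local updates overestimate near a point source, where the
  // front is strongly curved (worst along lattice directions without a
  // direct edge).  Within a ball of radius R around each source, nodes are
  // seeded with the straight-segment travel time under the slowest metric
  // among the elements the segment crosses: an upper bound on the true
  // time (so the label-correcting loop can only improve it) that is exact
  // in homogeneous tissue.  Segments are validated by sampling: any sample
  // outside the meshed ball (a cavity, a concavity) or inside blocked
  // tissue disqualifies the node, so no underestimate can occur.
  double h_mean = 0.0;
  {
    double acc = 0.0; long cnt = 0;
    int step = std::max(1, m / 2000);
    for (int e = 0; e < m; e += step) {
      for (int a = 0; a < 4; ++a) for (int b = a+1; b < 4; ++b) {
        double dx = nodes(elems(e,a),0)-nodes(elems(e,b),0);
        double dy = nodes(elems(e,a),1)-nodes(elems(e,b),1);
        double dz = nodes(elems(e,a),2)-nodes(elems(e,b),2);
        acc += std::sqrt(dx*dx+dy*dy+dz*dz); ++cnt;
      }
    }
    h_mean = cnt ? acc / cnt : 1.0;
  }
  double R = init_radius < 0.0 ? 8.0 * h_mean : init_radius;
  if (R > 0.0) {
    for (int si = 0; si < stim.size(); ++si) {
      int s = stim[si];
      double ps[3] = { nodes(s,0), nodes(s,1), nodes(s,2) };
      double Rg = R + 2.0 * h_mean;
      // gather candidate elements and nodes in the ball
      std::vector<int> ball_elems, ball_nodes;
      std::vector<bool> seen(n, false);
      for (int e = 0; e < m; ++e) {
        bool close = false;
        for (int k = 0; k < 4; ++k) {
          double dx = nodes(elems(e,k),0)-ps[0], dy = nodes(elems(e,k),1)-ps[1],
                 dz = nodes(elems(e,k),2)-ps[2];
          if (dx*dx+dy*dy+dz*dz <= Rg*Rg) { close = true; break; }
        }
        if (!close) continue;
        ball_elems.push_back(e);
        for (int k = 0; k < 4; ++k) {
          int v = elems(e,k);
          if (!seen[v]) {
            seen[v] = true;
            double dx = nodes(v,0)-ps[0], dy = nodes(v,1)-ps[1], dz = nodes(v,2)-ps[2];
            if (dx*dx+dy*dy+dz*dz <= R*R) ball_nodes.push_back(v);
          }
        }
      }
      // hash grid over ball elements (bin = h_mean) for point location
      double lo[3] = {ps[0]-Rg, ps[1]-Rg, ps[2]-Rg};
      int nb = std::max(1, (int)std::ceil(2.0*Rg/h_mean));
      std::vector<std::vector<int> > bins((size_t)nb*nb*nb);
      for (size_t ie = 0; ie < ball_elems.size(); ++ie) {
        int e = ball_elems[ie];
        double bl[3] = {1e300,1e300,1e300}, bh[3] = {-1e300,-1e300,-1e300};
        for (int k = 0; k < 4; ++k) for (int d = 0; d < 3; ++d) {
          double v = nodes(elems(e,k),d);
          if (v < bl[d]) bl[d] = v;
          if (v > bh[d]) bh[d] = v;
        }
        int i0[3], i1[3];
        for (int d = 0; d < 3; ++d) {
          i0[d] = std::max(0, std::min(nb-1, (int)((bl[d]-lo[d])/h_mean)));
          i1[d] = std::max(0, std::min(nb-1, (int)((bh[d]-lo[d])/h_mean)));
        }
        for (int a = i0[0]; a <= i1[0]; ++a)
          for (int b = i0[1]; b <= i1[1]; ++b)
            for (int c = i0[2]; c <= i1[2]; ++c)
              bins[(size_t)a + nb*((size_t)b + nb*c)].push_back(e);
      }
      for (size_t in = 0; in < ball_nodes.size(); ++in) {
        int v = ball_nodes[in];
        if (v == s) continue;
        double d[3] = { nodes(v,0)-ps[0], nodes(v,1)-ps[1], nodes(v,2)-ps[2] };
        double len = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
        if (len < 1e-12) continue;
        int nsamp = std::max(2, (int)std::ceil(2.0 * len / h_mean));
        bool valid = true;
        double worst = 0.0;
        for (int q = 1; q < nsamp && valid; ++q) {
          double f = (double)q / nsamp;
          double p[3] = { ps[0]+f*d[0], ps[1]+f*d[1], ps[2]+f*d[2] };
          int bi[3];
          for (int dd = 0; dd < 3; ++dd)
            bi[dd] = std::max(0, std::min(nb-1, (int)((p[dd]-lo[dd])/h_mean)));
          const std::vector<int>& cell = bins[(size_t)bi[0] + nb*((size_t)bi[1] + nb*bi[2])];
          bool found = false;
          for (size_t ci = 0; ci < cell.size(); ++ci) {
            int e = cell[ci];
            double A[3] = {nodes(elems(e,0),0),nodes(elems(e,0),1),nodes(elems(e,0),2)};
            double B[3] = {nodes(elems(e,1),0),nodes(elems(e,1),1),nodes(elems(e,1),2)};
            double C[3] = {nodes(elems(e,2),0),nodes(elems(e,2),1),nodes(elems(e,2),2)};
            double D[3] = {nodes(elems(e,3),0),nodes(elems(e,3),1),nodes(elems(e,3),2)};
            if (point_in_tet(p, A, B, C, D)) {
              if (blocked[e]) { valid = false; break; }
              double tt = met[e].norm(d);
              if (tt > worst) worst = tt;
              found = true;
              // keep scanning: a sample on a shared face may also lie in a
              // slower neighbour; taking the max of all containers is safe
            }
          }
          if (!found) valid = false;
        }
        if (valid && worst > 0.0) {
          double cand = onset + worst;
          if (cand < t[v] - 1e-10) { t[v] = cand; pq.push(QN(cand, v)); }
        }
      }
    }
  }
  // --------------------------------------------------------------------

  double X[4][3];
  while (!pq.empty()) {
    QN top = pq.top(); pq.pop();
    int v = top.second;
    if (top.first > t[v] + 1e-12) continue;  // stale entry
    for (int ii = ptr[v]; ii < ptr[v+1]; ++ii) {
      int e = inc[ii];
      const Metric& M = met[e];
      int vid[4];
      for (int k = 0; k < 4; ++k) {
        vid[k] = elems(e,k);
        X[k][0] = nodes(vid[k],0); X[k][1] = nodes(vid[k],1); X[k][2] = nodes(vid[k],2);
      }
      for (int j = 0; j < 4; ++j) {
        int nj = vid[j];
        // other three vertices
        int o[3]; int c = 0;
        for (int k = 0; k < 4; ++k) if (k != j) o[c++] = k;
        double tt[3] = { t[vid[o[0]]], t[vid[o[1]]], t[vid[o[2]]] };
        if (!(tt[0] < INF) && !(tt[1] < INF) && !(tt[2] < INF)) continue;
        double cand = INF;
        // one-point
        for (int k = 0; k < 3; ++k) {
          if (tt[k] < INF) {
            double d[3] = { X[j][0]-X[o[k]][0], X[j][1]-X[o[k]][1], X[j][2]-X[o[k]][2] };
            double val = tt[k] + M.norm(d);
            if (val < cand) cand = val;
          }
        }
        // two-point
        static const int pairs[3][2] = {{0,1},{0,2},{1,2}};
        for (int p = 0; p < 3; ++p) {
          int a = pairs[p][0], b = pairs[p][1];
          if (tt[a] < INF && tt[b] < INF) {
            double d0[3] = { X[j][0]-X[o[a]][0], X[j][1]-X[o[a]][1], X[j][2]-X[o[a]][2] };
            double u[3]  = { X[o[b]][0]-X[o[a]][0], X[o[b]][1]-X[o[a]][1], X[o[b]][2]-X[o[a]][2] };
            double val = edge_update(M, tt[a], tt[b], d0, u);
            if (val < cand) cand = val;
          }
        }
        // three-point
        if (tt[0] < INF && tt[1] < INF && tt[2] < INF) {
          double d0[3] = { X[j][0]-X[o[0]][0], X[j][1]-X[o[0]][1], X[j][2]-X[o[0]][2] };
          double u[3]  = { X[o[1]][0]-X[o[0]][0], X[o[1]][1]-X[o[0]][1], X[o[1]][2]-X[o[0]][2] };
          double w[3]  = { X[o[2]][0]-X[o[0]][0], X[o[2]][1]-X[o[0]][1], X[o[2]][2]-X[o[0]][2] };
          double val = face_update(M, tt[0], tt[1], tt[2], d0, u, w);
          if (val < cand) cand = val;
        }
        if (cand < t[nj] - 1e-10) {
          t[nj] = cand;
          pq.push(QN(cand, nj));
        }
      }
    }
  }

  NumericVector out(n);
  for (int v = 0; v < n; ++v) out[v] = t[v];
  return out;
}

// ---- point-to-triangle distances (Ericson's closest-point algorithm) ----

static void closest_on_tri(const double* p, const double* a, const double* b,
                           const double* c, double* out) {
  double ab[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
  double ac[3] = { c[0]-a[0], c[1]-a[1], c[2]-a[2] };
  double ap[3] = { p[0]-a[0], p[1]-a[1], p[2]-a[2] };
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }
  double bp[3] = { p[0]-b[0], p[1]-b[1], p[2]-b[2] };
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    out[0]=a[0]+v*ab[0]; out[1]=a[1]+v*ab[1]; out[2]=a[2]+v*ab[2]; return;
  }
  double cp[3] = { p[0]-c[0], p[1]-c[1], p[2]-c[2] };
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    out[0]=a[0]+w*ac[0]; out[1]=a[1]+w*ac[1]; out[2]=a[2]+w*ac[2]; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    out[0]=b[0]+w*(c[0]-b[0]); out[1]=b[1]+w*(c[1]-b[1]); out[2]=b[2]+w*(c[2]-b[2]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  out[0]=a[0]+ab[0]*v+ac[0]*w; out[1]=a[1]+ab[1]*v+ac[1]*w; out[2]=a[2]+ab[2]*v+ac[2]*w;
}

// For each query point: distance to the nearest triangle, the foot point and
// the triangle index.  Triangle bounding boxes give an early reject.
// [[Rcpp::export(name = ".closest_triangle_cpp")]]
List closest_triangle_cpp(const NumericMatrix& pts,      // q x 3
                          const NumericMatrix& nodes,    // n x 3
                          const IntegerMatrix& tris) {   // f x 3, 0-based
  const int q = pts.nrow(), nf = tris.nrow();
  if (nf == 0) stop("no triangles supplied");
  std::vector<double> lo(3*nf), hi(3*nf);
  for (int f = 0; f < nf; ++f) {
    for (int d = 0; d < 3; ++d) {
      double v0 = nodes(tris(f,0),d), v1 = nodes(tris(f,1),d), v2 = nodes(tris(f,2),d);
      lo[3*f+d] = std::min(v0, std::min(v1, v2));
      hi[3*f+d] = std::max(v0, std::max(v1, v2));
    }
  }
  NumericVector dist(q);
  NumericMatrix foot(q, 3);
  IntegerVector which(q);
  for (int i = 0; i < q; ++i) {
    double p[3] = { pts(i,0), pts(i,1), pts(i,2) };
    double best = INF, bf[3] = {0,0,0};
    int bidx = -1;
    for (int f = 0; f < nf; ++f) {
      double lb = 0.0;
      for (int d = 0; d < 3; ++d) {
        double e = 0.0;
        if (p[d] < lo[3*f+d]) e = lo[3*f+d] - p[d];
        else if (p[d] > hi[3*f+d]) e = p[d] - hi[3*f+d];
        lb += e*e;
      }
      if (lb >= best*best) continue;
      double A[3] = { nodes(tris(f,0),0), nodes(tris(f,0),1), nodes(tris(f,0),2) };
      double B[3] = { nodes(tris(f,1),0), nodes(tris(f,1),1), nodes(tris(f,1),2) };
      double C[3] = { nodes(tris(f,2),0), nodes(tris(f,2),1), nodes(tris(f,2),2) };
      double cp[3];
      closest_on_tri(p, A, B, C, cp);
      double dd = std::sqrt((p[0]-cp[0])*(p[0]-cp[0]) + (p[1]-cp[1])*(p[1]-cp[1]) +
                            (p[2]-cp[2])*(p[2]-cp[2]));
      if (dd < best) { best = dd; bf[0]=cp[0]; bf[1]=cp[1]; bf[2]=cp[2]; bidx = f; }
    }
    dist[i] = best;
    foot(i,0)=bf[0]; foot(i,1)=bf[1]; foot(i,2)=bf[2];
    which[i] = bidx + 1;  // 1-based for R
  }
  return List::create(_["dist"] = dist, _["foot"] = foot, _["triangle"] = which);
}
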