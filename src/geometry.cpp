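#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Uniform-grid cell list over an axis-aligned box, for neighbor queries.
// ---------------------------------------------------------------------------
struct CellList {
  double lo[3];
  double cell;
  int nc[3];
  std::vector< std::vector<int> > bins;

  CellList(const NumericMatrix& pts, const double* lo_, const double* hi_,
           double cell_size) {
    cell = cell_size;
    for (int d = 0; d < 3; d++) {
      lo[d] = lo_[d];
      nc[d] = std::max(1, (int)std::ceil((hi_[d] - lo_[d]) / cell));
    }
    bins.resize((size_t)nc[0] * nc[1] * nc[2]);
    for (int i = 0; i < pts.nrow(); i++) insert(pts(i,0), pts(i,1), pts(i,2), i);
  }
  CellList(const double* lo_, const double* hi_, double cell_size) {
    cell = cell_size;
    for (int d = 0; d < 3; d++) {
      lo[d] = lo_[d];
      nc[d] = std::max(1, (int)std::ceil((hi_[d] - lo_[d]) / cell));
    }
    bins.resize((size_t)nc[0] * nc[1] * nc[2]);
  }
  int binof(double x, double y, double z) const {
    int i = std::min(nc[0]-1, std::max(0, (int)((x - lo[0]) / cell)));
    int j = std::min(nc[1]-1, std::max(0, (int)((y - lo[1]) / cell)));
    int k = std::min(nc[2]-1, std::max(0, (int)((z - lo[2]) / cell)));
    return i + nc[0] * (j + nc[1] * k);
  }
  void insert(double x, double y, double z, int id) {
    bins[binof(x, y, z)].push_back(id);
  }
  // gather candidate ids within `rad` of (x,y,z) (superset; caller filters)
  void query(double x, double y, double z, double rad, std::vector<int>& out) const {
    out.clear();
    int span = (int)std::ceil(rad / cell);
    int ci = (int)((x - lo[0]) / cell), cj = (int)((y - lo[1]) / cell),
        ck = (int)((z - lo[2]) / cell);
    for (int k = std::max(0, ck - span); k <= std::min(nc[2]-1, ck + span); k++)
      for (int j = std::max(0, cj - span); j <= std::min(nc[1]-1, cj + span); j++)
        for (int i = std::max(0, ci - span); i <= std::min(nc[0]-1, ci + span); i++) {
          const std::vector<int>& b = bins[i + nc[0] * (j + nc[1] * k)];
          out.insert(out.end(), b.begin(), b.end());
        }
  }
};

// ---------------------------------------------------------------------------
// Random sequential addition of congruent hard spheres.
// Centers are uniform in the box; a trial is rejected if any accepted center
// lies closer than 2*radius. Stops at n_target or when max_attempts exhaust.
// Uses R's RNG so results are reproducible from set.seed().
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix rsa_pack_cpp(NumericVector lo, NumericVector hi, double radius,
                           int n_target, double max_attempts) {
  double l[3] = {lo[0], lo[1], lo[2]}, h[3] = {hi[0], hi[1], hi[2]};
  double dmin2 = 4.0 * radius * radius;
  CellList cl(l, h, std::max(2.0 * radius, 1e-12));
  std::vector<double> px, py, pz;
  px.reserve(n_target); py.reserve(n_target); pz.reserve(n_target);
  std::vector<int> cand;
  double attempts = 0;
  while ((int)px.size() < n_target && attempts < max_attempts) {
    attempts += 1;
    double x = l[0] + unif_rand() * (h[0] - l[0]);
    double y = l[1] + unif_rand() * (h[1] - l[1]);
    double z = l[2] + unif_rand() * (h[2] - l[2]);
    cl.query(x, y, z, 2.0 * radius, cand);
    bool ok = true;
    for (size_t c = 0; c < cand.size(); c++) {
      int id = cand[c];
      double dx = x - px[id], dy = y - py[id], dz = z - pz[id];
      if (dx*dx + dy*dy + dz*dz < dmin2) { ok = false; break; }
    }
    if (ok) {
      cl.insert(x, y, z, (int)px.size());
      px.push_back(x); py.push_back(y); pz.push_back(z);
    }
  }
  NumericMatrix out((int)px.size(), 3);
  for (int i = 0; i < (int)px.size(); i++) {
    out(i,0) = px[i]; out(i,1) = py[i]; out(i,2) = pz[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Mean nearest-neighbor distance (cell-list accelerated).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
double mean_nn_dist_cpp(NumericMatrix pts, NumericVector lo, NumericVector hi,
                        double guess) {
  int n = pts.nrow();
  if (n < 2) return NA_REAL;
  double l[3] = {lo[0], lo[1], lo[2]}, h[3] = {hi[0], hi[1], hi[2]};
  CellList cl(pts, l, h, std::max(guess, 1e-12));
  std::vector<int> cand;
  double tot = 0.0;
  for (int i = 0; i < n; i++) {
    double best = R_PosInf;
    double rad = guess;
    while (!R_finite(best)) {
      cl.query(pts(i,0), pts(i,1), pts(i,2), rad, cand);
      for (size_t c = 0; c < cand.size(); c++) {
        int j = cand[c];
        if (j == i) continue;
        double dx = pts(i,0)-pts(j,0), dy = pts(i,1)-pts(j,1), dz = pts(i,2)-pts(j,2);
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < best) best = d2;
      }
      rad *= 2.0; // grow search radius until a neighbor is found
      if (rad > 1e6) break;
    }
    tot += std::sqrt(best);
  }
  return tot / n;
}

// ---------------------------------------------------------------------------
// 2D linear-program feasibility (incremental / Seidel-style), used to decide
// whether two sites share a Voronoi face. Constraints a*s + b*t <= c are
// pre-normalized (hypot(a,b) == 1). Feasible region is intersected with the
// box [-bound, bound]^2. Objective: lexicographic minimum of (s, t) — the
// objective is irrelevant, only feasibility matters.
// ---------------------------------------------------------------------------
static bool lp2_feasible(const std::vector<double>& a, const std::vector<double>& b,
                         const std::vector<double>& c, double bound) {
  const double tol = 1e-10 * std::max(1.0, bound);
  double s = -bound, t = -bound;
  size_t m = a.size();
  for (size_t i = 0; i < m; i++) {
    if (a[i] * s + b[i] * t <= c[i] + tol) continue;
    // current point violates constraint i: new optimum lies on its boundary
    // line a_i s + b_i t = c_i. Parametrize by the better-conditioned axis.
    double ai = a[i], bi = b[i], ci = c[i];
    bool par_s; // if true: s = u free, t = (ci - ai*u)/bi
    if (std::fabs(bi) >= std::fabs(ai)) par_s = true; else par_s = false;
    double ulo = -bound, uhi = bound;
    // box constraint on the dependent coordinate
    {
      double A = par_s ? (-ai / bi) : (-bi / ai); // dependent = ci/den + A*u
      double off = par_s ? (ci / bi) : (ci / ai);
      // -bound <= off + A*u <= bound
      if (std::fabs(A) < 1e-300) {
        if (off < -bound - tol || off > bound + tol) return false;
      } else if (A > 0) {
        ulo = std::max(ulo, (-bound - off) / A);
        uhi = std::min(uhi, ( bound - off) / A);
      } else {
        ulo = std::max(ulo, ( bound - off) / A);
        uhi = std::min(uhi, (-bound - off) / A);
      }
    }
    for (size_t j = 0; j < i; j++) {
      // a_j s + b_j t <= c_j restricted to the line
      double coef, rhs;
      if (par_s) { coef = a[j] - b[j] * ai / bi; rhs = c[j] - b[j] * ci / bi; }
      else       { coef = b[j] - a[j] * bi / ai; rhs = c[j] - a[j] * ci / ai; }
      if (std::fabs(coef) < 1e-14) {
        if (rhs < -tol) return false;
      } else if (coef > 0) {
        uhi = std::min(uhi, rhs / coef);
      } else {
        ulo = std::max(ulo, rhs / coef);
      }
      if (ulo > uhi + tol) return false;
    }
    if (ulo > uhi + tol) return false;
    // lexicographic min: pick the endpoint minimizing s (then t)
    double u;
    if (par_s) u = ulo;
    else {
      // s = off + A*u with A = -bi/ai; minimize s over [ulo, uhi]
      double A = -bi / ai;
      u = (A > 0) ? ulo : uhi;
      if (std::fabs(A) < 1e-14) u = ulo;
    }
    if (par_s) { s = u; t = (ci - ai * u) / bi; }
    else       { t = u; s = (ci - bi * u) / ai; }
  }
  return true;
}

// Decide whether sites i and j share a Voronoi face, given constraint sites.
// eps_len: required clearance (a feasible face point must sit at least eps_len
// inside every halfplane), excluding degenerate zero-area contacts.
static bool share_face(const NumericMatrix& pts, int i, int j,
                       const std::vector<int>& con, double eps_len, double bound) {
  double pi[3] = {pts(i,0), pts(i,1), pts(i,2)};
  double pj[3] = {pts(j,0), pts(j,1), pts(j,2)};
  double m[3]  = {0.5*(pi[0]+pj[0]), 0.5*(pi[1]+pj[1]), 0.5*(pi[2]+pj[2])};
  double w[3]  = {pj[0]-pi[0], pj[1]-pi[1], pj[2]-pi[2]};
  double wn = std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
  if (wn < 1e-14) return false;
  for (int d = 0; d < 3; d++) w[d] /= wn;
  // orthonormal basis (u, v) of the bisector plane
  double u[3];
  if (std::fabs(w[0]) <= std::fabs(w[1]) && std::fabs(w[0]) <= std::fabs(w[2])) {
    u[0] = 0; u[1] = -w[2]; u[2] = w[1];
  } else if (std::fabs(w[1]) <= std::fabs(w[2])) {
    u[0] = -w[2]; u[1] = 0; u[2] = w[0];
  } else {
    u[0] = -w[1]; u[1] = w[0]; u[2] = 0;
  }
  double un = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
  for (int d = 0; d < 3; d++) u[d] /= un;
  double v[3] = {w[1]*u[2]-w[2]*u[1], w[2]*u[0]-w[0]*u[2], w[0]*u[1]-w[1]*u[0]};

  std::vector<double> A, B, C;
  A.reserve(con.size()); B.reserve(con.size()); C.reserve(con.size());
  for (size_t q = 0; q < con.size(); q++) {
    int k = con[q];
    if (k == i || k == j) continue;
    double dk[3] = {pts(k,0)-pi[0], pts(k,1)-pi[1], pts(k,2)-pi[2]};
    double km[3] = {pts(k,0)-m[0], pts(k,1)-m[1], pts(k,2)-m[2]};
    double im[3] = {pi[0]-m[0], pi[1]-m[1], pi[2]-m[2]};
    // |x - p_i|^2 <= |x - p_k|^2 with x = m + s*u + t*v:
    //   2(k-i).(s*u + t*v) <= |k-m|^2 - |i-m|^2
    double a = 2.0 * (dk[0]*u[0] + dk[1]*u[1] + dk[2]*u[2]);
    double b = 2.0 * (dk[0]*v[0] + dk[1]*v[1] + dk[2]*v[2]);
    double c = (km[0]*km[0]+km[1]*km[1]+km[2]*km[2]) -
               (im[0]*im[0]+im[1]*im[1]+im[2]*im[2]);
    double nrm = std::sqrt(a*a + b*b);
    if (nrm < 1e-14) {
      if (c < eps_len) return false; // parallel bisector cuts the whole plane
      continue;
    }
    A.push_back(a / nrm); B.push_back(b / nrm); C.push_back(c / nrm - eps_len);
  }
  return lp2_feasible(A, B, C, bound);
}

// ---------------------------------------------------------------------------
// Voronoi face-sharing adjacency. Candidate pairs are centers closer than
// `cutoff`; constraints for each pair come from sites within `cutoff` of both
// endpoints (all sites when exact_all is true). Returns a 2-column matrix of
// 0-based index pairs (i < j).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix voronoi_adjacency_cpp(NumericMatrix pts, NumericVector lo,
                                    NumericVector hi, double cutoff,
                                    bool exact_all, double eps_len,
                                    double bound) {
  int n = pts.nrow();
  double l[3] = {lo[0], lo[1], lo[2]}, h[3] = {hi[0], hi[1], hi[2]};
  CellList cl(pts, l, h, std::max(cutoff / 2.0, 1e-12));
  std::vector<int> cand, coni, conj, con;
  std::vector<int> out_i, out_j;
  double cut2 = cutoff * cutoff;
  std::vector<int> allidx;
  if (exact_all) { allidx.resize(n); for (int i = 0; i < n; i++) allidx[i] = i; }
  for (int i = 0; i < n; i++) {
    cl.query(pts(i,0), pts(i,1), pts(i,2), cutoff, cand);
    for (size_t c = 0; c < cand.size(); c++) {
      int j = cand[c];
      if (j <= i) continue;
      double dx = pts(i,0)-pts(j,0), dy = pts(i,1)-pts(j,1), dz = pts(i,2)-pts(j,2);
      if (dx*dx + dy*dy + dz*dz > cut2) continue;
      bool face;
      if (exact_all) {
        face = share_face(pts, i, j, allidx, eps_len, bound);
      } else {
        double mx = 0.5*(pts(i,0)+pts(j,0)), my = 0.5*(pts(i,1)+pts(j,1)),
               mz = 0.5*(pts(i,2)+pts(j,2));
        cl.query(mx, my, mz, cutoff, con);
        face = share_face(pts, i, j, con, eps_len, bound);
      }
      if (face) { out_i.push_back(i); out_j.push_back(j); }
    }
  }
  IntegerMatrix out((int)out_i.size(), 2);
  for (int r = 0; r < (int)out_i.size(); r++) { out(r,0) = out_i[r]; out(r,1) = out_j[r]; }
  return out;
}

// ---------------------------------------------------------------------------
// Distance-cutoff surrogate adjacency: all pairs closer than `cutoff`.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix surrogate_adjacency_cpp(NumericMatrix pts, NumericVector lo,
                                      NumericVector hi, double cutoff) {
  int n = pts.nrow();
  double l[3] = {lo[0], lo[1], lo[2]}, h[3] = {hi[0], hi[1], hi[2]};
  CellList cl(pts, l, h, std::max(cutoff / 2.0, 1e-12));
  std::vector<int> cand, out_i, out_j;
  double cut2 = cutoff * cutoff;
  for (int i = 0; i < n; i++) {
    cl.query(pts(i,0), pts(i,1), pts(i,2), cutoff, cand);
    for (size_t c = 0; c < cand.size(); c++) {
      int j = cand[c];
      if (j <= i) continue;
      double dx = pts(i,0)-pts(j,0), dy = pts(i,1)-pts(j,1), dz = pts(i,2)-pts(j,2);
      if (dx*dx + dy*dy + dz*dz <= cut2) { out_i.push_back(i); out_j.push_back(j); }
    }
  }
  IntegerMatrix out((int)out_i.size(), 2);
  for (int r = 0; r < (int)out_i.size(); r++) { out(r,0) = out_i[r]; out(r,1) = out_j[r]; }
  return out;
}

// ---------------------------------------------------------------------------
// Brute-force voxelized Voronoi: assign every sample voxel of a res^3 grid to
// its nearest site, then read adjacency off owner changes between 6-connected
// samples. The reference oracle for small instances.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix voronoi_bruteforce_cpp(NumericMatrix pts, NumericVector lo,
                                     NumericVector hi, int res) {
  int n = pts.nrow();
  double L[3] = {hi[0]-lo[0], hi[1]-lo[1], hi[2]-lo[2]};
  std::vector<int> owner((size_t)res * res * res);
  for (int k = 0; k < res; k++)
    for (int j = 0; j < res; j++)
      for (int i = 0; i < res; i++) {
        double x = lo[0] + (i + 0.5) * L[0] / res;
        double y = lo[1] + (j + 0.5) * L[1] / res;
        double z = lo[2] + (k + 0.5) * L[2] / res;
        double best = R_PosInf; int bi = -1;
        for (int s = 0; s < n; s++) {
          double dx = x-pts(s,0), dy = y-pts(s,1), dz = z-pts(s,2);
          double d2 = dx*dx + dy*dy + dz*dz;
          if (d2 < best) { best = d2; bi = s; }
        }
        owner[(size_t)i + res * ((size_t)j + res * k)] = bi;
      }
  std::vector< std::pair<int,int> > edges;
  for (int k = 0; k < res; k++)
    for (int j = 0; j < res; j++)
      for (int i = 0; i < res; i++) {
        size_t id = (size_t)i + res * ((size_t)j + res * k);
        int o = owner[id];
        if (i + 1 < res) { int o2 = owner[id + 1]; if (o2 != o) edges.push_back(std::minmax(o, o2)); }
        if (j + 1 < res) { int o2 = owner[id + res]; if (o2 != o) edges.push_back(std::minmax(o, o2)); }
        if (k + 1 < res) { int o2 = owner[id + (size_t)res*res]; if (o2 != o) edges.push_back(std::minmax(o, o2)); }
      }
  std::sort(edges.begin(), edges.end());
  edges.erase(std::unique(edges.begin(), edges.end()), edges.end());
  IntegerMatrix out((int)edges.size(), 2);
  for (int r = 0; r < (int)edges.size(); r++) { out(r,0) = edges[r].first; out(r,1) = edges[r].second; }
  return out;
}
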