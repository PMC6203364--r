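#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Site states (kept in sync with R/state codes in ca.R)
static const int ST_ECM = 0, ST_PROLIF = 1, ST_QUIES = 2, ST_NECRO = 3,
                 ST_INV = 4, ST_DEGR = 5, ST_BLOCK = 6;

static inline double d3(double ax, double ay, double az,
                        double bx, double by, double bz) {
  double dx = ax - bx, dy = ay - by, dz = az - bz;
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

// rim-thickness scalings delta = coef * Lt^((d-1)/d); coef in mm^(1/3),
// lengths internally in cm (1 cm = 10 mm)
static inline double thickness_cm(double coef_mm13, double Lt_cm) {
  if (Lt_cm <= 0) return 0.0;
  return coef_mm13 * std::pow(10.0 * Lt_cm, 2.0 / 3.0) / 10.0;
}

// tumor edge cells: noninvasive tumor sites with at least one ECM or
// degraded-ECM neighbor (the growth-permitting surface)
static void edge_cells(const IntegerVector& state, const IntegerVector& adj_ptr,
                       const IntegerVector& adj_idx, std::vector<int>& out) {
  out.clear();
  int n = state.size();
  for (int i = 0; i < n; i++) {
    int s = state[i];
    if (s == ST_PROLIF || s == ST_QUIES || s == ST_NECRO) {
      for (int p = adj_ptr[i]; p < adj_ptr[i+1]; p++) {
        int s2 = state[adj_idx[p]];
        if (s2 == ST_ECM || s2 == ST_DEGR) { out.push_back(i); break; }
      }
    }
  }
}

// nearest edge cell to site q: returns index into edges, fills dsurf
static int nearest_edge(const std::vector<int>& edges, const NumericMatrix& pos,
                        int q, double* dsurf) {
  double best = R_PosInf; int bi = -1;
  double qx = pos(q,0), qy = pos(q,1), qz = pos(q,2);
  for (size_t e = 0; e < edges.size(); e++) {
    int i = edges[e];
    double d = d3(qx, qy, qz, pos(i,0), pos(i,1), pos(i,2));
    if (d < best) { best = d; bi = i; }
  }
  *dsurf = best;
  return bi;
}

// ---------------------------------------------------------------------------
// Rule 1: quiescent cells farther than delta_n from the tumor surface turn
// necrotic. Lt = |centroid - nearest edge cell|. Returns number necrosed.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
int ca_necrosis_cpp(IntegerVector state, NumericMatrix pos,
                    IntegerVector adj_ptr, IntegerVector adj_idx,
                    NumericVector centroid, double a_mm13) {
  std::vector<int> edges;
  edge_cells(state, adj_ptr, adj_idx, edges);
  if (edges.empty()) return 0;
  int n = state.size();
  std::vector<int> flip;
  for (int q = 0; q < n; q++) {
    if (state[q] != ST_QUIES) continue;
    double dsurf;
    int e = nearest_edge(edges, pos, q, &dsurf);
    double Lt = d3(centroid[0], centroid[1], centroid[2],
                   pos(e,0), pos(e,1), pos(e,2));
    if (dsurf > thickness_cm(a_mm13, Lt)) flip.push_back(q);
  }
  for (size_t q = 0; q < flip.size(); q++) state[flip[q]] = ST_NECRO;
  return (int)flip.size();
}

// ---------------------------------------------------------------------------
// Rule 3: proliferative cells farther than delta_p from the surface, or with
// no adjacent ECM/degraded site to divide into, turn quiescent.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
int ca_quiescence_cpp(IntegerVector state, NumericMatrix pos,
                      IntegerVector adj_ptr, IntegerVector adj_idx,
                      NumericVector centroid, double b_mm13) {
  std::vector<int> edges;
  edge_cells(state, adj_ptr, adj_idx, edges);
  int n = state.size();
  std::vector<int> flip;
  for (int q = 0; q < n; q++) {
    if (state[q] != ST_PROLIF) continue;
    bool space = false;
    for (int p = adj_ptr[q]; p < adj_ptr[q+1]; p++) {
      int s2 = state[adj_idx[p]];
      if (s2 == ST_ECM || s2 == ST_DEGR) { space = true; break; }
    }
    if (!space) { flip.push_back(q); continue; }
    if (!edges.empty()) {
      double dsurf;
      int e = nearest_edge(edges, pos, q, &dsurf);
      double Lt = d3(centroid[0], centroid[1], centroid[2],
                     pos(e,0), pos(e,1), pos(e,2));
      if (dsurf > thickness_cm(b_mm13, Lt)) flip.push_back(q);
    }
  }
  for (size_t q = 0; q < flip.size(); q++) state[flip[q]] = ST_QUIES;
  return (int)flip.size();
}

// Fisher-Yates shuffle driven by R's RNG (reproducible via set.seed)
static void shuffle_rng(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; i--) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// distance from the centroid to the spherical domain boundary along the ray
// through point p (the closest growth-permitting boundary in that direction)
static double lmax_ray(const double* c, double px, double py, double pz,
                       const double* dc, double R) {
  double ux = px - c[0], uy = py - c[1], uz = pz - c[2];
  double un = std::sqrt(ux*ux + uy*uy + uz*uz);
  if (un < 1e-14) return R;
  ux /= un; uy /= un; uz /= un;
  double wx = c[0] - dc[0], wy = c[1] - dc[1], wz = c[2] - dc[2];
  double wu = wx*ux + wy*uy + wz*uz;
  double disc = wu*wu - (wx*wx + wy*wy + wz*wz) + R*R;
  if (disc < 0) disc = 0;
  return -wu + std::sqrt(disc);
}

// ---------------------------------------------------------------------------
// Rule 2 (+4): division of a cohort of proliferative cells, in random order.
// Each cell picks a random adjacent ECM/degraded target; division succeeds
// with probability
//   multiplicative (rule_additive = 0):
//       p0 * Pgf * (1 - r/Lmax) * (1 - rho_target)^2
//   literal additive (rule_additive = 1):
//       clamp01( p0 * Pgf * (1 - r/Lmax) + (1 - rho_target)^2 )
// with Pgf = 1 - (1 - Pgamma) * phi_norm. The daughter mutates to the
// invasive phenotype with probability gamma when its neighbor count (invasive
// neighbors by default, all tumor neighbors if adhesion_tumor) is < Ai.
// cstat = (cx, cy, cz, N) is the running centroid/count of noninvasive tumor
// cells, updated in place. phi_vox (length >0) supplies drug per grid voxel
// via site_voxel; otherwise phi_fixed is the uniform normalized level.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List ca_divide_cpp(IntegerVector cohort, IntegerVector state, NumericVector rho,
                   NumericMatrix pos, IntegerVector adj_ptr, IntegerVector adj_idx,
                   NumericVector cstat, NumericVector phi_vox,
                   IntegerVector site_voxel, double phi_fixed, double C0,
                   double p0, double Pgamma, double gamma_mut, double Ai,
                   int rule_additive, int adhesion_tumor,
                   NumericVector domain_center, double R_domain) {
  const bool use_field = phi_vox.size() > 0;
  double dc[3] = {domain_center[0], domain_center[1], domain_center[2]};
  std::vector<int> order(cohort.begin(), cohort.end());
  shuffle_rng(order);
  std::vector<int> daughters;
  std::vector<int> mutated;
  std::vector<int> cand;
  for (size_t q = 0; q < order.size(); q++) {
    int i = order[q];
    if (state[i] != ST_PROLIF) continue;
    cand.clear();
    for (int p = adj_ptr[i]; p < adj_ptr[i+1]; p++) {
      int j = adj_idx[p];
      if (state[j] == ST_ECM || state[j] == ST_DEGR) cand.push_back(j);
    }
    if (cand.empty()) continue; // no space; rule 3 handles the transition
    int pick = (int)std::floor(unif_rand() * cand.size());
    if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
    int tgt = cand[pick];
    double phin;
    if (use_field) {
      phin = phi_vox[site_voxel[i]] / C0;
    } else {
      phin = phi_fixed;
    }
    if (!(phin >= 0)) phin = 0;  // also catches NaN from a zero C0
    if (phin > 1) phin = 1;
    double Pgf = 1.0 - (1.0 - Pgamma) * phin;
    double c[3] = {cstat[0], cstat[1], cstat[2]};
    double r = d3(c[0], c[1], c[2], pos(i,0), pos(i,1), pos(i,2));
    double Lmax = lmax_ray(c, pos(i,0), pos(i,1), pos(i,2), dc, R_domain);
    double conf = (Lmax > 0) ? (1.0 - r / Lmax) : 0.0;
    if (conf < 0) conf = 0;
    double rhot = rho[tgt];
    if (rhot < 0) rhot = 0; if (rhot > 1) rhot = 1;
    double ecmf = (1.0 - rhot) * (1.0 - rhot);
    double Pdiv;
    if (rule_additive) {
      Pdiv = p0 * Pgf * conf + ecmf;
      if (Pdiv > 1) Pdiv = 1;
      if (Pdiv < 0) Pdiv = 0;
    } else {
      Pdiv = p0 * Pgf * conf * ecmf;
    }
    if (unif_rand() >= Pdiv) continue;
    // division succeeds: place daughter at tgt
    rho[tgt] = 0.0;
    // rule 4: mutation decided at birth, neighbor count before any migration
    int nnbr = 0;
    for (int p = adj_ptr[tgt]; p < adj_ptr[tgt+1]; p++) {
      int s2 = state[adj_idx[p]];
      if (adhesion_tumor) {
        if (s2 == ST_PROLIF || s2 == ST_QUIES || s2 == ST_NECRO || s2 == ST_INV) nnbr++;
      } else {
        if (s2 == ST_INV) nnbr++;
      }
    }
    bool invasive = false;
    if (nnbr < Ai && gamma_mut > 0) invasive = (unif_rand() < gamma_mut);
    if (invasive) {
      state[tgt] = ST_INV;
      mutated.push_back(tgt);
    } else {
      state[tgt] = ST_PROLIF;
      double Nold = cstat[3];
      cstat[0] = (cstat[0] * Nold + pos(tgt,0)) / (Nold + 1);
      cstat[1] = (cstat[1] * Nold + pos(tgt,1)) / (Nold + 1);
      cstat[2] = (cstat[2] * Nold + pos(tgt,2)) / (Nold + 1);
      cstat[3] = Nold + 1;
    }
    daughters.push_back(tgt);
  }
  return List::create(_["daughters"] = wrap(daughters),
                      _["mutated"] = wrap(mutated));
}

// ---------------------------------------------------------------------------
// Rule 5: invasive-cell ECM degradation and migration. Each invasive cell
// makes m ~ UniformInt{0..mu} attempts; every attempt degrades the target
// ECM/degraded neighbor by u ~ Uniform[0, chi]; when the target density
// reaches 0 the cell migrates there, leaving a degraded-ECM trail. Target
// choice: outward (maximizing distance from the primary-tumor centroid) or
// uniform random when dir_random. Returns the number of migrations.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
int ca_invasion_cpp(IntegerVector state, NumericVector rho, NumericMatrix pos,
                    IntegerVector adj_ptr, IntegerVector adj_idx,
                    NumericVector centroid, int mu, double chi, int dir_random) {
  int n = state.size();
  std::vector<int> inv;
  for (int i = 0; i < n; i++) if (state[i] == ST_INV) inv.push_back(i);
  shuffle_rng(inv);
  int moves = 0;
  std::vector<int> cand;
  for (size_t q = 0; q < inv.size(); q++) {
    int cur = inv[q];
    int m = (int)std::floor(unif_rand() * (mu + 1));
    if (m > mu) m = mu;
    for (int a = 0; a < m; a++) {
      cand.clear();
      for (int p = adj_ptr[cur]; p < adj_ptr[cur+1]; p++) {
        int j = adj_idx[p];
        if (state[j] == ST_ECM || state[j] == ST_DEGR) cand.push_back(j);
      }
      if (cand.empty()) break;
      int tgt;
      if (dir_random) {
        int pick = (int)std::floor(unif_rand() * cand.size());
        if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
        tgt = cand[pick];
      } else {
        double best = -1; tgt = cand[0];
        for (size_t c = 0; c < cand.size(); c++) {
          int j = cand[c];
          double d = d3(centroid[0], centroid[1], centroid[2],
                        pos(j,0), pos(j,1), pos(j,2));
          if (d > best) { best = d; tgt = j; }
        }
      }
      if (rho[tgt] > 0 && chi > 0) rho[tgt] -= unif_rand() * chi;
      if (rho[tgt] <= 0) {
        rho[tgt] = 0.0;
        state[cur] = ST_DEGR;
        rho[cur] = 0.0;
        state[tgt] = ST_INV;
        cur = tgt;
        moves++;
      }
    }
  }
  return moves;
}

// ---------------------------------------------------------------------------
// Per-voxel exchange fields for the coupled solver:
//   n: occupancy fraction of living tumor cells (proliferative, quiescent,
//      invasive) over non-blocked sites in the voxel (dimensionless 0..1)
//   D: eta*D0 in voxels containing >= 1 tumor cell, else
//      D0 * rho0 / (mean ECM density + rho_res)   (gas-diffusion form)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List voxel_fields_cpp(IntegerVector state, NumericVector rho,
                      IntegerVector site_voxel, int nvox,
                      double D0, double eta, double rho0, double rho_res) {
  std::vector<int> nsites(nvox, 0), nliving(nvox, 0), ntumor(nvox, 0),
                   necm(nvox, 0);
  std::vector<double> sumrho(nvox, 0.0);
  int n = state.size();
  for (int i = 0; i < n; i++) {
    int v = site_voxel[i];
    int s = state[i];
    if (s == ST_BLOCK) continue;
    nsites[v]++;
    if (s == ST_PROLIF || s == ST_QUIES || s == ST_INV) nliving[v]++;
    if (s == ST_PROLIF || s == ST_QUIES || s == ST_NECRO || s == ST_INV) ntumor[v]++;
    if (s == ST_ECM || s == ST_DEGR) { necm[v]++; sumrho[v] += rho[i]; }
  }
  NumericVector nf(nvox), Df(nvox);
  double Dref = D0 * rho0 / (rho0 + rho_res);
  for (int v = 0; v < nvox; v++) {
    nf[v] = (nsites[v] > 0) ? (double)nliving[v] / nsites[v] : 0.0;
    if (ntumor[v] > 0) {
      Df[v] = eta * D0;
    } else if (necm[v] > 0) {
      Df[v] = D0 * rho0 / (sumrho[v] / necm[v] + rho_res);
    } else {
      Df[v] = Dref;
    }
  }
  return List::create(_["n"] = nf, _["D"] = Df);
}
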