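#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Time-dependent boundary concentration. mode: 0 = constant, 1 = periodic
// infusion-decay (logistic in the cycle phase, steepness tau_decay/10).
static inline double boundary_conc(double t_s, int mode, double C0,
                                   double tau_cycle_s, double tau_decay_s) {
  if (mode == 0) return C0;
  double tm = t_s - std::floor(t_s / tau_cycle_s) * tau_cycle_s;
  return C0 / (1.0 + std::exp((tm - tau_decay_s) / (tau_decay_s / 10.0)));
}

// [[Rcpp::export]]
double boundary_conc_cpp(double t_s, int mode, double C0, double tau_cycle_s,
                         double tau_decay_s) {
  return boundary_conc(t_s, mode, C0, tau_cycle_s, tau_decay_s);
}

// ---------------------------------------------------------------------------
// Explicit Euler diffusion-reaction stepping on an N^3 grid with a Dirichlet
// shell. phi is updated in place.
//   interior update: phi += dt * (Dterm - Kmet*phi - lam14*n*phi/(phi+phi0))
//   uniform D:       Dterm = D0 * (7-point Laplacian)
//   heterogeneous D: Dterm = (Dc/2) * Laplacian
//                          + sum_faces (Dnb/2) * (phi_nb - phi_c) / dx^2
// dir_idx: 0-based linear indices of Dirichlet nodes (set to C(t) each step).
// zg_idx/zg_src: zero-gradient shell nodes copied from a designated inner
// neighbor (used by region-restricted dosing), ordered so sources come first.
// Interior nodes never touch the cube faces (the Dirichlet shell encloses
// them), so neighbor indexing by offset is always valid.
// Returns the minimum interior value reached (negative values flag trouble).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
double fd_run_cpp(NumericVector phi, IntegerVector int_idx, IntegerVector dir_idx,
                  IntegerVector zg_idx, IntegerVector zg_src,
                  NumericVector D, bool uniformD, double D0,
                  NumericVector nocc, double Kmet_s, double lam14_s, double phi0,
                  double dx, double dt, int nsteps, double t0_s,
                  int sched_mode, double C0, double tau_cycle_s,
                  double tau_decay_s, int N) {
  const int NN = N * N;
  const double idx2 = 1.0 / (dx * dx);
  R_xlen_t ntot = phi.size();
  std::vector<double> buf(phi.begin(), phi.end());
  double* a = &buf[0];          // current
  std::vector<double> buf2(ntot);
  double* b = &buf2[0];         // next
  const int* ii = &int_idx[0];
  const R_xlen_t ni = int_idx.size();
  double phimin = R_PosInf;
  const bool has_n = (nocc.size() == ntot) && lam14_s > 0;

  for (int step = 0; step < nsteps; step++) {
    double t = t0_s + step * dt;
    double cb = boundary_conc(t, sched_mode, C0, tau_cycle_s, tau_decay_s);
    for (R_xlen_t q = 0; q < dir_idx.size(); q++) a[dir_idx[q]] = cb;
    for (R_xlen_t q = 0; q < zg_idx.size(); q++) a[zg_idx[q]] = a[zg_src[q]];
    std::copy(a, a + ntot, b);
    for (R_xlen_t q = 0; q < ni; q++) {
      int id = ii[q];
      double c = a[id];
      double xp = a[id+1], xm = a[id-1], yp = a[id+N], ym = a[id-N],
             zp = a[id+NN], zm = a[id-NN];
      double lap = (xp + xm + yp + ym + zp + zm - 6.0 * c) * idx2;
      double Dterm;
      if (uniformD) {
        Dterm = D0 * lap;
      } else {
        double Dc = D[id];
        Dterm = 0.5 * Dc * lap +
          0.5 * idx2 * (D[id+1]  * (xp - c) + D[id-1]  * (xm - c) +
                        D[id+N]  * (yp - c) + D[id-N]  * (ym - c) +
                        D[id+NN] * (zp - c) + D[id-NN] * (zm - c));
      }
      double react = Kmet_s * c;
      if (has_n && c > 0) react += lam14_s * nocc[id] * c / (c + phi0);
      double v = c + dt * (Dterm - react);
      if (v < phimin) phimin = v;
      b[id] = v;
    }
    std::swap(a, b);
  }
  double tend = t0_s + (double)nsteps * dt;
  double cb = boundary_conc(tend, sched_mode, C0, tau_cycle_s, tau_decay_s);
  for (R_xlen_t q = 0; q < dir_idx.size(); q++) a[dir_idx[q]] = cb;
  for (R_xlen_t q = 0; q < zg_idx.size(); q++) a[zg_idx[q]] = a[zg_src[q]];
  std::copy(a, a + ntot, phi.begin());
  return phimin;
}

// ---------------------------------------------------------------------------
// Sealed (zero-flux) box variant for conservation / free-diffusion checks:
// reflective faces via mirrored neighbors. Optional Dirichlet nodes
// (dir_idx/dir_val, e.g. two opposite faces for slab problems) are
// re-imposed every step. phi updated in place.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
double fd_run_sealed_cpp(NumericVector phi, NumericVector D, bool uniformD,
                         double D0, NumericVector nocc, double Kmet_s,
                         double lam14_s, double phi0, double dx, double dt,
                         int nsteps, int N, IntegerVector dir_idx,
                         NumericVector dir_val) {
  const int NN = N * N;
  const double idx2 = 1.0 / (dx * dx);
  R_xlen_t ntot = phi.size();
  std::vector<double> buf(phi.begin(), phi.end());
  std::vector<double> buf2(ntot);
  double* a = &buf[0];
  double* b = &buf2[0];
  const bool has_n = (nocc.size() == ntot) && lam14_s > 0;
  double phimin = R_PosInf;
  for (int step = 0; step < nsteps; step++) {
    for (R_xlen_t q = 0; q < dir_idx.size(); q++) a[dir_idx[q]] = dir_val[q];
    for (int k = 0; k < N; k++)
      for (int j = 0; j < N; j++)
        for (int i = 0; i < N; i++) {
          R_xlen_t id = i + (R_xlen_t)N * (j + (R_xlen_t)N * k);
          double c = a[id];
          // reflective: out-of-box neighbor contributes phi_c (zero flux)
          double xp = (i+1 < N) ? a[id+1]  : c, xm = (i > 0) ? a[id-1]  : c;
          double yp = (j+1 < N) ? a[id+N]  : c, ym = (j > 0) ? a[id-N]  : c;
          double zp = (k+1 < N) ? a[id+NN] : c, zm = (k > 0) ? a[id-NN] : c;
          double lap = (xp + xm + yp + ym + zp + zm - 6.0 * c) * idx2;
          double Dterm;
          if (uniformD) {
            Dterm = D0 * lap;
          } else {
            double Dc = D[id];
            double Dxp = (i+1 < N) ? D[id+1]  : Dc, Dxm = (i > 0) ? D[id-1]  : Dc;
            double Dyp = (j+1 < N) ? D[id+N]  : Dc, Dym = (j > 0) ? D[id-N]  : Dc;
            double Dzp = (k+1 < N) ? D[id+NN] : Dc, Dzm = (k > 0) ? D[id-NN] : Dc;
            Dterm = 0.5 * Dc * lap +
              0.5 * idx2 * (Dxp * (xp - c) + Dxm * (xm - c) +
                            Dyp * (yp - c) + Dym * (ym - c) +
                            Dzp * (zp - c) + Dzm * (zm - c));
          }
          double react = Kmet_s * c;
          if (has_n && c > 0) react += lam14_s * nocc[id] * c / (c + phi0);
          double v = c + dt * (Dterm - react);
          if (v < phimin) phimin = v;
          b[id] = v;
        }
    std::swap(a, b);
  }
  for (R_xlen_t q = 0; q < dir_idx.size(); q++) a[dir_idx[q]] = dir_val[q];
  std::copy(a, a + ntot, phi.begin());
  return phimin;
}
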