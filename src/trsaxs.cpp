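#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// sin(x)/x with the q r -> 0 limit
static inline double sinc(double x) {
  if (std::fabs(x) < 1e-8) return 1.0 - x * x / 6.0;
  return std::sin(x) / x;
}

// Place a new point at bond length `r` from C, with bond angle `theta`
// (B-C-new) and dihedral `phi` about the B->C axis relative to A.
static inline void place_next(const double *A, const double *B, const double *C,
                              double r, double theta, double phi, double *out) {
  double u[3] = {C[0] - B[0], C[1] - B[1], C[2] - B[2]};
  double un = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
  for (int k = 0; k < 3; ++k) u[k] /= un;
  // reference direction: component of (B - A) orthogonal to u
  double ref[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
  double dot = ref[0]*u[0] + ref[1]*u[1] + ref[2]*u[2];
  double e1[3] = {ref[0] - dot*u[0], ref[1] - dot*u[1], ref[2] - dot*u[2]};
  double e1n = std::sqrt(e1[0]*e1[0] + e1[1]*e1[1] + e1[2]*e1[2]);
  if (e1n < 1e-10) { // A,B,C collinear: any perpendicular will do
    double alt[3] = {1.0, 0.0, 0.0};
    if (std::fabs(u[0]) > 0.9) { alt[0] = 0.0; alt[1] = 1.0; }
    double d2 = alt[0]*u[0] + alt[1]*u[1] + alt[2]*u[2];
    for (int k = 0; k < 3; ++k) e1[k] = alt[k] - d2*u[k];
    e1n = std::sqrt(e1[0]*e1[0] + e1[1]*e1[1] + e1[2]*e1[2]);
  }
  for (int k = 0; k < 3; ++k) e1[k] /= e1n;
  double e2[3] = {u[1]*e1[2] - u[2]*e1[1],
                  u[2]*e1[0] - u[0]*e1[2],
                  u[0]*e1[1] - u[1]*e1[0]};
  double st = std::sin(theta), ct = std::cos(theta);
  double cp = std::cos(phi), sp = std::sin(phi);
  // direction makes angle theta with (B - C) = -u
  for (int k = 0; k < 3; ++k)
    out[k] = C[k] + r * (-ct*u[k] + st*(cp*e1[k] + sp*e2[k]));
}

// Self-avoiding C-alpha random walk. Bond length fixed; pseudo-bond angle
// uniform in [ang_min, ang_max] (radians); dihedral uniform in [-pi, pi).
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix cpp_generate_chain(int n_res, double bond,
                                 double ang_min, double ang_max,
                                 double ev_cutoff, int max_retries,
                                 int max_restarts) {
  if (n_res < 3) stop("n_res must be >= 3");
  NumericMatrix xyz(n_res, 3);
  double cut2 = ev_cutoff * ev_cutoff;
  for (int restart = 0; restart <= max_restarts; ++restart) {
    bool failed = false;
    xyz(0, 0) = 0.0; xyz(0, 1) = 0.0; xyz(0, 2) = 0.0;
    xyz(1, 0) = bond; xyz(1, 1) = 0.0; xyz(1, 2) = 0.0;
    for (int i = 2; i < n_res && !failed; ++i) {
      bool placed = false;
      for (int attempt = 0; attempt < max_retries; ++attempt) {
        double theta = ang_min + (ang_max - ang_min) * unif_rand();
        double phi = -M_PI + 2.0 * M_PI * unif_rand();
        double nw[3];
        double Ap[3];
        if (i == 2) { // no dihedral reference yet: arbitrary off-axis point
          Ap[0] = xyz(0,0); Ap[1] = xyz(0,1) + 1.0; Ap[2] = xyz(0,2);
        } else {
          Ap[0] = xyz(i-3,0); Ap[1] = xyz(i-3,1); Ap[2] = xyz(i-3,2);
        }
        double Bp[3] = {xyz(i-2,0), xyz(i-2,1), xyz(i-2,2)};
        double Cp[3] = {xyz(i-1,0), xyz(i-1,1), xyz(i-1,2)};
        place_next(Ap, Bp, Cp, bond, theta, phi, nw);
        bool clash = false;
        for (int j = 0; j <= i - 2; ++j) {
          double dx = nw[0] - xyz(j,0), dy = nw[1] - xyz(j,1), dz = nw[2] - xyz(j,2);
          if (dx*dx + dy*dy + dz*dz < cut2) { clash = true; break; }
        }
        if (!clash) {
          xyz(i,0) = nw[0]; xyz(i,1) = nw[1]; xyz(i,2) = nw[2];
          placed = true;
          break;
        }
      }
      if (!placed) failed = true;
    }
    if (!failed) return xyz;
  }
  stop("chain generation failed: restart budget exhausted (n_res=%d, angles [%.1f, %.1f] rad, cutoff %.2f A)",
       n_res, ang_min, ang_max, ev_cutoff);
  return xyz; // unreachable
}

// Exact Debye sum for unit (point) form factors: I(q) = N + 2 sum_{i<j} sinc(q r_ij)
// [[Rcpp::export]]
NumericVector cpp_debye_exact(NumericMatrix xyz, NumericVector q) {
  int n = xyz.nrow(), nq = q.size();
  int npair = n * (n - 1) / 2;
  std::vector<double> d(npair);
  int m = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i,0) - xyz(j,0), dy = xyz(i,1) - xyz(j,1), dz = xyz(i,2) - xyz(j,2);
      d[m++] = std::sqrt(dx*dx + dy*dy + dz*dz);
    }
  NumericVector I(nq);
  for (int k = 0; k < nq; ++k) {
    double s = 0.0;
    for (int p = 0; p < npair; ++p) s += sinc(q[k] * d[p]);
    I[k] = n + 2.0 * s;
  }
  return I;
}

// Histogram of pairwise distances: per-bin count, sum of r and sum of r^2,
// so the Debye sum can use the within-bin mean and a curvature correction.
// [[Rcpp::export]]
NumericMatrix cpp_pair_hist(NumericMatrix xyz, double bin_width, int n_bins) {
  int n = xyz.nrow();
  NumericMatrix H(n_bins, 3); // count, sum r, sum r^2
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i,0) - xyz(j,0), dy = xyz(i,1) - xyz(j,1), dz = xyz(i,2) - xyz(j,2);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      int b = (int)(r / bin_width);
      if (b >= n_bins) b = n_bins - 1;
      H(b, 0) += 1.0;
      H(b, 1) += r;
      H(b, 2) += r * r;
    }
  return H;
}

// second derivative of sinc(x)
static inline double sinc_dd(double x) {
  if (std::fabs(x) < 1e-4) return -1.0 / 3.0 + x * x / 10.0;
  double x2 = x * x;
  return -std::sin(x) / x - 2.0 * std::cos(x) / x2 + 2.0 * std::sin(x) / (x2 * x);
}

// Debye sum from a distance histogram: per bin, E[sinc(q r)] is expanded to
// second order about the bin mean, sinc(q rbar) + q^2 var/2 * sinc''(q rbar).
// [[Rcpp::export]]
NumericVector cpp_debye_hist(NumericMatrix H, int n_scatterers,
                             NumericVector q) {
  int nb = H.nrow(), nq = q.size();
  NumericVector I(nq);
  for (int k = 0; k < nq; ++k) {
    double s = 0.0;
    for (int b = 0; b < nb; ++b) {
      double cnt = H(b, 0);
      if (cnt == 0.0) continue;
      double rbar = H(b, 1) / cnt;
      double var = H(b, 2) / cnt - rbar * rbar;
      if (var < 0) var = 0;
      double x = q[k] * rbar;
      s += cnt * (sinc(x) + 0.5 * q[k] * q[k] * var * sinc_dd(x));
    }
    I[k] = n_scatterers + 2.0 * s;
  }
  return I;
}

// Minimum distance between non-adjacent residues (excluded-volume audit)
// [[Rcpp::export]]
double cpp_min_nonadjacent_dist(NumericMatrix xyz) {
  int n = xyz.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j) {
      double dx = xyz(i,0) - xyz(j,0), dy = xyz(i,1) - xyz(j,1), dz = xyz(i,2) - xyz(j,2);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 < best) best = r2;
    }
  return std::sqrt(best);
}
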