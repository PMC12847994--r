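// Negative log-likelihood of the double-ring anchor mixture, called by the
// pose optimizer thousands of times per fit.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rotation taking e_z onto the unit axis (az > 0 assumed), composed with a
// spin about e_z; result stored row-major in R9.
static void pose_rotation(double ax, double ay, double az, double phi,
                          double R9[9]) {
  // Rodrigues for v = e_z x a = (-ay, ax, 0), c = az
  double c = az;
  double s2 = ax * ax + ay * ay;  // |v|^2
  double A[9];
  if (s2 < 1e-24) {
    A[0] = 1; A[1] = 0; A[2] = 0;
    A[3] = 0; A[4] = 1; A[5] = 0;
    A[6] = 0; A[7] = 0; A[8] = 1;
  } else {
    double vx = -ay, vy = ax, vz = 0.0;
    double f = (1.0 - c) / s2;
    A[0] = 1 + f * (-vy * vy - vz * vz);
    A[1] = -vz + f * vx * vy;
    A[2] = vy + f * vx * vz;
    A[3] = vz + f * vx * vy;
    A[4] = 1 + f * (-vx * vx - vz * vz);
    A[5] = -vx + f * vy * vz;
    A[6] = -vy + f * vx * vz;
    A[7] = vx + f * vy * vz;
    A[8] = 1 + f * (-vx * vx - vy * vy);
  }
  double cp = std::cos(phi), sp = std::sin(phi);
  // R = A * Rz(phi)
  R9[0] = A[0] * cp + A[1] * sp; R9[1] = -A[0] * sp + A[1] * cp; R9[2] = A[2];
  R9[3] = A[3] * cp + A[4] * sp; R9[4] = -A[3] * sp + A[4] * cp; R9[5] = A[5];
  R9[6] = A[6] * cp + A[7] * sp; R9[7] = -A[6] * sp + A[7] * cp; R9[8] = A[8];
}

// par = (cx, cy, cz, a1, a2, phi[, log diameter, log spacing])
// [[Rcpp::export(name = ".npc_nll_cpp")]]
double npc_nll_cpp(NumericVector par, NumericMatrix P, int nseg,
                   double twist_rad, double diameter, double spacing,
                   double sigma, double outlier_weight, double log_unif,
                   bool free_geometry) {
  const int n = P.nrow();
  double ax = par[3], ay = par[4], az = 1.0;
  double nrm = std::sqrt(ax * ax + ay * ay + 1.0);
  ax /= nrm; ay /= nrm; az /= nrm;
  if (free_geometry) {
    diameter = std::exp(par[6]);
    spacing = std::exp(par[7]);
  }
  double R9[9];
  pose_rotation(ax, ay, az, par[5], R9);
  const int m = 2 * nseg;
  std::vector<double> wx(m), wy(m), wz(m);
  const double r = diameter / 2.0, hz = spacing / 2.0;
  for (int j = 0; j < m; ++j) {
    int k = j % nseg;
    double ang = 2.0 * M_PI * k / nseg + (j >= nseg ? twist_rad : 0.0);
    double tx = r * std::cos(ang), ty = r * std::sin(ang);
    double tz = (j < nseg) ? hz : -hz;
    wx[j] = R9[0] * tx + R9[1] * ty + R9[2] * tz + par[0];
    wy[j] = R9[3] * tx + R9[4] * ty + R9[5] * tz + par[1];
    wz[j] = R9[6] * tx + R9[7] * ty + R9[8] * tz + par[2];
  }
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double log_norm = -1.5 * std::log(2.0 * M_PI * sigma * sigma);
  const double lb = std::log(outlier_weight) + log_unif;
  const double log_w = std::log(1.0 - outlier_weight);
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    double dmin2 = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = px - wx[j], dy = py - wy[j], dz = pz - wz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < dmin2) dmin2 = d2;
    }
    double la = log_w + log_norm - dmin2 * inv2s2;
    double hi = la > lb ? la : lb;
    double lo = la > lb ? lb : la;
    nll -= hi + std::log1p(std::exp(lo - hi));
  }
  return nll;
}
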