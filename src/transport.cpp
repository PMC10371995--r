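#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Voxelized Monte Carlo photon transport with weighted absorption,
// Henyey-Greenstein scattering, step-splitting at voxel boundaries
// (a sampled optical depth is consumed across voxels of differing
// attenuation) and Russian-roulette termination. Uses R's RNG so that
// set.seed() gives bit-identical runs. Units: mm.
//
// labels: material index per voxel (0 = inert/outside -> photon escapes);
// mu_abs/mu_ext/g are indexed by material (entry 0 unused). The stepping
// attenuation mu_ext is supplied by the caller (absorption + reduced
// scattering by default, or the full-scattering convention).

static inline double hg_cos(double g) {
  double u = unif_rand();
  if (g < 1e-6) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

static inline void spin(double &ux, double &uy, double &uz, double g) {
  double ct = hg_cos(g);
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double psi = 2.0 * M_PI * unif_rand();
  double cp = std::cos(psi), sp = std::sin(psi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

// [[Rcpp::export]]
List mc_transport(IntegerVector labels, int nx, int ny, int nz, double pitch,
                  double xmin, double ymin,
                  NumericVector mu_abs, NumericVector mu_ext, NumericVector g,
                  int profile, double rl, double x0, double y0,
                  int nphotons, double w_threshold, double roulette_m,
                  bool record_cyl, double dr, int nr) {
  RNGScope scope;
  NumericVector absorbed(nx * ny * nz);
  NumericMatrix phi_rz(record_cyl ? nr : 1, record_cyl ? nz : 1);
  double escaped = 0.0, total_absorbed = 0.0;
  const double eps = 1e-7 * pitch;
  const double xmax = xmin + nx * pitch, ymax = ymin + ny * pitch,
               zmax = nz * pitch;
  const long max_segments = 2000000L;

  for (int ph = 0; ph < nphotons; ++ph) {
    // launch: radial position from the beam profile, direction +z
    double u = unif_rand();
    double rad = (profile == 0) ? rl * std::sqrt(-std::log(u) / 2.0)
                                : rl * std::sqrt(u);
    double phi = 2.0 * M_PI * unif_rand();
    double x = x0 + rad * std::cos(phi), y = y0 + rad * std::sin(phi),
           z = eps;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double W = 1.0;
    double tau = -std::log(unif_rand());
    bool alive = true;
    long seg = 0;
    while (alive) {
      if (++seg > max_segments) { escaped += W; break; }
      if (x <= xmin || x >= xmax || y <= ymin || y >= ymax ||
          z <= 0.0 || z >= zmax) { escaped += W; break; }
      int ix = (int)((x - xmin) / pitch), iy = (int)((y - ymin) / pitch),
          iz = (int)(z / pitch);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
        escaped += W; break;
      }
      int idx = ix + nx * (iy + ny * iz);
      int lab = labels[idx];
      if (lab == 0) { escaped += W; break; }
      double mue = mu_ext[lab];
      // distance to the voxel boundary along the current direction
      double sb = 1e30;
      if (ux > 1e-12) sb = std::min(sb, (xmin + (ix + 1) * pitch - x) / ux);
      else if (ux < -1e-12) sb = std::min(sb, (xmin + ix * pitch - x) / ux);
      if (uy > 1e-12) sb = std::min(sb, (ymin + (iy + 1) * pitch - y) / uy);
      else if (uy < -1e-12) sb = std::min(sb, (ymin + iy * pitch - y) / uy);
      if (uz > 1e-12) sb = std::min(sb, ((iz + 1) * pitch - z) / uz);
      else if (uz < -1e-12) sb = std::min(sb, (iz * pitch - z) / uz);
      if (sb < 0) sb = 0;
      if (mue <= 0.0) {           // transparent voxel: ballistic traversal
        x += (sb + eps) * ux; y += (sb + eps) * uy; z += (sb + eps) * uz;
        continue;
      }
      double s_need = tau / mue;
      if (s_need < sb) {          // interaction inside this voxel
        x += s_need * ux; y += s_need * uy; z += s_need * uz;
        double dW = W * mu_abs[lab] / mue;
        absorbed[idx] += dW;
        total_absorbed += dW;
        if (record_cyl) {
          double rr = std::sqrt((x - x0) * (x - x0) + (y - y0) * (y - y0));
          int ir = (int)(rr / dr);
          if (ir < nr && iz < nz) phi_rz(ir, iz) += dW;
        }
        W -= dW;
        spin(ux, uy, uz, g[lab]);
        if (W < w_threshold) {    // Russian roulette
          if (unif_rand() < 1.0 / roulette_m) W *= roulette_m;
          else { alive = false; break; }
        }
        tau = -std::log(unif_rand());
      } else {                    // cross into the next voxel
        x += (sb + eps) * ux; y += (sb + eps) * uy; z += (sb + eps) * uz;
        tau -= sb * mue;
        if (tau < 0) tau = 0;
      }
    }
    if (ph % 8192 == 8191) Rcpp::checkUserInterrupt();
  }
  return List::create(_["absorbed"] = absorbed, _["escaped"] = escaped,
                      _["total_absorbed"] = total_absorbed,
                      _["phi_rz"] = phi_rz);
}
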