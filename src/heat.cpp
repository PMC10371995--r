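#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Explicit finite-difference heat diffusion on the voxel grid with
// harmonic-mean interface conductivities: the flux between voxels of
// conductivity ka, kb uses G = 2 ka kb / (ka + kb), which reduces to k for
// equal materials and to 0 against an inert (k = 0) voxel, making the
// embedded-cylinder boundary adiabatic automatically. Face conductances
// are precomputed once (properties are temperature-independent), so the
// time loop is pure stencil arithmetic; interior voxels take a
// branch-free fast path.
//
// Units: mm, s, W, degrees C. kmat in W/(mm K); rhoc in J/(mm^3 K);
// q in W/mm^3. Domain-face boundary conditions: 0 = adiabatic,
// 1 = fixed temperature (ghost cell of the same material one pitch away).
// Face order: x-, x+, y-, y+, z-, z+.

// [[Rcpp::export]]
List heat_run(IntegerVector labels, int nx, int ny, int nz, double dx,
              NumericVector kmat, NumericVector rhoc, NumericVector q,
              NumericVector T0, double dt, int nsteps,
              IntegerVector bc_type, NumericVector bc_value,
              int record_every, IntegerVector record_idx) {
  const size_t ntot = (size_t)nx * ny * nz;
  const size_t sxy = (size_t)nx * ny;
  std::vector<double> T(T0.begin(), T0.end()), Tn(ntot);
  std::vector<double> kv(ntot), aq(ntot), a(ntot);
  const double invdx2 = 1.0 / (dx * dx);
  for (size_t i = 0; i < ntot; ++i) {
    kv[i] = kmat[labels[i]];
    a[i] = dt / rhoc[labels[i]];
    aq[i] = a[i] * q[i];
  }
  // face conductances (harmonic means, invdx2 folded in):
  // Gx[idx] couples idx and idx+1 (0 on the last x-face), similarly y, z
  std::vector<double> Gx(ntot, 0.0), Gy(ntot, 0.0), Gz(ntot, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = i + (size_t)nx * j + sxy * k;
        double kc = kv[idx];
        if (i < nx - 1) {
          double kn = kv[idx + 1];
          Gx[idx] = (kc + kn > 0) ? 2.0 * kc * kn / (kc + kn) * invdx2 : 0.0;
        }
        if (j < ny - 1) {
          double kn = kv[idx + nx];
          Gy[idx] = (kc + kn > 0) ? 2.0 * kc * kn / (kc + kn) * invdx2 : 0.0;
        }
        if (k < nz - 1) {
          double kn = kv[idx + sxy];
          Gz[idx] = (kc + kn > 0) ? 2.0 * kc * kn / (kc + kn) * invdx2 : 0.0;
        }
      }
  // fixed-temperature faces: ghost cell of the local material
  const int bt[6] = {bc_type[0], bc_type[1], bc_type[2],
                     bc_type[3], bc_type[4], bc_type[5]};
  const double bv[6] = {bc_value[0], bc_value[1], bc_value[2],
                        bc_value[3], bc_value[4], bc_value[5]};

  // boundary voxel index list (any voxel touching a domain face)
  std::vector<size_t> bidx;
  std::vector<int> bi, bj, bk;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (i == 0 || i == nx - 1 || j == 0 || j == ny - 1 ||
            k == 0 || k == nz - 1) {
          bidx.push_back(i + (size_t)nx * j + sxy * k);
          bi.push_back(i); bj.push_back(j); bk.push_back(k);
        }

  const int nrec = record_idx.size();
  int nsnap = (record_every > 0) ? nsteps / record_every : 0;
  NumericMatrix snaps(nrec > 0 ? nrec : 1, nsnap > 0 ? nsnap : 1);
  NumericVector snap_times(nsnap > 0 ? nsnap : 1);
  int isnap = 0;

  for (int step = 0; step < nsteps; ++step) {
    const double *Tp = T.data();
    double *Tnp = Tn.data();
    // interior voxels: all six neighbors exist
    for (int k = 1; k < nz - 1; ++k) {
      for (int j = 1; j < ny - 1; ++j) {
        size_t idx = 1 + (size_t)nx * j + sxy * k;
        for (int i = 1; i < nx - 1; ++i, ++idx) {
          double Tc = Tp[idx];
          double flux =
            Gx[idx - 1] * (Tp[idx - 1] - Tc) + Gx[idx] * (Tp[idx + 1] - Tc) +
            Gy[idx - nx] * (Tp[idx - nx] - Tc) + Gy[idx] * (Tp[idx + nx] - Tc) +
            Gz[idx - sxy] * (Tp[idx - sxy] - Tc) + Gz[idx] * (Tp[idx + sxy] - Tc);
          Tnp[idx] = Tc + aq[idx] + a[idx] * flux;
        }
      }
    }
    // boundary voxels (precomputed index list)
    for (size_t b = 0; b < bidx.size(); ++b) {
      size_t idx = bidx[b];
      int i = bi[b], j = bj[b], k = bk[b];
      double Tc = Tp[idx], kc = kv[idx];
      double flux = 0.0;
      if (i > 0) flux += Gx[idx - 1] * (Tp[idx - 1] - Tc);
      else if (bt[0] == 1) flux += kc * invdx2 * (bv[0] - Tc);
      if (i < nx - 1) flux += Gx[idx] * (Tp[idx + 1] - Tc);
      else if (bt[1] == 1) flux += kc * invdx2 * (bv[1] - Tc);
      if (j > 0) flux += Gy[idx - nx] * (Tp[idx - nx] - Tc);
      else if (bt[2] == 1) flux += kc * invdx2 * (bv[2] - Tc);
      if (j < ny - 1) flux += Gy[idx] * (Tp[idx + nx] - Tc);
      else if (bt[3] == 1) flux += kc * invdx2 * (bv[3] - Tc);
      if (k > 0) flux += Gz[idx - sxy] * (Tp[idx - sxy] - Tc);
      else if (bt[4] == 1) flux += kc * invdx2 * (bv[4] - Tc);
      if (k < nz - 1) flux += Gz[idx] * (Tp[idx + sxy] - Tc);
      else if (bt[5] == 1) flux += kc * invdx2 * (bv[5] - Tc);
      Tnp[idx] = Tc + aq[idx] + a[idx] * flux;
    }
    T.swap(Tn);
    if (record_every > 0 && (step + 1) % record_every == 0 && isnap < nsnap) {
      if (!std::isfinite(T[ntot / 2]))
        stop("heat solver diverged (non-finite temperature) at step %d",
             step + 1);
      for (int rIdx = 0; rIdx < nrec; ++rIdx)
        snaps(rIdx, isnap) = T[record_idx[rIdx]];
      snap_times[isnap] = (step + 1) * dt;
      ++isnap;
    }
    if (step % 500 == 499) Rcpp::checkUserInterrupt();
  }
  for (size_t i = 0; i < ntot; ++i)
    if (!std::isfinite(T[i]))
      stop("heat solver diverged (non-finite temperature) at the final step");
  NumericVector Tout(T.begin(), T.end());
  return List::create(_["T"] = Tout, _["snapshots"] = snaps,
                      _["times"] = snap_times, _["nsnap"] = isnap);
}
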