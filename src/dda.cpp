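#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

// Coupled-dipole interaction kernels. The dipoles sit on a cubic lattice,
// so every pairwise tensor depends only on the integer displacement; all
// blocks are precomputed into a displacement-indexed table (6 unique
// components of the symmetric 3x3 block), which removes per-pair special
// functions from the matvec entirely.
//
// kernel 0 ("free"): the point-dipole tensor
//   A_ij v = Cv v + Cr rhat (rhat . v),
//   Cv = e^{ikR}/R^3 (1 - ikR - k^2R^2),
//   Cr = e^{ikR}/R^3 (k^2R^2 - 3(1 - ikR)).
// kernel 1 ("filtered"): the filtered coupled dipoles (FCD) tensor,
//   A = -(grad grad + k^2 I) g_F(R) with g_F the low-pass filtered scalar
//   Green function (cutoff kF = pi/d), expressed through sine/cosine
//   integrals. Filtering suppresses the spurious staircase surface
//   resonances that break the plain DDA for strongly negative
//   permittivities (metals in the near infrared).

// ---- sine and cosine integrals -------------------------------------------
// Series for small x; complex continued fraction for E1(ix) otherwise.
static void sici(double x, double &si, double &ci) {
  const double EULER = 0.57721566490153286;
  if (x <= 4.0) {
    double sum_s = 0.0, sum_c = 0.0, term = x, x2 = x * x;
    // Si series
    for (int n = 0; n < 60; ++n) {
      double add = term / (2 * n + 1);
      sum_s += add;
      term *= -x2 / ((2 * n + 2) * (2 * n + 3));
      if (std::fabs(add) < 1e-17 * std::fabs(sum_s)) break;
    }
    // Ci series
    term = -x2 / 2.0;
    for (int n = 1; n < 60; ++n) {
      double add = term / (2 * n);
      sum_c += add;
      term *= -x2 / ((2 * n + 1) * (2 * n + 2));
      if (std::fabs(add) < 1e-17) break;
    }
    si = sum_s;
    ci = EULER + std::log(x) + sum_c;
  } else {
    // modified Lentz continued fraction for E1(ix)
    cplx z(0.0, x);
    cplx b = z + 1.0, c = 1e300, d = 1.0 / b, h = d;
    for (int i = 1; i <= 200; ++i) {
      double an = -(double)i * (double)i;
      b += 2.0;
      d = 1.0 / (an * d + b);
      c = b + an / c;
      cplx del = c * d;
      h *= del;
      if (std::abs(del - 1.0) < 1e-15) break;
    }
    cplx e1 = h * std::exp(-z);
    ci = -e1.real();
    si = M_PI / 2.0 + e1.imag();
  }
}

// ---- kernel coefficients --------------------------------------------------
static void coeffs_free(double R, double k, cplx &Cv, cplx &Cr) {
  double kr = k * R;
  cplx eikr(std::cos(kr), std::sin(kr));
  cplx one_m_ikr(1.0, -kr);
  cplx pref = eikr / (R * R * R);
  Cv = pref * (one_m_ikr - cplx(kr * kr, 0.0));
  Cr = pref * (cplx(kr * kr, 0.0) - 3.0 * one_m_ikr);
}

static void coeffs_fcd(double R, double k, double kF, cplx &Cv, cplx &Cr) {
  double a = kF - k, b = kF + k;
  double Sa, Ca, Sb, Cb;
  sici(a * R, Sa, Ca);
  sici(b * R, Sb, Cb);
  double ckr = std::cos(k * R), skr = std::sin(k * R);
  double hc = (Sa + Sb) / M_PI;
  double hs = (Ca - Cb) / M_PI;
  double hc1 = (std::sin(a * R) + std::sin(b * R)) / (M_PI * R);
  double hs1 = (std::cos(a * R) - std::cos(b * R)) / (M_PI * R);
  double hc2 = (a * std::cos(a * R) + b * std::cos(b * R)) / (M_PI * R) - hc1 / R;
  double hs2 = (-a * std::sin(a * R) + b * std::sin(b * R)) / (M_PI * R) - hs1 / R;
  cplx i1(0.0, 1.0);
  cplx u = hc * ckr + (hs + i1) * skr;
  cplx A = hc1 + k * hs + i1 * k;
  cplx B = hs1 - k * hc;
  cplx u1 = ckr * A + skr * B;
  cplx A1 = hc2 + k * hs1;
  cplx B1 = hs2 - k * hc1;
  cplx u2 = -k * skr * A + ckr * A1 + k * ckr * B + skr * B1;
  cplx f = u / R;
  cplx f1 = u1 / R - u / (R * R);
  cplx f2 = u2 / R - 2.0 * u1 / (R * R) + 2.0 * u / (R * R * R);
  Cv = -(k * k * f + f1 / R);
  Cr = -(f2 - f1 / R);
}

// ---- displacement table ---------------------------------------------------
// Table layout: for displacement (di,dj,dk), di in [-(Lx-1), Lx-1] etc.,
// index t = (di+Lx-1) + (2Lx-1) * ((dj+Ly-1) + (2Ly-1) * (dk+Lz-1));
// 6 components per entry: Mxx, Mxy, Mxz, Myy, Myz, Mzz.
// [[Rcpp::export]]
ComplexVector dda_build_table(int Lx, int Ly, int Lz, double d, double k,
                              int kernel) {
  const int Dx = 2 * Lx - 1, Dy = 2 * Ly - 1, Dz = 2 * Lz - 1;
  const double kF = M_PI / d;
  ComplexVector tab(6 * (size_t)Dx * Dy * Dz);
  for (int dk_ = -(Lz - 1); dk_ <= Lz - 1; ++dk_) {
    for (int dj = -(Ly - 1); dj <= Ly - 1; ++dj) {
      for (int di = -(Lx - 1); di <= Lx - 1; ++di) {
        size_t t = (size_t)(di + Lx - 1) +
          (size_t)Dx * ((dj + Ly - 1) + (size_t)Dy * (dk_ + Lz - 1));
        cplx M[6] = {0, 0, 0, 0, 0, 0};
        if (di != 0 || dj != 0 || dk_ != 0) {
          double dx = di * d, dy = dj * d, dz = dk_ * d;
          double R = std::sqrt(dx * dx + dy * dy + dz * dz);
          double ux = dx / R, uy = dy / R, uz = dz / R;
          cplx Cv, Cr;
          if (kernel == 1) coeffs_fcd(R, k, kF, Cv, Cr);
          else coeffs_free(R, k, Cv, Cr);
          M[0] = Cv + Cr * ux * ux;
          M[1] = Cr * ux * uy;
          M[2] = Cr * ux * uz;
          M[3] = Cv + Cr * uy * uy;
          M[4] = Cr * uy * uz;
          M[5] = Cv + Cr * uz * uz;
        }
        for (int c = 0; c < 6; ++c) {
          tab[6 * t + c].r = M[c].real();
          tab[6 * t + c].i = M[c].imag();
        }
      }
    }
  }
  return tab;
}

// ---- matvec y = A x via the table ----------------------------------------
struct Table {
  std::vector<cplx> m;
  int Lx, Ly, Lz, Dx, Dy;
  inline const cplx *at(int di, int dj, int dk_) const {
    size_t t = (size_t)(di + Lx - 1) +
      (size_t)Dx * ((dj + Ly - 1) + (size_t)Dy * (dk_ + Lz - 1));
    return &m[6 * t];
  }
};

static void matvec_table(const std::vector<int> &cx,
                         const std::vector<int> &cy,
                         const std::vector<int> &cz,
                         const Table &tab, const std::vector<cplx> &x,
                         std::vector<cplx> &y) {
  const int N = (int)cx.size();
  std::fill(y.begin(), y.end(), cplx(0, 0));
  for (int i = 0; i < N; ++i) {
    const cplx xi0 = x[3 * i], xi1 = x[3 * i + 1], xi2 = x[3 * i + 2];
    cplx yi0(0, 0), yi1(0, 0), yi2(0, 0);
    for (int j = i + 1; j < N; ++j) {
      const cplx *M = tab.at(cx[i] - cx[j], cy[i] - cy[j], cz[i] - cz[j]);
      const cplx xj0 = x[3 * j], xj1 = x[3 * j + 1], xj2 = x[3 * j + 2];
      yi0 += M[0] * xj0 + M[1] * xj1 + M[2] * xj2;
      yi1 += M[1] * xj0 + M[3] * xj1 + M[4] * xj2;
      yi2 += M[2] * xj0 + M[4] * xj1 + M[5] * xj2;
      y[3 * j]     += M[0] * xi0 + M[1] * xi1 + M[2] * xi2;
      y[3 * j + 1] += M[1] * xi0 + M[3] * xi1 + M[4] * xi2;
      y[3 * j + 2] += M[2] * xi0 + M[4] * xi1 + M[5] * xi2;
    }
    y[3 * i] += yi0;
    y[3 * i + 1] += yi1;
    y[3 * i + 2] += yi2;
  }
}

static inline cplx cdot(const std::vector<cplx> &a, const std::vector<cplx> &b) {
  cplx s(0, 0);
  for (size_t i = 0; i < a.size(); ++i) s += std::conj(a[i]) * b[i];
  return s;
}
static inline cplx udot(const std::vector<cplx> &a, const std::vector<cplx> &b) {
  cplx s(0, 0);                               // unconjugated bilinear form
  for (size_t i = 0; i < a.size(); ++i) s += a[i] * b[i];
  return s;
}
static inline double cnorm(const std::vector<cplx> &a) {
  double s = 0;
  for (size_t i = 0; i < a.size(); ++i) s += std::norm(a[i]);
  return std::sqrt(s);
}

struct Problem {
  std::vector<int> cx, cy, cz;
  std::vector<cplx> al3;       // per-component alpha (3N)
  Table tab;
  int n;
  void applyB(const std::vector<cplx> &in, std::vector<cplx> &out) const {
    matvec_table(cx, cy, cz, tab, in, out);
    for (int i = 0; i < n; ++i) out[i] = in[i] + al3[i] * out[i];
  }
  double true_residual(const std::vector<cplx> &x,
                       const std::vector<cplx> &E,
                       std::vector<cplx> &scratch) const {
    matvec_table(cx, cy, cz, tab, x, scratch);
    double rr = 0;
    for (int i = 0; i < n; ++i) {
      cplx res = x[i] / al3[i] + scratch[i] - E[i];
      rr += std::norm(res);
    }
    double en = 0;
    for (int i = 0; i < n; ++i) en += std::norm(E[i]);
    return std::sqrt(rr / en);
  }
};

static Problem make_problem(IntegerMatrix coords, int Lx, int Ly, int Lz,
                            ComplexVector table, ComplexVector alpha) {
  Problem P;
  const int N = coords.nrow();
  P.n = 3 * N;
  P.cx.resize(N); P.cy.resize(N); P.cz.resize(N);
  for (int i = 0; i < N; ++i) {
    P.cx[i] = coords(i, 0); P.cy[i] = coords(i, 1); P.cz[i] = coords(i, 2);
  }
  P.al3.resize(3 * N);
  for (int i = 0; i < N; ++i) {
    cplx a(alpha[i].r, alpha[i].i);
    P.al3[3 * i] = P.al3[3 * i + 1] = P.al3[3 * i + 2] = a;
  }
  P.tab.Lx = Lx; P.tab.Ly = Ly; P.tab.Lz = Lz;
  P.tab.Dx = 2 * Lx - 1; P.tab.Dy = 2 * Ly - 1;
  P.tab.m.resize(table.size() / 6 * 6);
  for (R_xlen_t i = 0; i < table.size(); ++i)
    P.tab.m[i] = cplx(table[i].r, table[i].i);
  return P;
}

static List pack_solution(const std::vector<cplx> &x, double true_rel,
                          int it, double tol) {
  ComplexVector P(x.size());
  for (size_t i = 0; i < x.size(); ++i) {
    P[i].r = x[i].real(); P[i].i = x[i].imag();
  }
  return List::create(_["P"] = P, _["residual"] = true_rel,
                      _["iterations"] = it,
                      _["converged"] = (true_rel <= tol));
}

// Raw interaction matvec y = A x (zero diagonal blocks), for neighbor-sum
// construction and kernel-level tests.
// [[Rcpp::export]]
ComplexVector dda_apply(IntegerMatrix coords, int Lx, int Ly, int Lz,
                        ComplexVector table, ComplexVector x) {
  Problem Pr = make_problem(coords, Lx, Ly, Lz, table,
                            ComplexVector(coords.nrow()));
  const int n = Pr.n;
  std::vector<cplx> xin(n), y(n);
  for (int i = 0; i < n; ++i) xin[i] = cplx(x[i].r, x[i].i);
  matvec_table(Pr.cx, Pr.cy, Pr.cz, Pr.tab, xin, y);
  ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i].r = y[i].real(); out[i].i = y[i].imag();
  }
  return out;
}

// BiCGSTAB for block-diagonal inverse polarizabilities (3x3 per dipole),
// solving (D + A) P = E with block-Jacobi preconditioning. D and Dinv are
// passed as length-9N vectors (row-major 3x3 blocks per dipole).
// [[Rcpp::export]]
List dda_bicgstab_block(IntegerMatrix coords, int Lx, int Ly, int Lz,
                        ComplexVector table, ComplexVector D,
                        ComplexVector Dinv, ComplexVector Einc,
                        double tol, int maxit) {
  Problem Pr = make_problem(coords, Lx, Ly, Lz, table,
                            ComplexVector(coords.nrow()));
  const int N = coords.nrow();
  const int n = 3 * N;
  std::vector<cplx> Dm(9 * N), Di(9 * N);
  for (int i = 0; i < 9 * N; ++i) {
    Dm[i] = cplx(D[i].r, D[i].i);
    Di[i] = cplx(Dinv[i].r, Dinv[i].i);
  }
  auto blockmul = [&](const std::vector<cplx> &B, const std::vector<cplx> &v,
                      std::vector<cplx> &out) {
    for (int i = 0; i < N; ++i) {
      const cplx *b = &B[9 * i];
      const cplx v0 = v[3 * i], v1 = v[3 * i + 1], v2 = v[3 * i + 2];
      out[3 * i] = b[0] * v0 + b[1] * v1 + b[2] * v2;
      out[3 * i + 1] = b[3] * v0 + b[4] * v1 + b[5] * v2;
      out[3 * i + 2] = b[6] * v0 + b[7] * v1 + b[8] * v2;
    }
  };
  std::vector<cplx> E(n), b(n), tmp2(n);
  for (int i = 0; i < n; ++i) E[i] = cplx(Einc[i].r, Einc[i].i);
  blockmul(Di, E, b);                         // rhs = Dinv E
  // applyB: out = in + Dinv (A in)
  std::vector<cplx> Ax(n);
  auto applyB = [&](const std::vector<cplx> &in, std::vector<cplx> &out) {
    matvec_table(Pr.cx, Pr.cy, Pr.cz, Pr.tab, in, Ax);
    blockmul(Di, Ax, out);
    for (int i = 0; i < n; ++i) out[i] += in[i];
  };
  std::vector<cplx> x(b), rres(n), rhat(n), p(n), v(n), s(n), t(n), tmp(n);
  const double bnorm = cnorm(b);
  applyB(x, rres);
  for (int i = 0; i < n; ++i) rres[i] = b[i] - rres[i];
  rhat = rres;
  cplx rho(1, 0), alph(1, 0), omega(1, 0);
  std::fill(p.begin(), p.end(), cplx(0, 0));
  std::fill(v.begin(), v.end(), cplx(0, 0));
  int it = 0;
  double relres = cnorm(rres) / bnorm;
  for (it = 0; it < maxit && relres > tol * 0.1; ++it) {
    cplx rho1 = cdot(rhat, rres);
    if (std::abs(rho1) < 1e-300) break;
    if (it == 0) {
      p = rres;
    } else {
      cplx beta = (rho1 / rho) * (alph / omega);
      for (int i = 0; i < n; ++i)
        p[i] = rres[i] + beta * (p[i] - omega * v[i]);
    }
    rho = rho1;
    applyB(p, v);
    alph = rho / cdot(rhat, v);
    for (int i = 0; i < n; ++i) s[i] = rres[i] - alph * v[i];
    if (cnorm(s) / bnorm < tol * 0.1) {
      for (int i = 0; i < n; ++i) x[i] += alph * p[i];
      applyB(x, tmp);
      for (int i = 0; i < n; ++i) rres[i] = b[i] - tmp[i];
      relres = cnorm(rres) / bnorm;
      break;
    }
    applyB(s, t);
    omega = cdot(t, s) / cdot(t, t);
    for (int i = 0; i < n; ++i) {
      x[i] += alph * p[i] + omega * s[i];
      rres[i] = s[i] - omega * t[i];
    }
    relres = cnorm(rres) / bnorm;
    if (std::abs(omega) < 1e-300) break;
    if (it % 50 == 49) Rcpp::checkUserInterrupt();
  }
  // true residual of D P + A P = E
  matvec_table(Pr.cx, Pr.cy, Pr.cz, Pr.tab, x, tmp);
  blockmul(Dm, x, tmp2);
  double rr = 0, en = 0;
  for (int i = 0; i < n; ++i) {
    rr += std::norm(tmp2[i] + tmp[i] - E[i]);
    en += std::norm(E[i]);
  }
  double true_rel = std::sqrt(rr / en);
  return pack_solution(x, true_rel, it, tol);
}

// COCG for the complex-symmetric block system (D + A) P = E with
// block-diagonal D (3x3 symmetric per dipole) and initial guess x0.
// [[Rcpp::export]]
List dda_cocg_block(IntegerMatrix coords, int Lx, int Ly, int Lz,
                    ComplexVector table, ComplexVector D,
                    ComplexVector Einc, ComplexVector x0,
                    double tol, int maxit) {
  Problem Pr = make_problem(coords, Lx, Ly, Lz, table,
                            ComplexVector(coords.nrow()));
  const int N = coords.nrow();
  const int n = 3 * N;
  std::vector<cplx> Dm(9 * N);
  for (int i = 0; i < 9 * N; ++i) Dm[i] = cplx(D[i].r, D[i].i);
  std::vector<cplx> E(n), x(n), Ax(n);
  for (int i = 0; i < n; ++i) {
    E[i] = cplx(Einc[i].r, Einc[i].i);
    x[i] = cplx(x0[i].r, x0[i].i);
  }
  auto applyM = [&](const std::vector<cplx> &in, std::vector<cplx> &out) {
    matvec_table(Pr.cx, Pr.cy, Pr.cz, Pr.tab, in, Ax);
    for (int i = 0; i < N; ++i) {
      const cplx *b = &Dm[9 * i];
      const cplx v0 = in[3 * i], v1 = in[3 * i + 1], v2 = in[3 * i + 2];
      out[3 * i] = b[0] * v0 + b[1] * v1 + b[2] * v2 + Ax[3 * i];
      out[3 * i + 1] = b[3] * v0 + b[4] * v1 + b[5] * v2 + Ax[3 * i + 1];
      out[3 * i + 2] = b[6] * v0 + b[7] * v1 + b[8] * v2 + Ax[3 * i + 2];
    }
  };
  std::vector<cplx> rres(n), p(n), Ap(n);
  const double Enorm = cnorm(E);
  applyM(x, rres);
  for (int i = 0; i < n; ++i) rres[i] = E[i] - rres[i];
  p = rres;
  cplx rr = udot(rres, rres);
  int it = 0;
  double relres = cnorm(rres) / Enorm;
  for (it = 0; it < maxit && relres > tol; ++it) {
    applyM(p, Ap);
    cplx pAp = udot(p, Ap);
    if (std::abs(pAp) < 1e-300) break;
    cplx a = rr / pAp;
    for (int i = 0; i < n; ++i) {
      x[i] += a * p[i];
      rres[i] -= a * Ap[i];
    }
    cplx rr1 = udot(rres, rres);
    cplx beta = rr1 / rr;
    rr = rr1;
    for (int i = 0; i < n; ++i) p[i] = rres[i] + beta * p[i];
    relres = cnorm(rres) / Enorm;
    if (it % 50 == 49) Rcpp::checkUserInterrupt();
  }
  // recompute the true residual
  applyM(x, rres);
  double rsq = 0;
  for (int i = 0; i < n; ++i) rsq += std::norm(rres[i] - E[i]);
  return pack_solution(x, std::sqrt(rsq) / Enorm, it, tol);
}

// COCG for the complex-symmetric scaled system (uniform alpha).
// [[Rcpp::export]]
List dda_cocg(IntegerMatrix coords, int Lx, int Ly, int Lz,
              ComplexVector table, ComplexVector alpha, ComplexVector Einc,
              double tol, int maxit) {
  Problem Pr = make_problem(coords, Lx, Ly, Lz, table, alpha);
  const int n = Pr.n;
  std::vector<cplx> E(n), b(n);
  for (int i = 0; i < n; ++i) E[i] = cplx(Einc[i].r, Einc[i].i);
  for (int i = 0; i < n; ++i) b[i] = Pr.al3[i] * E[i];
  std::vector<cplx> x(b), rres(n), p(n), Ap(n), tmp(n);
  const double bnorm = cnorm(b);
  Pr.applyB(x, rres);
  for (int i = 0; i < n; ++i) rres[i] = b[i] - rres[i];
  p = rres;
  cplx rr = udot(rres, rres);
  int it = 0;
  double relres = cnorm(rres) / bnorm;
  for (it = 0; it < maxit && relres > tol * 0.1; ++it) {
    Pr.applyB(p, Ap);
    cplx pAp = udot(p, Ap);
    if (std::abs(pAp) < 1e-300) break;
    cplx a = rr / pAp;
    for (int i = 0; i < n; ++i) {
      x[i] += a * p[i];
      rres[i] -= a * Ap[i];
    }
    cplx rr1 = udot(rres, rres);
    cplx beta = rr1 / rr;
    rr = rr1;
    for (int i = 0; i < n; ++i) p[i] = rres[i] + beta * p[i];
    relres = cnorm(rres) / bnorm;
    if (it % 50 == 49) Rcpp::checkUserInterrupt();
  }
  double true_rel = Pr.true_residual(x, E, tmp);
  return pack_solution(x, true_rel, it, tol);
}

// BiCGSTAB fallback (non-uniform alpha breaks complex symmetry).
// [[Rcpp::export]]
List dda_bicgstab(IntegerMatrix coords, int Lx, int Ly, int Lz,
                  ComplexVector table, ComplexVector alpha,
                  ComplexVector Einc, double tol, int maxit) {
  Problem Pr = make_problem(coords, Lx, Ly, Lz, table, alpha);
  const int n = Pr.n;
  std::vector<cplx> E(n), b(n);
  for (int i = 0; i < n; ++i) E[i] = cplx(Einc[i].r, Einc[i].i);
  for (int i = 0; i < n; ++i) b[i] = Pr.al3[i] * E[i];
  std::vector<cplx> x(b), rres(n), rhat(n), p(n), v(n), s(n), t(n), tmp(n);
  const double bnorm = cnorm(b);
  Pr.applyB(x, rres);
  for (int i = 0; i < n; ++i) rres[i] = b[i] - rres[i];
  rhat = rres;
  cplx rho(1, 0), alph(1, 0), omega(1, 0);
  std::fill(p.begin(), p.end(), cplx(0, 0));
  std::fill(v.begin(), v.end(), cplx(0, 0));
  int it = 0;
  double relres = cnorm(rres) / bnorm;
  for (it = 0; it < maxit && relres > tol * 0.1; ++it) {
    cplx rho1 = cdot(rhat, rres);
    if (std::abs(rho1) < 1e-300) break;
    if (it == 0) {
      p = rres;
    } else {
      cplx beta = (rho1 / rho) * (alph / omega);
      for (int i = 0; i < n; ++i)
        p[i] = rres[i] + beta * (p[i] - omega * v[i]);
    }
    rho = rho1;
    Pr.applyB(p, v);
    alph = rho / cdot(rhat, v);
    for (int i = 0; i < n; ++i) s[i] = rres[i] - alph * v[i];
    if (cnorm(s) / bnorm < tol * 0.1) {
      for (int i = 0; i < n; ++i) x[i] += alph * p[i];
      Pr.applyB(x, tmp);
      for (int i = 0; i < n; ++i) rres[i] = b[i] - tmp[i];
      relres = cnorm(rres) / bnorm;
      break;
    }
    Pr.applyB(s, t);
    omega = cdot(t, s) / cdot(t, t);
    for (int i = 0; i < n; ++i) {
      x[i] += alph * p[i] + omega * s[i];
      rres[i] = s[i] - omega * t[i];
    }
    relres = cnorm(rres) / bnorm;
    if (std::abs(omega) < 1e-300) break;
    if (it % 50 == 49) Rcpp::checkUserInterrupt();
  }
  double true_rel = Pr.true_residual(x, E, tmp);
  return pack_solution(x, true_rel, it, tol);
}

// Dense 3N x 3N interaction matrix (zero diagonal blocks) from the table;
// the caller fills the diagonal with 1/alpha before a direct solve.
// [[Rcpp::export]]
ComplexMatrix dda_dense_matrix(IntegerMatrix coords, int Lx, int Ly, int Lz,
                               ComplexVector table) {
  Problem Pr = make_problem(coords, Lx, Ly, Lz, table,
                            ComplexVector(coords.nrow()));
  const int N = coords.nrow();
  ComplexMatrix A(3 * N, 3 * N);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < N; ++j) {
      if (i == j) continue;
      const cplx *M = Pr.tab.at(Pr.cx[i] - Pr.cx[j], Pr.cy[i] - Pr.cy[j],
                                Pr.cz[i] - Pr.cz[j]);
      int map[3][3] = {{0, 1, 2}, {1, 3, 4}, {2, 4, 5}};
      for (int a = 0; a < 3; ++a) {
        for (int bcol = 0; bcol < 3; ++bcol) {
          Rcomplex rc;
          rc.r = M[map[a][bcol]].real();
          rc.i = M[map[a][bcol]].imag();
          A(3 * i + a, 3 * j + bcol) = rc;
        }
      }
    }
  }
  return A;
}
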