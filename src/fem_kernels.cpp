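// Element kernels for the membrane finite-element core.
//
// Conventions: X is the current nodal position matrix (V x 3, micrometers);
// tri is 0-based (T x 3). Each element carries a reference local 2D frame in
// which Dinv (inverse reference edge matrix) and the fiber direction are
// expressed; the deformation gradient is the 3x2 map F = sum_a x_a B_a^T
// with B_2 = Dinv row 1, B_3 = Dinv row 2, B_1 = -(B_2+B_3).
// Strain is Green-Lagrange, E = (F^T F - I)/2, Voigt order (E11, E22, 2E12).
// Material: plane-stress Saint Venant-Kirchhoff matrix (lambda, mu are the
// plane-stress Lame coefficients) plus the transversely isotropic
// augmentation W_f = zeta/2 (a^T E a)^2. Stresses are 2nd Piola-Kirchhoff.
// Energies are in MPa*um^3 = pJ-scale units; forces in MPa*um^2.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List fem_membrane(const NumericMatrix& X, const IntegerMatrix& tri,
                  const NumericMatrix& Dinv, const NumericVector& coef,
                  const NumericVector& lam, const NumericVector& mu,
                  const NumericVector& zeta, const NumericMatrix& fib,
                  bool want_hess) {
  const int V = X.nrow(), T = tri.nrow();
  double energy = 0.0;
  NumericVector grad(3 * V);
  IntegerVector hi, hj;
  NumericVector hx;
  if (want_hess) {
    hi = IntegerVector(81 * T);
    hj = IntegerVector(81 * T);
    hx = NumericVector(81 * T);
  }
  int hp = 0;

  for (int e = 0; e < T; ++e) {
    const int n0 = tri(e, 0), n1 = tri(e, 1), n2 = tri(e, 2);
    const double d11 = Dinv(e, 0), d21 = Dinv(e, 1),
                 d12 = Dinv(e, 2), d22 = Dinv(e, 3); // column-major 2x2
    // B_a: 2-vectors
    double B[3][2];
    B[1][0] = d11; B[1][1] = d12;
    B[2][0] = d21; B[2][1] = d22;
    B[0][0] = -(B[1][0] + B[2][0]);
    B[0][1] = -(B[1][1] + B[2][1]);
    const int nd[3] = {n0, n1, n2};
    // F(3x2)
    double F[3][2] = {{0, 0}, {0, 0}, {0, 0}};
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i) {
        F[i][0] += X(nd[a], i) * B[a][0];
        F[i][1] += X(nd[a], i) * B[a][1];
      }
    // C = F^T F
    double C11 = 0, C22 = 0, C12 = 0;
    for (int i = 0; i < 3; ++i) {
      C11 += F[i][0] * F[i][0];
      C22 += F[i][1] * F[i][1];
      C12 += F[i][0] * F[i][1];
    }
    const double E11 = 0.5 * (C11 - 1.0), E22 = 0.5 * (C22 - 1.0),
                 G12 = C12; // gamma = 2 E12
    const double la = lam[e], m2 = mu[e], ze = zeta[e];
    const double a1 = fib(e, 0), a2 = fib(e, 1);
    const double v1 = a1 * a1, v2 = a2 * a2, v3 = a1 * a2;
    const double tr = E11 + E22;
    const double q = v1 * E11 + v2 * E22 + v3 * G12;
    // energy density
    const double W = 0.5 * la * tr * tr +
                     m2 * (E11 * E11 + E22 * E22 + 0.5 * G12 * G12) +
                     0.5 * ze * q * q;
    const double cf = coef[e]; // area0 * thickness
    energy += cf * W;
    // 2nd PK stress in Voigt pairing with (dE11, dE22, dGamma)
    const double S11 = la * tr + 2.0 * m2 * E11 + ze * q * v1;
    const double S22 = la * tr + 2.0 * m2 * E22 + ze * q * v2;
    const double S12 = m2 * G12 + ze * q * v3;
    // G_a[c][i]: d(strain c)/d(x_a[i])
    double Gm[3][3][3];
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i) {
        Gm[a][0][i] = B[a][0] * F[i][0];
        Gm[a][1][i] = B[a][1] * F[i][1];
        Gm[a][2][i] = B[a][0] * F[i][1] + B[a][1] * F[i][0];
      }
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i)
        grad[3 * nd[a] + i] +=
            cf * (S11 * Gm[a][0][i] + S22 * Gm[a][1][i] + S12 * Gm[a][2][i]);
    if (!want_hess) continue;
    // material tangent D_tot = D_mat + zeta v v^T (Voigt, gamma convention)
    double D[3][3] = {{la + 2 * m2, la, 0}, {la, la + 2 * m2, 0}, {0, 0, m2}};
    D[0][0] += ze * v1 * v1; D[0][1] += ze * v1 * v2; D[0][2] += ze * v1 * v3;
    D[1][0] += ze * v2 * v1; D[1][1] += ze * v2 * v2; D[1][2] += ze * v2 * v3;
    D[2][0] += ze * v3 * v1; D[2][1] += ze * v3 * v2; D[2][2] += ze * v3 * v3;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        // geometric part: (B_a^T S B_b) I3
        const double geo = B[a][0] * (S11 * B[b][0] + S12 * B[b][1]) +
                           B[a][1] * (S12 * B[b][0] + S22 * B[b][1]);
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            double kij = (i == j) ? geo : 0.0;
            for (int c = 0; c < 3; ++c)
              for (int d = 0; d < 3; ++d)
                kij += Gm[a][c][i] * D[c][d] * Gm[b][d][j];
            hi[hp] = 3 * nd[a] + i;
            hj[hp] = 3 * nd[b] + j;
            hx[hp] = cf * kij;
            ++hp;
          }
      }
  }
  List out = List::create(_["energy"] = energy, _["grad"] = grad);
  if (want_hess) {
    out["hi"] = hi; out["hj"] = hj; out["hx"] = hx;
  }
  return out;
}

// Per-element 2nd PK stress and deformation gradient (for post-processing).
// Returns T x 7: S11, S22, S12 and F flattened column-wise is too big; we
// return S plus the local deformed metric C for thickness bookkeeping.
// [[Rcpp::export]]
NumericMatrix fem_element_state(const NumericMatrix& X, const IntegerMatrix& tri,
                                const NumericMatrix& Dinv,
                                const NumericVector& lam, const NumericVector& mu,
                                const NumericVector& zeta, const NumericMatrix& fib) {
  const int T = tri.nrow();
  NumericMatrix out(T, 12); // S11 S22 S12 F(3x2 col-major, 6) E11 E22 G12
  for (int e = 0; e < T; ++e) {
    const int nd[3] = {tri(e, 0), tri(e, 1), tri(e, 2)};
    const double d11 = Dinv(e, 0), d21 = Dinv(e, 1),
                 d12 = Dinv(e, 2), d22 = Dinv(e, 3);
    double B[3][2];
    B[1][0] = d11; B[1][1] = d12;
    B[2][0] = d21; B[2][1] = d22;
    B[0][0] = -(B[1][0] + B[2][0]);
    B[0][1] = -(B[1][1] + B[2][1]);
    double F[3][2] = {{0, 0}, {0, 0}, {0, 0}};
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i) {
        F[i][0] += X(nd[a], i) * B[a][0];
        F[i][1] += X(nd[a], i) * B[a][1];
      }
    double C11 = 0, C22 = 0, C12 = 0;
    for (int i = 0; i < 3; ++i) {
      C11 += F[i][0] * F[i][0];
      C22 += F[i][1] * F[i][1];
      C12 += F[i][0] * F[i][1];
    }
    const double E11 = 0.5 * (C11 - 1.0), E22 = 0.5 * (C22 - 1.0), G12 = C12;
    const double la = lam[e], m2 = mu[e], ze = zeta[e];
    const double a1 = fib(e, 0), a2 = fib(e, 1);
    const double q = a1 * a1 * E11 + a2 * a2 * E22 + a1 * a2 * G12;
    const double tr = E11 + E22;
    out(e, 0) = la * tr + 2 * m2 * E11 + ze * q * a1 * a1;
    out(e, 1) = la * tr + 2 * m2 * E22 + ze * q * a2 * a2;
    out(e, 2) = m2 * G12 + ze * q * a1 * a2;
    out(e, 3) = F[0][0]; out(e, 4) = F[1][0]; out(e, 5) = F[2][0];
    out(e, 6) = F[0][1]; out(e, 7) = F[1][1]; out(e, 8) = F[2][1];
    out(e, 9) = E11; out(e, 10) = E22; out(e, 11) = G12;
  }
  return out;
}

// Axial bar (beam) elements: SVK 1D, W = 0.5 EA L0 Egl^2,
// Egl = (L^2 - L0^2)/(2 L0^2).
// [[Rcpp::export]]
List fem_bars(const NumericMatrix& X, const IntegerVector& bv1,
              const IntegerVector& bv2, const NumericVector& L0,
              const NumericVector& EA, bool want_hess) {
  const int V = X.nrow(), NB = bv1.size();
  double energy = 0.0;
  NumericVector grad(3 * V);
  IntegerVector hi, hj;
  NumericVector hx;
  if (want_hess) {
    hi = IntegerVector(36 * NB);
    hj = IntegerVector(36 * NB);
    hx = NumericVector(36 * NB);
  }
  int hp = 0;
  for (int b = 0; b < NB; ++b) {
    const int i = bv1[b], j = bv2[b];
    double d[3];
    double L2 = 0;
    for (int c = 0; c < 3; ++c) {
      d[c] = X(j, c) - X(i, c);
      L2 += d[c] * d[c];
    }
    const double l0 = L0[b], ea = EA[b];
    const double Eg = (L2 - l0 * l0) / (2.0 * l0 * l0);
    energy += 0.5 * ea * l0 * Eg * Eg;
    const double s = ea * Eg / l0; // dW/dx_j = s * d
    for (int c = 0; c < 3; ++c) {
      grad[3 * j + c] += s * d[c];
      grad[3 * i + c] -= s * d[c];
    }
    if (!want_hess) continue;
    // K_jj = s I + (ea/l0^3) d d^T ; K_ij = -K_jj
    for (int c = 0; c < 3; ++c)
      for (int cc = 0; cc < 3; ++cc) {
        double k = (ea / (l0 * l0 * l0)) * d[c] * d[cc];
        if (c == cc) k += s;
        const int dj = 3 * j + c, djj = 3 * j + cc,
                  di = 3 * i + c, dii = 3 * i + cc;
        hi[hp] = dj;  hj[hp] = djj; hx[hp] = k;  ++hp;
        hi[hp] = di;  hj[hp] = dii; hx[hp] = k;  ++hp;
        hi[hp] = dj;  hj[hp] = dii; hx[hp] = -k; ++hp;
        hi[hp] = di;  hj[hp] = djj; hx[hp] = -k; ++hp;
      }
  }
  List out = List::create(_["energy"] = energy, _["grad"] = grad);
  if (want_hess) {
    out["hi"] = hi; out["hj"] = hj; out["hx"] = hx;
  }
  return out;
}

// Follower pressure on an open flat-template surface through the potential
// -sum_e P_e V_e with V_e the z-projected prism volume
// V_e = (z1+z2+z3) A2 / 6, A2 the doubled signed projected area.
// Exact for cells whose boundary is held at z = 0.
// [[Rcpp::export]]
List fem_pressure_zvol(const NumericMatrix& X, const IntegerMatrix& tri,
                       const NumericVector& pel, bool want_hess) {
  const int V = X.nrow(), T = tri.nrow();
  double energy = 0.0, vol = 0.0;
  NumericVector grad(3 * V);
  IntegerVector hi, hj;
  NumericVector hx;
  if (want_hess) {
    hi = IntegerVector(54 * T);
    hj = IntegerVector(54 * T);
    hx = NumericVector(54 * T);
  }
  int hp = 0;
  static const double M[3][3] = {{0, 1, -1}, {-1, 0, 1}, {1, -1, 0}};
  for (int e = 0; e < T; ++e) {
    const double P = pel[e];
    const int nd[3] = {tri(e, 0), tri(e, 1), tri(e, 2)};
    double x[3], y[3], z[3];
    for (int a = 0; a < 3; ++a) {
      x[a] = X(nd[a], 0); y[a] = X(nd[a], 1); z[a] = X(nd[a], 2);
    }
    const double A2 = (x[1] - x[0]) * (y[2] - y[0]) -
                      (x[2] - x[0]) * (y[1] - y[0]);
    const double Z = z[0] + z[1] + z[2];
    vol += Z * A2 / 6.0;
    if (P == 0.0) continue;
    energy -= P * Z * A2 / 6.0;
    const double ax[3] = {y[1] - y[2], y[2] - y[0], y[0] - y[1]};
    const double ay[3] = {x[2] - x[1], x[0] - x[2], x[1] - x[0]};
    for (int a = 0; a < 3; ++a) {
      grad[3 * nd[a] + 0] -= P * Z * ax[a] / 6.0;
      grad[3 * nd[a] + 1] -= P * Z * ay[a] / 6.0;
      grad[3 * nd[a] + 2] -= P * A2 / 6.0;
    }
    if (!want_hess) continue;
    const double c = -P / 6.0;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        // (x_a, y_b) and (y_a, x_b)
        hi[hp] = 3 * nd[a] + 0; hj[hp] = 3 * nd[b] + 1;
        hx[hp] = c * Z * M[a][b]; ++hp;
        hi[hp] = 3 * nd[a] + 1; hj[hp] = 3 * nd[b] + 0;
        hx[hp] = c * Z * M[b][a]; ++hp;
        // (z_a, x_b) and (x_b, z_a)
        hi[hp] = 3 * nd[a] + 2; hj[hp] = 3 * nd[b] + 0;
        hx[hp] = c * ax[b]; ++hp;
        hi[hp] = 3 * nd[b] + 0; hj[hp] = 3 * nd[a] + 2;
        hx[hp] = c * ax[b]; ++hp;
        // (z_a, y_b) and (y_b, z_a)
        hi[hp] = 3 * nd[a] + 2; hj[hp] = 3 * nd[b] + 1;
        hx[hp] = c * ay[b]; ++hp;
        hi[hp] = 3 * nd[b] + 1; hj[hp] = 3 * nd[a] + 2;
        hx[hp] = c * ay[b]; ++hp;
      }
  }
  List out = List::create(_["energy"] = energy, _["grad"] = grad,
                          _["volume"] = vol);
  if (want_hess) {
    if (hp < hi.size()) {
      hi = IntegerVector(hi.begin(), hi.begin() + hp);
      hj = IntegerVector(hj.begin(), hj.begin() + hp);
      hx = NumericVector(hx.begin(), hx.begin() + hp);
    }
    out["hi"] = hi; out["hj"] = hj; out["hx"] = hx;
  }
  return out;
}

// Follower pressure on a closed surface: potential -P V,
// V = sum_e x1 . (x2 x x3) / 6 (outward-oriented triangles).
// [[Rcpp::export]]
List fem_pressure_closed(const NumericMatrix& X, const IntegerMatrix& tri,
                         const NumericVector& pel, bool want_hess) {
  const int V = X.nrow(), T = tri.nrow();
  double energy = 0.0, vol = 0.0;
  NumericVector grad(3 * V);
  IntegerVector hi, hj;
  NumericVector hx;
  if (want_hess) {
    hi = IntegerVector(54 * T);
    hj = IntegerVector(54 * T);
    hx = NumericVector(54 * T);
  }
  int hp = 0;
  for (int e = 0; e < T; ++e) {
    const double P = pel[e];
    const int nd[3] = {tri(e, 0), tri(e, 1), tri(e, 2)};
    double p[3][3];
    for (int a = 0; a < 3; ++a)
      for (int c = 0; c < 3; ++c) p[a][c] = X(nd[a], c);
    double c23[3], c31[3], c12[3];
    c23[0] = p[1][1] * p[2][2] - p[1][2] * p[2][1];
    c23[1] = p[1][2] * p[2][0] - p[1][0] * p[2][2];
    c23[2] = p[1][0] * p[2][1] - p[1][1] * p[2][0];
    c31[0] = p[2][1] * p[0][2] - p[2][2] * p[0][1];
    c31[1] = p[2][2] * p[0][0] - p[2][0] * p[0][2];
    c31[2] = p[2][0] * p[0][1] - p[2][1] * p[0][0];
    c12[0] = p[0][1] * p[1][2] - p[0][2] * p[1][1];
    c12[1] = p[0][2] * p[1][0] - p[0][0] * p[1][2];
    c12[2] = p[0][0] * p[1][1] - p[0][1] * p[1][0];
    const double Ve = (p[0][0] * c23[0] + p[0][1] * c23[1] + p[0][2] * c23[2]) / 6.0;
    vol += Ve;
    if (P == 0.0) continue;
    energy -= P * Ve;
    for (int c = 0; c < 3; ++c) {
      grad[3 * nd[0] + c] -= P * c23[c] / 6.0;
      grad[3 * nd[1] + c] -= P * c31[c] / 6.0;
      grad[3 * nd[2] + c] -= P * c12[c] / 6.0;
    }
    if (!want_hess) continue;
    // d2V/dx_a dx_b = skew matrices: block(a,b) with pair (a,b,other):
    // block(0,1) = -skew(x3)/6 etc. Hessian of (-P V): multiply by -P.
    const double s = -P / 6.0;
    // helper lambda-free: add s * skew(w)*sign into block (a,b)
    const int pairs[6][3] = {{0, 1, 2}, {1, 0, 2}, {1, 2, 0},
                             {2, 1, 0}, {2, 0, 1}, {0, 2, 1}};
    // d(gradV_a)/dx_b: for (a,b) adjacent with third vertex t:
    // gradV_0 = (x1 x x2)/6 -> d/dx1 h = (h x x2)/6 = -skew(x2) h /6 ...
    // We enumerate explicitly:
    // block(0,1): d(c23)/dx1: c23 = x1 x x2 (using 0-based p[1],p[2]) ...
    // Simpler: V = (x0 . (x1 x x2))/6; gradients g0 = (x1 x x2)/6,
    // g1 = (x2 x x0)/6, g2 = (x0 x x1)/6.
    // dg0/dx1 = -skew(x2)/6, dg0/dx2 = skew(x1)/6,
    // dg1/dx2 = -skew(x0)/6, dg1/dx0 = skew(x2)/6,
    // dg2/dx0 = -skew(x1)/6, dg2/dx1 = skew(x0)/6, diagonals zero.
    struct Blk { int a, b, w; double sign; };
    const Blk blks[6] = {{0, 1, 2, -1}, {0, 2, 1, +1}, {1, 2, 0, -1},
                         {1, 0, 2, +1}, {2, 0, 1, -1}, {2, 1, 0, +1}};
    (void)pairs;
    for (int k = 0; k < 6; ++k) {
      const double wx = p[blks[k].w][0], wy = p[blks[k].w][1],
                   wz = p[blks[k].w][2];
      const double sg = blks[k].sign * s * 6.0 / 6.0; // keep explicit
      // skew(w) = [[0,-wz,wy],[wz,0,-wx],[-wy,wx,0]]
      const double S3[3][3] = {{0, -wz, wy}, {wz, 0, -wx}, {-wy, wx, 0}};
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          if (S3[i][j] == 0.0) continue;
          hi[hp] = 3 * nd[blks[k].a] + i;
          hj[hp] = 3 * nd[blks[k].b] + j;
          hx[hp] = sg * S3[i][j];
          ++hp;
        }
    }
  }
  List out = List::create(_["energy"] = energy, _["grad"] = grad,
                          _["volume"] = vol);
  if (want_hess) {
    if (hp < hi.size()) {
      hi = IntegerVector(hi.begin(), hi.begin() + hp);
      hj = IntegerVector(hj.begin(), hj.begin() + hp);
      hx = NumericVector(hx.begin(), hx.begin() + hp);
    }
    out["hi"] = hi; out["hj"] = hj; out["hx"] = hx;
  }
  return out;
}
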