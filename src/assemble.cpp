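// Element assembly kernel for the incremental solver: trial internal force
// and (optionally) the tangent system (frozen material tangent via the
// start-geometry strain operator B0, exact geometry-variation term of the
// stress divergence) on the trial configuration. Mirrors the Mandel
// conventions of the R layer (component order 11,22,33,23,13,12 with
// sqrt(2) shear weights); hex8 with 2x2x2 Gauss quadrature.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static const double SQ2I = 0.7071067811865475244; // 1/sqrt(2)

// local node coordinates of the trilinear hex, matching hex8_local in R
static const double XL[8][3] = {
  {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
  {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1}
};

// dN/dxi at the 8 Gauss points, filled once
static double DN[8][8][3];
static bool dn_ready = false;

static void init_dn() {
  if (dn_ready) return;
  const double g = 1.0 / std::sqrt(3.0);
  // Gauss point ordering must match expand.grid(xi, eta, zeta): xi fastest
  double gp[8][3];
  int q = 0;
  for (int kz = 0; kz < 2; ++kz)
    for (int ky = 0; ky < 2; ++ky)
      for (int kx = 0; kx < 2; ++kx, ++q) {
        gp[q][0] = (kx == 0 ? -g : g);
        gp[q][1] = (ky == 0 ? -g : g);
        gp[q][2] = (kz == 0 ? -g : g);
      }
  for (int k = 0; k < 8; ++k)
    for (int a = 0; a < 8; ++a) {
      const double *s = XL[a];
      const double *x = gp[k];
      DN[k][a][0] = s[0] * (1 + s[1] * x[1]) * (1 + s[2] * x[2]) / 8.0;
      DN[k][a][1] = s[1] * (1 + s[0] * x[0]) * (1 + s[2] * x[2]) / 8.0;
      DN[k][a][2] = s[2] * (1 + s[0] * x[0]) * (1 + s[1] * x[1]) / 8.0;
    }
  dn_ready = true;
}

// J = X^T dN (3x3); returns det, writes gradN = dN J^{-1} (8x3)
static double grad_n(const double X[8][3], const double dn[8][3],
                     double gradN[8][3]) {
  double J[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  for (int a = 0; a < 8; ++a)
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        J[i][j] += X[a][i] * dn[a][j];
  const double det =
      J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
      J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
      J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
  if (det <= 0) return det;
  double Ji[3][3];
  const double id = 1.0 / det;
  Ji[0][0] = (J[1][1] * J[2][2] - J[1][2] * J[2][1]) * id;
  Ji[0][1] = (J[0][2] * J[2][1] - J[0][1] * J[2][2]) * id;
  Ji[0][2] = (J[0][1] * J[1][2] - J[0][2] * J[1][1]) * id;
  Ji[1][0] = (J[1][2] * J[2][0] - J[1][0] * J[2][2]) * id;
  Ji[1][1] = (J[0][0] * J[2][2] - J[0][2] * J[2][0]) * id;
  Ji[1][2] = (J[0][2] * J[1][0] - J[0][0] * J[1][2]) * id;
  Ji[2][0] = (J[1][0] * J[2][1] - J[1][1] * J[2][0]) * id;
  Ji[2][1] = (J[0][1] * J[2][0] - J[0][0] * J[2][1]) * id;
  Ji[2][2] = (J[0][0] * J[1][1] - J[0][1] * J[1][0]) * id;
  for (int a = 0; a < 8; ++a)
    for (int j = 0; j < 3; ++j)
      gradN[a][j] = dn[a][0] * Ji[0][j] + dn[a][1] * Ji[1][j] +
                    dn[a][2] * Ji[2][j];
  return det;
}

// Mandel strain-displacement matrix (6x24) from gradN
static void b_mat(const double gradN[8][3], double B[6][24]) {
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 24; ++c) B[r][c] = 0.0;
  for (int a = 0; a < 8; ++a) {
    const int c0 = 3 * a;
    const double gx = gradN[a][0], gy = gradN[a][1], gz = gradN[a][2];
    B[0][c0 + 0] = gx;
    B[1][c0 + 1] = gy;
    B[2][c0 + 2] = gz;
    B[3][c0 + 1] = SQ2I * gz; B[3][c0 + 2] = SQ2I * gy;
    B[4][c0 + 0] = SQ2I * gz; B[4][c0 + 2] = SQ2I * gx;
    B[5][c0 + 0] = SQ2I * gy; B[5][c0 + 1] = SQ2I * gx;
  }
}

// mean-dilatation adjustment of a set of B matrices (volume weights w)
static void bbar_adj(double B[8][6][24], const double w[8]) {
  double bmean[24];
  double wsum = 0.0;
  for (int c = 0; c < 24; ++c) bmean[c] = 0.0;
  for (int k = 0; k < 8; ++k) {
    wsum += w[k];
    for (int c = 0; c < 24; ++c)
      bmean[c] += (B[k][0][c] + B[k][1][c] + B[k][2][c]) * w[k];
  }
  for (int c = 0; c < 24; ++c) bmean[c] /= wsum;
  for (int k = 0; k < 8; ++k)
    for (int c = 0; c < 24; ++c) {
      const double b = B[k][0][c] + B[k][1][c] + B[k][2][c];
      const double add = (bmean[c] - b) / 3.0;
      B[k][0][c] += add; B[k][1][c] += add; B[k][2][c] += add;
    }
}

// Mandel vector -> symmetric 3x3
static void unvec(const double s[6], double T[3][3]) {
  T[0][0] = s[0]; T[1][1] = s[1]; T[2][2] = s[2];
  T[1][2] = T[2][1] = s[3] * SQ2I;
  T[0][2] = T[2][0] = s[4] * SQ2I;
  T[0][1] = T[1][0] = s[5] * SQ2I;
}

// [[Rcpp::export]]
List cpp_assemble(NumericMatrix nodes0, NumericMatrix x_trial,
                  IntegerMatrix elems, NumericVector tangents,
                  NumericMatrix s0, NumericVector dU,
                  bool bbar, bool want_K) {
  init_dn();
  const int ne = elems.nrow();
  const int nn = x_trial.nrow();
  const int ndof = 3 * nn;
  NumericVector f_int(ndof);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_K) {
    ti.reserve((size_t)ne * 576); tj.reserve((size_t)ne * 576);
    tx.reserve((size_t)ne * 576);
  }
  const double *tg = REAL(tangents);   // 36 x nGP, column-major per GP

  for (int e = 0; e < ne; ++e) {
    double X0[8][3], Xt[8][3];
    int edof[24];
    for (int a = 0; a < 8; ++a) {
      const int n = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) {
        X0[a][i] = nodes0(n, i);
        Xt[a][i] = x_trial(n, i);
      }
      edof[3 * a + 0] = 3 * n + 0;
      edof[3 * a + 1] = 3 * n + 1;
      edof[3 * a + 2] = 3 * n + 2;
    }
    double dUe[24];
    for (int c = 0; c < 24; ++c) dUe[c] = dU[edof[c]];

    double B0[8][6][24], Bt[8][6][24], G[8][8][3];
    double dJ0[8], dJt[8];
    for (int k = 0; k < 8; ++k) {
      double g0[8][3];
      dJ0[k] = grad_n(X0, DN[k], g0);
      if (dJ0[k] <= 0) stop("element %d inverted at Gauss point %d (start geometry)", e + 1, k + 1);
      b_mat(g0, B0[k]);
      dJt[k] = grad_n(Xt, DN[k], G[k]);
      if (dJt[k] <= 0) stop("element %d inverted at Gauss point %d", e + 1, k + 1);
      b_mat(G[k], Bt[k]);
    }
    if (bbar) { bbar_adj(B0, dJ0); bbar_adj(Bt, dJt); }

    double fe[24] = {0};
    double Ke[24][24];
    if (want_K) for (int r = 0; r < 24; ++r) for (int c = 0; c < 24; ++c) Ke[r][c] = 0.0;

    for (int k = 0; k < 8; ++k) {
      const int idx = e * 8 + k;
      const double *C = tg + 36 * idx;   // 6x6 column-major
      // strain increment on the start geometry: vD = B0 dUe
      double vD[6];
      for (int r = 0; r < 6; ++r) {
        double s = 0.0;
        for (int c = 0; c < 24; ++c) s += B0[k][r][c] * dUe[c];
        vD[r] = s;
      }
      // trial stress s_trial = s0 + C vD
      double st[6];
      for (int r = 0; r < 6; ++r) {
        double s = s0(r, idx);
        for (int c = 0; c < 6; ++c) s += C[r + 6 * c] * vD[c];
        st[r] = s;
      }
      // fe += Bt' st * dJt
      for (int c = 0; c < 24; ++c) {
        double s = 0.0;
        for (int r = 0; r < 6; ++r) s += Bt[k][r][c] * st[r];
        fe[c] += s * dJt[k];
      }
      if (want_K) {
        // material part: Bt' C B0 * dJt
        double CB0[6][24];
        for (int r = 0; r < 6; ++r)
          for (int c = 0; c < 24; ++c) {
            double s = 0.0;
            for (int m = 0; m < 6; ++m) s += C[r + 6 * m] * B0[k][m][c];
            CB0[r][c] = s;
          }
        for (int r = 0; r < 24; ++r)
          for (int c = 0; c < 24; ++c) {
            double s = 0.0;
            for (int m = 0; m < 6; ++m) s += Bt[k][m][r] * CB0[m][c];
            Ke[r][c] += s * dJt[k];
          }
        // exact geometry variation: block(a,b)[i,j] =
        //   (p_a)_i (g_b)_j - (g_a)_j (p_b)_i, p = sigma g
        double S[3][3], P[8][3];
        unvec(st, S);
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i)
            P[a][i] = S[i][0] * G[k][a][0] + S[i][1] * G[k][a][1] +
                      S[i][2] * G[k][a][2];
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b)
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j)
                Ke[3 * a + i][3 * b + j] +=
                    (P[a][i] * G[k][b][j] - G[k][a][j] * P[b][i]) * dJt[k];
      }
    }
    for (int c = 0; c < 24; ++c) f_int[edof[c]] += fe[c];
    if (want_K) {
      for (int c = 0; c < 24; ++c)
        for (int r = 0; r < 24; ++r) {
          ti.push_back(edof[r] + 1);
          tj.push_back(edof[c] + 1);
          tx.push_back(Ke[r][c]);
        }
    }
  }
  if (want_K) {
    return List::create(_["f_int"] = f_int,
                        _["i"] = IntegerVector(ti.begin(), ti.end()),
                        _["j"] = IntegerVector(tj.begin(), tj.end()),
                        _["x"] = NumericVector(tx.begin(), tx.end()));
  }
  return List::create(_["f_int"] = f_int);
}
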