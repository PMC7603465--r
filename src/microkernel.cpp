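// Mori-Tanaka rebuild kernel: per-family Eshelby rotation, dilute and
// Mori-Tanaka strain-rate concentrations, spin concentration operators and
// the homogenized tangent with Jaumann spin-convection terms. Pure linear
// algebra on 6x6 Mandel blocks; mirrors the R reference operations
// (rotation_with_axis3, mandel_rotation, dilute_concentration,
// spin_tau_operator, spin_convection_matrix) exactly.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static const double SQ2 = 1.4142135623730950488;
static const double SQ2I = 0.7071067811865475244;

typedef double M6[6][6];

static void matmul6(const M6 A, const M6 B, M6 C) {
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) {
      double s = 0;
      for (int k = 0; k < 6; ++k) s += A[i][k] * B[k][j];
      C[i][j] = s;
    }
}

// Gauss-Jordan inverse with partial pivoting; returns false if singular
static bool inv6(const M6 A, M6 Ai) {
  double W[6][12];
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) {
      W[i][j] = A[i][j];
      W[i][j + 6] = (i == j) ? 1.0 : 0.0;
    }
  for (int c = 0; c < 6; ++c) {
    int p = c;
    for (int r = c + 1; r < 6; ++r)
      if (std::fabs(W[r][c]) > std::fabs(W[p][c])) p = r;
    if (std::fabs(W[p][c]) < 1e-300) return false;
    if (p != c)
      for (int j = 0; j < 12; ++j) std::swap(W[p][j], W[c][j]);
    const double piv = W[c][c];
    for (int j = 0; j < 12; ++j) W[c][j] /= piv;
    for (int r = 0; r < 6; ++r) {
      if (r == c) continue;
      const double f = W[r][c];
      if (f != 0.0)
        for (int j = 0; j < 12; ++j) W[r][j] -= f * W[c][j];
    }
  }
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) Ai[i][j] = W[i][j + 6];
  return true;
}

// rotation with prescribed third axis (same completion as the R helper)
static void rot_axis3(const double a[3], double R[3][3]) {
  double h[3] = {1, 0, 0};
  if (std::fabs(a[0]) >= 0.9) { h[0] = 0; h[1] = 1; }
  const double d = h[0] * a[0] + h[1] * a[1] + h[2] * a[2];
  double e1[3] = {h[0] - d * a[0], h[1] - d * a[1], h[2] - d * a[2]};
  const double n = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  for (int i = 0; i < 3; ++i) e1[i] /= n;
  const double e2[3] = {a[1] * e1[2] - a[2] * e1[1],
                        a[2] * e1[0] - a[0] * e1[2],
                        a[0] * e1[1] - a[1] * e1[0]};
  for (int i = 0; i < 3; ++i) {
    R[i][0] = e1[i];
    R[i][1] = e2[i];   // e2 = a x e1: columns (e1, a x e1, a) have det = +1
    R[i][2] = a[i];
  }
}

// Mandel (orthonormal) representation of the change of basis a' = R a R^T;
// component order (11,22,33,23,13,12), sqrt(2) shear weights.
static void mandel_rot(const double R[3][3], M6 Q) {
  const int pr[3][2] = {{1, 2}, {0, 2}, {0, 1}};
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) Q[i][j] = R[i][j] * R[i][j];
    for (int J = 0; J < 3; ++J)
      Q[i][3 + J] = SQ2 * R[i][pr[J][0]] * R[i][pr[J][1]];
  }
  for (int I = 0; I < 3; ++I) {
    const int p = pr[I][0], q = pr[I][1];
    for (int j = 0; j < 3; ++j) Q[3 + I][j] = SQ2 * R[p][j] * R[q][j];
    for (int J = 0; J < 3; ++J) {
      const int r = pr[J][0], s = pr[J][1];
      Q[3 + I][3 + J] = R[p][r] * R[q][s] + R[p][s] * R[q][r];
    }
  }
}

static void unvec6(const double s[6], double T[3][3]) {
  T[0][0] = s[0]; T[1][1] = s[1]; T[2][2] = s[2];
  T[1][2] = T[2][1] = s[3] * SQ2I;
  T[0][2] = T[2][0] = s[4] * SQ2I;
  T[0][1] = T[1][0] = s[5] * SQ2I;
}

static void vec6(const double T[3][3], double s[6]) {
  s[0] = T[0][0]; s[1] = T[1][1]; s[2] = T[2][2];
  s[3] = SQ2 * T[1][2]; s[4] = SQ2 * T[0][2]; s[5] = SQ2 * T[0][1];
}

// spin-convection 6x6: column J = vec( w_J t - t w_J ), w_J = cross(Rw[,J])
static void conv_mat(const double Rw[3][6], const double t[3][3], M6 L) {
  for (int J = 0; J < 6; ++J) {
    const double w1 = Rw[0][J], w2 = Rw[1][J], w3 = Rw[2][J];
    double W[3][3] = {{0, -w3, w2}, {w3, 0, -w1}, {-w2, w1, 0}};
    double Wt[3][3], tW[3][3], D[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s1 = 0, s2 = 0;
        for (int k = 0; k < 3; ++k) {
          s1 += W[i][k] * t[k][j];
          s2 += t[i][k] * W[k][j];
        }
        Wt[i][j] = s1; tW[i][j] = s2;
      }
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) D[i][j] = Wt[i][j] - tW[i][j];
    double col[6];
    vec6(D, col);
    for (int r = 0; r < 6; ++r) L[r][J] = col[r];
  }
}

// [[Rcpp::export]]
List cpp_rebuild(NumericMatrix Cm, NumericMatrix Cm_inv,
                 NumericMatrix S_local, double mu_m, double f_m,
                 NumericMatrix axes, NumericMatrix Ci_all,
                 NumericVector fvec, NumericMatrix fam_stress,
                 NumericVector matrix_stress) {
  const int nf = axes.ncol();
  M6 CmM, CmI, Sl;
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) {
      CmM[i][j] = Cm(i, j);
      CmI[i][j] = Cm_inv(i, j);
      Sl[i][j] = S_local(i, j);
    }

  std::vector<std::array<std::array<double, 6>, 6> > Adil(nf);
  M6 Abar;
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) Abar[i][j] = (i == j) ? f_m : 0.0;

  std::vector<std::array<double, 36> > CiM(nf);
  for (int q = 0; q < nf; ++q) {
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 6; ++j) CiM[q][i + 6 * j] = Ci_all(i + 6 * j, q);
    double ax[3] = {axes(0, q), axes(1, q), axes(2, q)};
    double R3[3][3];
    rot_axis3(ax, R3);
    M6 Q, Qt, T1, Sg;
    mandel_rot(R3, Q);
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 6; ++j) Qt[i][j] = Q[j][i];
    matmul6(Q, Sl, T1);
    matmul6(T1, Qt, Sg);           // S in the global basis
    // B = I + Sg * Cm_inv * (Ci - Cm)
    M6 dC, T2, T3, Bm, Ainv;
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 6; ++j) dC[i][j] = CiM[q][i + 6 * j] - CmM[i][j];
    matmul6(CmI, dC, T2);
    matmul6(Sg, T2, T3);
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 6; ++j) Bm[i][j] = T3[i][j] + ((i == j) ? 1.0 : 0.0);
    if (!inv6(Bm, Ainv)) stop("singular dilute-concentration bracket");
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 6; ++j) {
        Adil[q][i][j] = Ainv[i][j];
        Abar[i][j] += fvec[q] * Ainv[i][j];
      }
  }
  M6 AbarI;
  if (!inv6(Abar, AbarI)) stop("singular reference strain-rate average");

  NumericMatrix A_out(36, nf), Rw_out(18, nf);
  M6 Chom, Tmp;
  // matrix contribution Cm * AbarI
  matmul6(CmM, AbarI, Tmp);
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) Chom[i][j] = f_m * Tmp[i][j];

  double Rsum[3][6] = {{0}};
  double tmat[3][3];
  unvec6(&matrix_stress[0], tmat);   // matrix_stress passed as Mandel 6-vec
  for (int q = 0; q < nf; ++q) {
    M6 Aq, CA;
    M6 AdilQ;
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 6; ++j) AdilQ[i][j] = Adil[q][i][j];
    matmul6(AdilQ, AbarI, Aq);
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 6; ++j) A_out(i + 6 * j, q) = Aq[i][j];
    // M = (Cm - Ci) * Aq ; spin column J: w = ((tau_J) c) x c / (4 mu)
    M6 dCm, Mq;
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 6; ++j) dCm[i][j] = CmM[i][j] - CiM[q][i + 6 * j];
    matmul6(dCm, Aq, Mq);
    const double c0 = axes(0, q), c1 = axes(1, q), c2 = axes(2, q);
    double Rw[3][6];
    for (int J = 0; J < 6; ++J) {
      double col[6];
      for (int r = 0; r < 6; ++r) col[r] = Mq[r][J];
      double tau[3][3];
      unvec6(col, tau);
      const double w0 = tau[0][0] * c0 + tau[0][1] * c1 + tau[0][2] * c2;
      const double w1 = tau[1][0] * c0 + tau[1][1] * c1 + tau[1][2] * c2;
      const double w2 = tau[2][0] * c0 + tau[2][1] * c1 + tau[2][2] * c2;
      // (tau c) x c / (4 mu)
      Rw[0][J] = (w1 * c2 - w2 * c1) / (4 * mu_m);
      Rw[1][J] = (w2 * c0 - w0 * c2) / (4 * mu_m);
      Rw[2][J] = (w0 * c1 - w1 * c0) / (4 * mu_m);
    }
    for (int i = 0; i < 3; ++i)
      for (int J = 0; J < 6; ++J) {
        Rw_out(i + 3 * J, q) = Rw[i][J];
        Rsum[i][J] += fvec[q] * Rw[i][J];
      }
    // tangent contribution f ( Ci Aq + conv(Rw, t_fam) )
    M6 CiQ;
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 6; ++j) CiQ[i][j] = CiM[q][i + 6 * j];
    matmul6(CiQ, Aq, CA);
    double tq[3][3];
    double sfam[6];
    for (int r = 0; r < 6; ++r) sfam[r] = fam_stress(r, q);
    unvec6(sfam, tq);
    bool has_stress = false;
    for (int r = 0; r < 6; ++r) if (sfam[r] != 0.0) { has_stress = true; break; }
    M6 Lc = {{0}};
    if (has_stress) conv_mat(Rw, tq, Lc);
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 6; ++j)
        Chom[i][j] += fvec[q] * (CA[i][j] + Lc[i][j]);
  }
  // matrix spin balances the fiber spins
  double Rm[3][6];
  for (int i = 0; i < 3; ++i)
    for (int J = 0; J < 6; ++J) Rm[i][J] = -Rsum[i][J] / f_m;
  bool mat_stressed = false;
  for (int r = 0; r < 6; ++r) if (matrix_stress[r] != 0.0) { mat_stressed = true; break; }
  if (mat_stressed) {
    M6 Lm;
    conv_mat(Rm, tmat, Lm);
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 6; ++j) Chom[i][j] += f_m * Lm[i][j];
  }

  NumericMatrix Am(6, 6), Ch(6, 6), Rm_out(3, 6);
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) {
      Am(i, j) = AbarI[i][j];
      Ch(i, j) = Chom[i][j];
    }
  for (int i = 0; i < 3; ++i)
    for (int J = 0; J < 6; ++J) Rm_out(i, J) = Rm[i][J];
  return List::create(_["A"] = A_out, _["Rw"] = Rw_out, _["A_m"] = Am,
                      _["Rw_m"] = Rm_out, _["tangent"] = Ch);
}
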