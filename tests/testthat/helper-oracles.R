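# Test-side oracles, independent of the package implementation paths they
# check.

# Brute-force double contraction (C : D)_ij = C_ijkl D_kl by explicit loops.
contract4_loop <- function(C4, D) {
  out <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    out[i, j] <- out[i, j] + C4[i, j, k, l] * D[k, l]
  }
  out
}

# Brute-force rotation (R o C)_ijkl = R_ip R_jq R_kr R_ls C_pqrs.
rotate4_loop <- function(C4, R) {
  out <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- 0
    for (p in 1:3) for (q in 1:3) for (r in 1:3) for (w in 1:3) {
      s <- s + R[i, p] * R[j, q] * R[k, r] * R[l, w] * C4[p, q, r, w]
    }
    out[i, j, k, l] <- s
  }
  out
}

# Random minor-symmetric fourth-order tensor (as 3x3x3x3 array).
random_minor_symmetric <- function() {
  C4 <- array(stats::rnorm(81), c(3, 3, 3, 3))
  C4 <- (C4 + aperm(C4, c(2, 1, 3, 4))) / 2
  (C4 + aperm(C4, c(1, 2, 4, 3))) / 2
}

random_symmetric2 <- function() {
  a <- matrix(stats::rnorm(9), 3, 3)
  (a + t(a)) / 2
}

# Random proper-orthogonal matrix.
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Rotation by angle about a unit axis (Rodrigues), for exact-rotation
# comparisons.
axis_angle_rotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  W <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * W + (1 - cos(angle)) * (W %*% W)
}

# Flat-measure curvilinear averages of the crimped-beam integrands via
# Bessel functions (small-slope closed forms): <cos a> = J0(k),
# <cos^2 a> = (1 + J0(2k))/2, <g^2> = h^2/2, with k = h/ell.
bessel_chord_modulus <- function(E_f, h, ell, r_c) {
  k <- h / ell
  m_cos <- besselJ(k, 0)
  m_cos2 <- (1 + besselJ(2 * k, 0)) / 2
  m_g2 <- h^2 / 2
  A <- pi * r_c^2
  I <- pi * r_c^4 / 4
  E_f * I * m_cos / (I * m_cos2 + A * m_g2)
}

# Arc length of one sinusoid period by adaptive quadrature (oracle for the
# recruitment stretch).
arc_length_quad <- function(h, ell) {
  ell * stats::integrate(function(u) sqrt(1 + (h / ell)^2 * cos(u)^2),
                         0, 2 * pi, rel.tol = 1e-12)$value
}

# Small tension-inflation configuration for fast finite-element tests.
tiny_config <- function(...) {
  cfg <- generate_fixture("tiny")
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

# Lame thick-walled cylinder (plane strain) radial/hoop stress at radius r
# for inner pressure P, inner/outer radii a, b.
lame_stress <- function(P, a, b, r) {
  A <- P * a^2 / (b^2 - a^2)
  c(radial = A * (1 - b^2 / r^2), hoop = A * (1 + b^2 / r^2))
}
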