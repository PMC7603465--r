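# Fourth-order tensor algebra in Mandel (orthonormal-basis) representation.
#
# All tensors are stored in the global Cartesian basis; local frames are
# explicit rotation operators applied on demand. Second-order symmetric
# tensors map to 6-vectors, minor-symmetric fourth-order tensors to 6x6
# matrices, with sqrt(2) weights on the shear slots so that double
# contractions, products and inversions coincide with plain matrix algebra.
# Component order: (11, 22, 33, 23, 13, 12).

SQRT2 <- sqrt(2)

#' Symmetric 3x3 tensor to Mandel 6-vector
#'
#' @param a symmetric 3x3 matrix.
#' @return numeric length-6 vector `(a11, a22, a33, s2*a23, s2*a13, s2*a12)`
#'   with `s2 = sqrt(2)`.
#' @export
mandel_vec <- function(a) {
  c(a[1, 1], a[2, 2], a[3, 3], SQRT2 * a[2, 3], SQRT2 * a[1, 3], SQRT2 * a[1, 2])
}

#' Mandel 6-vector to symmetric 3x3 tensor
#'
#' @param v numeric length-6 Mandel vector.
#' @return symmetric 3x3 matrix.
#' @export
mandel_unvec <- function(v) {
  s <- v[4:6] / SQRT2
  matrix(c(v[1], s[3], s[2],
           s[3], v[2], s[1],
           s[2], s[1], v[3]), 3, 3)
}

# The six orthonormal symmetric basis tensors B_I (mandel_vec(B_I) = e_I).
mandel_basis <- local({
  B <- vector("list", 6)
  idx <- list(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  for (I in 1:6) {
    b <- matrix(0, 3, 3)
    ij <- idx[[I]]
    if (ij[1] == ij[2]) b[ij[1], ij[2]] <- 1
    else { b[ij[1], ij[2]] <- 1 / SQRT2; b[ij[2], ij[1]] <- 1 / SQRT2 }
    B[[I]] <- b
  }
  B
})

#' Convert a 3x3x3x3 array with both minor symmetries to its 6x6 Mandel matrix
#'
#' Rejects input whose minor symmetries (`t[i,j,k,l] == t[j,i,k,l]` and
#' `t[i,j,k,l] == t[i,j,l,k]`) do not hold, since such a tensor has no
#' faithful 6x6 representation.
#'
#' @param t4 3x3x3x3 numeric array with both minor symmetries.
#' @param tol tolerance for the minor-symmetry check, relative to the largest
#'   entry magnitude.
#' @return 6x6 Mandel matrix.
#' @export
as_mandel <- function(t4, tol = 1e-8) {
  stopifnot(length(dim(t4)) == 4L, all(dim(t4) == 3L))
  scale <- max(abs(t4), 1e-300)
  if (max(abs(t4 - aperm(t4, c(2, 1, 3, 4)))) > tol * scale ||
      max(abs(t4 - aperm(t4, c(1, 2, 4, 3)))) > tol * scale) {
    stop("as_mandel(): input lacks minor symmetry")
  }
  w <- c(1, 1, 1, SQRT2, SQRT2, SQRT2)
  ij <- list(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  M <- matrix(0, 6, 6)
  for (I in 1:6) for (J in 1:6) {
    M[I, J] <- w[I] * w[J] * t4[ij[[I]][1], ij[[I]][2], ij[[J]][1], ij[[J]][2]]
  }
  M
}

#' Convert a 6x6 Mandel matrix back to the full 3x3x3x3 array
#'
#' @param M 6x6 Mandel matrix.
#' @return 3x3x3x3 numeric array with both minor symmetries.
#' @export
as_tensor4 <- function(M) {
  stopifnot(all(dim(M) == c(6, 6)))
  t4 <- array(0, c(3, 3, 3, 3))
  ij <- list(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  w <- c(1, 1, 1, SQRT2, SQRT2, SQRT2)
  for (I in 1:6) for (J in 1:6) {
    v <- M[I, J] / (w[I] * w[J])
    i <- ij[[I]][1]; j <- ij[[I]][2]; k <- ij[[J]][1]; l <- ij[[J]][2]
    t4[i, j, k, l] <- v; t4[j, i, k, l] <- v
    t4[i, j, l, k] <- v; t4[j, i, l, k] <- v
  }
  t4
}

#' Mandel representation of an orthogonal change of basis
#'
#' Builds the 6x6 matrix Q such that, for any symmetric a,
#' `mandel_vec(R a t(R)) = Q %*% mandel_vec(a)`. Q is orthogonal whenever R is.
#'
#' @param R 3x3 proper-orthogonal matrix.
#' @return 6x6 orthogonal matrix.
#' @export
mandel_rotation <- function(R) {
  check_rotation(R)
  Q <- matrix(0, 6, 6)
  for (J in 1:6) Q[, J] <- mandel_vec(R %*% mandel_basis[[J]] %*% t(R))
  Q
}

check_rotation <- function(R, tol = 1e-10) {
  stopifnot(all(dim(R) == c(3, 3)))
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    stop("expected a proper-orthogonal rotation (R'R = I, det R = +1)")
  }
  invisible(R)
}

#' Rotate a minor-symmetric fourth-order tensor
#'
#' Computes `(R o t4)_{ijkl} = R_ip R_jq R_kr R_ls t4_{pqrs}` on the 6x6
#' Mandel representation, where the operation is the congruence
#' `Q M t(Q)` with `Q = mandel_rotation(R)`.
#'
#' @param M 6x6 Mandel matrix (or 3x3x3x3 array, converted on the fly).
#' @param R 3x3 proper-orthogonal matrix.
#' @return rotated tensor, in the same representation as the input.
#' @export
rotate_tensor4 <- function(M, R) {
  if (is.array(M) && length(dim(M)) == 4L) {
    return(as_tensor4(rotate_tensor4(as_mandel(M), R)))
  }
  Q <- mandel_rotation(R)
  Q %*% M %*% t(Q)
}

#' Isotropic stiffness tensor in Mandel form
#'
#' @param E Young's modulus (Pa, or any consistent stress unit).
#' @param nu Poisson ratio, in (-1, 0.5).
#' @return 6x6 Mandel stiffness matrix.
#' @export
isotropic_stiffness <- function(E, nu) {
  stopifnot(E > 0, nu > -1, nu < 0.5)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- lam
  diag(M)[1:3] <- lam + 2 * mu
  diag(M)[4:6] <- 2 * mu
  M
}

#' Isotropic compliance tensor in Mandel form
#'
#' @inheritParams isotropic_stiffness
#' @return 6x6 Mandel compliance matrix (inverse of [isotropic_stiffness()]).
#' @export
isotropic_compliance <- function(E, nu) {
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- -nu / E
  diag(M)[1:3] <- 1 / E
  diag(M)[4:6] <- (1 + nu) / E
  M
}

#' Recover the material stress rate from a Jaumann (corotational) rate
#'
#' The Jaumann rate is `t_jau = t_dot + t.w - w.t` with spin `w`; this returns
#' the material rate `t_dot = t_jau - t.w + w.t`.
#'
#' @param t symmetric 3x3 stress.
#' @param spin antisymmetric 3x3 spin tensor.
#' @param objective_rate symmetric 3x3 Jaumann rate of `t`.
#' @param tol symmetry-check tolerance, relative to entry magnitudes.
#' @return symmetric 3x3 material rate of `t`.
#' @export
jaumann_to_material_rate <- function(t, spin, objective_rate, tol = 1e-8) {
  sc <- max(abs(t), 1e-300)
  if (max(abs(t - t(t))) > tol * sc) stop("stress must be symmetric")
  ssc <- max(abs(spin), 1e-300)
  if (max(abs(spin + t(spin))) > tol * ssc) stop("spin must be antisymmetric")
  objective_rate - t %*% spin + spin %*% t
}

# Small second-order helpers ------------------------------------------------

sym_part <- function(a) (a + t(a)) / 2
skew_part <- function(a) (a - t(a)) / 2

# Axial vector w of an antisymmetric W (W x = w x x), and its inverse.
axial_vector <- function(W) c(W[3, 2], W[1, 3], W[2, 1])

cross_matrix <- function(w) {
  matrix(c(0, w[3], -w[2],
           -w[3], 0, w[1],
           w[2], -w[1], 0), 3, 3)
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps * 100) stop("cannot normalize a (near-)zero vector")
  v / n
}

# Rotation with prescribed third axis; the transverse pair is an arbitrary
# orthonormal completion (used for transversely isotropic quantities, for
# which the completion is immaterial).
rotation_with_axis3 <- function(axis) {
  a <- unit_vector(axis)
  helper <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vector(helper - sum(helper * a) * a)
  e2 <- cross_vec(a, e1)
  cbind(e1, e2, a, deparse.level = 0)
}

cross_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
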