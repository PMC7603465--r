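# Large-strain continuum micromechanics of the adventitial representative
# volume element: Eshelby tensors of the infinite circular cylinder in an
# isotropic matrix, Mori-Tanaka strain-rate and spin concentration tensors,
# phase averages and the homogenized hypoelastic tangent.
#
# All stiffnesses live in the 6x6 Mandel representation (see tensors.R);
# spin operators are 3x6 matrices mapping a Mandel strain-rate vector to the
# axial vector of the phase spin.

#' Isotropic hypoelastic phase
#'
#' @param E Young's modulus (stress units, consistently with the rest of the
#'   model, e.g. MPa).
#' @param nu Poisson ratio in (-1, 0.5).
#' @return object of class `elastic_phase` with the Mandel stiffness attached.
#' @export
elastic_phase <- function(E, nu) {
  stopifnot(E > 0, nu > -1, nu < 0.5)
  structure(list(E = E, nu = nu,
                 mu = E / (2 * (1 + nu)),
                 C = isotropic_stiffness(E, nu)),
            class = "elastic_phase")
}

#' Eshelby tensor of an infinite circular cylinder (closed form)
#'
#' Classical interior Eshelby tensor S of an infinitely long circular
#' cylinder embedded in an isotropic matrix with Poisson ratio `nu_m`,
#' expressed in the global basis for an arbitrary cylinder axis (computed in
#' the fiber frame, then rotated). Components along the axis vanish
#' (`S_aaaa = 0`). S has both minor symmetries but is not majorly symmetric.
#'
#' @param nu_m matrix Poisson ratio, < 0.5 (the incompressible limit is not
#'   supported).
#' @param axis cylinder axis (length-3, normalized internally).
#' @return 6x6 Mandel matrix of S.
#' @export
eshelby_cylinder <- function(nu_m, axis = c(0, 0, 1)) {
  if (nu_m >= 0.5) stop("eshelby_cylinder(): incompressible matrix (nu >= 0.5) not supported")
  S <- eshelby_cylinder_local(nu_m)
  R <- rotation_with_axis3(axis)
  rotate_tensor4(S, R)
}

# Mandel form with the cylinder axis along e3.
eshelby_cylinder_local <- function(nu_m) {
  d <- 8 * (1 - nu_m)
  S1111 <- (5 - 4 * nu_m) / d
  S1122 <- (4 * nu_m - 1) / d
  S1133 <- nu_m / (2 * (1 - nu_m))
  S1212 <- (3 - 4 * nu_m) / d
  S1313 <- 1 / 4
  M <- matrix(0, 6, 6)
  M[1, 1] <- M[2, 2] <- S1111
  M[1, 2] <- M[2, 1] <- S1122
  M[1, 3] <- M[2, 3] <- S1133
  # rows 3 (axis normal strain) are zero: S_33kl = 0
  M[4, 4] <- M[5, 5] <- 2 * S1313
  M[6, 6] <- 2 * S1212
  M
}

#' Interior Hill operators of the infinite cylinder by numerical integration
#'
#' Independent route to the cylinder inclusion problem: integrates the
#' acoustic-tensor (Green operator) expression of the interior displacement
#' gradient over directions normal to the axis, and splits it into the
#' symmetric (Eshelby S) and antisymmetric (rotation) parts. Used as a
#' cross-check of the closed forms and to derive the spin operator.
#'
#' For the infinite cylinder the fields are independent of the axial
#' coordinate, so the direction integral reduces to the unit circle in the
#' transverse plane.
#'
#' @param nu_m matrix Poisson ratio (< 0.5).
#' @param axis cylinder axis.
#' @param n_quad number of quadrature points on the circle (the integrand is
#'   a trigonometric polynomial of degree 4, so moderate n is exact).
#' @return list with `S` (6x6 Mandel Eshelby tensor) and `Pi` (3x6 matrix
#'   mapping the Mandel eigenstrain vector to the axial vector of the
#'   interior rotation).
#' @export
eshelby_cylinder_numeric <- function(nu_m, axis = c(0, 0, 1), n_quad = 64L) {
  if (nu_m >= 0.5) stop("incompressible matrix not supported")
  mu <- 1 / (2 * (1 + nu_m))      # E = 1; S and Pi depend on nu only
  Cm <- isotropic_stiffness(1, nu_m)
  beta <- 1 / (2 * (1 - nu_m))    # (lambda+mu)/(lambda+2mu)
  R <- rotation_with_axis3(axis)
  theta <- (seq_len(n_quad) - 0.5) * 2 * pi / n_quad
  S <- matrix(0, 6, 6)
  Pi <- matrix(0, 3, 6)
  for (J in 1:6) {
    tauJ <- mandel_unvec(Cm %*% mandel_vec(mandel_basis[[J]]))
    G <- matrix(0, 3, 3)   # interior displacement gradient, axis = e3 frame
    for (th in theta) {
      n <- c(cos(th), sin(th), 0)
      Nik <- (diag(3) - beta * tcrossprod(n)) / mu
      # G_ij += N_ik n_j n_l tau_kl / n_quad
      G <- G + (Nik %*% tauJ %*% n) %*% t(n) / n_quad
    }
    S[, J] <- mandel_vec(sym_part(G))
    Pi[, J] <- axial_vector(skew_part(G))
  }
  # rotate to the requested axis: strain in global -> local, apply, -> global
  Q <- mandel_rotation(R)
  list(S = Q %*% S %*% t(Q), Pi = R %*% Pi %*% t(Q))
}

#' Spin operator of a cylindrical inclusion (closed form)
#'
#' 3x6 matrix W mapping the Mandel vector of the polarization eigenstrain to
#' the axial vector of the interior rotation of an infinite circular cylinder
#' with axis `c`: `omega = (1/(4 mu_m)) [ (c o c) tau - tau (c o c) ]` with
#' `tau = C_m : eigenstrain`. Equivalent to the antisymmetric part of the
#' interior Hill operator (see [eshelby_cylinder_numeric()]).
#'
#' @param c_axis unit cylinder axis.
#' @param mu_m matrix shear modulus.
#' @param nu_m matrix Poisson ratio (used to form `C_m`).
#' @return 3x6 matrix.
#' @export
spin_operator_cylinder <- function(c_axis, mu_m, nu_m) {
  a <- unit_vector(c_axis)
  P <- tcrossprod(a)
  Cm <- isotropic_stiffness(2 * mu_m * (1 + nu_m), nu_m)
  W <- matrix(0, 3, 6)
  for (J in 1:6) {
    tau <- mandel_unvec(Cm %*% mandel_vec(mandel_basis[[J]]))
    W[, J] <- axial_vector((P %*% tau - tau %*% P) / (4 * mu_m))
  }
  W
}

#' Dilute strain-rate concentration tensor
#'
#' `A_dil = [I + S : C_m^-1 : (C_i - C_m)]^-1` in Mandel representation.
#'
#' @param S 6x6 Eshelby tensor of the inclusion shape.
#' @param C_m 6x6 matrix stiffness (invertible on the symmetric space).
#' @param C_i 6x6 inclusion stiffness.
#' @return 6x6 dilute concentration tensor.
#' @export
dilute_concentration <- function(S, C_m, C_i) {
  B <- diag(6) + S %*% solve(C_m, C_i - C_m)
  A <- tryCatch(solve(B), error = function(e) {
    stop(sprintf(
      "dilute_concentration(): singular bracket (phase contrast cond = %.3g): %s",
      kappa(B), conditionMessage(e)))
  })
  A
}

#' Representative volume element of the adventitia
#'
#' A matrix phase filled with n discrete families of infinitely long
#' cylindrical fiber inclusions.
#'
#' @param matrix_phase an [elastic_phase()]; its Poisson ratio must be
#'   <= 0.49 to keep the cylinder Eshelby forms well-conditioned.
#' @param inclusions list of inclusions, each a list with fields `phase`
#'   (an [elastic_phase()]), `axis` (unit vector) and `f` (volume fraction).
#' @return object of class `rve_model` with `f_m = 1 - sum(f)` attached.
#' @export
rve_model <- function(matrix_phase, inclusions) {
  stopifnot(inherits(matrix_phase, "elastic_phase"))
  if (matrix_phase$nu > 0.49) stop("rve_model(): matrix Poisson ratio capped at 0.49")
  f_tot <- 0
  for (inc in inclusions) {
    stopifnot(inherits(inc$phase, "elastic_phase"), inc$f >= 0)
    if (abs(sqrt(sum(inc$axis^2)) - 1) > 1e-8) stop("inclusion axis must be a unit vector")
    f_tot <- f_tot + inc$f
  }
  if (f_tot >= 1) stop("rve_model(): inclusion volume fractions must sum below 1")
  structure(list(matrix = matrix_phase, inclusions = inclusions,
                 f_m = 1 - f_tot),
            class = "rve_model")
}

#' Mori-Tanaka strain-rate concentration tensors
#'
#' `A_i^MT = A_i_dil : <A>^-1` with `<A> = f_m I + sum_j f_j A_j_dil`. The
#' matrix tensor is `A_m^MT = <A>^-1`. The volume-weighted sum of all
#' concentration tensors equals the identity by construction.
#'
#' @param rve an [rve_model()].
#' @return list with `matrix` (6x6), `families` (list of 6x6) and `Abar`
#'   (the 6x6 reference average).
#' @export
mt_concentrations <- function(rve) {
  stopifnot(inherits(rve, "rve_model"))
  Cm <- rve$matrix$C
  Abar <- rve$f_m * diag(6)
  A_dil <- vector("list", length(rve$inclusions))
  for (i in seq_along(rve$inclusions)) {
    inc <- rve$inclusions[[i]]
    S <- eshelby_cylinder(rve$matrix$nu, inc$axis)
    A_dil[[i]] <- dilute_concentration(S, Cm, inc$phase$C)
    Abar <- Abar + inc$f * A_dil[[i]]
  }
  Abar_inv <- tryCatch(solve(Abar), error = function(e) {
    stop("mt_concentrations(): singular reference average <A>")
  })
  list(matrix = Abar_inv,
       families = lapply(A_dil, function(A) A %*% Abar_inv),
       Abar = Abar)
}

#' Strain-rate-to-spin concentration tensor of one fiber family
#'
#' Returns the 3x6 matrix R mapping the Mandel vector of the macroscopic
#' strain rate D to the axial vector of the family's average spin. Built
#' from the antisymmetric (rotation) interior operator of the cylinder acting
#' on the family's polarization strain rate:
#' `omega_i = Pi : C_m^-1 : (C_m - C_i) : A_i^MT : D`.
#' The output spin is antisymmetric for any symmetric input by construction,
#' vanishes for a homogeneous medium, and reaches the Jeffery rigid-needle
#' affine limit for infinitely stiff fibers.
#'
#' @param rve an [rve_model()].
#' @param family index of the fiber family.
#' @param concentrations optional precomputed [mt_concentrations()].
#' @return 3x6 spin concentration matrix.
#' @export
spin_concentration <- function(rve, family, concentrations = NULL) {
  stopifnot(inherits(rve, "rve_model"))
  if (is.null(concentrations)) concentrations <- mt_concentrations(rve)
  inc <- rve$inclusions[[family]]
  W <- spin_operator_cylinder(inc$axis, rve$matrix$mu, rve$matrix$nu)
  # polarization tau = (C_m - C_i) : A_i : D; W already includes C_m : eps*,
  # and eps* = C_m^-1 : (C_m - C_i) : d_in, so compose W o C_m^-1 o (C_m-C_i) o A
  Cm <- rve$matrix$C
  W %*% solve(Cm, (Cm - inc$phase$C) %*% concentrations$families[[family]])
}

#' Per-phase average strain rates and spins
#'
#' `d_i = A_i : D` and `omega_i = R_i : D` for every fiber family, plus the
#' matrix strain rate. The volume-weighted average of all phase strain rates
#' equals D (strain-rate average rule); the matrix spin balances the fiber
#' spins so the volume-averaged spin vanishes under pure straining.
#'
#' @param rve an [rve_model()].
#' @param D symmetric 3x3 macroscopic strain rate.
#' @return list with `matrix` (list `d`, `omega`) and `families` (list of
#'   lists `d`, `omega`), 3x3 tensors.
#' @export
phase_fields <- function(rve, D) {
  sc <- max(abs(D), 1e-300)
  if (max(abs(D - t(D))) > 1e-8 * sc) stop("phase_fields(): D must be symmetric")
  conc <- mt_concentrations(rve)
  vD <- mandel_vec(D)
  fam <- vector("list", length(rve$inclusions))
  w_sum <- c(0, 0, 0)
  for (i in seq_along(rve$inclusions)) {
    R_i <- spin_concentration(rve, i, conc)
    w <- as.numeric(R_i %*% vD)
    fam[[i]] <- list(d = mandel_unvec(conc$families[[i]] %*% vD),
                     omega = cross_matrix(w))
    w_sum <- w_sum + rve$inclusions[[i]]$f * w
  }
  list(matrix = list(d = mandel_unvec(conc$matrix %*% vD),
                     omega = cross_matrix(-w_sum / rve$f_m)),
       families = fam)
}

#' Homogenized hypoelastic tangent of the RVE
#'
#' Assembles the macroscopic tangent `C_hom` such that the macroscopic
#' material stress rate is `T_dot = C_hom : D`:
#' `C_hom = sum_r f_r [ C_r : A_r + conv_r ]`, where `conv_r` converts the
#' phase Jaumann rate to a material rate using the phase stress `t_r` and the
#' phase spin `omega_r = R_r : D` (`conv_r : D = omega_r t_r - t_r omega_r`).
#' With all phase stresses zero it reduces to `sum_r f_r C_r : A_r`.
#'
#' @param rve an [rve_model()].
#' @param phase_stresses list with `matrix` (3x3) and `families` (list of
#'   3x3) phase Cauchy stresses; `NULL` means all zero.
#' @param concentrations optional precomputed [mt_concentrations()].
#' @return 6x6 Mandel tangent (minor-symmetric; majorly symmetric at zero
#'   phase stress).
#' @export
homogenized_tangent <- function(rve, phase_stresses = NULL,
                                concentrations = NULL) {
  stopifnot(inherits(rve, "rve_model"))
  nfam <- length(rve$inclusions)
  if (is.null(phase_stresses)) {
    phase_stresses <- list(matrix = matrix(0, 3, 3),
                           families = replicate(nfam, matrix(0, 3, 3),
                                                simplify = FALSE))
  }
  if (is.null(phase_stresses$matrix) ||
      length(phase_stresses$families) != nfam) {
    stop("homogenized_tangent(): a phase stress is missing")
  }
  if (is.null(concentrations)) concentrations <- mt_concentrations(rve)
  Cm <- rve$matrix$C
  C_hom <- rve$f_m * (Cm %*% concentrations$matrix)
  R_sum <- matrix(0, 3, 6)
  for (i in seq_len(nfam)) {
    inc <- rve$inclusions[[i]]
    A_i <- concentrations$families[[i]]
    R_i <- spin_concentration(rve, i, concentrations)
    C_hom <- C_hom + inc$f * (inc$phase$C %*% A_i +
                                spin_convection_matrix(R_i, phase_stresses$families[[i]]))
    R_sum <- R_sum + inc$f * R_i
  }
  R_m <- -R_sum / rve$f_m
  C_hom + rve$f_m * spin_convection_matrix(R_m, phase_stresses$matrix)
}

# 3x6 operator mapping the Mandel vector of the polarization stress tau
# directly to the axial spin vector: omega = (1/(4 mu_m)) (P tau - tau P),
# P = c o c. Same operator as spin_operator_cylinder() without the C_m
# round-trip (spin_operator_cylinder = spin_tau_operator o C_m).
spin_tau_operator <- function(c_axis, mu_m) {
  P <- tcrossprod(c_axis)
  W <- matrix(0, 3, 6)
  for (J in 1:6) {
    B <- mandel_basis[[J]]
    W[, J] <- axial_vector((P %*% B - B %*% P) / (4 * mu_m))
  }
  W
}

# 6x6 matrix L with L : D = omega(D) t - t omega(D), omega = cross_matrix(R D).
spin_convection_matrix <- function(R_op, t_phase) {
  L <- matrix(0, 6, 6)
  if (max(abs(t_phase)) == 0) return(L)
  for (J in 1:6) {
    w <- R_op[, J]
    Wm <- cross_matrix(w)
    L[, J] <- mandel_vec(Wm %*% t_phase - t_phase %*% Wm)
  }
  L
}
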