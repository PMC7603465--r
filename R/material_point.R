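# Material-point state and the staggered constitutive update: macroscopic
# hypoelastic stress update with the frozen tangent, local-frame convection,
# RVE phase fields, fiber-frame evolution, chord-strain-driven de-crimping
# and the rebuild of the homogenized tangent for the next increment.
#
# Quasi-static convention: one unit time step per load increment, so strain
# rates equal increments throughout.

#' Material point of the arterial wall
#'
#' Creates the integration-point state for either layer. Medial points carry
#' a constant isotropic tangent; adventitial points carry the full fiber
#' microstructure (families, crimp states, Mori-Tanaka concentrations) and a
#' homogenized tangent that is rebuilt after every increment.
#'
#' @param layer `"media"` or `"adventitia"`.
#' @param lrs initial [local_frame()] at the point.
#' @param props material properties: for the media a list with `E_M`, `nu_M`
#'   (MPa, -); for the adventitia a list with `E_m`, `nu_m` (matrix), `nu_c`,
#'   `E_f`, `f_c`, `theta0`, `phi0` (rad, one entry per family), `crimp`
#'   (a shared [crimp_table()]) and optionally `micro_substeps`.
#' @return object of class `material_point`.
#' @export
material_point <- function(layer = c("adventitia", "media"), lrs, props) {
  layer <- match.arg(layer)
  stopifnot(inherits(lrs, "local_frame"))
  mp <- list(layer = layer, lrs = lrs,
             stress = matrix(0, 3, 3), F = diag(3))
  if (layer == "media") {
    mp$tangent <- isotropic_stiffness(props$E_M, props$nu_M)
    class(mp) <- "material_point"
    return(mp)
  }
  nfam <- length(props$theta0)
  stopifnot(length(props$phi0) == nfam, nfam >= 1)
  if (props$nu_m > 0.49) stop("matrix Poisson ratio capped at 0.49")
  mp$Cm <- isotropic_stiffness(props$E_m, props$nu_m)
  mp$Cm_inv <- isotropic_compliance(props$E_m, props$nu_m)
  mp$mu_m <- props$E_m / (2 * (1 + props$nu_m))
  mp$nu_m <- props$nu_m
  mp$nu_c <- props$nu_c
  mp$E_f <- props$E_f
  mp$crimp <- props$crimp
  mp$micro_substeps <- props$micro_substeps
  mp$f_m <- 1 - props$f_c
  mp$S_local <- eshelby_cylinder_local(props$nu_m)
  mp$matrix_stress <- matrix(0, 3, 3)
  f_i <- props$f_c / nfam   # equal split across families
  mp$families <- vector("list", nfam)
  E_c0 <- props$crimp$E(0)
  for (i in seq_len(nfam)) {
    fr <- frame_from_angles(props$phi0[i], props$theta0[i], lrs)
    mp$families[[i]] <- list(
      frame = fr, f = f_i, eps = 0, E_chord = E_c0,
      C = isotropic_stiffness(E_c0, props$nu_c),
      stress = matrix(0, 3, 3),
      phi = props$phi0[i], theta = props$theta0[i])
  }
  class(mp) <- "material_point"
  rebuild_microstructure(mp)
}

# Recompute Eshelby/Mori-Tanaka concentrations, spin operators and the
# homogenized tangent from the current fiber axes, chord moduli and phase
# stresses (compiled kernel; see src/microkernel.cpp). Returns the updated
# point.
rebuild_microstructure <- function(mp) {
  nfam <- length(mp$families)
  axes <- vapply(mp$families, function(f) f$frame$c, numeric(3))
  Ci <- vapply(mp$families, function(f) as.numeric(f$C), numeric(36))
  fvec <- vapply(mp$families, function(f) f$f, numeric(1))
  fstress <- vapply(mp$families, function(f) mandel_vec(f$stress), numeric(6))
  out <- cpp_rebuild(mp$Cm, mp$Cm_inv, mp$S_local, mp$mu_m, mp$f_m,
                     axes, Ci, fvec, fstress, mandel_vec(mp$matrix_stress))
  for (i in seq_len(nfam)) {
    mp$families[[i]]$A <- matrix(out$A[, i], 6, 6)
    mp$families[[i]]$Rw <- matrix(out$Rw[, i], 3, 6)
  }
  mp$A_m <- out$A_m
  mp$Rw_m <- out$Rw_m
  mp$tangent <- out$tangent
  if (isTRUE(getOption("arterymech.debug"))) {
    Ssum <- mp$f_m * A_m
    for (i in seq_len(nfam)) Ssum <- Ssum + mp$families[[i]]$f * mp$families[[i]]$A
    if (max(abs(Ssum - diag(6))) > 1e-10) {
      stop("concentration-tensor sum rule violated beyond 1e-10")
    }
  }
  mp
}

#' Staggered constitutive update of a material point
#'
#' Executes, in order: the macroscopic hypoelastic stress update with the
#' frozen tangent; local-frame convection; RVE loading by the incremental
#' velocity gradient; per-family phase strain rates and spins; phase stress
#' updates (Jaumann-convected); fiber-frame evolution and Euler-angle
#' extraction; chord-strain increments and crimp update; and the rebuild of
#' the homogenized tangent for the next increment. Medial points only update
#' stress and deformation gradient (constant isotropic tangent).
#'
#' @param mp a [material_point()].
#' @param dF 3x3 incremental deformation gradient (`det(dF) > 0`).
#' @param ortho_warn per-call fiber-frame orthogonality warning threshold
#'   (the finite-element driver monitors the drift once per run instead).
#' @param micro_substeps number of sub-increments used to integrate the
#'   internal variables (phase stresses, fiber frames, crimp states) along
#'   the strain increment, with the concentration tensors rebuilt between
#'   sub-increments. The macroscopic stress update keeps the frozen tangent
#'   and the whole increment regardless. Defaults to `mp$micro_substeps`
#'   (set from the configuration) or 4.
#' @return the updated `material_point`.
#' @export
update_constitutive <- function(mp, dF, ortho_warn = Inf,
                                micro_substeps = NULL) {
  stopifnot(inherits(mp, "material_point"))
  if (det(dF) <= 0) stop("update_constitutive(): det(dF) must be positive")
  L <- velocity_gradient_increment(dF)
  D <- sym_part(L)
  vD <- mandel_vec(D)
  mp$stress <- mp$stress + mandel_unvec(mp$tangent %*% vD)
  mp$F <- dF %*% mp$F
  mp$lrs <- convect_local_frame(mp$lrs, dF)
  if (mp$layer == "media") return(mp)

  if (is.null(micro_substeps)) {
    micro_substeps <- if (!is.null(mp$micro_substeps)) mp$micro_substeps else 4L
  }
  m_sub <- max(1L, as.integer(micro_substeps))
  vDs <- vD / m_sub
  nfam <- length(mp$families)
  w_used <- mp$crimp
  for (s in seq_len(m_sub)) {
    for (i in seq_len(nfam)) {
      fam <- mp$families[[i]]
      d_i <- mandel_unvec(fam$A %*% vDs)
      om_i <- cross_matrix(as.numeric(fam$Rw %*% vDs))
      # chord strain uses the family direction at the start of the sub-step
      d_eps <- as.numeric(fam$frame$c %*% d_i %*% fam$frame$c)
      fam$stress <- fam$stress + mandel_unvec(fam$C %*% mandel_vec(d_i)) +
        om_i %*% fam$stress - fam$stress %*% om_i
      fam$frame <- evolve_fiber_frame(fam$frame, d_i, om_i, ortho_warn = ortho_warn)
      drift <- max(abs(sum(fam$frame$c * fam$frame$c_perp)),
                   abs(sum(fam$frame$c * fam$frame$c_N)),
                   abs(sum(fam$frame$c_perp * fam$frame$c_N)))
      if (is.null(mp$max_drift) || drift > mp$max_drift) mp$max_drift <- drift
      fam$eps <- fam$eps + d_eps
      E_new <- w_used$E(fam$eps)
      if (E_new != fam$E_chord) {
        fam$E_chord <- E_new
        fam$C <- isotropic_stiffness(E_new, mp$nu_c)
      }
      mp$families[[i]] <- fam
    }
    d_m <- mandel_unvec(mp$A_m %*% vDs)
    om_m <- cross_matrix(as.numeric(mp$Rw_m %*% vDs))
    mp$matrix_stress <- mp$matrix_stress +
      mandel_unvec(mp$Cm %*% mandel_vec(d_m)) +
      om_m %*% mp$matrix_stress - mp$matrix_stress %*% om_m
    mp <- rebuild_microstructure(mp)
  }
  for (i in seq_len(nfam)) {
    ang <- angles_from_frame(mp$families[[i]]$frame, mp$lrs)
    mp$families[[i]]$phi <- ang[["phi"]]
    mp$families[[i]]$theta <- ang[["theta"]]
    mp$families[[i]]$frame$phi <- ang[["phi"]]
    mp$families[[i]]$frame$theta <- ang[["theta"]]
  }
  mp
}

#' Drive a material point along a homogeneous deformation path
#'
#' Applies [update_constitutive()] to a sequence of incremental deformation
#' gradients without any finite-element solve — a desk-scale surrogate for
#' homogeneous regions. A single finite element loaded by the same affine
#' boundary displacements follows the identical trajectory.
#'
#' @param mp a [material_point()].
#' @param path list of 3x3 incremental deformation gradients.
#' @return list with `state` (final point) and `trajectory` (tibble with one
#'   row per increment: Cauchy stress components in the local frame, first
#'   family angle and chord modulus).
#' @export
material_point_driver <- function(mp, path) {
  rows <- vector("list", length(path))
  for (n in seq_along(path)) {
    mp <- update_constitutive(mp, path[[n]])
    rows[[n]] <- summarize_point(mp, n)
  }
  warn_frame_drift(mp$max_drift)
  list(state = mp, trajectory = do.call(rbind, rows))
}

summarize_point <- function(mp, n) {
  sTT <- as.numeric(mp$lrs$T %*% mp$stress %*% mp$lrs$T)
  sKK <- as.numeric(mp$lrs$K %*% mp$stress %*% mp$lrs$K)
  if (mp$layer == "adventitia") {
    fam1 <- mp$families[[1]]
    th <- angle_from_axial(fam1$frame$c, mp$lrs)
    Ec <- fam1$E_chord
    sf <- as.numeric(fam1$frame$c %*% fam1$stress %*% fam1$frame$c)
  } else {
    th <- NA_real_; Ec <- NA_real_; sf <- NA_real_
  }
  tibble::tibble(increment = n, stress_TT = sTT, stress_KK = sKK,
                 theta1_deg = th, E_chord = Ec, fiber_stress = sf)
}

# One warning per run if the accumulated fiber-frame orthogonality drift of
# the normalized (non-re-orthogonalized) triad updates exceeds the monitor
# threshold.
warn_frame_drift <- function(drift, threshold = 1e-3) {
  if (!is.null(drift) && is.finite(drift) && drift > threshold) {
    warning(sprintf(
      "fiber-frame orthogonality drift reached %.2e (monitor threshold %.0e)",
      drift, threshold), call. = FALSE)
  }
  invisible(NULL)
}

# Angle between a fiber direction and the local axial direction, mapped to
# [0, 90] degrees (0 = axial) for reporting.
angle_from_axial <- function(cdir, lrs) {
  acos(clamp1(abs(sum(cdir * lrs$T)))) * 180 / pi
}
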