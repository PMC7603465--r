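# Frames and their evolution: the macroscopic local reference system
# (K = circumferential, T = axial, N = radial) convected with the incremental
# deformation gradient, and per-family fiber frames (c, perp-c, N-c) evolved
# by the microscopic strain rate + spin with explicit normalized updates.

#' Local reference system at a wall point
#'
#' @param K,T,N circumferential, axial and radial unit vectors in the global
#'   basis; must be orthonormal with `N = K x T` within 1e-8.
#' @param Tbar convected (pre-orthogonalization) axial direction carried by
#'   the frame-update recursion; defaults to `T`.
#' @return object of class `local_frame`.
#' @export
local_frame <- function(K, T, N = NULL, Tbar = NULL) {
  K <- as.numeric(K); T <- as.numeric(T)
  if (is.null(N)) N <- cross_vec(K, T)
  N <- as.numeric(N)
  G <- cbind(K, T, N)
  if (max(abs(crossprod(G) - diag(3))) > 1e-8) {
    stop("local_frame(): K, T, N must be orthonormal")
  }
  if (max(abs(cross_vec(K, T) - N)) > 1e-8) {
    stop("local_frame(): frame must satisfy N = K x T")
  }
  if (is.null(Tbar)) Tbar <- T
  structure(list(K = K, T = T, N = N, Tbar = as.numeric(Tbar)),
            class = "local_frame")
}

#' Fiber frame from Euler angles
#'
#' Builds the fiber triad (c, perp-c, N-c) from the Euler angles (phi, theta)
#' expressed in a local reference system:
#' `c = cos(phi)cos(theta) N + sin(phi)cos(theta) T - sin(theta) K`,
#' `perp_c = -sin(phi) N + cos(phi) T`,
#' `N_c = cos(phi)sin(theta) N + sin(phi)sin(theta) T + cos(theta) K`.
#' theta = 0 with phi = pi/2 puts the fiber along the axial direction.
#'
#' @param phi,theta Euler angles (rad).
#' @param lrs a [local_frame()].
#' @return object of class `fiber_frame` with fields `c`, `c_perp`, `c_N`,
#'   `phi`, `theta`.
#' @export
frame_from_angles <- function(phi, theta, lrs) {
  stopifnot(inherits(lrs, "local_frame"))
  cphi <- cos(phi); sphi <- sin(phi); cth <- cos(theta); sth <- sin(theta)
  cdir <- cphi * cth * lrs$N + sphi * cth * lrs$T - sth * lrs$K
  cperp <- -sphi * lrs$N + cphi * lrs$T
  cN <- cphi * sth * lrs$N + sphi * sth * lrs$T + cth * lrs$K
  structure(list(c = cdir, c_perp = cperp, c_N = cN,
                 phi = phi, theta = theta),
            class = "fiber_frame")
}

#' Euler angles from a fiber frame
#'
#' Inverts [frame_from_angles()] for a given local reference system:
#' `theta = acos(N_c . K)` and `phi = acos(perp_c . T)` with the quadrant
#' branch `phi -> 2*pi - phi` when `sin(phi) = -(perp_c . N) < 0`. Round-trips
#' with [frame_from_angles()] for theta in (0, pi), phi in [0, 2*pi).
#'
#' @param frame a [fiber_frame()].
#' @param lrs a [local_frame()].
#' @return named numeric vector `c(phi, theta)` (rad).
#' @export
angles_from_frame <- function(frame, lrs) {
  stopifnot(inherits(frame, "fiber_frame"), inherits(lrs, "local_frame"))
  cth <- clamp1(sum(frame$c_N * lrs$K))
  theta <- acos(cth)
  cperp_T <- clamp1(sum(frame$c_perp * lrs$T))
  sphi <- -sum(frame$c_perp * lrs$N)
  phi0 <- acos(cperp_T)
  phi <- if (sphi >= 0) phi0 else 2 * pi - phi0
  if (abs(abs(cth) - 1) < 1e-12 && abs(cperp_T) < 1e-12 && abs(sphi) < 1e-12) {
    stop("angles_from_frame(): degenerate frame, phi undefined")
  }
  c(phi = phi, theta = theta)
}

clamp1 <- function(x) max(-1, min(1, x))

#' Evolve a fiber frame by a microscopic strain rate and spin
#'
#' Each triad vector is updated by the explicit normalized Euler step
#' `a <- (a + (d + omega) . a) / || a + (d + omega) . a ||`. The update
#' normalizes each vector independently and deliberately does not
#' re-orthogonalize the triad; pairwise orthogonality drift beyond
#' `ortho_warn` triggers a warning.
#'
#' @param frame a [fiber_frame()].
#' @param d symmetric 3x3 strain-rate increment.
#' @param omega antisymmetric 3x3 spin increment.
#' @param ortho_warn drift threshold for the orthogonality warning.
#' @return updated `fiber_frame` (angles left untouched; recompute with
#'   [angles_from_frame()]).
#' @export
evolve_fiber_frame <- function(frame, d, omega, ortho_warn = 1e-3) {
  stopifnot(inherits(frame, "fiber_frame"))
  sc <- max(abs(d), 1e-300)
  if (max(abs(d - t(d))) > 1e-8 * sc) stop("d must be symmetric")
  so <- max(abs(omega), 1e-300)
  if (max(abs(omega + t(omega))) > 1e-8 * so) stop("omega must be antisymmetric")
  L <- d + omega
  upd <- function(a) {
    b <- a + as.numeric(L %*% a)
    n <- sqrt(sum(b^2))
    if (n < 1e-12) stop("evolve_fiber_frame(): vanishing updated vector")
    b / n
  }
  frame$c <- upd(frame$c)
  frame$c_perp <- upd(frame$c_perp)
  frame$c_N <- upd(frame$c_N)
  drift <- max(abs(sum(frame$c * frame$c_perp)),
               abs(sum(frame$c * frame$c_N)),
               abs(sum(frame$c_perp * frame$c_N)))
  if (drift > ortho_warn) {
    warning(sprintf("fiber frame orthogonality drift %.2e exceeds %.1e",
                    drift, ortho_warn))
  }
  frame
}

#' Accumulate the deformation gradient
#'
#' `F_new = dF . F` with `dF = I + grad(dU)`; rejects non-positive
#' incremental Jacobians (element inversion).
#'
#' @param F current 3x3 deformation gradient.
#' @param dU_gradient 3x3 gradient of the displacement increment (current
#'   configuration).
#' @return updated 3x3 deformation gradient.
#' @export
update_deformation_gradient <- function(F, dU_gradient) {
  dF <- diag(3) + dU_gradient
  if (det(dF) <= 0) stop("update_deformation_gradient(): non-positive incremental Jacobian (element inversion)")
  dF %*% F
}

#' Convect the local reference system by an incremental deformation gradient
#'
#' Three-step update: K is convected and normalized; the convected
#' (un-orthogonalized) axial direction Tbar is carried along and T is its
#' Gram-Schmidt complement to K; N closes the right-handed triad `N = K x T`.
#'
#' @param lrs a [local_frame()].
#' @param dF 3x3 incremental deformation gradient with positive determinant.
#' @return updated `local_frame`.
#' @export
convect_local_frame <- function(lrs, dF) {
  stopifnot(inherits(lrs, "local_frame"))
  if (det(dF) <= 0) stop("convect_local_frame(): dF must have positive determinant")
  K <- unit_vector(as.numeric(dF %*% lrs$K))
  Tbar <- unit_vector(as.numeric(dF %*% lrs$Tbar))
  Tres <- Tbar - sum(Tbar * K) * K
  nT <- sqrt(sum(Tres^2))
  if (nT < 1e-10) stop("convect_local_frame(): degenerate frame (K parallel to convected T)")
  T <- Tres / nT
  local_frame(K, T, cross_vec(K, T), Tbar = Tbar)
}

# Incremental velocity gradient from the incremental deformation gradient.
# The forward-Euler loading identifies rates with increments (unit time step
# per increment); the strain-rate loading of the RVE is the symmetric part.
velocity_gradient_increment <- function(dF) dF - diag(3)
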