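# Explicit incremental finite-element core: linearized weak form with the
# tangent frozen over the increment, follower pressure on the current inner
# surface, direct sparse solve, and the staggered per-Gauss-point
# constitutive update.
#
# Units: lengths mm, stresses MPa, forces N. 2x2x2 Gauss quadrature on hex8.

#' Set up a simulation state from a case configuration
#'
#' Builds the mesh (honoring `config$mesh` overrides), initializes one
#' [material_point()] per Gauss point (local frames from the cylinder
#' geometry, fiber families from the configured Euler angles) and tabulates
#' the de-crimping law once for all points.
#'
#' @param config a [case_config()].
#' @return a `simulation` object (list with `mesh`, current `nodes`, flat
#'   `states` list indexed `(element-1)*8 + gp`, total displacement `U`,
#'   current pressure `P` in MPa and stretch `lambda`).
#' @export
setup_simulation <- function(config) {
  mesh <- build_cylinder_mesh(config)
  geom <- crimp_geometry(config$h0_over_ell * config$ell0,
                         config$ell0, config$r_c_over_ell * config$ell0)
  crimp <- crimp_table(geom, config$E_f)
  adv_props <- list(E_m = config$E_m, nu_m = config$nu_m,
                    nu_c = config$nu_c, E_f = config$E_f,
                    f_c = config$f_c,
                    theta0 = config$theta0_deg * pi / 180,
                    phi0 = config$phi0_deg * pi / 180,
                    crimp = crimp,
                    micro_substeps = config$micro_substeps)
  med_props <- list(E_M = config$E_M, nu_M = config$nu_M)
  ne <- nrow(mesh$elems)
  states <- vector("list", ne * 8L)
  for (e in seq_len(ne)) {
    Xe <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    for (k in 1:8) {
      xg <- as.numeric(t(Xe) %*% hex8_N(gauss_pts_hex[k, ]))
      lrs <- cylinder_local_frame(xg)
      states[[(e - 1L) * 8L + k]] <-
        if (mesh$layer[e] == "media") material_point("media", lrs, med_props)
        else material_point("adventitia", lrs, adv_props)
    }
  }
  structure(list(mesh = mesh, nodes = mesh$nodes, states = states,
                 config = config, U = matrix(0, nrow(mesh$nodes), 3),
                 P = 0, lambda = 1),
            class = "simulation")
}

# Local (K = circumferential, T = axial, N = radial) frame at a point of the
# undeformed cylinder.
cylinder_local_frame <- function(x) {
  r <- sqrt(x[1]^2 + x[2]^2)
  N <- c(x[1] / r, x[2] / r, 0)
  T <- c(0, 0, 1)
  local_frame(cross_vec(T, N), T, N)
}

#' Solve one load increment
#'
#' Advances the staggered scheme by one increment. The material tangent is
#' frozen over the increment; the incremental displacement is obtained by
#' Newton-type iterations on the force balance between the follower
#' pressure (total pressure after the increment, integrated on the trial
#' inner surface) and the internal force of the trial stress
#' `T_n + C_n : D(dU)`; the stiffness (frozen material part + initial-stress
#' term of the trial stress) and both force vectors are integrated on the
#' trial geometry. With `max_iter = 1` this reduces to a single linear solve
#' of the incremental weak form. After convergence every Gauss point is
#' updated once through [update_constitutive()] and the nodes are moved.
#'
#' @param sim a `simulation` from [setup_simulation()].
#' @param step list with fields `P` (total inner pressure after the
#'   increment, MPa), `du_axial` (axial displacement increment imposed on the
#'   right end, mm), optional `bc_left` (`"fixed"` (default), `"roller"` or
#'   `"free"`), optional `right` (`"full"` (default) prescribes the whole
#'   displacement vector on the right end — axial ramp, zero lateral motion,
#'   a rigid grip; `"axial"` prescribes only the axial component; `"free"`
#'   leaves the end untouched),
#'   optional `prescribed` (data.frame `node`, `dof`, `value` of extra
#'   Dirichlet increments which override the standard sets), and optional
#'   `max_iter` / `tol` for the equilibrium iterations (defaults 30 and
#'   1e-4; configurable globally via `config$max_iter`).
#' @return the updated `simulation`, with attribute `"residual"` holding the
#'   final relative force-balance norm and `"iterations"` the iteration
#'   count.
#' @export
solve_increment <- function(sim, step) {
  mesh <- sim$mesh
  nodes0 <- sim$nodes
  ne <- nrow(mesh$elems)
  nn <- nrow(nodes0)
  ndof <- 3L * nn
  P0 <- sim$P
  P <- if (is.null(step$P)) sim$P else step$P
  max_iter <- if (!is.null(step$max_iter)) step$max_iter
              else if (!is.null(sim$config$max_iter)) sim$config$max_iter else 30L
  tol <- if (!is.null(step$tol)) step$tol else 1e-4
  bbar <- isTRUE(sim$config$bbar)

  # --- packed per-Gauss-point state for the assembly kernel ---------------
  tangents <- vapply(sim$states, function(st) as.numeric(st$tangent),
                     numeric(36))
  s0m <- vapply(sim$states, function(st) mandel_vec(st$stress), numeric(6))

  # --- Dirichlet data ------------------------------------------------------
  bc_left <- if (!is.null(step$bc_left)) step$bc_left
             else if (!is.null(sim$config$bc_left)) sim$config$bc_left else "fixed"
  fix_node <- integer(0); fix_dof <- integer(0); fix_val <- numeric(0)
  add_bc <- function(nodes_set, dofs, values) {
    for (d in seq_along(dofs)) {
      fix_node <<- c(fix_node, nodes_set)
      fix_dof <<- c(fix_dof, rep(dofs[d], length(nodes_set)))
      fix_val <<- c(fix_val, rep(values[d], length(nodes_set)))
    }
  }
  if (bc_left == "fixed") add_bc(mesh$nodes_zminus, 1:3, c(0, 0, 0))
  else if (bc_left == "roller") add_bc(mesh$nodes_zminus, 3L, 0)
  right <- if (!is.null(step$right)) step$right
           else if (!is.null(sim$config$bc_right)) sim$config$bc_right else "full"
  du_ax <- if (is.null(step$du_axial)) 0 else step$du_axial
  if (right == "full") add_bc(mesh$nodes_zplus, 1:3, c(0, 0, du_ax))
  else if (right == "axial") add_bc(mesh$nodes_zplus, 3L, du_ax)
  if (!is.null(step$prescribed)) {
    pr <- step$prescribed
    fix_node <- c(fix_node, pr$node); fix_dof <- c(fix_dof, pr$dof)
    fix_val <- c(fix_val, pr$value)
  }
  gdof <- 3L * (fix_node - 1L) + fix_dof
  keep <- !duplicated(gdof, fromLast = TRUE)  # later entries override
  gdof <- gdof[keep]; pval <- fix_val[keep]
  if (length(gdof) == 0) stop("insufficient boundary conditions: no constrained dof")
  free <- setdiff(seq_len(ndof), gdof)

  # --- equilibrium iterations with the frozen material tangent -------------
  # The material part of the stiffness stays at C_n (staggered scheme); the
  # integration domain and the initial-stress term follow the trial state.
  dU <- numeric(ndof)
  dU[gdof] <- pval
  if (du_ax != 0) {
    # affine initial guess for stretch steps: linear axial ramp between the
    # two grips, so the first residual is not dominated by a strain spike in
    # the end element rings
    z <- nodes0[, 3]
    zmin <- min(z); zmax <- max(z)
    guess <- numeric(ndof)
    guess[seq(3L, ndof, by = 3L)] <- du_ax * (z - zmin) / (zmax - zmin)
    dU[free] <- guess[free]
  }
  # residual evaluation (no stiffness): trial stress divergence + follower load
  eval_res <- function(dU_try) {
    x_trial <- nodes0 + matrix(dU_try, ncol = 3, byrow = TRUE)
    f_int <- tryCatch(
      cpp_assemble(nodes0, x_trial, mesh$elems, tangents, s0m, dU_try,
                   bbar, FALSE)$f_int,
      error = function(e) NULL)
    if (is.null(f_int)) return(NULL)
    f_ext <- if (P != 0) pressure_load(mesh, x_trial, P) else numeric(ndof)
    R <- f_ext - f_int
    # reference scale includes the reactions at constrained dofs, so pure
    # displacement-driven increments (f_ext = 0) are normalized by the load
    # actually carried by the structure
    ref <- max(sqrt(sum(f_ext[free]^2)), sqrt(sum(f_int^2)), 1e-10)
    list(R = R, resid = sqrt(sum(R[free]^2)) / ref)
  }
  best <- eval_res(dU)
  if (is.null(best)) stop("element inversion under the prescribed boundary displacements")
  best$dU <- dU
  Kff <- NULL; fresh <- FALSE
  iters <- 1L
  while (best$resid >= tol && iters < max_iter) {
    if (is.null(Kff)) {
      x_cur <- nodes0 + matrix(best$dU, ncol = 3, byrow = TRUE)
      asm <- cpp_assemble(nodes0, x_cur, mesh$elems, tangents, s0m, best$dU,
                          bbar, TRUE)
      K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$x,
                                dims = c(ndof, ndof))
      if (P != 0) K <- K - pressure_load_stiffness(mesh, x_cur, P)
      Kff <- K[free, free, drop = FALSE]
      fresh <- TRUE
    }
    delta <- tryCatch(
      as.numeric(Matrix::solve(Kff, best$R[free])),
      error = function(e) stop("singular stiffness (insufficient boundary conditions?): ",
                               conditionMessage(e)))
    # backtracking line search on the residual norm
    improved <- FALSE
    relax <- 1
    while (relax >= 1 / 256) {
      dU_try <- best$dU
      dU_try[free] <- dU_try[free] + relax * delta
      cand <- eval_res(dU_try)
      iters <- iters + 1L
      if (!is.null(cand) && cand$resid < best$resid) {
        slow <- cand$resid > 0.5 * best$resid
        best <- cand; best$dU <- dU_try
        improved <- TRUE
        # reform the stiffness next round if convergence is slow
        if (slow && !fresh) Kff <- NULL
        fresh <- FALSE
        break
      }
      relax <- relax / 2
    }
    if (isTRUE(step$trace)) {
      message(sprintf("  iter %d: resid %.4g (relax %.3g, improved %s)",
                      iters, best$resid, relax, improved))
    }
    if (!improved) {
      if (fresh) break          # fresh stiffness and still no admissible step
      Kff <- NULL               # stale stiffness: reform and retry
    }
  }
  dU <- best$dU
  resid <- best$resid

  # adaptive substepping: if the increment did not converge, redo it as two
  # half-increments (recursively, up to 4 levels)
  substep_tol <- if (!is.null(step$substep_tol)) step$substep_tol else 0.01
  depth <- if (is.null(step$.depth)) 0L else step$.depth
  if (resid > substep_tol && depth < 4L && max_iter > 1L) {
    step1 <- step
    step1$P <- (P0 + P) / 2
    step1$du_axial <- du_ax / 2
    step1$.depth <- depth + 1L
    if (!is.null(step1$prescribed)) step1$prescribed$value <- step1$prescribed$value / 2
    step2 <- step1
    step2$P <- P
    sim_half <- solve_increment(sim, step1)
    return(solve_increment(sim_half, step2))
  }
  if (resid > max(10 * tol, 0.01) && max_iter > 1L) {
    warning(sprintf("equilibrium iterations stalled: residual %.3g after %d iterations",
                    resid, iters))
  }
  dUm <- matrix(dU, ncol = 3, byrow = TRUE)

  # --- constitutive update at every Gauss point ----------------------------
  for (e in seq_len(ne)) {
    conn <- mesh$elems[e, ]
    Xe <- nodes0[conn, , drop = FALSE]
    dUe <- dUm[conn, , drop = FALSE]
    for (k in 1:8) {
      idx <- (e - 1L) * 8L + k
      gradN <- hex8_dN_gauss[[k]] %*% solve(crossprod(Xe, hex8_dN_gauss[[k]]))
      dF <- diag(3) + crossprod(dUe, gradN)  # I + sum_a dU_a (x) gradN_a
      sim$states[[idx]] <- update_constitutive(sim$states[[idx]], dF)
    }
  }
  sim$nodes <- nodes0 + dUm
  sim$U <- sim$U + dUm
  sim$P <- P
  attr(sim, "residual") <- resid
  attr(sim, "iterations") <- iters
  sim
}

# Mandel-convention strain-displacement matrix (6 x 24) from the 8x3 matrix
# of shape-function gradients.
b_matrix <- function(gradN) {
  B <- matrix(0, 6, 24)
  s <- 1 / SQRT2
  for (a in 1:8) {
    c0 <- 3L * (a - 1L)
    gx <- gradN[a, 1]; gy <- gradN[a, 2]; gz <- gradN[a, 3]
    B[1, c0 + 1] <- gx
    B[2, c0 + 2] <- gy
    B[3, c0 + 3] <- gz
    B[4, c0 + 2] <- s * gz; B[4, c0 + 3] <- s * gy
    B[5, c0 + 1] <- s * gz; B[5, c0 + 3] <- s * gx
    B[6, c0 + 1] <- s * gy; B[6, c0 + 2] <- s * gx
  }
  B
}

# Load-stiffness (geometry derivative) of the follower pressure:
# d f_a / d u_b = P N_a [ -C(t_eta) dNq_b,xi + C(t_xi) dNq_b,eta ],
# with C(.) the cross-product matrix and t_xi, t_eta the surface tangents.
pressure_load_stiffness <- function(mesh, nodes, P) {
  quads <- mesh$facets$inner
  g <- 1 / sqrt(3)
  qp <- as.matrix(expand.grid(c(-g, g), c(-g, g)))
  nq <- nrow(quads)
  ti <- vector("list", nq); tj <- vector("list", nq); tx <- vector("list", nq)
  for (q in seq_len(nq)) {
    conn <- quads[q, ]
    X <- nodes[conn, , drop = FALSE]
    dofs <- as.integer(as.vector(t(outer(conn, 0:2, function(n, d) 3L * (n - 1L) + d + 1L))))
    Kq <- matrix(0, 12, 12)
    for (k in 1:4) {
      xi <- qp[k, ]
      d <- quad4_dN(xi)
      t1 <- as.numeric(crossprod(X, d[, 1]))
      t2 <- as.numeric(crossprod(X, d[, 2]))
      Nq <- quad4_N(xi)
      M <- -cross_matrix(t2)
      M2 <- cross_matrix(t1)
      for (a in 1:4) for (b in 1:4) {
        blk <- P * Nq[a] * (d[b, 1] * M + d[b, 2] * M2)
        ra <- 3L * (a - 1L) + 1:3; rb <- 3L * (b - 1L) + 1:3
        Kq[ra, rb] <- Kq[ra, rb] + blk
      }
    }
    ti[[q]] <- rep(dofs, times = 12)
    tj[[q]] <- rep(dofs, each = 12)
    tx[[q]] <- as.numeric(Kq)
  }
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                       dims = c(3L * nrow(nodes), 3L * nrow(nodes)))
}

# Consistent nodal forces of a uniform follower pressure P (MPa) on the
# current inner surface; quads are oriented so the patch normal is the push
# direction.
pressure_load <- function(mesh, nodes, P) {
  f <- numeric(3L * nrow(nodes))
  quads <- mesh$facets$inner
  g <- 1 / sqrt(3)
  qp <- as.matrix(expand.grid(c(-g, g), c(-g, g)))
  for (q in seq_len(nrow(quads))) {
    conn <- quads[q, ]
    X <- nodes[conn, , drop = FALSE]
    for (k in 1:4) {
      xi <- qp[k, ]
      d <- quad4_dN(xi)
      t1 <- as.numeric(crossprod(X, d[, 1]))
      t2 <- as.numeric(crossprod(X, d[, 2]))
      ndS <- cross_vec(t1, t2)
      Nq <- quad4_N(xi)
      for (a in 1:4) {
        dofs <- 3L * (conn[a] - 1L) + 1:3
        f[dofs] <- f[dofs] + P * Nq[a] * ndS
      }
    }
  }
  f
}
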