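# Structured hexahedral meshing of the two-layer hollow cylinder.
#
# Geometry convention: the cylinder axis is the global z axis; R_o is the
# OUTER radius, the inner radius is R_o - delta_o and the media/adventitia
# interface sits at R_o - delta_o + delta_M. The left end (z = 0) is the
# fully clamped section, the right end (z = L) carries the imposed axial
# displacement.

#' Build a hexahedral mesh of the two-layer arterial segment
#'
#' Structured hex8 mesh with `n_circ` circumferential, `n_axial` axial and
#' `n_r_media + n_r_adv` radial divisions. By default the circumferential and
#' axial divisions target an average edge length of `R_o/12` with at least 3
#' elements through the media and 2 through the adventitia; all counts can be
#' overridden for scaled-down runs.
#'
#' @param config a [case_config()] (uses `L0`, `R0`, `delta0`, `deltaM`).
#' @param n_circ,n_axial,n_r_media,n_r_adv optional division overrides; if
#'   missing, taken from `config$mesh` or from the default target size.
#' @param target_size target edge length (mm) used when counts are not given.
#' @return object of class `artery_mesh`: nodes (n x 3, mm), `elems`
#'   (m x 8 node indices), `layer` (per element, `"media"`/`"adventitia"`),
#'   facet sets `inner`, `outer`, `zminus`, `zplus` (k x 4, oriented so that
#'   the bilinear-patch normal is the pressure push direction on `inner`),
#'   and node sets `nodes_zminus`, `nodes_zplus`.
#' @export
build_cylinder_mesh <- function(config, n_circ = NULL, n_axial = NULL,
                                n_r_media = NULL, n_r_adv = NULL,
                                target_size = NULL) {
  g <- config
  stopifnot(g$L0 > 0, g$R0 > 0, g$delta0 > 0, g$deltaM > 0,
            g$delta0 > g$deltaM)
  R_out <- g$R0
  R_in <- g$R0 - g$delta0
  if (R_in <= 0) stop("degenerate geometry: thickness exceeds the radius")
  R_int <- R_in + g$deltaM
  msh <- if (!is.null(config$mesh)) config$mesh else list()
  pick <- function(x, stored, default) {
    if (!is.null(x)) x else if (!is.null(stored)) stored else default
  }
  if (is.null(target_size)) target_size <- g$R0 / 12
  n_circ <- pick(n_circ, msh$n_circ, max(8L, round(2 * pi * R_out / target_size)))
  n_axial <- pick(n_axial, msh$n_axial, max(4L, round(g$L0 / target_size)))
  n_r_media <- pick(n_r_media, msh$n_r_media, 3L)
  n_r_adv <- pick(n_r_adv, msh$n_r_adv, 2L)
  n_r <- n_r_media + n_r_adv
  radii <- c(seq(R_in, R_int, length.out = n_r_media + 1),
             seq(R_int, R_out, length.out = n_r_adv + 1)[-1])
  thetas <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  zs <- seq(0, g$L0, length.out = n_axial + 1)

  # node id for (radial ir in 1..n_r+1, circumferential ic in 1..n_circ
  # (periodic), axial iz in 1..n_axial+1)
  nid <- function(ir, ic, iz) {
    ic <- ((ic - 1L) %% n_circ) + 1L
    ((iz - 1L) * (n_r + 1L) + (ir - 1L)) * n_circ + ic
  }
  grid <- expand.grid(ic = seq_len(n_circ), ir = seq_len(n_r + 1),
                      iz = seq_len(n_axial + 1))
  r <- radii[grid$ir]; th <- thetas[grid$ic]; z <- zs[grid$iz]
  nodes <- cbind(r * cos(th), r * sin(th), z)

  eg <- expand.grid(ic = seq_len(n_circ), ir = seq_len(n_r),
                    iz = seq_len(n_axial))
  elems <- cbind(nid(eg$ir,     eg$ic,     eg$iz),
                 nid(eg$ir + 1L, eg$ic,     eg$iz),
                 nid(eg$ir + 1L, eg$ic + 1L, eg$iz),
                 nid(eg$ir,     eg$ic + 1L, eg$iz),
                 nid(eg$ir,     eg$ic,     eg$iz + 1L),
                 nid(eg$ir + 1L, eg$ic,     eg$iz + 1L),
                 nid(eg$ir + 1L, eg$ic + 1L, eg$iz + 1L),
                 nid(eg$ir,     eg$ic + 1L, eg$iz + 1L))
  layer <- ifelse(eg$ir <= n_r_media, "media", "adventitia")

  fg <- expand.grid(ic = seq_len(n_circ), iz = seq_len(n_axial))
  # inner surface quads, ordered so t_xi x t_eta points away from the axis
  # (the direction an internal pressure pushes the wall)
  inner <- cbind(nid(1L, fg$ic, fg$iz), nid(1L, fg$ic + 1L, fg$iz),
                 nid(1L, fg$ic + 1L, fg$iz + 1L), nid(1L, fg$ic, fg$iz + 1L))
  outer <- cbind(nid(n_r + 1L, fg$ic, fg$iz), nid(n_r + 1L, fg$ic, fg$iz + 1L),
                 nid(n_r + 1L, fg$ic + 1L, fg$iz + 1L),
                 nid(n_r + 1L, fg$ic + 1L, fg$iz))
  rg <- expand.grid(ic = seq_len(n_circ), ir = seq_len(n_r))
  zminus <- cbind(nid(rg$ir, rg$ic, 1L), nid(rg$ir + 1L, rg$ic, 1L),
                  nid(rg$ir + 1L, rg$ic + 1L, 1L), nid(rg$ir, rg$ic + 1L, 1L))
  zplus <- cbind(nid(rg$ir, rg$ic, n_axial + 1L),
                 nid(rg$ir + 1L, rg$ic, n_axial + 1L),
                 nid(rg$ir + 1L, rg$ic + 1L, n_axial + 1L),
                 nid(rg$ir, rg$ic + 1L, n_axial + 1L))
  mesh <- structure(list(
    nodes = nodes, elems = elems, layer = layer,
    facets = list(inner = inner, outer = outer, zminus = zminus, zplus = zplus),
    nodes_zminus = which(abs(nodes[, 3]) < 1e-12),
    nodes_zplus = which(abs(nodes[, 3] - g$L0) < 1e-12),
    n_circ = n_circ, n_axial = n_axial,
    n_r_media = n_r_media, n_r_adv = n_r_adv,
    R_in = R_in, R_int = R_int, R_out = R_out, L0 = g$L0
  ), class = "artery_mesh")
  jac <- mesh_jacobians(mesh)
  if (min(jac) <= 0) stop("build_cylinder_mesh(): non-positive Jacobian")
  mesh
}

#' @export
print.artery_mesh <- function(x, ...) {
  cat(sprintf(
    "artery mesh: %d hex8 elements (%d media / %d adventitia), %d nodes\n",
    nrow(x$elems), sum(x$layer == "media"), sum(x$layer == "adventitia"),
    nrow(x$nodes)))
  cat(sprintf("  radii %.3f / %.3f / %.3f mm, length %.3f mm, %d x %d x %d divisions\n",
              x$R_in, x$R_int, x$R_out, x$L0,
              x$n_circ, x$n_axial, x$n_r_media + x$n_r_adv))
  invisible(x)
}

# Trilinear hex8 shape functions: local node coordinates and dN/dxi at the
# 2x2x2 Gauss points (weights all 1).
hex8_local <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1, -1, 1, -1,
                       -1, -1,  1,  1, -1,  1,  1, 1,  1, -1, 1,  1),
                     nrow = 8, byrow = TRUE)

hex8_dN <- function(xi) {
  # 8x3 matrix of shape-function gradients at local point xi
  out <- matrix(0, 8, 3)
  for (a in 1:8) {
    s <- hex8_local[a, ]
    out[a, 1] <- s[1] * (1 + s[2] * xi[2]) * (1 + s[3] * xi[3]) / 8
    out[a, 2] <- s[2] * (1 + s[1] * xi[1]) * (1 + s[3] * xi[3]) / 8
    out[a, 3] <- s[3] * (1 + s[1] * xi[1]) * (1 + s[2] * xi[2]) / 8
  }
  out
}

hex8_N <- function(xi) {
  sapply(1:8, function(a) {
    s <- hex8_local[a, ]
    (1 + s[1] * xi[1]) * (1 + s[2] * xi[2]) * (1 + s[3] * xi[3]) / 8
  })
}

gauss_pts_hex <- local({
  g <- 1 / sqrt(3)
  as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
})

hex8_dN_gauss <- local({
  lapply(seq_len(8), function(k) hex8_dN(gauss_pts_hex[k, ]))
})

#' Jacobian determinants of all elements at all Gauss points
#'
#' @param mesh an [artery_mesh()].
#' @param nodes optional current nodal coordinates (defaults to the mesh's).
#' @return matrix (n_elements x 8) of Jacobian determinants.
#' @export
mesh_jacobians <- function(mesh, nodes = NULL) {
  if (is.null(nodes)) nodes <- mesh$nodes
  ne <- nrow(mesh$elems)
  out <- matrix(0, ne, 8)
  X <- array(0, c(ne, 8, 3))
  for (a in 1:8) X[, a, ] <- nodes[mesh$elems[, a], , drop = FALSE]
  for (k in 1:8) {
    dN <- hex8_dN_gauss[[k]]
    J <- array(0, c(ne, 3, 3))
    for (i in 1:3) for (j in 1:3) {
      J[, i, j] <- X[, , i] %*% dN[, j]
    }
    out[, k] <- J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
      J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
      J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  }
  out
}

#' Area of a boundary facet set
#'
#' Integrates the bilinear surface patches of a facet set with 2x2 Gauss
#' quadrature on the current coordinates.
#'
#' @param mesh an [artery_mesh()].
#' @param set one of `"inner"`, `"outer"`, `"zminus"`, `"zplus"`.
#' @param nodes optional current nodal coordinates.
#' @return total area (mm^2).
#' @export
facet_area <- function(mesh, set = c("inner", "outer", "zminus", "zplus"),
                       nodes = NULL) {
  set <- match.arg(set)
  if (is.null(nodes)) nodes <- mesh$nodes
  quads <- mesh$facets[[set]]
  g <- 1 / sqrt(3)
  qp <- as.matrix(expand.grid(c(-g, g), c(-g, g)))
  total <- 0
  for (q in seq_len(nrow(quads))) {
    X <- nodes[quads[q, ], , drop = FALSE]
    for (k in 1:4) {
      d <- quad4_dN(qp[k, ])
      t1 <- as.numeric(t(X) %*% d[, 1])
      t2 <- as.numeric(t(X) %*% d[, 2])
      total <- total + sqrt(sum(cross_vec(t1, t2)^2))
    }
  }
  total
}

quad4_local <- matrix(c(-1, -1, 1, -1, 1, 1, -1, 1), nrow = 4, byrow = TRUE)

quad4_dN <- function(xi) {
  out <- matrix(0, 4, 2)
  for (a in 1:4) {
    s <- quad4_local[a, ]
    out[a, 1] <- s[1] * (1 + s[2] * xi[2]) / 4
    out[a, 2] <- s[2] * (1 + s[1] * xi[1]) / 4
  }
  out
}

quad4_N <- function(xi) {
  sapply(1:4, function(a) {
    s <- quad4_local[a, ]
    (1 + s[1] * xi[1]) * (1 + s[2] * xi[2]) / 4
  })
}
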