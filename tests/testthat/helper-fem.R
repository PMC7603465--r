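# Minimal single-hex "mesh" compatible with the increment solver, for patch
# and equivalence tests (no pressure surface).
cube_mesh <- function(a = 1) {
  nodes <- a * matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0,
                        0, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1),
                      ncol = 3, byrow = TRUE)
  structure(list(
    nodes = nodes, elems = matrix(1:8, nrow = 1), layer = "media",
    facets = list(inner = matrix(integer(0), 0, 4),
                  outer = matrix(integer(0), 0, 4),
                  zminus = matrix(c(1L, 4L, 3L, 2L), 1),
                  zplus = matrix(c(5L, 6L, 7L, 8L), 1)),
    nodes_zminus = 1:4, nodes_zplus = 5:8,
    n_circ = 1L, n_axial = 1L, n_r_media = 1L, n_r_adv = 0L,
    R_in = NA, R_int = NA, R_out = NA, L0 = a
  ), class = "artery_mesh")
}

cube_sim <- function(states1, a = 1) {
  mesh <- cube_mesh(a)
  structure(list(mesh = mesh, nodes = mesh$nodes,
                 states = states1,
                 config = list(bbar = FALSE, max_iter = 30L,
                               bc_left = "free", bc_right = "free"),
                 U = matrix(0, 8, 3), P = 0, lambda = 1),
            class = "simulation")
}

# Dirichlet table imposing the affine displacement du = (dF - I) x on every
# node of a simulation.
affine_bc <- function(sim, dF) {
  G <- dF - diag(3)
  du <- sim$nodes %*% t(G)
  data.frame(node = rep(seq_len(nrow(sim$nodes)), each = 3),
             dof = rep(1:3, nrow(sim$nodes)),
             value = as.vector(t(du)))
}

cfg_props <- function(cfg) {
  geom <- crimp_geometry(cfg$h0_over_ell * cfg$ell0, cfg$ell0,
                         cfg$r_c_over_ell * cfg$ell0)
  list(E_m = cfg$E_m, nu_m = cfg$nu_m, nu_c = cfg$nu_c, E_f = cfg$E_f,
       f_c = cfg$f_c, theta0 = cfg$theta0_deg * pi / 180,
       phi0 = cfg$phi0_deg * pi / 180, crimp = crimp_table(geom, cfg$E_f))
}
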