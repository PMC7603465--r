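# Case-study drivers: tension-inflation protocols (inflation at constant
# stretch, tension at constant pressure), collagen-disorder sweeps,
# shear-stiffness readouts, fixture configurations and central-region
# post-processing.

MMHG_TO_MPA <- 133.322e-6

config_fields <- c("name", "L0", "R0", "delta0", "deltaM", "deltaA",
                   "f_c", "theta0_deg", "phi0_deg", "h0_over_ell",
                   "r_c_over_ell", "ell0", "nu_c", "E_m", "nu_m",
                   "E_M", "nu_M", "E_f", "dP_mmHg", "dlambda",
                   "mesh", "bc_left", "bc_right", "bbar", "max_iter",
                   "micro_substeps")

#' Case configuration for a tension-inflation simulation
#'
#' Collects the geometry (mm), microstructure and material parameters
#' (moduli in MPa), the load-step sizes and the mesh overrides. Unknown
#' fields are rejected; thicknesses must satisfy
#' `deltaM + deltaA = delta0`.
#'
#' @param ... named fields; see [generate_fixture()] for the two reference
#'   parameter sets.
#' @return validated object of class `case_config`.
#' @export
case_config <- function(...) {
  x <- list(...)
  unknown <- setdiff(names(x), config_fields)
  if (length(unknown)) {
    stop("case_config(): unknown fields: ", paste(unknown, collapse = ", "))
  }
  defaults <- list(name = "custom", dP_mmHg = 5, dlambda = 0.03,
                   mesh = NULL, bc_left = "fixed", bc_right = "full",
                   bbar = FALSE, max_iter = 30L, micro_substeps = 4L)
  for (nm in names(defaults)) {
    if (is.null(x[[nm]])) x[nm] <- list(defaults[[nm]])   # keeps NULL fields
  }
  required <- setdiff(config_fields, names(x))
  if (length(required)) {
    stop("case_config(): missing fields: ", paste(required, collapse = ", "))
  }
  with(x, {
    stopifnot(L0 > 0, R0 > 0, delta0 > 0, deltaM > 0, deltaA > 0,
              f_c > 0, f_c < 1, ell0 > 0, h0_over_ell >= 0,
              r_c_over_ell > 0, E_m > 0, E_M > 0, E_f > 0,
              dP_mmHg > 0, dlambda > 0)
    if (abs(deltaM + deltaA - delta0) > 1e-9) {
      stop("case_config(): layer thicknesses must sum to the wall thickness")
    }
    if (length(theta0_deg) != length(phi0_deg)) {
      stop("case_config(): theta0_deg and phi0_deg must have the same length")
    }
    if (nu_m > 0.49) stop("case_config(): matrix Poisson ratio capped at 0.49")
  })
  structure(x[config_fields], class = "case_config")
}

#' @export
print.case_config <- function(x, ...) {
  cat(sprintf("case config '%s': L0 = %.2f mm, R0 = %.2f mm, wall %.3f mm (media %.3f / adventitia %.3f)\n",
              x$name, x$L0, x$R0, x$delta0, x$deltaM, x$deltaA))
  cat(sprintf("  f_c = %.0f%%, theta0 = {%s} deg, h0 = %.2f ell0, E_f = %g MPa\n",
              100 * x$f_c, paste(x$theta0_deg, collapse = ", "),
              x$h0_over_ell, x$E_f))
  invisible(x)
}

#' Reference case configurations
#'
#' Returns a fully populated, validated [case_config()]:
#' * `"s_test"` — the tension-at-constant-pressure reference set (rabbit
#'   carotid segment, 7.8 mm long, f_c = 15%, fiber families at
#'   {60, -60, 10, -10} degrees from the axial direction, h0 = 0.2 ell0);
#' * `"p_test"` — the inflation-at-constant-stretch set (8.0 mm, f_c = 20%,
#'   families at {70, -70, 35, -35} degrees, h0 = 0.25 ell0);
#' * `"disorder"` — the s_test set, the baseline of the collagen-disorder
#'   sweeps;
#' * `"tiny"` — the s_test set with a coarse mesh and large load steps, for
#'   sub-minute desk-scale runs.
#'
#' @param name one of `"s_test"`, `"p_test"`, `"disorder"`, `"tiny"`.
#' @return a [case_config()].
#' @export
generate_fixture <- function(name = c("s_test", "p_test", "disorder", "tiny")) {
  name <- match.arg(name)
  s_base <- list(
    name = "s_test", L0 = 7.8, R0 = 1.2, delta0 = 0.19,
    deltaM = 0.125, deltaA = 0.065, f_c = 0.15,
    theta0_deg = c(60, -60, 10, -10), phi0_deg = c(90, -90, 90, -90),
    h0_over_ell = 0.2, r_c_over_ell = 0.04, ell0 = 50e-3,
    nu_c = 0.35, E_m = 0.010, nu_m = 0.4, E_M = 0.12, nu_M = 0.49,
    E_f = 50)
  cfg <- switch(name,
    s_test = s_base,
    disorder = { s_base$name <- "disorder"; s_base },
    p_test = list(
      name = "p_test", L0 = 8.0, R0 = 1.1, delta0 = 0.155,
      deltaM = 0.1, deltaA = 0.055, f_c = 0.20,
      theta0_deg = c(70, -70, 35, -35), phi0_deg = c(90, -90, 90, -90),
      h0_over_ell = 0.25, r_c_over_ell = 0.04, ell0 = 50e-3,
      nu_c = 0.35, E_m = 0.010, nu_m = 0.4, E_M = 0.12, nu_M = 0.49,
      E_f = 50),
    tiny = {
      s_base$name <- "tiny"
      s_base$mesh <- list(n_circ = 8L, n_axial = 6L,
                          n_r_media = 2L, n_r_adv = 1L)
      s_base
    })
  do.call(case_config, cfg)
}

#' Coarsen the mesh of a configuration
#'
#' Keeps the geometry, material parameters and load steps, replaces the mesh
#' divisions by desk-scale values.
#'
#' @param config a [case_config()].
#' @param n_circ,n_axial,n_r_media,n_r_adv division counts.
#' @return the modified `case_config`.
#' @export
coarsen <- function(config, n_circ = 8L, n_axial = 6L,
                    n_r_media = 2L, n_r_adv = 1L) {
  config$mesh <- list(n_circ = n_circ, n_axial = n_axial,
                      n_r_media = n_r_media, n_r_adv = n_r_adv)
  config
}

# --- load programs ---------------------------------------------------------

pressure_steps <- function(cfg, from_mmHg, to_mmHg, dP = NULL) {
  if (is.null(dP)) dP <- cfg$dP_mmHg
  if (to_mmHg <= from_mmHg + 1e-12) return(numeric(0))
  n <- ceiling((to_mmHg - from_mmHg) / dP - 1e-9)
  seq(from_mmHg, to_mmHg, length.out = n + 1)[-1]
}

stretch_steps <- function(cfg, from_l, to_l, dl = NULL) {
  if (is.null(dl)) dl <- cfg$dlambda
  if (to_l <= from_l + 1e-12) return(numeric(0))
  n <- ceiling((to_l - from_l) / dl - 1e-9)
  seq(from_l, to_l, length.out = n + 1)[-1]
}

run_program <- function(config, program, verbose = FALSE) {
  sim <- setup_simulation(config)
  rows <- vector("list", nrow(program) + 1L)
  rows[[1]] <- central_summary(sim, increment = 0L, phase = "initial")
  for (n in seq_len(nrow(program))) {
    stp <- program[n, ]
    du <- (stp$lambda - sim$lambda) * config$L0
    sim2 <- tryCatch(
      solve_increment(sim, list(P = stp$P_mmHg * MMHG_TO_MPA, du_axial = du)),
      error = function(e) stop(sprintf("increment %d (%s) failed: %s",
                                       n, stp$phase, conditionMessage(e))))
    sim2$lambda <- stp$lambda
    sim <- sim2
    rows[[n + 1L]] <- central_summary(sim, increment = n, phase = stp$phase)
    if (verbose) message(sprintf("  inc %d/%d: P = %g mmHg, lambda = %.3f",
                                 n, nrow(program), stp$P_mmHg, stp$lambda))
  }
  drifts <- vapply(sim$states, function(st) {
    if (is.null(st$max_drift)) 0 else st$max_drift
  }, numeric(1))
  warn_frame_drift(max(drifts))
  series <- do.call(rbind, rows)
  series$rel_diameter <- series$mean_radius / series$mean_radius[1]
  series$axial_stiffness_kPa <- series_stiffness(series)
  structure(series, class = c("artery_series", class(series)),
            final_state = sim, config = config)
}

# Incremental tangent stiffness d(sigma_TT)/d(lambda) by finite differences
# along the stretch-controlled part of the series.
series_stiffness <- function(series) {
  out <- rep(NA_real_, nrow(series))
  dl <- diff(series$lambda)
  ds <- diff(series$axial_stress_kPa)
  idx <- which(dl > 1e-12)
  out[idx + 1L] <- ds[idx] / dl[idx]
  out
}

#' Tension test at constant inner pressure
#'
#' Two-stage protocol: the inner pressure is ramped from 0 to `pressure`
#' (increments of `dP_mmHg`), then an axial stretch is ramped from 1 to
#' `stretch_max` (increments of `dlambda`) at constant pressure.
#'
#' @param config a [case_config()].
#' @param pressure held inner pressure (mmHg).
#' @param stretch_max final axial stretch.
#' @param verbose print per-increment progress.
#' @return an `artery_series` tibble (one row per increment, increment 0 =
#'   unloaded state) with the central-region averages; the final
#'   `simulation` is attached as attribute `final_state`.
#' @export
run_s_test <- function(config, pressure = 20, stretch_max = 1.8,
                       verbose = FALSE) {
  stopifnot(pressure >= 0, stretch_max >= 1)
  Ps <- pressure_steps(config, 0, pressure)
  ls <- stretch_steps(config, 1, stretch_max)
  program <- rbind(
    if (length(Ps)) data.frame(phase = "pressure", P_mmHg = Ps, lambda = 1),
    if (length(ls)) data.frame(phase = "stretch", P_mmHg = pressure, lambda = ls))
  if (is.null(program)) program <- data.frame(phase = character(0),
                                              P_mmHg = numeric(0),
                                              lambda = numeric(0))
  run_program(config, program, verbose)
}

#' Inflation test at constant axial stretch
#'
#' Two-stage protocol: the axial stretch is ramped from 1 to `stretch`,
#' then the inner pressure is ramped from 0 to `pressure_max` mmHg at
#' constant stretch.
#'
#' @param config a [case_config()].
#' @param stretch held axial stretch (>= 1).
#' @param pressure_max final pressure (mmHg).
#' @param dP_mmHg,dlambda optional step-size overrides (defaults from the
#'   configuration).
#' @inheritParams run_s_test
#' @return an `artery_series`, see [run_s_test()].
#' @export
run_p_test <- function(config, stretch = 1.5, pressure_max = 140,
                       dP_mmHg = NULL, dlambda = NULL, verbose = FALSE) {
  stopifnot(stretch >= 1)
  ls <- stretch_steps(config, 1, stretch, dlambda)
  Ps <- pressure_steps(config, 0, pressure_max, dP_mmHg)
  program <- rbind(
    if (length(ls)) data.frame(phase = "stretch", P_mmHg = 0, lambda = ls),
    if (length(Ps)) data.frame(phase = "pressure", P_mmHg = Ps, lambda = stretch))
  if (is.null(program)) program <- data.frame(phase = character(0),
                                              P_mmHg = numeric(0),
                                              lambda = numeric(0))
  run_program(config, program, verbose)
}

#' Collagen-disorder sweep
#'
#' Repeats the tension test at 20 mmHg up to stretch 1.6 while varying
#' either the collagen volume fraction `f_c` or the initial crimp amplitude
#' `h0` (as a multiple of the crimp period parameter), all other parameters
#' fixed. Reports the central-region fiber stress, axial tissue stress and
#' axial tangent stiffness per run and their ratios at the final stretch.
#'
#' @param config baseline [case_config()].
#' @param param `"f_c"` (volume fractions) or `"h0"` (values of
#'   `h0_over_ell`).
#' @param values parameter values, one run each.
#' @param pressure held pressure (mmHg).
#' @param stretch_max final stretch.
#' @param verbose print progress.
#' @return list with `series` (named list of `artery_series`) and
#'   `comparison` (tibble: final-state fiber stress, axial stress, axial
#'   stiffness and their ratios to the first value).
#' @export
run_disorder_sweep <- function(config, param = c("f_c", "h0"), values,
                               pressure = 20, stretch_max = 1.6,
                               verbose = FALSE) {
  param <- match.arg(param)
  stopifnot(all(values > 0))
  series <- list()
  rows <- vector("list", length(values))
  for (v in seq_along(values)) {
    cfg <- config
    if (param == "f_c") cfg$f_c <- values[v] else cfg$h0_over_ell <- values[v]
    cfg$name <- sprintf("%s=%g", param, values[v])
    if (verbose) message("running ", cfg$name)
    ser <- run_s_test(cfg, pressure = pressure, stretch_max = stretch_max,
                      verbose = verbose)
    series[[cfg$name]] <- ser
    last <- ser[nrow(ser), ]
    rows[[v]] <- tibble::tibble(
      param = param, value = values[v],
      fiber_stress_kPa = last$fiber_stress_kPa,
      axial_stress_kPa = last$axial_stress_kPa,
      axial_stiffness_kPa = last$axial_stiffness_kPa)
  }
  comparison <- do.call(rbind, rows)
  comparison$fiber_stress_ratio <- comparison$fiber_stress_kPa / comparison$fiber_stress_kPa[1]
  comparison$axial_stress_ratio <- comparison$axial_stress_kPa / comparison$axial_stress_kPa[1]
  comparison$axial_stiffness_ratio <- comparison$axial_stiffness_kPa / comparison$axial_stiffness_kPa[1]
  list(series = series, comparison = comparison)
}

#' Axial-circumferential shear-stiffness evolution
#'
#' Tracks the central-region average of the axial-circumferential shear
#' component of the homogenized adventitial tangent (in the local frame)
#' during either a stretching test at constant 120 mmHg or an inflation test
#' at constant stretch 1.3.
#'
#' @param config a [case_config()].
#' @param mode `"stretch"` (tension at P = 120 mmHg) or `"inflate"`
#'   (inflation at stretch 1.3).
#' @param stretch_max,pressure_max protocol end points.
#' @param verbose print progress.
#' @return an `artery_series` (the shear stiffness is the
#'   `shear_stiffness_kPa` column).
#' @export
shear_stiffness_series <- function(config, mode = c("stretch", "inflate"),
                                   stretch_max = 1.8, pressure_max = 140,
                                   verbose = FALSE) {
  mode <- match.arg(mode)
  if (mode == "stretch") {
    run_s_test(config, pressure = 120, stretch_max = stretch_max,
               verbose = verbose)
  } else {
    run_p_test(config, stretch = 1.3, pressure_max = pressure_max,
               verbose = verbose)
  }
}

# --- central-region post-processing ---------------------------------------

# Averages over the central region: the material span of length L/4
# centered at mid-length of the unloaded sample (away from the clamped
# ends), evaluated on the current configuration.
central_summary <- function(sim, increment, phase) {
  mesh <- sim$mesh
  nodes <- sim$nodes
  cz0 <- numeric(nrow(mesh$elems))
  cr <- numeric(nrow(mesh$elems))
  for (e in seq_len(nrow(mesh$elems))) {
    cz0[e] <- mean(mesh$nodes[mesh$elems[e, ], 3])
    Xc <- colMeans(nodes[mesh$elems[e, ], , drop = FALSE])
    cr[e] <- sqrt(Xc[1]^2 + Xc[2]^2)
  }
  zc <- mesh$L0 / 2; half <- mesh$L0 / 8; tol <- 1e-8 * mesh$L0
  central <- which(cz0 >= zc - half - tol & cz0 <= zc + half + tol)
  adv <- central[mesh$layer[central] == "adventitia"]

  theta <- sTT <- sfib <- shear <- numeric(0)
  for (e in adv) {
    for (k in 1:8) {
      st <- sim$states[[(e - 1L) * 8L + k]]
      theta <- c(theta, angle_from_axial(st$families[[1]]$frame$c, st$lrs))
      # collagen-phase stress: volume-weighted along-fiber component over
      # all families
      fsum <- 0; ftot <- 0
      for (fm in st$families) {
        fsum <- fsum + fm$f * as.numeric(fm$frame$c %*% fm$stress %*% fm$frame$c)
        ftot <- ftot + fm$f
      }
      sfib <- c(sfib, fsum / ftot)
      Rl <- cbind(st$lrs$K, st$lrs$T, st$lrs$N)
      Cloc <- rotate_tensor4(st$tangent, t(Rl))
      shear <- c(shear, Cloc[6, 6] / 2)
    }
  }
  for (e in central) {
    for (k in 1:8) {
      st <- sim$states[[(e - 1L) * 8L + k]]
      sTT <- c(sTT, as.numeric(st$lrs$T %*% st$stress %*% st$lrs$T))
    }
  }
  cnodes <- unique(as.vector(mesh$elems[central, , drop = FALSE]))
  u_norm <- mean(sqrt(rowSums(sim$U[cnodes, , drop = FALSE]^2)))
  tibble::tibble(
    increment = increment, phase = phase,
    P_mmHg = sim$P / MMHG_TO_MPA, lambda = sim$lambda,
    mean_radius = mean(cr[central]),
    theta1_deg = if (length(theta)) mean(theta) else NA_real_,
    axial_stress_kPa = 1e3 * mean(sTT),
    fiber_stress_kPa = if (length(sfib)) 1e3 * mean(sfib) else NA_real_,
    shear_stiffness_kPa = if (length(shear)) 1e3 * mean(shear) else NA_real_,
    mean_U_mm = u_norm)
}

#' Post-increment global force balance
#'
#' Assembles the internal force of the current stress field on the current
#' geometry and compares it with the external (pressure) load on the free
#' degrees of freedom; the ratio measures the equilibrium drift of the
#' explicit scheme.
#'
#' @param sim a `simulation`.
#' @return residual norm divided by the external load norm.
#' @export
force_residual <- function(sim) {
  mesh <- sim$mesh
  nodes <- sim$nodes
  ndof <- 3L * nrow(nodes)
  f_int <- numeric(ndof)
  for (e in seq_len(nrow(mesh$elems))) {
    conn <- mesh$elems[e, ]
    Xe <- nodes[conn, , drop = FALSE]
    edof <- as.integer(as.vector(t(outer(conn, 0:2, function(n, d) 3L * (n - 1L) + d + 1L))))
    fe <- numeric(24)
    for (k in 1:8) {
      dN <- hex8_dN_gauss[[k]]
      J <- crossprod(Xe, dN)
      gradN <- dN %*% solve(J)
      B <- b_matrix(gradN)
      st <- sim$states[[(e - 1L) * 8L + k]]
      fe <- fe + as.numeric(crossprod(B, mandel_vec(st$stress))) * det(J)
    }
    f_int[edof] <- f_int[edof] + fe
  }
  f_ext <- if (sim$P != 0) pressure_load(mesh, nodes, sim$P) else numeric(ndof)
  constrained <- c(outer(3L * (mesh$nodes_zminus - 1L), 1:3, `+`),
                   outer(3L * (mesh$nodes_zplus - 1L), 1:3, `+`))
  free <- setdiff(seq_len(ndof), constrained)
  ref <- max(sqrt(sum(f_ext[free]^2)), sqrt(sum(f_int^2)), 1e-12)
  sqrt(sum((f_int[free] - f_ext[free])^2)) / ref
}
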