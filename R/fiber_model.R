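# Crimped collagen fiber model: sinusoidal centerline geometry, curvilinear
# averages, chord elastic modulus and kinematic de-crimping with an
# inextensible centerline.
#
# The fiber centerline over one period is y = g(s) = h*sin(s/ell) for
# s in [0, 2*pi*ell] (small-slope beam convention: s is the abscissa, the
# centerline slope is alpha(s) = (h/ell)*cos(s/ell), in radians). The chord
# modulus relates the end-to-end (chord) strain of the crimped beam to the
# axial force, and tends to the straight-fiber modulus E_f as h -> 0.

#' Crimped fiber geometry
#'
#' @param h sinusoid amplitude (um).
#' @param ell sinusoid period parameter (um); the geometric period is
#'   `2*pi*ell`.
#' @param r_c fiber cross-section radius (um).
#' @return object of class `crimp_geometry`.
#' @export
crimp_geometry <- function(h, ell, r_c) {
  stopifnot(h >= 0, ell > 0, r_c > 0)
  structure(list(h = h, ell = ell, r_c = r_c), class = "crimp_geometry")
}

#' @export
print.crimp_geometry <- function(x, ...) {
  cat(sprintf("crimp geometry: h = %.4g, ell = %.4g, r_c = %.4g (h/ell = %.4g)\n",
              x$h, x$ell, x$r_c, x$h / x$ell))
  invisible(x)
}

#' Curvilinear average of a scalar function over one crimp period
#'
#' Computes `int fn(s) dL / int dL` over `s in [0, 2*pi*ell]`, with arc
#' element `dL = sqrt(1 + g'(s)^2) ds` (measure `"arc"`, the literal
#' along-the-centerline average) or `dL = ds` (measure `"flat"`, provided for
#' sensitivity checks).
#'
#' @param fn vectorized scalar function of the abscissa s.
#' @param geom a [crimp_geometry()].
#' @param measure `"arc"` (default) or `"flat"`.
#' @param rel.tol quadrature relative tolerance.
#' @return scalar average.
#' @export
curvilinear_average <- function(fn, geom, measure = c("arc", "flat"),
                                rel.tol = 1e-10) {
  measure <- match.arg(measure)
  stopifnot(inherits(geom, "crimp_geometry"))
  period <- 2 * pi * geom$ell
  w <- if (measure == "arc") {
    function(s) sqrt(1 + ((geom$h / geom$ell) * cos(s / geom$ell))^2)
  } else {
    function(s) rep(1, length(s))
  }
  f_num <- function(s) {
    v <- fn(s) * w(s)
    if (any(!is.finite(v))) stop("curvilinear_average(): non-finite integrand values")
    v
  }
  num <- stats::integrate(f_num, 0, period, rel.tol = rel.tol,
                          subdivisions = 500L)$value
  den <- stats::integrate(w, 0, period, rel.tol = rel.tol,
                          subdivisions = 500L)$value
  num / den
}

# Arc length over one period; scales as ell * a(h/ell).
crimp_arc_length <- function(h, ell, rel.tol = 1e-10) {
  k <- h / ell
  ell * stats::integrate(function(u) sqrt(1 + (k * cos(u))^2), 0, 2 * pi,
                         rel.tol = rel.tol, subdivisions = 500L)$value
}

#' Chord elastic modulus of a crimped fiber
#'
#' `E_c = E_f * I <cos a> / (I <cos^2 a> + A <g^2>)` with `A = pi r^2`,
#' `I = pi r^4 / 4`, slope `a(s) = (h/ell) cos(s/ell)` and `< >` the
#' curvilinear average. `E_c = E_f` for a straight fiber (h = 0) and decays
#' toward 0 as the crimp amplitude grows or the radius shrinks.
#'
#' @param E_f straight-fiber Young's modulus (stress units; returned value is
#'   in the same units).
#' @inheritParams curvilinear_average
#' @return chord modulus, same units as `E_f`.
#' @export
chord_modulus <- function(E_f, geom, measure = c("arc", "flat")) {
  measure <- match.arg(measure)
  stopifnot(E_f > 0, inherits(geom, "crimp_geometry"))
  if (geom$h == 0) return(E_f)
  k <- geom$h / geom$ell
  alpha <- function(s) k * cos(s / geom$ell)
  m_cos <- curvilinear_average(function(s) cos(alpha(s)), geom, measure)
  m_cos2 <- curvilinear_average(function(s) cos(alpha(s))^2, geom, measure)
  m_g2 <- curvilinear_average(function(s) (geom$h * sin(s / geom$ell))^2, geom, measure)
  A <- pi * geom$r_c^2
  I <- pi * geom$r_c^4 / 4
  E_f * I * m_cos / (I * m_cos2 + A * m_g2)
}

#' Along-the-chord strain increment of a fiber family
#'
#' Projects a (symmetric) fiber-phase strain-rate tensor on the fiber
#' direction: `d_eps = c . d . c`. With the quasi-static convention of one
#' unit time step per load increment, strain rates are increments.
#'
#' @param c_dir unit fiber direction (length-3).
#' @param d_fiber symmetric 3x3 strain-rate (increment) tensor.
#' @return scalar chord-strain increment.
#' @export
chord_strain_increment <- function(c_dir, d_fiber) {
  if (abs(sqrt(sum(c_dir^2)) - 1) > 1e-8) stop("c_dir must be a unit vector")
  sc <- max(abs(d_fiber), 1e-300)
  if (max(abs(d_fiber - t(d_fiber))) > 1e-8 * sc) stop("d_fiber must be symmetric")
  as.numeric(c_dir %*% d_fiber %*% c_dir)
}

#' Crimped fiber state
#'
#' Tracks the accumulated chord strain, the evolving crimp geometry and the
#' current chord modulus of one fiber family.
#'
#' @param geom initial [crimp_geometry()].
#' @param E_f straight-fiber Young's modulus.
#' @param measure curvilinear-average measure, see [curvilinear_average()].
#' @return object of class `crimped_fiber`.
#' @export
crimped_fiber <- function(geom, E_f, measure = "arc") {
  stopifnot(inherits(geom, "crimp_geometry"), E_f > 0)
  structure(list(
    h0 = geom$h, ell0 = geom$ell, r_c = geom$r_c,
    h = geom$h, ell = geom$ell,
    eps_chord = 0,
    E_f = E_f,
    E_chord = chord_modulus(E_f, geom, measure),
    recruited = (geom$h == 0),
    arc0 = crimp_arc_length(geom$h, geom$ell),
    measure = measure
  ), class = "crimped_fiber")
}

#' Update a crimped fiber state by a chord-strain increment
#'
#' Kinematic de-crimping with an inextensible centerline: the period
#' parameter stretches affinely with the accumulated chord strain,
#' `ell = ell0 (1 + eps)`, and the amplitude h follows from conservation of
#' the centerline arc length over one period. When the stretched chord
#' reaches the initial arc length the fiber is fully recruited: h = 0 and
#' `E_chord = E_f` thereafter (sticky).
#'
#' @param state a [crimped_fiber()].
#' @param d_eps chord-strain increment (finite scalar).
#' @return updated `crimped_fiber`.
#' @export
update_crimp <- function(state, d_eps) {
  stopifnot(inherits(state, "crimped_fiber"), is.finite(d_eps))
  eps <- state$eps_chord + d_eps
  if (eps < -1) stop("update_crimp(): chord strain below -1 is non-physical")
  state$eps_chord <- eps
  state$ell <- state$ell0 * (1 + eps)
  if (state$recruited || 2 * pi * state$ell >= state$arc0) {
    state$recruited <- TRUE
    state$h <- 0
    state$E_chord <- state$E_f
    return(state)
  }
  state$h <- crimp_amplitude_from_arc(state$arc0, state$ell)
  geom <- crimp_geometry(state$h, state$ell, state$r_c)
  state$E_chord <- chord_modulus(state$E_f, geom, state$measure)
  state
}

# Amplitude h with arc length `arc` at period parameter ell (arc > 2*pi*ell).
crimp_amplitude_from_arc <- function(arc, ell) {
  target <- arc / ell   # = a(k) with k = h/ell
  a_of_k <- function(k) {
    stats::integrate(function(u) sqrt(1 + (k * cos(u))^2), 0, 2 * pi,
                     rel.tol = 1e-12, subdivisions = 500L)$value
  }
  k_hi <- 0.5
  while (a_of_k(k_hi) < target) k_hi <- k_hi * 2
  ell * stats::uniroot(function(k) a_of_k(k) - target, c(0, k_hi),
                       tol = 1e-13)$root
}

#' Tabulate the de-crimping law for fast repeated evaluation
#'
#' Precomputes `h(eps)` and `E_chord(eps)` of [update_crimp()] on a chord
#' strain grid and returns cubic-spline evaluators. The finite-element core
#' and the material-point driver both evaluate the law through this table so
#' their trajectories coincide exactly.
#'
#' @param geom initial [crimp_geometry()].
#' @param E_f straight-fiber Young's modulus.
#' @param eps_min,eps_max tabulated chord-strain range; defaults bracket the
#'   full recruitment strain with margin.
#' @param n grid size.
#' @param measure see [curvilinear_average()].
#' @return object of class `crimp_table` with fields `E(eps)`, `h(eps)`,
#'   `eps_recruit` and the generating parameters.
#' @export
crimp_table <- function(geom, E_f, eps_min = -0.2, eps_max = NULL, n = 400L,
                        measure = "arc") {
  stopifnot(inherits(geom, "crimp_geometry"))
  key <- paste(signif(c(geom$h, geom$ell, geom$r_c, E_f, eps_min,
                        eps_max %||% -1, n), 12),
               measure, collapse = "|")
  cached <- .crimp_cache[[key]]
  if (!is.null(cached)) return(cached)
  if (geom$h == 0) {
    return(structure(list(
      E = function(eps) rep(E_f, length(eps)),
      h = function(eps) rep(0, length(eps)),
      eps_recruit = 0, E_f = E_f, geom = geom
    ), class = "crimp_table"))
  }
  arc0 <- crimp_arc_length(geom$h, geom$ell)
  eps_recruit <- arc0 / (2 * pi * geom$ell) - 1
  if (is.null(eps_max)) eps_max <- eps_recruit
  # the chord modulus varies steeply as h -> 0, so the grid is concentrated
  # toward the recruitment strain
  s <- seq(0, 1, length.out = n)
  eps_grid <- eps_max - (eps_max - eps_min) * (1 - s)^2.5
  eps_grid <- sort(unique(c(eps_grid, eps_recruit)))
  h_grid <- numeric(length(eps_grid))
  E_grid <- numeric(length(eps_grid))
  for (i in seq_along(eps_grid)) {
    ell_i <- geom$ell * (1 + eps_grid[i])
    if (2 * pi * ell_i >= arc0) {
      h_grid[i] <- 0
      E_grid[i] <- E_f
    } else {
      h_grid[i] <- crimp_amplitude_from_arc(arc0, ell_i)
      E_grid[i] <- chord_modulus(E_f, crimp_geometry(h_grid[i], ell_i, geom$r_c),
                                 measure)
    }
  }
  E_fun <- stats::splinefun(eps_grid, E_grid, method = "hyman")
  h_fun <- stats::splinefun(eps_grid, h_grid, method = "hyman")
  out <- structure(list(
    E = function(eps) {
      pmin(pmax(ifelse(eps >= eps_recruit, E_f,
                       E_fun(pmax(eps, eps_grid[1]))), 0), E_f)
    },
    h = function(eps) ifelse(eps >= eps_recruit, 0, h_fun(pmax(eps, eps_grid[1]))),
    eps_recruit = eps_recruit, E_f = E_f, geom = geom
  ), class = "crimp_table")
  .crimp_cache[[key]] <- out
  out
}

# session cache of tabulated de-crimping laws (keyed by geometry/modulus)
.crimp_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fiber recruitment curve
#'
#' Chord-modulus ratio `E_c/E_f` as a function of the fiber chord stretch,
#' convenient for plotting and CSV export.
#'
#' @param geom initial [crimp_geometry()].
#' @param E_f straight-fiber modulus.
#' @param stretch_max maximum chord stretch (1 + chord strain).
#' @param n number of points.
#' @return tibble with columns `stretch`, `E_ratio`, `h`.
#' @export
recruitment_curve <- function(geom, E_f, stretch_max = NULL, n = 100L) {
  tab <- crimp_table(geom, E_f)
  if (is.null(stretch_max)) stretch_max <- 1 + tab$eps_recruit * 1.2
  eps <- seq(0, stretch_max - 1, length.out = n)
  tibble::tibble(stretch = 1 + eps,
                 E_ratio = tab$E(eps) / E_f,
                 h = tab$h(eps))
}
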