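test_that("curvilinear averages normalize and reach the flat-measure limit", {
  g <- crimp_geometry(h = 10, ell = 50, r_c = 2)
  expect_equal(curvilinear_average(function(s) rep(1, length(s)), g), 1,
               tolerance = 1e-10)

  g0 <- crimp_geometry(h = 0, ell = 50, r_c = 2)
  expect_equal(curvilinear_average(function(s) (0 * sin(s / 50))^2, g0), 0)

  # <g^2> -> h^2/2 in the small-slope limit (flat measure is exact there)
  gs <- crimp_geometry(h = 0.002 * 50, ell = 50, r_c = 2)
  got <- curvilinear_average(function(s) (gs$h * sin(s / gs$ell))^2, gs)
  expect_equal(got, gs$h^2 / 2, tolerance = 1e-5)
  # and exactly h^2/2 under the flat measure at any amplitude
  gb <- crimp_geometry(h = 0.2 * 50, ell = 50, r_c = 2)
  got_flat <- curvilinear_average(function(s) (gb$h * sin(s / gb$ell))^2, gb,
                                  measure = "flat")
  expect_equal(got_flat, gb$h^2 / 2, tolerance = 1e-9)

  expect_error(curvilinear_average(function(s) rep(NaN, length(s)), g),
               "non-finite")
})

test_that("chord modulus limits, reference value and Bessel cross-check", {
  ell <- 50
  expect_equal(chord_modulus(50, crimp_geometry(0, ell, 2)), 50)

  # r_c -> 0 with h > 0: bending compliance dominates, E_c -> 0
  expect_lt(chord_modulus(50, crimp_geometry(0.2 * ell, ell, 1e-4 * ell)) / 50,
            1e-6)

  # reference parameter set: E_f = 50 MPa, r_c = 0.04 ell, h = 0.2 ell
  Ec <- chord_modulus(50, crimp_geometry(0.2 * ell, ell, 0.04 * ell))
  expect_equal(Ec / 50, 0.0195, tolerance = 0.02)

  # quadrature agrees with the Bessel closed forms (which live in the
  # flat-measure limit) to < 1% for h/ell <= 0.3; the default arc measure
  # deviates from that limit by at most ~1.1% at h/ell = 0.3
  for (k in c(0.05, 0.1, 0.2, 0.3)) {
    geom <- crimp_geometry(k * ell, ell, 0.04 * ell)
    bes <- bessel_chord_modulus(50, k * ell, ell, 0.04 * ell)
    expect_equal(chord_modulus(50, geom, measure = "flat"), bes,
                 tolerance = 1e-6)
    expect_equal(chord_modulus(50, geom), bes, tolerance = 0.011)
  }
})

test_that("chord modulus is monotone in crimp amplitude and fiber radius", {
  ell <- 50
  ks <- c(0.05, 0.1, 0.2, 0.3, 0.4)
  Ecs <- vapply(ks, function(k) chord_modulus(50, crimp_geometry(k * ell, ell, 2)),
                numeric(1))
  expect_true(all(diff(Ecs) < 0))
  expect_true(all(Ecs > 0 & Ecs < 50))
  rs <- c(0.5, 1, 2, 4)
  Ecr <- vapply(rs, function(r) chord_modulus(50, crimp_geometry(10, ell, r)),
                numeric(1))
  expect_true(all(diff(Ecr) > 0))
})

test_that("chord strain increment is the fiber-direction projection", {
  expect_equal(chord_strain_increment(c(1, 0, 0), matrix(0, 3, 3)), 0)
  d <- diag(c(0.1, -0.05, 0))
  expect_equal(chord_strain_increment(c(1, 0, 0), d), 0.1)
  # 45-degree fiber in a pure shear d12 = gamma picks up exactly gamma
  gam <- 0.02
  dsh <- matrix(c(0, gam, 0, gam, 0, 0, 0, 0, 0), 3, 3)
  expect_equal(chord_strain_increment(c(1, 1, 0) / sqrt(2), dsh), gam,
               tolerance = 1e-14)
  expect_error(chord_strain_increment(c(1, 1, 0), d), "unit")
})

test_that("kinematic de-crimping conserves arc length and recruits sharply", {
  ell <- 50
  geom <- crimp_geometry(0.2 * ell, ell, 0.04 * ell)
  st <- crimped_fiber(geom, 50)

  expect_equal(update_crimp(st, 0)$E_chord, st$E_chord, tolerance = 1e-10)

  # arc length conserved along the way (relative 1e-6)
  L0 <- arc_length_quad(geom$h, geom$ell)
  s <- st
  for (i in 1:5) {
    s <- update_crimp(s, 0.0015)
    expect_equal(arc_length_quad(s$h, s$ell), L0, tolerance = 1e-6)
  }

  # increments summing to the arc/chord ratio - 1 reach full recruitment
  eps_rec <- L0 / (2 * pi * ell) - 1
  s2 <- update_crimp(st, eps_rec + 1e-12)
  expect_equal(s2$h, 0)
  expect_equal(s2$E_chord, 50)
  # recruitment is sticky
  expect_equal(update_crimp(s2, -1e-4)$E_chord, 50)

  # monotone extension gives monotone non-decreasing chord modulus
  s <- st; Es <- s$E_chord
  for (i in 1:12) { s <- update_crimp(s, eps_rec / 10); Es <- c(Es, s$E_chord) }
  expect_true(all(diff(Es) >= 0))

  expect_error(update_crimp(st, -2), "non-physical")
})

test_that("tabulated de-crimping law matches the exact updates", {
  ell <- 50
  geom <- crimp_geometry(0.2 * ell, ell, 0.04 * ell)
  tab <- crimp_table(geom, 50)
  L0 <- arc_length_quad(geom$h, geom$ell)
  expect_equal(tab$eps_recruit, L0 / (2 * pi * ell) - 1, tolerance = 1e-8)

  st <- crimped_fiber(geom, 50)
  for (eps in c(-0.05, -0.01, 0.002, 0.005, 0.009)) {
    ex <- update_crimp(st, eps)
    expect_equal(tab$E(eps), ex$E_chord, tolerance = 1e-5)
    expect_equal(tab$h(eps), ex$h, tolerance = 1e-5)
  }
  expect_equal(tab$E(tab$eps_recruit + 0.1), 50)
  expect_equal(tab$h(1), 0)

  curve <- recruitment_curve(geom, 50, n = 20)
  expect_true(all(diff(curve$E_ratio) >= 0))
  expect_equal(tail(curve$E_ratio, 1), 1)
})
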