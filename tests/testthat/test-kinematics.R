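lrs0 <- local_frame(K = c(1, 0, 0), T = c(0, 0, 1), N = c(0, -1, 0))

test_that("fiber frames from Euler angles match direct substitution", {
  # phi = pi/2, theta = 0: fiber along the axial direction
  fr <- frame_from_angles(pi / 2, 0, lrs0)
  expect_equal(fr$c, lrs0$T, tolerance = 1e-14)
  # phi = pi/2, theta = pi/2: fiber along -K
  fr2 <- frame_from_angles(pi / 2, pi / 2, lrs0)
  expect_equal(fr2$c, -lrs0$K, tolerance = 1e-14)

  set.seed(41)
  for (i in 1:20) {
    fr <- frame_from_angles(stats::runif(1, 0, 2 * pi),
                            stats::runif(1, 0, pi), lrs0)
    G <- cbind(fr$c, fr$c_perp, fr$c_N)
    expect_lt(max(abs(crossprod(G) - diag(3))), 1e-12)   # orthonormal triad
    expect_equal(abs(det(G)), 1, tolerance = 1e-12)
  }
})

test_that("angle extraction round-trips with frame construction", {
  ang <- angles_from_frame(frame_from_angles(1.0, 0.5, lrs0), lrs0)
  expect_equal(unname(ang), c(1.0, 0.5), tolerance = 1e-12)

  # second quadrant branch for phi
  ang2 <- angles_from_frame(frame_from_angles(3 * pi / 2, 0.5, lrs0), lrs0)
  expect_equal(ang2[["phi"]], 3 * pi / 2, tolerance = 1e-12)

  set.seed(43)
  max_err <- 0
  for (i in 1:1000) {
    phi <- stats::runif(1, 0, 2 * pi)
    theta <- stats::runif(1, 1e-3, pi - 1e-3)
    ang <- angles_from_frame(frame_from_angles(phi, theta, lrs0), lrs0)
    max_err <- max(max_err, abs(ang[["phi"]] - phi), abs(ang[["theta"]] - theta))
  }
  expect_lt(max_err, 1e-8)
})

test_that("explicit normalized frame evolution matches exact rotations", {
  fr <- frame_from_angles(pi / 2, 1.0, lrs0)
  # no strain, no spin: unchanged
  same <- evolve_fiber_frame(fr, matrix(0, 3, 3), matrix(0, 3, 3))
  expect_equal(same$c, fr$c)

  # pure small spin about the local radial axis N changes theta by ~ delta
  delta <- 1e-4
  W <- delta * (outer(lrs0$K, lrs0$T) - outer(lrs0$T, lrs0$K))
  rotated <- evolve_fiber_frame(fr, matrix(0, 3, 3), W)
  Rex <- axis_angle_rotation(cross_axis <- lrs0$N, -delta)
  # compare against the exact rotation to O(delta^2)
  expect_equal(rotated$c, as.numeric(Rex %*% fr$c), tolerance = 10 * delta^2 + 1e-12)

  # pure uniaxial stretching along c leaves the direction unchanged
  d <- 0.1 * outer(fr$c, fr$c)
  stretched <- evolve_fiber_frame(fr, d, matrix(0, 3, 3))
  expect_equal(stretched$c, fr$c, tolerance = 1e-12)

  expect_error(evolve_fiber_frame(fr, matrix(0, 3, 3), diag(3)), "antisymmetric")
})

test_that("affine limit: strain rate + matching spin convect the fiber with dF", {
  set.seed(47)
  for (i in 1:5) {
    dt <- 1e-3
    L <- matrix(stats::rnorm(9), 3, 3) * dt
    dF <- diag(3) + L
    d <- (L + t(L)) / 2
    w <- (L - t(L)) / 2
    fr <- frame_from_angles(stats::runif(1, 0, 2 * pi),
                            stats::runif(1, 0.2, pi - 0.2), lrs0)
    # a stretching map breaks triad orthogonality at first order in d; that
    # drift is the monitored (warned-about) behavior, not an error here
    moved <- suppressWarnings(evolve_fiber_frame(fr, d, w))
    affine <- as.numeric(dF %*% fr$c)
    affine <- affine / sqrt(sum(affine^2))
    expect_equal(moved$c, affine, tolerance = 50 * dt^2)
  }
})

test_that("deformation-gradient accumulation composes increments in order", {
  F <- diag(3)
  F <- update_deformation_gradient(F, diag(c(0.2, 0, 0)))   # stretch 1.2
  F <- update_deformation_gradient(F, diag(c(0.1, 0, 0)))   # then 1.1
  expect_equal(F[1, 1], 1.2 * 1.1, tolerance = 1e-14)

  set.seed(53)
  F <- diag(3); prod <- diag(3)
  for (i in 1:10) {
    G <- matrix(stats::rnorm(9, sd = 0.02), 3, 3)
    F <- update_deformation_gradient(F, G)
    prod <- (diag(3) + G) %*% prod
  }
  expect_equal(F, prod, tolerance = 1e-12)

  expect_error(update_deformation_gradient(diag(3), diag(c(-2, 0, 0))),
               "element inversion")
})

test_that("local-frame convection is exact for rigid rotations and shear", {
  lrs <- lrs0
  # identity: unchanged
  expect_equal(convect_local_frame(lrs, diag(3))$K, lrs$K)

  # rigid rotation: frame rotates exactly
  R <- axis_angle_rotation(c(1, 2, 3), 0.4)
  out <- convect_local_frame(lrs, R)
  expect_equal(out$K, as.numeric(R %*% lrs$K), tolerance = 1e-12)
  expect_equal(out$T, as.numeric(R %*% lrs$T), tolerance = 1e-12)
  expect_equal(out$N, as.numeric(R %*% lrs$N), tolerance = 1e-12)

  # simple shear: K tilts with the motion, T re-orthogonalized by hand
  gam <- 0.1
  dF <- diag(3); dF[1, 3] <- gam   # K-direction displacement on T planes
  out2 <- convect_local_frame(lrs, dF)
  K_hand <- as.numeric(dF %*% lrs$K) / sqrt(sum((dF %*% lrs$K)^2))
  Tbar <- as.numeric(dF %*% lrs$T) / sqrt(sum((dF %*% lrs$T)^2))
  T_hand <- Tbar - sum(Tbar * K_hand) * K_hand
  T_hand <- T_hand / sqrt(sum(T_hand^2))
  expect_equal(out2$K, K_hand, tolerance = 1e-14)
  expect_equal(out2$T, T_hand, tolerance = 1e-14)
  # orthonormal right-handed output
  G <- cbind(out2$K, out2$T, out2$N)
  expect_lt(max(abs(crossprod(G) - diag(3))), 1e-12)
  expect_equal(det(G), 1, tolerance = 1e-12)

  # frames stay orthonormal after many random convections
  cur <- lrs
  set.seed(59)
  for (i in 1:200) {
    dF <- diag(3) + matrix(stats::rnorm(9, sd = 0.02), 3, 3)
    if (det(dF) <= 0) next
    cur <- convect_local_frame(cur, dF)
  }
  G <- cbind(cur$K, cur$T, cur$N)
  expect_lt(max(abs(crossprod(G) - diag(3))), 1e-8)
})
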