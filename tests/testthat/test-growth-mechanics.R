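test_that("area stretch follows Nanson's relation on canonical deformations", {
  e3 <- c(0, 0, 1)
  expect_equal(area_stretch(diag(3), e3), 1)
  expect_equal(area_stretch(diag(c(1.2, 1.2, 1)), e3), 1.44)
  expect_equal(area_stretch(diag(c(1.3, 1, 1)), e3), 1.3)
  expect_error(area_stretch(diag(c(1, 1, 0)), e3), "det")
  expect_error(area_stretch(diag(3), c(0, 0, 2)), "unit")
})

test_that("growth tensor realises in-plane isotropic area growth with no thickness change", {
  e3 <- c(0, 0, 1)
  expect_equal(growth_tensor(1, e3), diag(3))
  expect_equal(growth_tensor(1.44, e3), diag(c(1.2, 1.2, 1)))
  expect_equal(area_stretch(growth_tensor(1.7, e3), e3), 1.7)
  expect_error(growth_tensor(0, e3), "positive")
  # arbitrary normal: normal direction unstretched, area stretch preserved
  n <- c(1, 2, 2) / 3
  Fg <- growth_tensor(1.3, n)
  expect_equal(drop(Fg %*% n), n)
  expect_equal(area_stretch(Fg, n), 1.3)
})

test_that("multiplicative split recovers the elastic part and the area identity", {
  e3 <- c(0, 0, 1)
  F <- diag(c(1.5, 1.5, 1))
  em <- elastic_part(F, 1.44, e3)
  expect_equal(em$Fe, diag(c(1.25, 1.25, 1)))
  expect_equal(em$theta_e, 1.5625)
  expect_equal(1.44 * em$theta_e, area_stretch(F, e3))
  expect_equal(elastic_part(F, 1, e3)$Fe, F)
  # random in-plane deformations: identity to near machine precision
  set.seed(1)
  for (i in 1:20) {
    A <- diag(3) + 0.3 * matrix(stats::rnorm(9), 3)
    if (det(A) <= 0.1) next
    tg <- stats::runif(1, 1, 1.8)
    em <- elastic_part(A, tg, e3)
    expect_equal(tg * em$theta_e, area_stretch(A, e3), tolerance = 1e-12)
  }
})

test_that("strain energy matches hand evaluation and is rotation-invariant and non-negative", {
  mp <- material_params(mu = 0.05, k = 1, theta_nat = 1.1, rho = 1116, lame1 = 2)
  em <- list(I1e = 3.88, Je = 1.44) # Fe = diag(1.2, 1.2, 1)
  expect_equal(strain_energy(em, mp), 0.05 / 2 * 0.88 + 2 / 2 * log(1.44)^2)
  expect_equal(strain_energy(list(I1e = 3, Je = 1), mp), 0)
  set.seed(2)
  for (i in 1:10) {
    Fe <- diag(3) + 0.2 * matrix(stats::rnorm(9), 3)
    if (det(Fe) <= 0) next
    R <- random_rotation()
    em1 <- list(I1e = sum(Fe^2), Je = det(Fe))
    RFe <- R %*% Fe
    em2 <- list(I1e = sum(RFe^2), Je = det(RFe))
    expect_equal(strain_energy(em1, mp), strain_energy(em2, mp),
                 tolerance = 1e-10)
    expect_gte(strain_energy(em1, mp), 0)
  }
  # zero iff rotation
  em_rot <- local({
    R <- random_rotation()
    list(I1e = sum(R^2), Je = det(R))
  })
  expect_equal(strain_energy(em_rot, mp), 0, tolerance = 1e-12)
})

test_that("Cauchy stress is symmetric, vanishes at rotations, and is consistent with the energy", {
  mp <- material_params(mu = 0.05, k = 1, theta_nat = 1.1, rho = 1116, lame1 = 2)
  e3 <- c(0, 0, 1)
  expect_equal(cauchy_stress(elastic_part(diag(3), 1, e3), mp),
               matrix(0, 3, 3))
  set.seed(3)
  for (i in 1:5) {
    Fe <- diag(3) + 0.2 * matrix(stats::rnorm(9), 3)
    if (det(Fe) <= 0) next
    em <- list(Fe = Fe, I1e = sum(Fe^2), Je = det(Fe))
    sig <- cauchy_stress(em, mp)
    expect_equal(sig, t(sig), tolerance = 1e-12)
    # finite-difference first Piola oracle: P = dPsi*/dF, sigma = P F^T / J,
    # where Psi* is the stress potential (the stored energy plus the standard
    # -mu ln(Je) volumetric coupling that makes the rest state stress-free)
    h <- 1e-6
    P <- matrix(0, 3, 3)
    psi <- function(Fx) {
      Jx <- det(Fx)
      strain_energy(list(I1e = sum(Fx^2), Je = Jx), mp) - mp$mu * log(Jx)
    }
    for (a in 1:3) for (b in 1:3) {
      Fp <- Fe; Fp[a, b] <- Fp[a, b] + h
      Fm <- Fe; Fm[a, b] <- Fm[a, b] - h
      P[a, b] <- (psi(Fp) - psi(Fm)) / (2 * h)
    }
    sig_fd <- P %*% t(Fe) / det(Fe)
    expect_equal(sig, sig_fd, tolerance = 1e-6)
  }
})

test_that("growth rate is rectified and linear above the natural pre-stretch", {
  mp <- material_params(mu = 0.05, k = 1.2, theta_nat = 1.125, rho = 1116)
  expect_equal(growth_rate(1.125, mp), 0)
  expect_equal(growth_rate(1.05, mp), 0)
  expect_equal(growth_rate(1.35, mp), 0.27)
  expect_equal(growth_rate(c(1, 1.125, 1.35), mp), c(0, 0, 0.27))
})

test_that("homogeneous growth trajectory matches an adaptive ODE oracle and its limits", {
  skip_if_not_installed("deSolve")
  mp <- material_params(mu = 0.05, k = 1.2, theta_nat = 1.125, rho = 1116)

  # baseline: no over-stretch, no growth
  tr0 <- integrate_homogeneous(1.125, mp, t_end = 7)
  expect_true(all(tr0$theta_g == 1))

  # steady state
  tr_inf <- integrate_homogeneous(1.5, mp, t_end = 100)
  expect_equal(tail(tr_inf$theta_g, 1), 1.5 / 1.125, tolerance = 1e-6)

  # adaptive Runge-Kutta oracle at day 7
  oracle <- deSolve::lsoda(c(th = 1), c(0, 7),
                           function(t, y, p) list(1.2 * max(0, 1.5 / y - 1.125)),
                           rtol = 1e-10, atol = 1e-12)
  tr7 <- integrate_homogeneous(1.5, mp, t_end = 7)
  expect_lt(abs(tail(tr7$theta_g, 1) - oracle[2, "th"]), 1e-6)

  # monotone, bounded, and step-size converged
  expect_true(all(diff(tr7$theta_g) >= 0))
  expect_true(all(tr7$theta_g <= 1.5 / 1.125 + 1e-12))
  tr7b <- integrate_homogeneous(1.5, mp, t_end = 7, dt = 0.005)
  expect_lt(abs(tail(tr7$theta_g, 1) - tail(tr7b$theta_g, 1)), 1e-4)

  expect_error(integrate_homogeneous(1.5, mp, 7, dt = 0), "positive")
})

test_that("plane-stress thickness solve agrees with a bisection oracle and is monotone", {
  mp <- material_params(mu = 0.05, k = 1, theta_nat = 1.1, rho = 1116) # lame1 = 2
  expect_equal(plane_stress_thickness(1, 1, mp), 1, tolerance = 1e-10)

  g <- function(x, A) mp$mu * (x^2 - 1) + mp$lame1 * log(A * x)
  bisect <- function(A) {
    lo <- 1e-4; hi <- 10
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid, A) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  l3 <- plane_stress_thickness(1.2, 1.2, mp)
  expect_equal(l3, bisect(1.44), tolerance = 1e-8)
  expect_lt(abs(l3 - 1 / 1.44), 0.02) # near-incompressible limit

  # unique and monotone decreasing in the in-plane area over the sampled box
  lam <- seq(1, 1.5, by = 0.05)
  l3s <- plane_stress_thickness(lam, lam, mp)
  expect_true(all(diff(l3s) < 0))
  # vectorised residuals all below the contract
  expect_true(all(abs(g(l3s, lam^2) / (lam^2 * l3s)) < 1e-10))
})
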