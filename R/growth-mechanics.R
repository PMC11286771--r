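# Point-wise constitutive and growth kinematics for skin under sustained
# stretch: compressible neo-Hookean elasticity, a multiplicative split of the
# deformation gradient into elastic and growth parts, and a stretch-driven
# area-growth evolution law.
#
# Unit conventions used throughout the package: lengths mm, stresses MPa,
# density kg m^-3, growth time days, wave time seconds.

#' Material parameters for one virtual subject
#'
#' Bundles the constitutive tuple describing one subject's skin: shear modulus
#' `mu`, first Lame parameter `lame1` (by convention tied to the shear modulus
#' as `lame1 = 40 * mu`, a near-incompressible setting), density `rho`, growth
#' rate `k`, and natural pre-stretch `theta_nat` (the in vivo elastic *area*
#' stretch of resting skin relative to its excised, stress-free state).
#'
#' @param mu Shear modulus, MPa.
#' @param k Growth rate, day^-1: proportionality constant between area
#'   over-stretch beyond `theta_nat` and the rate of irreversible area growth.
#' @param theta_nat Natural pre-stretch (elastic area stretch), dimensionless.
#' @param rho Density, kg m^-3.
#' @param lame1 First Lame parameter, MPa. Defaults to `40 * mu`.
#' @return An object of class `material_params`.
#' @examples
#' mp <- material_params(mu = 0.058335, k = 1.2, theta_nat = 1.125, rho = 1120)
#' mp$lame1 # 40 * mu
#' @export
material_params <- function(mu, k, theta_nat, rho, lame1 = 40 * mu) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu > 0,
            is.numeric(k), length(k) == 1L, k >= 0,
            is.numeric(theta_nat), length(theta_nat) == 1L, theta_nat >= 1,
            is.numeric(rho), length(rho) == 1L, rho > 0,
            is.numeric(lame1), length(lame1) == 1L, lame1 > 0)
  structure(list(mu = mu, lame1 = lame1, rho = rho, k = k,
                 theta_nat = theta_nat),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("Material parameters (one virtual subject)\n")
  cat(sprintf("  mu        = %.6g MPa\n", x$mu))
  cat(sprintf("  lame1     = %.6g MPa (lame1/mu = %.3g)\n", x$lame1,
              x$lame1 / x$mu))
  cat(sprintf("  k         = %.6g /day\n", x$k))
  cat(sprintf("  theta_nat = %.6g\n", x$theta_nat))
  cat(sprintf("  rho       = %.6g kg/m^3\n", x$rho))
  invisible(x)
}

cofactor <- function(F) {
  d <- det(F)
  if (!is.finite(d) || abs(d) < .Machine$double.eps^0.75)
    stop("singular deformation gradient: det(F) ~ 0 is not a valid deformation")
  d * t(solve(F))
}

#' Area stretch of a material surface element
#'
#' Nanson-type area transport: a surface element with unit reference normal
#' `N` changes area by the factor `||cof(F) . N||` under a deformation with
#' gradient `F`.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param N Unit reference normal (length-3 vector).
#' @return Strictly positive scalar area stretch.
#' @examples
#' area_stretch(diag(c(1.2, 1.2, 1)), c(0, 0, 1)) # 1.44
#' @export
area_stretch <- function(F, N) {
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)), length(N) == 3L)
  if (abs(sqrt(sum(N^2)) - 1) > 1e-8)
    stop("N must be a unit vector")
  if (det(F) <= 0)
    stop("invalid deformation: det(F) must be positive")
  sqrt(sum((cofactor(F) %*% N)^2))
}

#' In-plane isotropic growth tensor
#'
#' Constructs the growth part of the deformation gradient for transversely
#' isotropic area growth: equal in-plane growth `sqrt(theta_g)` in each
#' direction of the surface plane and no growth along the normal `N`, so that
#' the grown area stretch equals `theta_g` and the thickness is unchanged.
#'
#' @param theta_g Growth area stretch (scalar, > 0; physically >= 1).
#' @param N Unit reference normal.
#' @return 3x3 growth tensor `Fg = sqrt(theta_g) (I - N N^T) + N N^T`.
#' @export
growth_tensor <- function(theta_g, N) {
  stopifnot(length(theta_g) == 1L, length(N) == 3L)
  if (!is.finite(theta_g) || theta_g <= 0)
    stop("theta_g must be positive")
  P <- outer(N, N)
  sqrt(theta_g) * (diag(3) - P) + P
}

#' Elastic part of a deformation with known growth
#'
#' Splits a total deformation gradient multiplicatively, `F = Fe Fg`, with the
#' growth part constructed from `theta_g` and `N`, and returns the elastic
#' measures entering the strain-energy function: `Fe`, the first invariant
#' `I1e = tr(Fe Fe^T)`, the elastic volume change `Je = det(Fe)` and the
#' elastic area stretch `theta_e = ||cof(Fe) . N||`. The split preserves the
#' area identity `area_stretch(F, N) = theta_g * theta_e`.
#'
#' @param F 3x3 total deformation gradient, `det(F) > 0`.
#' @param theta_g Growth area stretch.
#' @param N Unit reference normal.
#' @return An object of class `elastic_measures` with fields `Fe`, `I1e`,
#'   `Je`, `theta_e`.
#' @export
elastic_part <- function(F, theta_g, N) {
  if (det(F) <= 0) stop("invalid deformation: det(F) must be positive")
  Fg <- growth_tensor(theta_g, N)
  Fe <- F %*% solve(Fg)
  structure(list(Fe = Fe,
                 I1e = sum(Fe^2),
                 Je = det(Fe),
                 theta_e = area_stretch(Fe, N)),
            class = "elastic_measures")
}

#' Neo-Hookean strain-energy density
#'
#' Compressible neo-Hookean energy of the elastic part of the deformation,
#' `Psi = mu/2 (I1e - 3) + lame1/2 ln^2(Je)`, in MPa. Zero exactly when `Fe`
#' is a rotation.
#'
#' @param em `elastic_measures` as returned by [elastic_part()], or any list
#'   with fields `I1e` and `Je`.
#' @param mp [material_params()].
#' @return Energy density, MPa.
#' @export
strain_energy <- function(em, mp) {
  stopifnot(em$Je > 0)
  mp$mu / 2 * (em$I1e - 3) + mp$lame1 / 2 * log(em$Je)^2
}

#' Cauchy stress of the neo-Hookean material
#'
#' Standard Cauchy stress derived from the strain energy:
#' `sigma = (mu (be - I) + lame1 ln(Je) I) / Je` with `be = Fe Fe^T`.
#' Symmetric; vanishes when `Fe` is a rotation.
#'
#' @inheritParams strain_energy
#' @return 3x3 symmetric Cauchy stress tensor, MPa.
#' @export
cauchy_stress <- function(em, mp) {
  stopifnot(em$Je > 0)
  be <- em$Fe %*% t(em$Fe)
  (mp$mu * (be - diag(3)) + mp$lame1 * log(em$Je) * diag(3)) / em$Je
}

#' Stretch-driven growth rate
#'
#' Rate of irreversible area growth: proportional to the elastic area stretch
#' in excess of the natural pre-stretch, `k * (theta_e - theta_nat)`, and
#' rectified at zero below the natural pre-stretch (stretch short of the
#' natural state does not shrink the skin).
#'
#' @param theta_e Elastic area stretch (vectorised).
#' @param mp [material_params()].
#' @return Growth rate(s), day^-1.
#' @export
growth_rate <- function(theta_e, mp) {
  stopifnot(all(theta_e > 0))
  mp$k * pmax(0, theta_e - mp$theta_nat)
}

# One explicit-midpoint step of d(theta_g)/dt = k max(0, Theta/theta_g -
# theta_nat) for vector/matrix states held at fixed total stretch Theta.
growth_step <- function(theta_g, Theta, mp, dt) {
  f1 <- mp$k * pmax(0, Theta / theta_g - mp$theta_nat)
  th_half <- theta_g + dt / 2 * f1
  f2 <- mp$k * pmax(0, Theta / th_half - mp$theta_nat)
  theta_g + dt * f2
}

#' Growth trajectory of a homogeneously stretched patch
#'
#' Integrates the growth law for a patch held at fixed total area stretch
#' `Theta`, so that the elastic stretch is `theta_e = Theta / theta_g` at
#' every instant. Starting from `theta_g = 1`, growth monotonically converts
#' elastic stretch into permanent area gain until `theta_e` relaxes to the
#' natural pre-stretch; the steady state is `theta_g = Theta / theta_nat`
#' (when `Theta > theta_nat`; otherwise no growth occurs).
#'
#' Integration uses an explicit midpoint scheme with step `dt` (default 0.01
#' day, small against the fastest relaxation time in the sampled parameter
#' ranges); the final step is shortened to land exactly on `t_end`.
#'
#' @param Theta Total area stretch held fixed (>= 1).
#' @param mp [material_params()].
#' @param t_end End time, days.
#' @param dt Time step, days (> 0).
#' @return A data frame with columns `t`, `theta_g`, `theta_e`.
#' @examples
#' mp <- material_params(0.058335, 1.2, 1.125, 1120)
#' tr <- integrate_homogeneous(1.5, mp, t_end = 7)
#' tail(tr, 1) # theta_g approaching 1.5 / 1.125
#' @export
integrate_homogeneous <- function(Theta, mp, t_end, dt = 0.01) {
  stopifnot(length(Theta) == 1L, Theta >= 1, t_end >= 0)
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  n <- if (t_end == 0) 0L else as.integer(ceiling(t_end / dt - 1e-9))
  t <- c(if (n > 0) seq(0, by = dt, length.out = n) else 0, t_end)
  t <- unique(pmin(t, t_end))
  th <- numeric(length(t))
  th[1] <- 1
  for (i in seq_along(t)[-1])
    th[i] <- growth_step(th[i - 1], Theta, mp, t[i] - t[i - 1])
  data.frame(t = t, theta_g = th, theta_e = Theta / th)
}

#' Thickness stretch under plane stress
#'
#' Solves the zero-normal-stress condition `sigma_33 = 0` for the elastic
#' thickness stretch `lam3` of a membrane point with in-plane elastic
#' stretches `lam1e`, `lam2e` under the neo-Hookean material, i.e. the root of
#' `mu (lam3^2 - 1) + lame1 ln(lam1e lam2e lam3) = 0`, which is strictly
#' increasing in `lam3` and therefore unique. Vectorised over the in-plane
#' stretches; solved by safeguarded Newton iteration.
#'
#' @param lam1e,lam2e In-plane elastic principal stretches (> 0, vectorised).
#' @param mp [material_params()].
#' @param tol Convergence tolerance on the normal Cauchy stress, MPa.
#' @return Thickness stretch(es) `lam3 > 0`.
#' @export
plane_stress_thickness <- function(lam1e, lam2e, mp, tol = 1e-12) {
  stopifnot(all(lam1e > 0), all(lam2e > 0))
  A <- lam1e * lam2e
  # near-incompressible initial guess: Je = 1
  x <- 1 / A
  g <- function(x) mp$mu * (x^2 - 1) + mp$lame1 * log(A * x)
  for (it in 1:100) {
    gx <- g(x)
    if (all(abs(gx) < tol)) break
    step <- gx / (2 * mp$mu * x + mp$lame1 / x)
    x_new <- x - step
    # safeguard: keep iterates positive
    x <- ifelse(x_new > 0, x_new, x / 2)
  }
  Je <- A * x
  resid <- abs(g(x)) / Je # sigma_33 in MPa
  if (any(resid > 1e-10) || any(!is.finite(x)))
    stop(sprintf(
      "plane-stress thickness solve failed to converge (max |sigma_33| = %g MPa)",
      max(resid)))
  x
}

# In-plane Cauchy stress of a locally equi-biaxial membrane point with
# elastic area stretch theta_e: lam_e = sqrt(theta_e) in each in-plane
# direction, thickness stretch from plane stress. Returns a list with the
# isotropic in-plane stress (MPa), the thickness stretch and Je. Vectorised.
equibiaxial_membrane_stress <- function(theta_e, mp) {
  lam <- sqrt(theta_e)
  lam3 <- plane_stress_thickness(lam, lam, mp)
  Je <- theta_e * lam3
  sigma <- (mp$mu * (theta_e - 1) + mp$lame1 * log(Je)) / Je
  list(sigma = sigma, lam3 = lam3, Je = Je)
}
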