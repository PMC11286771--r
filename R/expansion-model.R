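# Reduced membrane model of the expanded skin patch. One quarter of a
# rectangular skin block is modelled (the expander has two mirror planes);
# the expander-dome deformation is imposed geometrically on top of an
# isotropic natural pre-stretch, growth then evolves point-wise under held
# displacement. This keeps every constitutive and growth equation exact while
# omitting the in-plane equilibrium redistribution a full 3D solver performs.

#' Quarter-domain patch grid
#'
#' Regular cell grid over the quarter skin patch `[0, Lx] x [0, Ly]` with the
#' symmetry edges at `x = 0` and `y = 0`. Reference dimensions default to one
#' quarter of a 100 mm x 75 mm x 3 mm skin block.
#'
#' @param lx,ly Quarter-domain reference dimensions, mm.
#' @param h Reference thickness, mm.
#' @param nx,ny Number of cells along x and y.
#' @return An object of class `patch_grid` with node coordinates (`x_nodes`,
#'   `y_nodes`; `(nx+1) (ny+1)` nodes), cell-centre coordinates (`x_cells`,
#'   `y_cells`), spacings `dx`, `dy` and the cell area.
#' @export
build_patch <- function(lx = 50, ly = 37.5, h = 3, nx = 40, ny = 30) {
  stopifnot(lx > 0, ly > 0, h > 0, nx >= 1, ny >= 1)
  nx <- as.integer(nx); ny <- as.integer(ny)
  dx <- lx / nx; dy <- ly / ny
  structure(list(
    lx = lx, ly = ly, h = h, nx = nx, ny = ny, dx = dx, dy = dy,
    x_nodes = seq(0, lx, length.out = nx + 1L),
    y_nodes = seq(0, ly, length.out = ny + 1L),
    x_cells = (seq_len(nx) - 0.5) * dx,
    y_cells = (seq_len(ny) - 0.5) * dy,
    cell_area = dx * dy), class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf(
    "Quarter skin patch: %g x %g x %g mm, %d x %d cells (dx = %g, dy = %g mm)\n",
    x$lx, x$ly, x$h, x$nx, x$ny, x$dx, x$dy))
  invisible(x)
}

#' Expander dome profile
#'
#' Smooth dome standing in for the inflated rectangular tissue expander on
#' the quarter domain: `z(x, y) = h_apex cos(pi x / 2a) cos(pi y / 2b)` on
#' the footprint `[0, a] x [0, b]`, zero outside, apex at the symmetry corner.
#'
#' @param a,b Quarter-footprint half-spans along x and y, mm.
#' @param h_apex Dome apex height, mm.
#' @return An object of class `expander_profile`.
#' @seealso [calibrate_apex()] to choose `h_apex` for a requested peak
#'   stretch.
#' @export
expander_profile <- function(a = 50, b = 37.5, h_apex = 23.4) {
  stopifnot(a > 0, b > 0, h_apex >= 0)
  structure(list(a = a, b = b, h_apex = h_apex), class = "expander_profile")
}

# Dome height and analytic gradient, vectorised over point coordinates.
dome_height <- function(profile, x, y) {
  inside <- x <= profile$a & y <= profile$b
  z <- ifelse(inside,
              profile$h_apex * cos(pi * x / (2 * profile$a)) *
                cos(pi * y / (2 * profile$b)), 0)
  z
}

dome_grad_sq <- function(profile, x, y) {
  a <- profile$a; b <- profile$b; h <- profile$h_apex
  inside <- x <= a & y <= b
  zx <- -h * pi / (2 * a) * sin(pi * x / (2 * a)) * cos(pi * y / (2 * b))
  zy <- -h * pi / (2 * b) * cos(pi * x / (2 * a)) * sin(pi * y / (2 * b))
  ifelse(inside, zx^2 + zy^2, 0)
}

#' Calibrate the dome apex height for a requested peak stretch
#'
#' Chooses `h_apex` so that the peak of `Theta / theta_nat` (the geometric
#' area-stretch factor of the dome) equals `peak_ratio`. The dome gradient is
#' largest at the footprint mid-edge of the shorter half-span, where
#' `|grad z| = h_apex * pi / (2 min(a, b))`.
#'
#' @param profile [expander_profile()] providing the footprint.
#' @param peak_ratio Requested peak `sqrt(1 + |grad z|^2)` (> 1).
#' @return A new `expander_profile` with the calibrated apex height.
#' @export
calibrate_apex <- function(profile, peak_ratio) {
  stopifnot(peak_ratio > 1)
  s <- min(profile$a, profile$b)
  expander_profile(profile$a, profile$b,
                   h_apex = 2 * s / pi * sqrt(peak_ratio^2 - 1))
}

#' Total area-stretch field imposed by pre-stretch and expander
#'
#' The skin is first taken to its isotropic natural pre-stretch (area stretch
#' `theta_nat` everywhere), then deformed over the expander dome; the membrane
#' area-stretch factor of mapping the flat plane onto the dome surface is
#' `sqrt(1 + |grad z|^2)`. The total held area stretch is their product, so
#' `Theta = theta_nat` outside the footprint and `Theta >= theta_nat`
#' everywhere.
#'
#' @param grid [build_patch()].
#' @param profile [expander_profile()].
#' @param theta_nat Natural pre-stretch (>= 1).
#' @param at Evaluate at `"cells"` (default) or `"nodes"`.
#' @return Matrix of `Theta` values (`nx x ny` for cells,
#'   `(nx+1) x (ny+1)` for nodes; rows index x).
#' @export
total_area_stretch <- function(grid, profile, theta_nat, at = c("cells", "nodes")) {
  stopifnot(theta_nat >= 1)
  at <- match.arg(at)
  xs <- if (at == "cells") grid$x_cells else grid$x_nodes
  ys <- if (at == "cells") grid$y_cells else grid$y_nodes
  g2 <- outer(xs, ys, function(x, y) dome_grad_sq(profile, x, y))
  theta_nat * sqrt(1 + g2)
}

#' Growth-field state of the patch
#'
#' Container for the per-cell (or per-node) state of the held patch: total
#' area stretch `Theta` (fixed while the expander is held), growth stretch
#' `theta_g` and elastic stretch `theta_e = Theta / theta_g`.
#'
#' @param Theta Matrix of total area stretches (>= theta_nat).
#' @param theta_g Matrix of growth stretches; defaults to 1 (no growth yet).
#' @return An object of class `growth_field`.
#' @export
growth_field <- function(Theta, theta_g = NULL) {
  stopifnot(is.matrix(Theta), all(Theta >= 1))
  if (is.null(theta_g)) theta_g <- array(1, dim(Theta))
  stopifnot(all(dim(theta_g) == dim(Theta)), all(theta_g >= 1))
  structure(list(Theta = Theta, theta_g = theta_g,
                 theta_e = Theta / theta_g, t = 0),
            class = "growth_field")
}

#' Evolve the growth field under held displacement
#'
#' Advances every point of the field through the homogeneous growth law for
#' `t_end` days at fixed local `Theta` (the hold phase of the expansion
#' protocol): point-wise `d theta_g / dt = k max(0, Theta/theta_g -
#' theta_nat)` with `theta_g(0)` taken from the field, integrated by the same
#' explicit midpoint scheme as [integrate_homogeneous()].
#'
#' @param field [growth_field()].
#' @param mp [material_params()].
#' @param t_end Hold duration, days (>= 0).
#' @param dt Time step, days.
#' @return The evolved `growth_field` (with `t` advanced by `t_end`).
#' @export
evolve_growth <- function(field, mp, t_end, dt = 0.01) {
  stopifnot(inherits(field, "growth_field"), t_end >= 0, dt > 0)
  th <- field$theta_g
  if (t_end > 0) {
    n <- as.integer(ceiling(t_end / dt - 1e-9))
    steps <- c(rep(dt, n - 1L), t_end - (n - 1L) * dt)
    for (s in steps) th <- growth_step(th, field$Theta, mp, s)
  }
  out <- field
  out$theta_g <- th
  out$theta_e <- field$Theta / th
  out$t <- field$t + t_end
  out
}

#' In-plane membrane stress field
#'
#' Per-point Cauchy stress of the held membrane under the locally
#' equi-biaxial approximation: each point carries elastic in-plane stretch
#' `lam_e = sqrt(theta_e)` in both directions, the thickness stretch follows
#' from plane stress ([plane_stress_thickness()]), and the in-plane stress is
#' isotropic. As growth converts elastic stretch into permanent area, the
#' stress relaxes towards the (non-zero) natural pre-stretch stress.
#'
#' @param field [growth_field()].
#' @param mp [material_params()].
#' @return List with matrices `sigma` (isotropic in-plane Cauchy stress,
#'   MPa), `lam3` (elastic thickness stretch) and `Je`.
#' @export
stress_field <- function(field, mp) {
  stopifnot(inherits(field, "growth_field"))
  s <- equibiaxial_membrane_stress(field$theta_e, mp)
  s$sigma <- array(s$sigma, dim(field$Theta))
  s$lam3 <- array(s$lam3, dim(field$Theta))
  s$Je <- array(s$Je, dim(field$Theta))
  s
}
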