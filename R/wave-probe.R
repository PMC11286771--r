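# Explicit-dynamics probe of the held membrane: a short pressure impulse
# excites a transverse (out-of-plane) wave whose local speed sqrt(sigma/rho)
# is set by the in-plane skin tension; the receiver waveform therefore
# encodes the tension state, which relaxes as growth proceeds. The wave runs
# on the flat reference plane with the heterogeneous tension field of the
# current protocol stage.

# Unit constant: 1 MPa / (kg m^-3) = 1e6 m^2 s^-2 = 1e12 mm^2 s^-2. The only
# place where MPa / (kg m^-3) is converted to the mm/s unit system.
MPA_PER_KG_M3_IN_MM2_S2 <- 1e12

# Fraction of each node's dual cell covered by a disc of radius r0 centred
# at xy0, by midpoint subsampling (ns x ns per cell).
disc_coverage <- function(x_nodes, y_nodes, dx, dy, xy0, r0, ns = 16L) {
  out <- matrix(0, length(x_nodes), length(y_nodes))
  reach <- r0 + max(dx, dy)
  ix <- which(abs(x_nodes - xy0[1]) <= reach)
  iy <- which(abs(y_nodes - xy0[2]) <= reach)
  if (!length(ix) || !length(iy)) return(out)
  off_x <- ((seq_len(ns) - 0.5) / ns - 0.5) * dx
  off_y <- ((seq_len(ns) - 0.5) / ns - 0.5) * dy
  for (i in ix) for (j in iy) {
    px <- x_nodes[i] + off_x
    py <- y_nodes[j] + off_y
    d2 <- outer(px - xy0[1], py - xy0[2], function(a, b) a^2 + b^2)
    out[i, j] <- mean(d2 <= r0^2)
  }
  out
}

#' Impact and receiver configuration for a wave experiment
#'
#' @param p0 Impulse pressure, MPa.
#' @param t_pulse Pulse duration, s.
#' @param r0 Impactor disc radius, mm.
#' @param impact_xy Impact centre `(x, y)`, mm. The default places the probe
#'   pair on the dome flank, where the held tension (and hence the wave
#'   speed) contrasts strongly between the protocol stages.
#' @param recv_xy Receiver location `(x, y)`, mm; defaults 5 mm from the
#'   impact centre, toward the apex.
#' @param duration Recording window, s.
#' @param cfl Courant factor for the explicit time step.
#' @return An object of class `impact_config`.
#' @export
impact_config <- function(p0 = 0.5, t_pulse = 2e-5, r0 = 1.0,
                          impact_xy = c(20, 15), recv_xy = c(15, 15),
                          duration = 0.0125, cfl = 0.5) {
  stopifnot(p0 >= 0, t_pulse > 0, r0 > 0, length(impact_xy) == 2L,
            length(recv_xy) == 2L, duration > 0, cfl > 0, cfl <= 1)
  structure(list(p0 = p0, t_pulse = t_pulse, r0 = r0,
                 impact_xy = impact_xy, recv_xy = recv_xy,
                 duration = duration, cfl = cfl),
            class = "impact_config")
}

#' Transverse membrane wave on a heterogeneous tension field
#'
#' Integrates `rho h w_tt = div(sigma h grad w) + p(t)` for the out-of-plane
#' displacement `w` (mm) on the quarter-domain node grid by explicit central
#' differences with lumped mass. `tension = sigma h` (MPa mm) and
#' `areal_density = rho h` (kg m^-3 mm) are nodal fields. Boundary
#' conditions: symmetry (zero normal derivative) on the `x = 0` and `y = 0`
#' edges, clamped (`w = 0`) on the outer edges. The pressure `p0` acts on
#' nodes within `r0` of the impact centre for `t <= t_pulse`. The time step
#' is `cfl * min(dx, dy) / c_max` with `c_max = sqrt(max(sigma)/rho)`.
#'
#' @param grid [build_patch()].
#' @param tension Nodal `sigma * h` field, MPa mm (`(nx+1) x (ny+1)`).
#' @param areal_density Nodal `rho * h` field (kg m^-3 mm), or a scalar.
#' @param impact [impact_config()].
#' @param diagnostics If `TRUE`, also return the discrete energy trace (the
#'   conserved mixed-product energy of the central scheme), evaluated after
#'   the pulse ends.
#' @return An object of class `waveform`: list with `t` (s, starting at 0),
#'   `w` (mm, receiver displacement), `dt`, the snapped receiver node, and
#'   optionally `energy`.
#' @export
simulate_membrane_wave <- function(grid, tension, areal_density, impact,
                                   diagnostics = FALSE) {
  nx1 <- grid$nx + 1L; ny1 <- grid$ny + 1L
  stopifnot(is.matrix(tension), all(dim(tension) == c(nx1, ny1)),
            all(is.finite(tension)), all(tension > 0))
  if (length(areal_density) == 1L)
    areal_density <- matrix(areal_density, nx1, ny1)
  stopifnot(all(dim(areal_density) == c(nx1, ny1)), all(areal_density > 0))
  inside <- function(p) p[1] >= 0 && p[1] <= grid$lx && p[2] >= 0 && p[2] <= grid$ly
  if (!inside(impact$impact_xy) || !inside(impact$recv_xy))
    stop("impact and receiver must lie inside the patch domain")

  dx <- grid$dx; dy <- grid$dy
  # wave speed in mm/s; tension/areal_density = sigma/rho in MPa/(kg m^-3)
  c2 <- tension / areal_density * MPA_PER_KG_M3_IN_MM2_S2
  c_max <- sqrt(max(c2))
  dt <- impact$cfl * min(dx, dy) / c_max
  nsteps <- as.integer(ceiling(impact$duration / dt)) + 1L
  if (!is.finite(dt) || dt <= 0)
    stop("unstable configuration: non-positive time step")

  # face tensions (arithmetic mean of adjacent nodes)
  tx <- (tension[-1, ] + tension[-nx1, ]) / 2        # nx x ny1 faces in x
  ty <- (tension[, -1] + tension[, -ny1]) / 2        # nx1 x ny faces in y

  # forcing: the disc pressure is distributed by the fraction of each node's
  # dual cell covered by the impactor disc (deterministic 16x16 subsampling),
  # so the total impulse p0 * pi * r0^2 is conserved under grid refinement
  frac <- disc_coverage(grid$x_nodes, grid$y_nodes, dx, dy,
                        impact$impact_xy, impact$r0)
  if (all(frac == 0)) { # sub-cell disc on a very coarse grid: nearest node
    dist2 <- outer(grid$x_nodes, grid$y_nodes,
                   function(x, y) (x - impact$impact_xy[1])^2 +
                     (y - impact$impact_xy[2])^2)
    frac[which.min(dist2)] <- pi * impact$r0^2 / (dx * dy)
  }
  accel_src <- impact$p0 * frac / areal_density * MPA_PER_KG_M3_IN_MM2_S2 # mm/s^2

  ir <- which.min(abs(grid$x_nodes - impact$recv_xy[1]))
  jr <- which.min(abs(grid$y_nodes - impact$recv_xy[2]))

  lap <- function(w) {
    # div(tension grad w) / (dx dy) with symmetry at x=0,y=0 (ghost mirror)
    gx <- tx * (w[-1, ] - w[-nx1, ]) / dx            # nx x ny1
    gy <- ty * (w[, -1] - w[, -ny1]) / dy            # nx1 x ny
    out <- matrix(0, nx1, ny1)
    out[2:(nx1 - 1L), ] <- (gx[-1, ] - gx[-grid$nx, ]) / dx
    out[1, ] <- gx[1, ] / (dx / 2) # mirror ghost: flux through x=0 face is 0
    out[, 2:(ny1 - 1L)] <- out[, 2:(ny1 - 1L)] +
      (gy[, -1] - gy[, -grid$ny]) / dy
    out[, 1] <- out[, 1] + gy[, 1] / (dy / 2)
    out
  }

  w <- matrix(0, nx1, ny1)
  w_prev <- w
  rec <- numeric(nsteps + 1L)
  tgrid <- (0:nsteps) * dt
  energy <- if (diagnostics) rep(NA_real_, nsteps) else NULL
  inv_m <- MPA_PER_KG_M3_IN_MM2_S2 / areal_density

  clamp <- function(w) { w[nx1, ] <- 0; w[, ny1] <- 0; w }

  for (n in seq_len(nsteps)) {
    t_now <- tgrid[n]
    a <- lap(w) * inv_m
    # impulse-conserving pulse: weight by the overlap of [t, t+dt] with the
    # pulse window, so the delivered impulse p0 * t_pulse is dt-independent
    pulse_frac <- max(0, min(impact$t_pulse, t_now + dt) - t_now) / dt
    if (pulse_frac > 0) a <- a + accel_src * pulse_frac
    w_next <- clamp(2 * w - w_prev + dt^2 * a)
    if (!all(is.finite(w_next)))
      stop(sprintf("wave solver produced non-finite values at step %d (t = %g s); CFL violation likely", n, t_now))
    if (diagnostics && t_now > impact$t_pulse) {
      v <- (w_next - w) / dt
      # conserved mixed-product energy of the central scheme, with dual-cell
      # node weights (half on boundary rows/columns)
      wx <- c(0.5, rep(1, nx1 - 2L), 0.5); wy <- c(0.5, rep(1, ny1 - 2L), 0.5)
      gx1 <- (w[-1, ] - w[-nx1, ]) / dx; gx2 <- (w_next[-1, ] - w_next[-nx1, ]) / dx
      gy1 <- (w[, -1] - w[, -ny1]) / dy; gy2 <- (w_next[, -1] - w_next[, -ny1]) / dy
      pot <- sum(sweep(tx * gx1 * gx2, 2, wy, `*`)) * dx * dy +
        sum(sweep(ty * gy1 * gy2, 1, wx, `*`)) * dx * dy
      kin <- sum(outer(wx, wy) * v^2 / inv_m) * dx * dy
      energy[n] <- 0.5 * (kin + pot)
    }
    w_prev <- w
    w <- w_next
    rec[n + 1L] <- w[ir, jr]
  }

  structure(list(t = tgrid, w = rec, dt = dt,
                 recv_node = c(grid$x_nodes[ir], grid$y_nodes[jr]),
                 energy = energy),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("Waveform: %d samples, dt = %.3g s, window [0, %.4g] s, peak |w| = %.3g mm\n",
              length(x$t), x$dt, max(x$t), max(abs(x$w))))
  invisible(x)
}

#' First-arrival time of a waveform
#'
#' Onset detector: first time the absolute displacement exceeds a fraction of
#' its peak.
#'
#' @param wf [simulate_membrane_wave()] result (or any list with `t`, `w`).
#' @param frac Detection threshold as a fraction of the peak |w|.
#' @return Arrival time, s.
#' @export
arrival_time <- function(wf, frac = 0.1) {
  peak <- max(abs(wf$w))
  if (peak == 0) return(NA_real_)
  wf$t[which(abs(wf$w) >= frac * peak)[1]]
}

#' Stage arrival times of a subject record
#'
#' Compares the first-arrival times of the three protocol waveforms with a
#' threshold shared across the stages (a fraction of the *baseline* peak), so
#' the comparison is not distorted by stage-to-stage amplitude differences.
#' As tension rises with expansion and relaxes back with growth, the expected
#' ordering is `day0 < day3p5 <= baseline`.
#'
#' @param record `subject_record` from [run_protocol()].
#' @param frac Threshold as a fraction of the baseline peak displacement.
#' @return Named numeric vector of arrival times (s): `baseline`, `day0`,
#'   `day3p5`.
#' @export
protocol_arrivals <- function(record, frac = 0.05) {
  thr <- frac * max(abs(record$waveforms$baseline$w))
  vapply(record$waveforms,
         function(wf) wf$t[which(abs(wf$w) >= thr)[1]], numeric(1))
}

#' Probe one protocol stage of a held growth field
#'
#' Computes the membrane tension of the current field state via
#' [stress_field()] (current thickness `h lam3`, no thickness growth) and
#' runs the wave experiment on it.
#'
#' @param field [growth_field()] evaluated at grid *nodes*.
#' @param grid [build_patch()].
#' @param mp [material_params()].
#' @param impact [impact_config()].
#' @param ... Passed to [simulate_membrane_wave()].
#' @return A `waveform`.
#' @export
simulate_wave <- function(field, grid, mp, impact = impact_config(), ...) {
  sf <- stress_field(field, mp)
  tension <- sf$sigma * grid$h * sf$lam3
  areal_density <- mp$rho * grid$h * sf$lam3 # current thickness h * lam3
  simulate_membrane_wave(grid, tension, areal_density, impact, ...)
}

#' Run the full measurement protocol for one subject
#'
#' The four-stage protocol probed at the receiver:
#' 1. baseline — skin held at the natural pre-stretch only (no expander);
#' 2. day 0 — expander inflated, held for `t0_days` (default 1e-5 day,
#'    under a second) before probing;
#' 3. day 3.5 — same configuration held for `t_mid_days`;
#' 4. day 7 — growth field after `t_final_days`, stored as the prediction
#'    target (no waveform).
#'
#' @param mp [material_params()] for the subject.
#' @param grid [build_patch()].
#' @param profile [expander_profile()].
#' @param impact [impact_config()].
#' @param t0_days,t_mid_days,t_final_days Hold durations of the three growth
#'   stages, days.
#' @param growth_dt Growth integration step, days.
#' @return An object of class `subject_record`: list with `waveforms` (named
#'   list `baseline`, `day0`, `day3p5`), `growth_day7` (cell-centre `theta_g`
#'   matrix), `field_day7` (full `growth_field`), and `mp`.
#' @export
run_protocol <- function(mp, grid = build_patch(), profile = expander_profile(),
                         impact = impact_config(), t0_days = 1e-5,
                         t_mid_days = 3.5, t_final_days = 7,
                         growth_dt = 0.01) {
  # node fields drive the wave; cell fields carry the growth targets
  Theta_n <- total_area_stretch(grid, profile, mp$theta_nat, at = "nodes")
  Theta_c <- total_area_stretch(grid, profile, mp$theta_nat, at = "cells")
  base_n <- growth_field(array(mp$theta_nat, dim(Theta_n)))

  wf_base <- simulate_wave(base_n, grid, mp, impact)

  f_n <- evolve_growth(growth_field(Theta_n), mp, t0_days, dt = growth_dt)
  wf_day0 <- simulate_wave(f_n, grid, mp, impact)

  f_n <- evolve_growth(f_n, mp, t_mid_days - t0_days, dt = growth_dt)
  wf_day35 <- simulate_wave(f_n, grid, mp, impact)

  f_c <- evolve_growth(growth_field(Theta_c), mp, t_final_days, dt = growth_dt)

  structure(list(
    waveforms = list(baseline = wf_base, day0 = wf_day0, day3p5 = wf_day35),
    growth_day7 = f_c$theta_g,
    field_day7 = f_c,
    mp = mp),
    class = "subject_record")
}
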