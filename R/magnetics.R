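# Dipolar-field model of a magnetized object over a rectangular GMR sensing
# element. All quantities are SI internally: meters, tesla, A.m^2. Magnetic
# moments quoted in emu by bead datasheets are converted at the boundary
# (1 emu = 1e-3 A.m^2). Fields are emitted in tesla, i.e. the mu0/4pi
# prefactor is included in front of the CGS-style dipole expression.

.mu0_4pi <- 1e-7
.EMU_TO_SI <- 1e-3

#' Rectangular GMR sensor geometry
#'
#' Describes the active area of a spin-valve sensing element as its bounding
#' rectangle, long axis along x, short axis along y. The sensor responds to
#' the surface average of the y-component of the field (the pinned-layer
#' direction); `detectivity` is the smallest field amplitude distinguishable
#' from noise, conventionally three times the measured noise level.
#'
#' @param length_L long-axis extent in meters (default 120 um).
#' @param width_l short-axis extent in meters (default 4 um); must be smaller
#'   than `length_L`.
#' @param plane_z height of the sensor plane in meters (default 0).
#' @param detectivity smallest detectable field amplitude, tesla
#'   (default 2.2 uT, the pooled analysis threshold).
#' @return an object of class `sensor_geometry`.
#' @export
#' @examples
#' sensor_geometry()
sensor_geometry <- function(length_L = 120e-6, width_l = 4e-6, plane_z = 0,
                            detectivity = 2.2e-6) {
  stopifnot(length_L > 0, width_l > 0, detectivity > 0)
  if (length_L <= width_l)
    stop("'length_L' must exceed 'width_l' (long axis is x)")
  structure(list(length_L = length_L, width_l = width_l, plane_z = plane_z,
                 detectivity = detectivity),
            class = "sensor_geometry")
}

#' @export
print.sensor_geometry <- function(x, ...) {
  cat(sprintf("GMR sensor: %.1f um x %.1f um at z = %.2f um, detectivity %.3g uT\n",
              x$length_L * 1e6, x$width_l * 1e6, x$plane_z * 1e6,
              x$detectivity * 1e6))
  invisible(x)
}

#' Superparamagnetic bead magnetic properties
#'
#' Moments are supplied in emu (as printed on datasheets and magnetometry
#' reports) and stored in A.m^2. `moment_operating` is the moment reached at
#' the operating field of the permanent magnet (90 mT for the reference
#' system), necessarily no larger than the saturation moment.
#'
#' @param diameter bead diameter in meters (default 1 um, Dynabeads MyOne).
#' @param moment_sat_emu per-bead saturation moment, emu (default 2.1e-11).
#' @param moment_op_emu per-bead moment at the operating field, emu
#'   (default 1.6e-11).
#' @return an object of class `bead_magnetics` with fields
#'   `moment_saturation` and `moment_operating` in A.m^2.
#' @export
bead_magnetics <- function(diameter = 1e-6, moment_sat_emu = 2.1e-11,
                           moment_op_emu = 1.6e-11) {
  stopifnot(diameter > 0, moment_sat_emu > 0, moment_op_emu > 0)
  if (moment_op_emu > moment_sat_emu)
    stop("operating moment cannot exceed saturation moment")
  structure(list(diameter = diameter,
                 moment_saturation = moment_sat_emu * .EMU_TO_SI,
                 moment_operating = moment_op_emu * .EMU_TO_SI),
            class = "bead_magnetics")
}

#' @export
print.bead_magnetics <- function(x, ...) {
  cat(sprintf("bead: d = %.2f um, m_sat = %.3g A.m^2, m_op = %.3g A.m^2\n",
              x$diameter * 1e6, x$moment_saturation, x$moment_operating))
  invisible(x)
}

#' Point-dipole state
#'
#' Position and moment of a single magnetized bead (or a co-located cluster).
#' `theta` is the tilt of the moment from the vertical (z) axis, `psi` its
#' azimuth measured from the sensor long axis (x).
#'
#' @param position numeric length-3, (xB, yB, zB) in meters.
#' @param moment moment magnitude in A.m^2.
#' @param theta polar angle to z, radians, in `[0, pi]`.
#' @param psi azimuthal angle to x, radians.
#' @return an object of class `dipole_state`.
#' @export
dipole_state <- function(position, moment, theta = 0, psi = 0) {
  stopifnot(length(position) == 3, is.finite(position), moment > 0,
            theta >= 0, theta <= pi)
  structure(list(position = as.numeric(position), moment = moment,
                 theta = theta, psi = psi),
            class = "dipole_state")
}

#' Magnetic field of a point dipole
#'
#' Field in tesla at an observation point, for `n_beads` co-located beads
#' (the field is exactly linear in `n_beads`):
#' `B = mu0/(4 pi) * (3 (r . m) r / |r|^5 - m / |r|^3)` with `r` running from
#' the dipole to the observation point and `m` the total moment vector.
#'
#' @param dipole a [dipole_state()].
#' @param observation numeric length-3 observation point, meters.
#' @param n_beads number of co-located beads sharing the dipole state.
#' @return numeric length-3 field vector `(Bx, By, Bz)` in tesla.
#' @export
#' @examples
#' d <- dipole_state(c(0, 0, 5e-6), moment = 1.6e-14)
#' point_dipole_field(d, c(0, 0, 0))  # purely axial below a vertical moment
point_dipole_field <- function(dipole, observation, n_beads = 1) {
  stopifnot(inherits(dipole, "dipole_state"), length(observation) == 3,
            n_beads >= 1)
  r <- as.numeric(observation) - dipole$position
  rn <- sqrt(sum(r^2))
  if (rn == 0)
    stop("observation point coincides with the dipole position")
  m <- n_beads * dipole$moment *
    c(sin(dipole$theta) * cos(dipole$psi),
      sin(dipole$theta) * sin(dipole$psi),
      cos(dipole$theta))
  .mu0_4pi * (3 * sum(r * m) * r / rn^5 - m / rn^3)
}

# Closed-form surface average of the y-component of the dipolar field over
# the sensor rectangle [-L/2, L/2] x [-l/2, l/2] at height h below the dipole.
# Corner-evaluated antiderivatives of the three moment projections:
#   m_x term: 1/R,  m_y term: -u v / (q^2 R),  m_z term: h u / (q^2 R)
# with u, v relative to the dipole and q^2 = v^2 + h^2. Fully vectorized over
# the dipole coordinates.
.hy_closed <- function(xB, yB, h, moment, theta, psi, L, l) {
  xl <- -L / 2 - xB; xr <- L / 2 - xB
  yl <- -l / 2 - yB; yr <- l / 2 - yB
  r1 <- sqrt(xl^2 + yl^2 + h^2); r2 <- sqrt(xr^2 + yl^2 + h^2)
  r3 <- sqrt(xr^2 + yr^2 + h^2); r4 <- sqrt(xl^2 + yr^2 + h^2)
  q2 <- yl^2 + h^2; q4 <- yr^2 + h^2
  sA <- 1 / r1 - 1 / r2 + 1 / r3 - 1 / r4
  sB <- (yl / q2) * (xr / r2 - xl / r1) + (yr / q4) * (xl / r4 - xr / r3)
  sC <- (h / q2) * (xl / r1 - xr / r2) + (h / q4) * (xr / r3 - xl / r4)
  .mu0_4pi * moment / (L * l) *
    (sin(theta) * sin(psi) * sB + sin(theta) * cos(psi) * sA +
       cos(theta) * sC)
}

#' Sensor-averaged in-plane field, closed form
#'
#' Surface average over the sensor rectangle of the y-component of the
#' dipolar field of a magnetized bead, evaluated in closed form. For a
#' vertical moment (`theta = 0`) the result is an odd function of the bead's
#' y-offset, which is the physical origin of the bipolar transit pulse.
#'
#' @param dipole a [dipole_state()]; its height above the sensor plane must
#'   be positive.
#' @param sensor a [sensor_geometry()].
#' @return scalar averaged field in tesla.
#' @seealso [sensor_averaged_hy_quadrature()] for the numerical oracle this
#'   expression is validated against.
#' @export
sensor_averaged_hy <- function(dipole, sensor) {
  stopifnot(inherits(dipole, "dipole_state"), inherits(sensor, "sensor_geometry"))
  h <- dipole$position[3] - sensor$plane_z
  if (h <= 0)
    stop("dipole must lie strictly above the sensor plane (h > 0)")
  .hy_closed(dipole$position[1], dipole$position[2], h, dipole$moment,
             dipole$theta, dipole$psi, sensor$length_L, sensor$width_l)
}

#' Sensor-averaged in-plane field, adaptive quadrature
#'
#' Numerical oracle for [sensor_averaged_hy()]: integrates the y-component of
#' the point-dipole field over the sensor rectangle with nested adaptive
#' quadrature and divides by the sensor area. The integration is performed in
#' coordinates scaled by the dipole height and the outer domain is split
#' around the dipole so that the sharply peaked near-field (heights of order
#' 1 um against a 120 um sensor) is resolved.
#'
#' @inheritParams sensor_averaged_hy
#' @param rel_tol relative tolerance passed to the quadrature.
#' @return scalar averaged field in tesla.
#' @export
sensor_averaged_hy_quadrature <- function(dipole, sensor, rel_tol = 1e-10) {
  stopifnot(inherits(dipole, "dipole_state"), inherits(sensor, "sensor_geometry"))
  h <- dipole$position[3] - sensor$plane_z
  if (h <= 0)
    stop("dipole must lie strictly above the sensor plane (h > 0)")
  L <- sensor$length_L; l <- sensor$width_l
  mx <- sin(dipole$theta) * cos(dipole$psi)
  my <- sin(dipole$theta) * sin(dipole$psi)
  mz <- cos(dipole$theta)
  g <- function(v, u) {
    R <- sqrt(u^2 + v^2 + 1)
    3 * (u * mx + v * my - mz) * v / R^5 - my / R^3
  }
  ulo <- (-L / 2 - dipole$position[1]) / h
  uhi <- (L / 2 - dipole$position[1]) / h
  vlo <- (-l / 2 - dipole$position[2]) / h
  vhi <- (l / 2 - dipole$position[2]) / h
  inner <- function(us) {
    vapply(us, function(uu) {
      stats::integrate(function(v) g(v, uu), vlo, vhi,
                       rel.tol = rel_tol, abs.tol = 1e-13,
                       subdivisions = 200L)$value
    }, numeric(1))
  }
  cuts <- sort(unique(pmin(pmax(c(ulo, -10, -2, 0, 2, 10, uhi), ulo), uhi)))
  tot <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    if (cuts[i + 1L] <= cuts[i]) next
    piece <- tryCatch(
      stats::integrate(inner, cuts[i], cuts[i + 1L], rel.tol = rel_tol,
                       abs.tol = 1e-13, subdivisions = 200L),
      error = function(e) stop("quadrature failed on [", cuts[i], ", ",
                               cuts[i + 1L], "] (scaled units): ",
                               conditionMessage(e)))
    tot <- tot + piece$value
  }
  .mu0_4pi * dipole$moment * tot / (h * L * l)
}

#' Sensor signal of a composite magnetic object
#'
#' Sum of the sensor-averaged fields of every bead carried by the object,
#' placed at a given in-plane displacement of the object center from the
#' sensor center. Aggregates are modeled as N co-located beads, so their
#' signal is exactly N times the single-bead signal; labeled cells carry
#' beads spread over their surface and produce placement-dependent shapes.
#'
#' @param object a [magnetic_object()].
#' @param displacement in-plane displacement `(dx, dy)` of the object center
#'   in meters; may be an n-by-2 matrix to evaluate a whole transit at once.
#' @param height height of the object center above the sensor plane, meters.
#' @param sensor a [sensor_geometry()].
#' @return averaged field in tesla, one value per displacement row.
#' @export
object_signal <- function(object, displacement, height, sensor) {
  stopifnot(inherits(object, "magnetic_object"),
            inherits(sensor, "sensor_geometry"))
  if (object$n_beads < 1)
    stop("object carries no beads")
  disp <- if (is.matrix(displacement)) displacement else
    matrix(displacement, ncol = 2)
  stopifnot(ncol(disp) == 2)
  L <- sensor$length_L; l <- sensor$width_l
  hz <- height + object$offsets[, 3]
  if (any(hz <= 0))
    stop("all bead heights must lie strictly above the sensor plane")
  if (isTRUE(object$colocated)) {
    return(.hy_closed(disp[, 1], disp[, 2], height,
                      sum(object$moment), object$theta[1], object$psi[1],
                      L, l))
  }
  out <- numeric(nrow(disp))
  for (b in seq_len(object$n_beads)) {
    out <- out + .hy_closed(disp[, 1] + object$offsets[b, 1],
                            disp[, 2] + object$offsets[b, 2],
                            hz[b], object$moment[b],
                            object$theta[b], object$psi[b], L, l)
  }
  out
}

#' Peak transit amplitude of an object
#'
#' Maximum of the absolute sensor-averaged signal over a dense sweep of the
#' transit coordinate, for an object crossing the sensor at a fixed height.
#' The default transit axis is y (across the short sensor dimension), which
#' produces the bipolar signature for vertically magnetized objects. A local
#' golden-section refinement around the best grid point makes the result
#' insensitive to the sweep resolution.
#'
#' @inheritParams object_signal
#' @param transit_height height of the object center above the sensor plane,
#'   meters; must be positive (and exceed the object's lower extent).
#' @param transit_axis `"y"` (default) or `"x"`.
#' @param lateral_offset fixed coordinate along the other axis, meters.
#' @param n_grid number of sweep points before refinement.
#' @return peak absolute field in tesla; strictly decreasing in
#'   `transit_height` for a fixed object.
#' @export
peak_amplitude <- function(object, transit_height, sensor,
                           transit_axis = c("y", "x"), lateral_offset = 0,
                           n_grid = 512L) {
  transit_axis <- match.arg(transit_axis)
  stopifnot(transit_height > 0)
  extent <- max(abs(object$offsets))
  half <- switch(transit_axis, y = sensor$width_l / 2, x = sensor$length_L / 2)
  span <- half + 6 * (transit_height + extent) + 5e-6
  s <- seq(-span, span, length.out = n_grid)
  disp <- switch(transit_axis,
                 y = cbind(rep(lateral_offset, n_grid), s),
                 x = cbind(s, rep(lateral_offset, n_grid)))
  v <- abs(object_signal(object, disp, transit_height, sensor))
  i <- which.max(v)
  lo <- s[max(1L, i - 1L)]; hi <- s[min(n_grid, i + 1L)]
  f <- function(si) {
    d <- switch(transit_axis, y = cbind(lateral_offset, si),
                x = cbind(si, lateral_offset))
    -abs(object_signal(object, d, transit_height, sensor))
  }
  unname(-stats::optimize(f, c(lo, hi), tol = span * 1e-7)$objective)
}
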