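# Equation of motion and its closed-form velocity profile.
#
# With the forcing phase frozen at the reference position x = 0 the equation
# of motion is linear and time-invariant,
#
#   m dv/dt = F0 cos(omega t) + F_b - b v,    b = 6 pi mu R,
#
# whose solution is v(t) = A cos(omega t) - B sin(omega t) + C exp(-alpha t)
# + v_offset with alpha = b/m, v_offset = F_b/b and the harmonic response
# A = F0 b / (b^2 + (m omega)^2), B = -F0 m omega / (b^2 + (m omega)^2).
# The phase origin is chosen so the forcing is a cosine at t = 0, matching
# the cos/sin structure of the closed form; all decay, averaging and peak
# quantities are invariant to that choice.

#' Coefficients of the closed-form velocity profile
#'
#' Container for the constants of
#' v(t) = A cos(omega t) - B sin(omega t) + C exp(-alpha t) + v_offset.
#' Use [derive_coefficients()] to obtain them from physical parameters
#' ("physical mode") or construct them directly from fitted/assumed values
#' ("empirical mode").
#'
#' @param A,B Harmonic response amplitudes (m/s).
#' @param C Transient amplitude (m/s).
#' @param alpha Decay rate (1/s), strictly positive.
#' @param v_offset Steady buoyancy/drag drift velocity (m/s); 0 when
#'   buoyancy is disabled.
#' @param omega Angular frequency of the forcing (rad/s).
#' @return An object of class `model_coefficients`.
#' @examples
#' model_coefficients(A = 0, B = 0, C = 0.04, alpha = 1.2, omega = 2 * pi * 40e6)
#' @export
model_coefficients <- function(A = 0, B = 0, C = 0, alpha, v_offset = 0,
                               omega = 2 * pi * 40e6) {
  vals <- c(A = A, B = B, C = C, alpha = alpha, v_offset = v_offset,
            omega = omega)
  if (any(!is.finite(vals))) {
    validation_abort("all coefficients must be finite.")
  }
  check_positive(alpha, "alpha")
  check_positive(omega, "omega")
  structure(
    list(A = A, B = B, C = C, alpha = alpha, v_offset = v_offset,
         omega = omega),
    class = "model_coefficients"
  )
}

#' @export
print.model_coefficients <- function(x, ...) {
  cat(sprintf(
    "<model_coefficients> A = %.4g, B = %.4g, C = %.4g m/s; alpha = %.4g 1/s; v_offset = %.4g m/s; omega = %.4g rad/s\n",
    x$A, x$B, x$C, x$alpha, x$v_offset, x$omega))
  cat(sprintf("  v(0) = %.4g m/s\n", x$A + x$C + x$v_offset))
  invisible(x)
}

# shared assembly of the LTI equation-of-motion parameters
eom_parameters <- function(bubble, fluid, beam, forces = force_toggles(),
                           beam_vertical_angle = 0, added_mass = FALSE) {
  b <- drag_coefficient(bubble, fluid)
  m <- bubble$mass
  if (isTRUE(added_mass)) {
    m <- m + 0.5 * fluid$density * bubble$volume
  }
  if (!is.finite(m) || m <= 0 || b <= 0) {
    validation_abort("bubble mass and drag coefficient must be positive.")
  }
  f0 <- if (forces$bjerknes) {
    bubble$volume * beam$pressure_amplitude * wavenumber(beam, fluid)
  } else {
    0
  }
  fb <- if (forces$buoyancy) {
    project_buoyancy(buoyancy_force(bubble, fluid), beam_vertical_angle)
  } else {
    0
  }
  list(m = m, b = b, f0 = f0, fb = fb, omega = beam$angular_frequency)
}

#' Derive the closed-form coefficients from physical parameters
#'
#' Solves the linearised equation of motion
#' m dv/dt = F0 cos(omega t) + F_b - b v, with F0 = V P0 k the Bjerknes
#' forcing amplitude at the reference position x = 0, F_b the projected
#' buoyancy and b = 6 pi mu R the Stokes drag coefficient.
#'
#' @inheritParams net_force
#' @param v0 Initial velocity v(0) (m/s). Default 0: the bubble starts at
#'   rest when the Doppler beam switches on.
#' @param added_mass If `TRUE`, add the added-mass inertia (rho_fluid V / 2)
#'   to the bubble mass. Off by default: the closed form's constants depend
#'   on the bubble's own mass.
#' @return A [model_coefficients()] object satisfying
#'   A + C + v_offset = v0.
#' @examples
#' co <- derive_coefficients(nanobubble(), fluid_medium(), ultrasound_beam(),
#'                           forces = force_toggles(buoyancy = FALSE))
#' co$alpha   # b / m, about 4.5e8 1/s for a 100 nm bubble
#' @export
derive_coefficients <- function(bubble, fluid, beam, v0 = 0,
                                forces = force_toggles(),
                                beam_vertical_angle = 0, added_mass = FALSE) {
  if (!forces$drag) {
    validation_abort(
      "the closed-form profile requires the drag term; use numerical_velocity() for the undamped limit.")
  }
  p <- eom_parameters(bubble, fluid, beam, forces, beam_vertical_angle,
                      added_mass)
  denom <- p$b^2 + (p$m * p$omega)^2
  A <- p$f0 * p$b / denom
  B <- -p$f0 * p$m * p$omega / denom
  v_offset <- p$fb / p$b
  model_coefficients(A = A, B = B, C = v0 - A - v_offset,
                     alpha = p$b / p$m, v_offset = v_offset, omega = p$omega)
}

check_time <- function(t) {
  if (any(!is.finite(t)) || any(t < 0)) {
    validation_abort("`t` must be non-negative.")
  }
  invisible(t)
}

#' Closed-form velocity profile
#'
#' v(t) = A cos(omega t) - B sin(omega t) + C exp(-alpha t) + v_offset.
#'
#' @param coeffs A [model_coefficients()] object.
#' @param t Time(s) (s), non-negative; vectorised.
#' @return Velocity (m/s).
#' @export
analytic_velocity <- function(coeffs, t) {
  check_time(t)
  coeffs$A * cos(coeffs$omega * t) - coeffs$B * sin(coeffs$omega * t) +
    coeffs$C * exp(-coeffs$alpha * t) + coeffs$v_offset
}

#' Cycle-averaged velocity profile
#'
#' Average of [analytic_velocity()] over each acoustic period 2 pi / omega:
#' the harmonic terms vanish, leaving v_offset + C exp(-alpha t). This is
#' what frame-rate-limited Doppler/B-mode imaging effectively observes, and
#' it is the "velocity" reported when comparing with measured traces.
#'
#' @inheritParams analytic_velocity
#' @return Cycle-averaged velocity (m/s).
#' @export
cycle_averaged_velocity <- function(coeffs, t) {
  check_time(t)
  coeffs$v_offset + coeffs$C * exp(-coeffs$alpha * t)
}

#' Residual of the closed form in the equation of motion
#'
#' Substitutes the closed-form v(t) (with its exact time derivative) back
#' into m dv/dt + b v - F0 cos(omega t) - F_b and returns the residual,
#' normalised by the maximum forcing magnitude. A correct solution leaves a
#' residual at rounding level.
#'
#' @inheritParams derive_coefficients
#' @param coeffs The [model_coefficients()] under test (typically from
#'   [derive_coefficients()] with the same physical arguments).
#' @param t Time grid (s).
#' @return Tibble with columns `time`, `residual` (N) and the scalar
#'   attribute `max_relative` (max |residual| / max |forcing|).
#' @export
motion_residual <- function(coeffs, bubble, fluid, beam, t,
                            forces = force_toggles(),
                            beam_vertical_angle = 0, added_mass = FALSE) {
  check_time(t)
  p <- eom_parameters(bubble, fluid, beam, forces, beam_vertical_angle,
                      added_mass)
  w <- coeffs$omega
  v <- analytic_velocity(coeffs, t)
  vdot <- -coeffs$A * w * sin(w * t) - coeffs$B * w * cos(w * t) -
    coeffs$C * coeffs$alpha * exp(-coeffs$alpha * t)
  forcing <- p$f0 * cos(w * t) + p$fb
  resid <- p$m * vdot + p$b * v - forcing
  scale <- max(abs(forcing), p$b * max(abs(v)), .Machine$double.xmin)
  out <- tibble(time = t, residual = resid)
  attr(out, "max_relative") <- max(abs(resid)) / scale
  out
}

#' Numerically integrated velocity (independent oracle)
#'
#' Integrates the same equation of motion with deSolve's adaptive explicit
#' Runge-Kutta scheme (ode45). Internally the system is rescaled to
#' dimensionless time tau = alpha t, which removes the stiffness of the
#' drag term so a single explicit scheme covers decay rates from 0.1 to
#' 1e9 1/s. With `position_dependent = TRUE` the forcing phase follows the
#' bubble position (omega t - k x(t)) and attenuation applies, making the
#' system nonlinear; otherwise the linearised cosine forcing of
#' [derive_coefficients()] is used, so the result should match
#' [analytic_velocity()] to integration tolerance.
#'
#' @inheritParams derive_coefficients
#' @param t_grid Strictly increasing time grid starting at 0 (s).
#' @param position_dependent If `TRUE`, evaluate the instantaneous Bjerknes
#'   force at the integrated position instead of x = 0.
#' @param rtol Relative integration tolerance (default 1e-11).
#' @return A [velocity_trace()] tibble (`label = "numerical"`). Integration
#'   failure raises a computation error carrying the solver diagnostics.
#' @export
numerical_velocity <- function(bubble, fluid, beam, v0 = 0, t_grid,
                               forces = force_toggles(),
                               beam_vertical_angle = 0, added_mass = FALSE,
                               position_dependent = FALSE, rtol = 1e-11) {
  if (length(t_grid) < 2L || t_grid[1] != 0 || any(diff(t_grid) <= 0)) {
    validation_abort("`t_grid` must be strictly increasing and start at 0.")
  }
  p <- eom_parameters(bubble, fluid, beam, forces, beam_vertical_angle,
                      added_mass)
  if (!forces$drag) {
    # undamped limit: m dv/dt = F(t), no time rescaling needed
    deriv <- function(t, y, parms) {
      f_bj <- if (!forces$bjerknes) 0
              else if (position_dependent) {
                bjerknes_force(bubble, beam, fluid, max(y[2], 0), t)
              } else {
                p$f0 * cos(p$omega * t)
              }
      dv <- (f_bj + p$fb) / p$m
      if (position_dependent) list(c(dv, y[1])) else list(dv)
    }
    y0 <- if (position_dependent) c(v = v0, x = 0) else c(v = v0)
    v_scale <- max(abs(v0), 1e-12)
    sol <- deSolve::ode(y = y0, times = t_grid, func = deriv, parms = NULL,
                        method = "ode45", rtol = rtol, atol = rtol * v_scale)
    return(velocity_trace(time = t_grid, speed = as.numeric(sol[, "v"]),
                          label = "numerical"))
  }
  alpha <- p$b / p$m
  r <- p$omega / alpha              # forcing periods per decay time
  # harmonic response amplitude, not the quasi-static f0/b, sets the
  # solution scale used for the absolute tolerance
  v_scale <- max(abs(v0), abs(p$f0 / p$b) / sqrt(1 + r^2),
                 abs(p$fb / p$b), 1e-15)

  deriv <- if (position_dependent) {
    function(tau, y, parms) {
      t_real <- tau / alpha
      f_bj <- if (forces$bjerknes) {
        bjerknes_force(bubble, beam, fluid, max(y[2], 0), t_real)
      } else {
        0
      }
      list(c((f_bj + p$fb) / p$b - y[1], y[1] / alpha))
    }
  } else {
    function(tau, y, parms) {
      list((p$f0 * cos(r * tau) + p$fb) / p$b - y[1])
    }
  }
  y0 <- if (position_dependent) c(v = v0, x = 0) else c(v = v0)
  # cap the internal step at 1/32 forcing period so the dense-output
  # interpolation between steps stays far below the requested tolerance
  hmax <- min(0.1, if (r > 0) 2 * pi / (32 * r) else Inf)
  sol <- try(deSolve::ode(y = y0, times = alpha * t_grid, func = deriv,
                          parms = NULL, method = "ode45", rtol = rtol,
                          atol = rtol * v_scale, hmax = hmax),
             silent = TRUE)
  if (inherits(sol, "try-error") ||
      nrow(sol) < length(t_grid) || any(!is.finite(sol[, "v"]))) {
    computation_abort("ODE integration failed: %s",
                      if (inherits(sol, "try-error")) {
                        conditionMessage(attr(sol, "condition"))
                      } else {
                        "solver returned a truncated or non-finite solution"
                      })
  }
  velocity_trace(time = t_grid, speed = as.numeric(sol[, "v"]),
                 label = "numerical")
}

#' Maximum speed of the closed-form profile
#'
#' Maximum of |v(t)| over [0, horizon], located by dense deterministic
#' sampling (4096 samples per decay time, and for the full oscillatory form
#' 64 per acoustic period, capped at 2^20 samples) followed by golden-section
#' refinement around the best grid point.
#'
#' @inheritParams analytic_velocity
#' @param horizon Upper end of the search interval (s), positive.
#' @param form `"cycle_averaged"` (default; the observable speed) or
#'   `"full"` (includes the acoustic oscillation).
#' @return Maximum speed (m/s).
#' @export
max_speed <- function(coeffs, horizon, form = c("cycle_averaged", "full")) {
  form <- match.arg(form)
  check_positive(horizon, "horizon")
  f <- switch(form,
    cycle_averaged = function(t) abs(cycle_averaged_velocity(coeffs, t)),
    full = function(t) abs(analytic_velocity(coeffs, t))
  )
  n <- 4096 * horizon * coeffs$alpha
  if (form == "full") {
    n <- max(n, 64 * horizon * coeffs$omega / (2 * pi))
  }
  n <- min(max(ceiling(n), 4096), 2^20)
  grid <- seq(0, horizon, length.out = n + 1L)
  vals <- f(grid)
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  refined <- if (hi > lo) optimize(f, c(lo, hi), maximum = TRUE)$objective
             else vals[i]
  max(vals[i], refined)
}

#' Imaging-plane trajectory of a propelled bubble
#'
#' Cumulative trapezoid integral of the velocity profile along the unit
#' vector at `beam_angle` from the transducer axis. The axial coordinate
#' increases away from the transducer; the lateral coordinate spans the
#' imaging plane. Changing the angle rotates the trajectory rigidly and
#' preserves path length.
#'
#' @inheritParams max_speed
#' @param beam_angle Imaging-plane beam angle (degrees).
#' @param t_grid Strictly increasing time grid starting at 0 (s).
#' @param origin Length-2 numeric, the starting position (m) as
#'   (lateral, axial).
#' @return Tibble with columns `time` (s), `arc_length` (m, signed path
#'   coordinate), `lateral` and `axial` (m).
#' @export
trajectory <- function(coeffs, beam_angle = 0, t_grid, origin = c(0, 0),
                       form = c("cycle_averaged", "full")) {
  form <- match.arg(form)
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0)) {
    validation_abort("`t_grid` must be strictly increasing.")
  }
  v <- switch(form,
    cycle_averaged = cycle_averaged_velocity(coeffs, t_grid),
    full = analytic_velocity(coeffs, t_grid)
  )
  s <- as.numeric(pracma::cumtrapz(t_grid, v))
  th <- beam_angle * pi / 180
  tibble(time = t_grid, arc_length = s,
         lateral = origin[1] + s * sin(th),
         axial = origin[2] + s * cos(th))
}

#' Sweep the transmit power and record the peak cycle-averaged speed
#'
#' For each power fraction the beam is rebuilt through its power-to-pressure
#' mapping, coefficients are derived from the physical parameters, and the
#' maximum cycle-averaged speed over the horizon is recorded. Under the
#' default square-root mapping the peak speed increases strictly with power.
#'
#' @inheritParams derive_coefficients
#' @param beam_template An [ultrasound_beam()] whose power fraction is
#'   overridden per sweep point.
#' @param powers Sorted power fractions in (0, 1].
#' @param horizon Search horizon for the peak speed (s). Default 5.
#' @return Tibble with columns `power_fraction`, `p0_pa` and
#'   `peak_speed` (m/s).
#' @export
power_sweep <- function(bubble, fluid, beam_template, powers, horizon = 5,
                        v0 = 0, forces = force_toggles(),
                        beam_vertical_angle = 0, added_mass = FALSE) {
  if (length(powers) < 1L || any(powers <= 0) || any(powers > 1) ||
      is.unsorted(powers, strictly = TRUE)) {
    validation_abort("`powers` must be strictly increasing fractions in (0, 1].")
  }
  purrr::map_dfr(powers, function(p) {
    beam <- ultrasound_beam(
      frequency = beam_template$frequency,
      peak_pressure_full_power = beam_template$peak_pressure_full_power,
      power_fraction = p,
      beam_angle = beam_template$beam_angle,
      attenuation = beam_template$attenuation,
      power_mapping = beam_template$power_mapping
    )
    co <- derive_coefficients(bubble, fluid, beam, v0 = v0, forces = forces,
                              beam_vertical_angle = beam_vertical_angle,
                              added_mass = added_mass)
    tibble(power_fraction = p, p0_pa = beam$pressure_amplitude,
           peak_speed = max_speed(co, horizon))
  })
}
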