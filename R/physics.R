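# Physical types and individual force/field operators.
#
# Geometry convention: the dynamics are 1-D along the beam axis. The positive
# axis points from the transducer into the lumen, so Bjerknes propulsion is
# positive and (with the default vertical beam, transducer on top) buoyancy
# projects negatively onto the axis.

#' Fluid medium carrying the bubble
#'
#' Describes the liquid (urine or saline in the intravesical setting) through
#' which nanobubbles move. All quantities are strict SI.
#'
#' @param density Mass density of the fluid (kg/m^3). Default 1015, a typical
#'   urine density.
#' @param dynamic_viscosity Dynamic viscosity (Pa s). Default 1e-3,
#'   water/urine at body-ish temperature.
#' @param sound_speed Speed of sound in the fluid (m/s). Default 1520.
#' @param gravity Gravitational acceleration (m/s^2). Default 9.81.
#'
#' @return An object of class `fluid_medium`.
#' @examples
#' fluid_medium()
#' @export
fluid_medium <- function(density = 1015, dynamic_viscosity = 1e-3,
                         sound_speed = 1520, gravity = 9.81) {
  check_positive(density, "density")
  check_positive(dynamic_viscosity, "dynamic_viscosity")
  check_positive(sound_speed, "sound_speed")
  check_positive(gravity, "gravity", strict = FALSE)
  structure(
    list(density = density, dynamic_viscosity = dynamic_viscosity,
         sound_speed = sound_speed, gravity = gravity),
    class = "fluid_medium"
  )
}

#' @export
print.fluid_medium <- function(x, ...) {
  cat(sprintf(
    "<fluid_medium> rho = %g kg/m^3, mu = %g Pa s, c = %g m/s, g = %g m/s^2\n",
    x$density, x$dynamic_viscosity, x$sound_speed, x$gravity))
  invisible(x)
}

#' Nanobubble geometry and inertia
#'
#' A single gas-filled nanobubble described by its radius and an effective
#' density of the shell + gas composite. Volume and mass are derived. The
#' effective density is a free parameter of the model: the bubble is mostly
#' gas inside a thin cellulosic shell, so it is far lighter than the fluid;
#' 100 kg/m^3 is the default composite value.
#'
#' @param radius Bubble radius (m). Default 1e-7 (100 nm, i.e. a 200 nm
#'   diameter bubble).
#' @param effective_density Composite shell+gas density (kg/m^3). Default 100.
#'
#' @return An object of class `nanobubble` with fields `radius`,
#'   `effective_density`, `volume` (m^3) and `mass` (kg).
#' @examples
#' b <- nanobubble(radius = 1e-7)
#' b$volume   # (4/3) * pi * R^3
#' @export
nanobubble <- function(radius = 1e-7, effective_density = 100) {
  check_positive(radius, "radius")
  check_positive(effective_density, "effective_density")
  volume <- (4 / 3) * pi * radius^3
  structure(
    list(radius = radius, effective_density = effective_density,
         volume = volume, mass = effective_density * volume),
    class = "nanobubble"
  )
}

#' @export
print.nanobubble <- function(x, ...) {
  cat(sprintf(
    "<nanobubble> R = %g nm, rho_eff = %g kg/m^3, V = %.4g m^3, m = %.4g kg\n",
    x$radius * 1e9, x$effective_density, x$volume, x$mass))
  invisible(x)
}

#' Pulsed-wave Doppler ultrasound beam
#'
#' The forcing field: a harmonic plane pressure wave at the transducer centre
#' frequency. The working pressure amplitude P0 is derived from the
#' full-power peak pressure through a power-to-pressure mapping; the default
#' square-root mapping reflects acoustic power scaling with pressure squared.
#'
#' @param frequency Centre frequency (Hz). Default 40e6 (40 MHz).
#' @param peak_pressure_full_power Peak pressure amplitude at 100% transmit
#'   power (Pa). Default 1e6 (1 MPa).
#' @param power_fraction Transmit power as a fraction in (0, 1]. Default 1.
#' @param beam_angle Imaging-plane angle of the beam relative to the
#'   transducer axis (degrees). Default 0.
#' @param attenuation Amplitude attenuation coefficient (Np/m). Default 0:
#'   the plane-wave model is unattenuated.
#' @param power_mapping `"sqrt"` (default, P0 = peak * sqrt(power)) or
#'   `"linear"` (P0 = peak * power).
#'
#' @return An object of class `ultrasound_beam` with the derived
#'   `angular_frequency` (rad/s) and `pressure_amplitude` (Pa).
#' @seealso [wavenumber()] for the fluid-dependent wavenumber.
#' @examples
#' ultrasound_beam(power_fraction = 0.25)$pressure_amplitude  # 0.5 * peak
#' @export
ultrasound_beam <- function(frequency = 40e6, peak_pressure_full_power = 1e6,
                            power_fraction = 1, beam_angle = 0,
                            attenuation = 0,
                            power_mapping = c("sqrt", "linear")) {
  power_mapping <- match.arg(power_mapping)
  check_positive(frequency, "frequency")
  check_positive(peak_pressure_full_power, "peak_pressure_full_power")
  check_fraction(power_fraction, "power_fraction")
  check_positive(attenuation, "attenuation", strict = FALSE)
  if (!is.numeric(beam_angle) || length(beam_angle) != 1L ||
      !is.finite(beam_angle)) {
    validation_abort("`beam_angle` must be a single finite angle in degrees.")
  }
  p0 <- peak_pressure_full_power * power_to_pressure(power_fraction,
                                                     power_mapping)
  structure(
    list(frequency = frequency,
         peak_pressure_full_power = peak_pressure_full_power,
         power_fraction = power_fraction,
         beam_angle = beam_angle,
         attenuation = attenuation,
         power_mapping = power_mapping,
         angular_frequency = 2 * pi * frequency,
         pressure_amplitude = p0),
    class = "ultrasound_beam"
  )
}

#' @export
print.ultrasound_beam <- function(x, ...) {
  cat(sprintf(
    "<ultrasound_beam> f = %g MHz, P0 = %.4g Pa (%g%% power, %s mapping), angle = %g deg\n",
    x$frequency / 1e6, x$pressure_amplitude, 100 * x$power_fraction,
    x$power_mapping, x$beam_angle))
  invisible(x)
}

#' Power-fraction to relative pressure mapping
#'
#' @param power_fraction Fraction(s) in (0, 1].
#' @param mapping `"sqrt"` or `"linear"`.
#' @return Relative pressure amplitude(s), i.e. P0 / peak pressure.
#' @export
power_to_pressure <- function(power_fraction, mapping = c("sqrt", "linear")) {
  mapping <- match.arg(mapping)
  switch(mapping, sqrt = sqrt(power_fraction), linear = power_fraction)
}

#' Acoustic wavenumber of a beam in a fluid
#'
#' @param beam An [ultrasound_beam()].
#' @param fluid A [fluid_medium()].
#' @return k = omega / c (rad/m).
#' @export
wavenumber <- function(beam, fluid) {
  beam$angular_frequency / fluid$sound_speed
}

check_x <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    validation_abort(
      "`x` must be non-negative (distance from the transducer is out of the field of view when negative).")
  }
  invisible(x)
}

#' Harmonic plane-wave pressure field
#'
#' p(x, t) = P0 * exp(-attenuation * x) * cos(omega t - k x), with x the
#' distance from the transducer along the beam axis.
#'
#' @param beam An [ultrasound_beam()].
#' @param fluid A [fluid_medium()] (sets the wavenumber).
#' @param x Distance(s) from the transducer (m), non-negative.
#' @param t Time(s) (s).
#' @return Pressure (Pa), vectorised over `x` and `t`.
#' @export
pressure_field <- function(beam, fluid, x, t) {
  check_x(x)
  k <- wavenumber(beam, fluid)
  beam$pressure_amplitude * exp(-beam$attenuation * x) *
    cos(beam$angular_frequency * t - k * x)
}

#' Spatial gradient of the plane-wave pressure field
#'
#' Analytic derivative of [pressure_field()] with respect to `x`:
#' dp/dx = P0 e^(-a x) (k sin(omega t - k x) - a cos(omega t - k x)).
#'
#' @inheritParams pressure_field
#' @return Pressure gradient (Pa/m).
#' @export
pressure_gradient <- function(beam, fluid, x, t) {
  check_x(x)
  k <- wavenumber(beam, fluid)
  a <- beam$attenuation
  phase <- beam$angular_frequency * t - k * x
  beam$pressure_amplitude * exp(-a * x) * (k * sin(phase) - a * cos(phase))
}

#' Primary Bjerknes force on a bubble
#'
#' The net acoustic radiation force from the pressure gradient, modelled with
#' the bubble volume held constant (no radial oscillation dynamics):
#' F = -V dp/dx. Positive values point away from the transducer.
#'
#' @param bubble A [nanobubble()].
#' @inheritParams pressure_field
#' @return Force (N) along the beam axis.
#' @export
bjerknes_force <- function(bubble, beam, fluid, x, t) {
  -bubble$volume * pressure_gradient(beam, fluid, x, t)
}

#' Buoyancy force on a bubble
#'
#' Weight of the displaced fluid minus the bubble's own weight:
#' (rho_fluid - rho_bubble) V g, signed positive upward (the bubble is
#' lighter than the fluid, so the default is positive). Project onto the beam
#' axis with [project_buoyancy()].
#'
#' @param bubble A [nanobubble()].
#' @param fluid A [fluid_medium()].
#' @return Vertical force (N), positive upward.
#' @export
buoyancy_force <- function(bubble, fluid) {
  (fluid$density - bubble$effective_density) * bubble$volume * fluid$gravity
}

#' Project the vertical buoyancy force onto the beam axis
#'
#' With the default configuration the beam axis is vertical with the
#' transducer on top, so the positive axis points downward and upward
#' buoyancy opposes propulsion: projection = -cos(tilt) * F.
#'
#' @param force_vertical Vertical buoyancy force (N), positive upward.
#' @param beam_vertical_angle Tilt of the beam axis from vertical (degrees).
#' @return Along-axis force component (N).
#' @export
project_buoyancy <- function(force_vertical, beam_vertical_angle = 0) {
  -cos(beam_vertical_angle * pi / 180) * force_vertical
}

#' Stokes drag force
#'
#' Linear viscous drag on a sphere at low Reynolds number: F = -6 pi mu R v,
#' opposing the motion. The linear law is justified by the laminar regime
#' (see [reynolds_number()]).
#'
#' @param bubble A [nanobubble()].
#' @param fluid A [fluid_medium()].
#' @param v Bubble velocity (m/s) along the axis.
#' @return Force (N), vectorised over `v`.
#' @export
drag_force <- function(bubble, fluid, v) {
  -drag_coefficient(bubble, fluid) * v
}

#' Stokes drag coefficient b = 6 pi mu R
#'
#' @inheritParams drag_force
#' @return Drag coefficient (N s/m).
#' @export
drag_coefficient <- function(bubble, fluid) {
  6 * pi * fluid$dynamic_viscosity * bubble$radius
}

#' Particle Reynolds number
#'
#' Re = rho v d / mu with d = 2R. Values well below 1 justify the linear
#' Stokes drag law used throughout.
#'
#' @inheritParams drag_force
#' @param v Speed (m/s), non-negative.
#' @return Dimensionless Reynolds number, vectorised over `v`.
#' @export
reynolds_number <- function(bubble, fluid, v) {
  if (any(!is.finite(v)) || any(v < 0)) {
    validation_abort("`v` must be a non-negative speed.")
  }
  fluid$density * v * (2 * bubble$radius) / fluid$dynamic_viscosity
}

#' Force toggles for the equation of motion
#'
#' The gravitational weight of the bubble itself is always excluded (its
#' mass is negligible against the other terms); each remaining term can be
#' switched off individually.
#'
#' @param bjerknes,buoyancy,drag Logical switches.
#' @return A named list of toggles.
#' @export
force_toggles <- function(bjerknes = TRUE, buoyancy = TRUE, drag = TRUE) {
  list(bjerknes = isTRUE(bjerknes), buoyancy = isTRUE(buoyancy),
       drag = isTRUE(drag))
}

#' Net force on a propelled nanobubble
#'
#' Sum of the instantaneous Bjerknes force, the projected buoyancy force and
#' the Stokes drag, each individually toggleable.
#'
#' @param bubble A [nanobubble()].
#' @param beam An [ultrasound_beam()].
#' @param fluid A [fluid_medium()].
#' @param x Position along the beam axis (m), non-negative.
#' @param v Velocity (m/s).
#' @param t Time (s).
#' @param forces A [force_toggles()] list.
#' @param beam_vertical_angle Tilt of the beam axis from vertical (degrees).
#' @return Net force (N) along the beam axis.
#' @export
net_force <- function(bubble, beam, fluid, x, v, t, forces = force_toggles(),
                      beam_vertical_angle = 0) {
  f <- 0
  if (forces$bjerknes) {
    f <- f + bjerknes_force(bubble, beam, fluid, x, t)
  }
  if (forces$buoyancy) {
    f <- f + project_buoyancy(buoyancy_force(bubble, fluid),
                              beam_vertical_angle)
  }
  if (forces$drag) {
    f <- f + drag_force(bubble, fluid, v)
  }
  f
}
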