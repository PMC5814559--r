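# Field and force operators: hand-evaluated values, analytic-vs-finite
# difference oracles, and scaling/symmetry properties.

test_that("pressure field matches the harmonic plane wave at landmark phases", {
  fluid <- fluid_medium(sound_speed = 1500)
  beam <- ultrasound_beam(frequency = 40e6, peak_pressure_full_power = 1e6)

  expect_equal(pressure_field(beam, fluid, x = 0, t = 0), 1e6)
  # quarter-period zero crossing
  t_quarter <- pi / (2 * beam$angular_frequency)
  expect_equal(pressure_field(beam, fluid, x = 0, t = t_quarter), 0,
               tolerance = 1e-9)
  # full-wavelength periodicity: x = lambda = c/f returns the x = 0 value
  lambda <- fluid$sound_speed / beam$frequency
  expect_equal(pressure_field(beam, fluid, x = lambda, t = 0), 1e6,
               tolerance = 1e-9)
  expect_error(pressure_field(beam, fluid, x = -1e-3, t = 0),
               class = "bubblesteer_validation_error")
})

test_that("pressure gradient is the analytic derivative of the field", {
  fluid <- fluid_medium()
  # peak at sin = 1: gradient equals P0 * k
  beam <- ultrasound_beam(frequency = 40e6, peak_pressure_full_power = 2e6)
  k <- wavenumber(beam, fluid)
  t_peak <- pi / (2 * beam$angular_frequency)
  expect_equal(pressure_gradient(beam, fluid, x = 0, t = t_peak),
               beam$pressure_amplitude * k, tolerance = 1e-12)

  # attenuated case against a central finite difference of the field
  beam_att <- ultrasound_beam(frequency = 40e6,
                              peak_pressure_full_power = 1e6,
                              attenuation = 50)
  withr::with_seed(11, {
    for (i in 1:25) {
      x <- runif(1, 1e-4, 5e-3)
      t <- runif(1, 0, 1e-6)
      h <- 1e-12
      fd <- (pressure_field(beam_att, fluid, x + h, t) -
               pressure_field(beam_att, fluid, x - h, t)) / (2 * h)
      an <- pressure_gradient(beam_att, fluid, x, t)
      expect_equal(an, fd, tolerance = 1e-6)
    }
  })

  # quasi-uniform field (sound speed -> Inf makes k -> 0): gradient vanishes
  fluid_stiff <- fluid_medium(sound_speed = 1e22)
  expect_lt(abs(pressure_gradient(ultrasound_beam(), fluid_stiff, 0, 1e-8)),
            1e-6)
})

test_that("Bjerknes force is -V grad p with cubic radius scaling", {
  fluid <- fluid_medium()
  beam <- ultrasound_beam(frequency = 40e6, peak_pressure_full_power = 1e6)
  bub <- nanobubble(radius = 1e-7)
  k <- wavenumber(beam, fluid)

  # hand value: gradient of 1e11 Pa/m at the sin = 1 phase via P0 = 1e11/k
  beam_g <- ultrasound_beam(frequency = 40e6,
                            peak_pressure_full_power = 1e11 / k)
  t_peak <- pi / (2 * beam_g$angular_frequency)
  f <- bjerknes_force(bub, beam_g, fluid, x = 0, t = t_peak)
  expect_equal(abs(f), 4.18879e-10, tolerance = 1e-5)
  expect_lt(f, 0)  # instantaneous force at this phase points at the transducer

  # V scales as R^3: doubling the radius multiplies the force by 8
  bub2 <- nanobubble(radius = 2e-7)
  t <- 3.7e-9
  expect_equal(bjerknes_force(bub2, beam, fluid, 1e-4, t),
               8 * bjerknes_force(bub, beam, fluid, 1e-4, t))

  # periodic in t with period 2 pi / omega when unattenuated
  period <- 2 * pi / beam$angular_frequency
  expect_equal(bjerknes_force(bub, beam, fluid, 1e-4, t + period),
               bjerknes_force(bub, beam, fluid, 1e-4, t), tolerance = 1e-9)
})

test_that("buoyancy force follows the displaced-fluid weight", {
  bub <- nanobubble(radius = 1e-7, effective_density = 100)
  fluid <- fluid_medium(density = 1000, gravity = 9.81)
  expect_equal(buoyancy_force(bub, fluid), 900 * 4.18879e-21 * 9.81,
               tolerance = 1e-5)
  expect_equal(buoyancy_force(bub, fluid), 3.699e-17, tolerance = 1e-3)

  # neutral buoyancy and zero gravity both vanish
  expect_equal(buoyancy_force(nanobubble(effective_density = 1000), fluid), 0)
  expect_equal(buoyancy_force(bub, fluid_medium(density = 1000, gravity = 0)),
               0)

  # default projection: vertical beam, transducer on top -> opposes propulsion
  expect_equal(project_buoyancy(1e-17), -1e-17)
  expect_equal(project_buoyancy(1e-17, beam_vertical_angle = 90), 0,
               tolerance = 1e-30)
})

test_that("Stokes drag is linear and odd in velocity", {
  bub <- nanobubble(radius = 1e-7)
  fluid <- fluid_medium(dynamic_viscosity = 1e-3)
  expect_equal(drag_force(bub, fluid, 0), 0)
  expect_equal(abs(drag_force(bub, fluid, 1e-3)),
               6 * pi * 1e-3 * 1e-7 * 1e-3)
  expect_equal(abs(drag_force(bub, fluid, 1e-3)), 1.885e-12,
               tolerance = 1e-3)
  withr::with_seed(5, {
    v <- runif(10, -0.05, 0.05)
    expect_equal(drag_force(bub, fluid, 2 * v), 2 * drag_force(bub, fluid, v))
    expect_equal(drag_force(bub, fluid, -v), -drag_force(bub, fluid, v))
  })
})

test_that("Reynolds number stays laminar over the working envelope", {
  fluid <- fluid_medium(density = 1000, dynamic_viscosity = 1e-3)
  bub <- nanobubble(radius = 1e-7)  # 200 nm diameter
  expect_equal(reynolds_number(bub, fluid, 0), 0)
  expect_equal(reynolds_number(bub, fluid, 0.02), 4.0e-3, tolerance = 1e-9)

  # default bubble, speeds up to 40 mm/s: Re < 0.01
  speeds <- seq(0, 0.04, length.out = 50)
  expect_true(all(reynolds_number(nanobubble(), fluid_medium(), speeds) <
                    0.01))
  # full factorial envelope up to 800 nm diameter: still well inside laminar
  expect_true(all(reynolds_number(nanobubble(radius = 4e-7), fluid_medium(),
                                  speeds) < 1))
})

test_that("net force composes the toggled operators", {
  bub <- nanobubble()
  fluid <- fluid_medium()
  beam <- ultrasound_beam()
  off <- force_toggles(FALSE, FALSE, FALSE)
  expect_equal(net_force(bub, beam, fluid, 1e-4, 0.01, 1e-8, forces = off), 0)

  # v = 0 in a quasi-uniform field leaves only projected buoyancy
  fluid_stiff <- fluid_medium(sound_speed = 1e20)
  expect_equal(net_force(bub, ultrasound_beam(), fluid_stiff, 0, 0, 1e-8),
               project_buoyancy(buoyancy_force(bub, fluid_stiff)),
               tolerance = 1e-6)

  # arbitrary state: equals the sum of the three operators
  withr::with_seed(7, {
    for (i in 1:10) {
      x <- runif(1, 0, 1e-3); v <- runif(1, -0.04, 0.04)
      t <- runif(1, 0, 1e-6)
      expect_equal(
        net_force(bub, beam, fluid, x, v, t),
        bjerknes_force(bub, beam, fluid, x, t) +
          project_buoyancy(buoyancy_force(bub, fluid)) +
          drag_force(bub, fluid, v))
    }
  })
})

test_that("constructors reject non-physical parameters", {
  expect_error(fluid_medium(density = -1),
               class = "bubblesteer_validation_error")
  expect_error(nanobubble(radius = 0),
               class = "bubblesteer_validation_error")
  expect_error(ultrasound_beam(power_fraction = 0),
               class = "bubblesteer_validation_error")
  expect_error(ultrasound_beam(power_fraction = 1.2),
               class = "bubblesteer_validation_error")
  # derived quantities are consistent
  b <- nanobubble(radius = 3e-7, effective_density = 250)
  expect_equal(b$volume, (4 / 3) * pi * (3e-7)^3)
  expect_equal(b$mass, 250 * b$volume)
  beam <- ultrasound_beam(power_fraction = 0.25)
  expect_equal(beam$pressure_amplitude, 0.5 * beam$peak_pressure_full_power)
  expect_lte(beam$pressure_amplitude, beam$peak_pressure_full_power)
})
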