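# Closed-form coefficients, the analytic profile, the numerical oracle and
# the derived trajectory/sweep utilities.

test_that("derived coefficients satisfy the stated closed form", {
  fluid <- fluid_medium(dynamic_viscosity = 1e-3)
  beam <- ultrasound_beam()

  # unforced decay: no Bjerknes, no buoyancy -> A = B = v_offset = 0, C = v0
  co <- derive_coefficients(nanobubble(), fluid, beam, v0 = 0.01,
                            forces = force_toggles(FALSE, FALSE, TRUE))
  expect_equal(co$A, 0)
  expect_equal(co$B, 0)
  expect_equal(co$v_offset, 0)
  expect_equal(co$C, 0.01)

  # quasi-static limit omega -> 0: A -> F0/b, B -> 0
  bub <- bubble_for_alpha(2)
  slow <- beam_for_omega(1e-4)
  co_s <- derive_coefficients(bub, fluid, slow, forces = no_buoyancy())
  f0 <- bub$volume * slow$pressure_amplitude * wavenumber(slow, fluid)
  b <- drag_coefficient(bub, fluid)
  expect_equal(co_s$A, f0 / b, tolerance = 1e-6)
  expect_lt(abs(co_s$B), 1e-4 * abs(co_s$A))

  # alpha = 6 pi mu R / m ~ 4.5e8 1/s for a 100 nm, 1000 kg/m^3 bubble
  co_a <- derive_coefficients(nanobubble(effective_density = 1000), fluid,
                              beam, forces = no_buoyancy())
  expect_equal(co_a$alpha, 4.5e8, tolerance = 1e-2)

  # v(0) consistency: A + C + v_offset = v0 on random parameter draws
  withr::with_seed(13, {
    for (i in 1:20) {
      bub_i <- nanobubble(radius = runif(1, 5e-8, 4e-7),
                          effective_density = runif(1, 50, 1200))
      beam_i <- ultrasound_beam(frequency = runif(1, 32e6, 40e6),
                                power_fraction = runif(1, 0.05, 1))
      v0 <- runif(1, -0.01, 0.04)
      co_i <- derive_coefficients(bub_i, fluid, beam_i, v0 = v0)
      expect_equal(co_i$A + co_i$C + co_i$v_offset, v0, tolerance = 1e-12)
      expect_equal(analytic_velocity(co_i, 0), v0, tolerance = 1e-12)
    }
  })

  expect_error(
    derive_coefficients(nanobubble(), fluid, beam,
                        forces = force_toggles(drag = FALSE)),
    class = "bubblesteer_validation_error")
})

test_that("analytic profile evaluates the closed form and decays as exp(-alpha t)", {
  co <- model_coefficients(A = 0, B = 0, C = 0.02, alpha = 1.5,
                           v_offset = 0)
  # pure exponential halves every ln(2)/alpha
  th <- log(2) / 1.5
  expect_equal(analytic_velocity(co, th), 0.01, tolerance = 1e-12)
  expect_equal(analytic_velocity(co, 2 * th), 0.005, tolerance = 1e-12)
  expect_error(analytic_velocity(co, -0.1),
               class = "bubblesteer_validation_error")

  # log-slope of the transient equals -alpha on noiseless data
  t <- seq(0, 2, by = 0.01)
  slope <- coef(lm(log(analytic_velocity(co, t)) ~ t))[[2]]
  expect_equal(slope, -1.5, tolerance = 1e-3)
})

test_that("the closed form leaves a rounding-level residual in the equation of motion", {
  fluid <- fluid_medium()
  withr::with_seed(17, {
    for (i in 1:20) {
      bub <- nanobubble(radius = runif(1, 5e-8, 4e-7),
                        effective_density = runif(1, 50, 1200))
      beam <- ultrasound_beam(frequency = runif(1, 32e6, 40e6),
                              power_fraction = runif(1, 0.05, 1))
      co <- derive_coefficients(bub, fluid, beam, v0 = runif(1, 0, 0.04))
      t <- seq(0, 5 / co$alpha, length.out = 400)
      mr <- motion_residual(co, bub, fluid, beam, t)
      expect_lt(attr(mr, "max_relative"), 1e-9)
    }
  })
})

test_that("cycle averaging removes the harmonic terms", {
  co <- model_coefficients(A = 0.01, B = -0.004, C = 0.03, alpha = 0.8,
                           v_offset = 0.002, omega = 2 * pi * 50)
  expect_equal(cycle_averaged_velocity(co, 0), co$v_offset + co$C)

  # trapezoid average of the full profile over one period, slow-decay regime
  period <- 2 * pi / co$omega
  t0 <- 0.5
  grid <- seq(t0, t0 + period, length.out = 4001)
  avg <- pracma::trapz(grid, analytic_velocity(co, grid)) / period
  expect_equal(avg, cycle_averaged_velocity(co, t0 + period / 2),
               tolerance = 1e-4)

  # late-time average approaches the steady offset
  late <- seq(40, 40 + period, length.out = 4001)
  avg_late <- pracma::trapz(late, analytic_velocity(co, late)) / period
  expect_equal(avg_late, co$v_offset, tolerance = 1e-8)
})

test_that("numerical oracle reproduces the analytic solution and closed-form limits", {
  fluid <- fluid_medium()
  bub <- bubble_for_alpha(2)
  beam <- beam_for_omega(12)
  co <- derive_coefficients(bub, fluid, beam)
  tg <- seq(0, 3, length.out = 601)
  num <- numerical_velocity(bub, fluid, beam, v0 = 0, t_grid = tg)
  expect_s3_class(num, "onb_trace")
  ana <- analytic_velocity(co, tg)
  expect_lt(max(abs(num$speed - ana)), 1e-6 * max(abs(ana)))

  # buoyant relaxation without forcing: v_offset + (v0 - v_offset) e^(-at)
  num_b <- numerical_velocity(bub, fluid, beam, v0 = 0.01, t_grid = tg,
                              forces = force_toggles(bjerknes = FALSE))
  co_b <- derive_coefficients(bub, fluid, beam, v0 = 0.01,
                              forces = force_toggles(bjerknes = FALSE))
  closed <- co_b$v_offset + (0.01 - co_b$v_offset) * exp(-co_b$alpha * tg)
  expect_equal(num_b$speed, closed, tolerance = 1e-8)

  # all forces off from rest: identically zero
  num_0 <- numerical_velocity(bub, fluid, beam, v0 = 0, t_grid = tg,
                              forces = force_toggles(FALSE, FALSE, FALSE))
  expect_equal(max(abs(num_0$speed)), 0)

  expect_error(numerical_velocity(bub, fluid, beam, v0 = 0,
                                  t_grid = c(0.5, 1)),
               class = "bubblesteer_validation_error")
})

test_that("oracle equivalence holds across a wide stiffness range", {
  fluid <- fluid_medium()
  withr::with_seed(23, {
    for (i in 1:30) {
      alpha <- 10^runif(1, -1, 9)
      bub <- bubble_for_alpha(alpha)
      beam <- beam_for_omega(alpha * 10^runif(1, log10(0.5), log10(50)))
      co <- derive_coefficients(bub, fluid, beam, v0 = 0,
                                forces = no_buoyancy())
      tg <- seq(0, 5 / alpha, length.out = 201)
      num <- numerical_velocity(bub, fluid, beam, v0 = 0, t_grid = tg,
                                forces = no_buoyancy())
      ana <- analytic_velocity(co, tg)
      expect_lt(max(abs(num$speed - ana)), 1e-6 * max(abs(ana)))
    }
  })
})

test_that("max_speed locates the envelope maximum", {
  # pure transient: maximum C at t = 0
  co1 <- model_coefficients(C = 0.03, alpha = 1.2)
  expect_equal(max_speed(co1, horizon = 5), 0.03, tolerance = 1e-9)

  # pure harmonic: amplitude sqrt(A^2 + B^2)
  co2 <- model_coefficients(A = 3e-3, B = 4e-3, C = 0, alpha = 1,
                            omega = 2 * pi * 20)
  expect_equal(max_speed(co2, horizon = 1, form = "full"), 5e-3,
               tolerance = 1e-6)

  # mixed case against a brute-force 1e6-point grid
  co3 <- model_coefficients(A = 0.01, B = -0.006, C = 0.02, alpha = 2,
                            v_offset = 0.001, omega = 2 * pi * 35)
  grid <- seq(0, 2, length.out = 1e6)
  brute <- max(abs(analytic_velocity(co3, grid)))
  expect_equal(max_speed(co3, horizon = 2, form = "full"), brute,
               tolerance = 1e-3)
})

test_that("trajectories rotate rigidly with the beam angle", {
  co <- model_coefficients(C = 0.02, alpha = 1.2, v_offset = 0.002)
  tg <- seq(0, 2, by = 0.01)

  tr0 <- trajectory(co, beam_angle = 0, t_grid = tg)
  expect_equal(max(abs(tr0$lateral)), 0)           # purely axial at 0 deg
  tr15 <- trajectory(co, beam_angle = 15, t_grid = tg)
  expect_equal(tr15$arc_length, tr0$arc_length, tolerance = 1e-12)
  # rotation is an isometry of the displacement
  expect_equal(sqrt(tr15$lateral^2 + tr15$axial^2),
               sqrt(tr0$lateral^2 + tr0$axial^2), tolerance = 1e-12)

  # constant 40 mm/s for 0.1 s covers 4 mm
  co_c <- model_coefficients(C = 0, alpha = 1, v_offset = 0.04)
  tr_c <- trajectory(co_c, beam_angle = 0, t_grid = seq(0, 0.1, by = 1e-3))
  expect_equal(tr_c$arc_length[length(tr_c$arc_length)], 4e-3,
               tolerance = 1e-9)
})

test_that("power sweep rises strictly under the sqrt mapping", {
  bub <- nanobubble()
  fluid <- fluid_medium()
  beam <- ultrasound_beam()

  tab <- power_sweep(bub, fluid, beam, powers = c(0.05, 0.25, 0.5, 0.75, 1),
                     horizon = 1)
  expect_equal(nrow(tab), 5)
  expect_true(all(diff(tab$peak_speed) > 0))
  expect_equal(tab$p0_pa, 1e6 * sqrt(tab$power_fraction))

  single <- power_sweep(bub, fluid, beam, powers = 0.3, horizon = 1)
  co_3 <- derive_coefficients(bub, fluid,
                              ultrasound_beam(power_fraction = 0.3))
  expect_equal(single$peak_speed, max_speed(co_3, 1))

  expect_error(power_sweep(bub, fluid, beam, powers = c(0.5, 0.2)),
               class = "bubblesteer_validation_error")
})
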