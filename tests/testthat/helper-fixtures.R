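# Shared builders for test fixtures. Everything is generated in code with
# fixed seeds; no data files.

default_fluid <- function(...) fluid_medium(...)
default_bubble <- function(...) nanobubble(...)
default_beam <- function(...) ultrasound_beam(...)

# bubble whose effective density is chosen so that alpha = b/m takes a given
# value: lets second-scale dynamics be exercised with the physical machinery
bubble_for_alpha <- function(alpha, radius = 1e-7, fluid = default_fluid()) {
  b <- drag_coefficient(nanobubble(radius = radius), fluid)
  v <- (4 / 3) * pi * radius^3
  nanobubble(radius = radius, effective_density = b / (alpha * v))
}

# a beam whose angular frequency is omega (for slow-forcing regimes where
# the numerical oracle can resolve every cycle)
beam_for_omega <- function(omega, p0 = 1e6, ...) {
  ultrasound_beam(frequency = omega / (2 * pi),
                  peak_pressure_full_power = p0, ...)
}

no_buoyancy <- function() force_toggles(buoyancy = FALSE)

# deterministic depth profile with an exact, noise-free group separation:
# treated replicates at `hot_depths` sit far above baseline, elsewhere they
# straddle the baseline mean symmetrically (t statistic exactly 0)
constructed_profile <- function(hot_depths, depths = seq(0, 500, by = 100),
                                base_mean = 100, shift = 10 * 8.66) {
  base_reps <- base_mean + c(-10, -5, 5, 10)      # mean 100, sd ~ 8.66
  rows <- lapply(depths, function(d) {
    dens <- if (d %in% hot_depths) {
      base_mean + shift + c(-1, 0, 1)
    } else {
      base_mean + c(-2, 0, 2)
    }
    data.frame(depth_um = d, density_au = dens,
               replicate_id = seq_along(dens), group = "treated")
  })
  rows <- do.call(rbind, rows)
  base <- data.frame(depth_um = NA_real_, density_au = base_reps,
                     replicate_id = seq_along(base_reps), group = "baseline")
  depth_profile(rbind(rows, base))
}
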