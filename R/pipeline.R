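# Configuration-driven pipeline: each run_*() function is a thin
# orchestration of the modelling, fitting and profiling functions, reading
# one config (YAML or JSON, flat blocks) and writing CSV data plus JSON
# reports and a run manifest (config + seed + package version), so any run
# is reproducible from its manifest alone.
#
# Units at the boundary follow imaging practice: mm/s, um, MHz, % power.
# Everything is converted to strict SI on entry; conversion is this layer's
# sole responsibility. Validation failures signal conditions of class
# `bubblesteer_validation_error`, computation failures
# `bubblesteer_computation_error`, so callers can distinguish them.

#' Default run configuration
#'
#' @return A nested list with blocks `mode`, `seed`, `alpha_level`, `fluid`,
#'   `bubble`, `beam`, `model`, `empirical`, `simulate`, `sweep` and
#'   `synth`, in boundary units (MHz, % power, mm/s, um).
#' @export
default_run_config <- function() {
  list(
    mode = "physical",
    seed = 1L,
    alpha_level = 0.05,
    fluid = list(density = 1015, dynamic_viscosity = 1e-3,
                 sound_speed = 1520, gravity = 9.81),
    bubble = list(radius_nm = 100, effective_density = 100),
    beam = list(frequency_mhz = 40, peak_pressure_full_power_pa = 1e6,
                power_percent = 100, beam_angle_deg = 0,
                attenuation_np_m = 0, power_mapping = "sqrt"),
    model = list(bjerknes = TRUE, buoyancy = TRUE, drag = TRUE,
                 added_mass = FALSE, beam_vertical_angle_deg = 0,
                 v0_mm_s = 0),
    empirical = list(alpha_per_s = 1.2, c_mm_s = 40, v_offset_mm_s = 0,
                     a_mm_s = 0, b_mm_s = 0),
    simulate = list(duration_s = 5, frame_rate_hz = 100),
    sweep = list(powers_percent = c(5, 25, 50, 100), horizon_s = 5),
    synth = list(powers_percent = c(30, 70, 80, 100))
  )
}

#' Read a run configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`); missing fields fall back to
#' [default_run_config()].
#'
#' @param path Config file path.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    validation_abort("config file '%s' does not exist.", path)
  }
  ext <- tolower(sub(".*\\.", "", path))
  cfg <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    validation_abort("config file '%s' must be YAML or JSON.", path)
  )
  merge_config(default_run_config(), cfg)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

# config -> SI physical objects
config_objects <- function(config) {
  f <- config$fluid
  b <- config$bubble
  m <- config$beam
  if (is.null(b$radius_nm) || b$radius_nm <= 0) {
    validation_abort("config field `bubble.radius_nm` must be positive.")
  }
  if (is.null(m$frequency_mhz) || m$frequency_mhz <= 0) {
    validation_abort("config field `beam.frequency_mhz` must be positive.")
  }
  if (is.null(m$power_percent) || m$power_percent <= 0 ||
      m$power_percent > 100) {
    validation_abort("config field `beam.power_percent` must lie in (0, 100].")
  }
  list(
    fluid = fluid_medium(density = f$density,
                         dynamic_viscosity = f$dynamic_viscosity,
                         sound_speed = f$sound_speed, gravity = f$gravity),
    bubble = nanobubble(radius = b$radius_nm * 1e-9,
                        effective_density = b$effective_density),
    beam = ultrasound_beam(
      frequency = m$frequency_mhz * 1e6,
      peak_pressure_full_power = m$peak_pressure_full_power_pa,
      power_fraction = m$power_percent / 100,
      beam_angle = m$beam_angle_deg,
      attenuation = m$attenuation_np_m,
      power_mapping = m$power_mapping),
    forces = force_toggles(bjerknes = config$model$bjerknes,
                           buoyancy = config$model$buoyancy,
                           drag = config$model$drag),
    added_mass = isTRUE(config$model$added_mass),
    beam_vertical_angle = config$model$beam_vertical_angle_deg,
    v0 = config$model$v0_mm_s / 1e3
  )
}

config_coefficients <- function(config) {
  if (identical(config$mode, "physical")) {
    o <- config_objects(config)
    derive_coefficients(o$bubble, o$fluid, o$beam, v0 = o$v0,
                        forces = o$forces,
                        beam_vertical_angle = o$beam_vertical_angle,
                        added_mass = o$added_mass)
  } else if (identical(config$mode, "empirical")) {
    e <- config$empirical
    model_coefficients(A = (e$a_mm_s %||% 0) / 1e3,
                       B = (e$b_mm_s %||% 0) / 1e3,
                       C = e$c_mm_s / 1e3, alpha = e$alpha_per_s,
                       v_offset = (e$v_offset_mm_s %||% 0) / 1e3,
                       omega = 2 * pi * config$beam$frequency_mhz * 1e6)
  } else {
    validation_abort("config field `mode` must be 'physical' or 'empirical'.")
  }
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

write_manifest <- function(config, out_dir, command) {
  write_json_report(
    list(command = command,
         package = "bubblesteer",
         version = as.character(packageVersion("bubblesteer")),
         seed = config$seed,
         config = config),
    file.path(out_dir, paste0(command, "_manifest.json")))
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  invisible(out_dir)
}

#' Simulate a velocity trace and trajectory from a configuration
#'
#' Derives coefficients (physical or empirical mode), samples the
#' cycle-averaged speed |v| on the configured time grid, integrates the
#' imaging-plane trajectory, and writes `trace.csv`, `trajectory.csv` and a
#' run manifest.
#'
#' @param config Configuration list (see [default_run_config()]) or a path
#'   accepted by [read_run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the coefficients, the trace tibble, the
#'   trajectory tibble and the written file paths.
#' @export
run_simulate <- function(config = default_run_config(), out_dir) {
  config <- as_config(config)
  ensure_dir(out_dir)
  co <- config_coefficients(config)
  sim <- config$simulate
  n <- floor(sim$duration_s * sim$frame_rate_hz)
  t <- (seq_len(n) - 1) / sim$frame_rate_hz
  trace <- velocity_trace(
    time = t, speed = abs(cycle_averaged_velocity(co, t)),
    power_fraction = config$beam$power_percent / 100,
    frame_rate = sim$frame_rate_hz, label = "simulated")
  traj <- trajectory(co, beam_angle = config$beam$beam_angle_deg,
                     t_grid = t)
  files <- c(trace = file.path(out_dir, "trace.csv"),
             trajectory = file.path(out_dir, "trajectory.csv"))
  write_velocity_trace(trace, files[["trace"]])
  writeLines(c("time_s,arc_length_mm,lateral_mm,axial_mm",
               sprintf("%s,%s,%s,%s", format_num(traj$time),
                       format_num(traj$arc_length * 1e3),
                       format_num(traj$lateral * 1e3),
                       format_num(traj$axial * 1e3))),
             files[["trajectory"]])
  write_manifest(config, out_dir, "simulate")
  invisible(list(coefficients = co, trace = trace, trajectory = traj,
                 files = files))
}

as_config <- function(config) {
  if (is.character(config)) read_run_config(config)
  else merge_config(default_run_config(), config)
}

#' Fit the transient model to a trace file
#'
#' Reads the trace named in `config$fit$trace`, runs [fit_transient()],
#' adds the effective forcing estimate when physical parameters are
#' configured, and writes `fit.json` plus a manifest.
#'
#' @inheritParams run_simulate
#' @return Invisibly, the `onb_fit` object.
#' @export
run_fit <- function(config, out_dir) {
  config <- as_config(config)
  ensure_dir(out_dir)
  path <- config$fit$trace
  if (is.null(path)) {
    validation_abort("config field `fit.trace` (trace file path) is required.")
  }
  trace <- read_velocity_trace(path)
  fit <- fit_transient(trace, form = config$fit$form %||% "cycle_averaged")
  report <- list(
    trace = path,
    form = fit$form,
    converged = fit$converged,
    degenerate = fit$degenerate,
    estimates = list(
      c_mm_s = fit$estimates[["C"]] * 1e3,
      alpha_per_s = fit$estimates[["alpha"]],
      v_offset_mm_s = fit$estimates[["v_offset"]] * 1e3),
    std_errors = list(
      c_mm_s = fit$se[["C"]] * 1e3,
      alpha_per_s = fit$se[["alpha"]],
      v_offset_mm_s = fit$se[["v_offset"]] * 1e3),
    r_squared = fit$r_squared,
    rss = fit$rss,
    iterations = fit$iterations
  )
  if (identical(config$mode, "physical") && fit$converged) {
    o <- config_objects(config)
    forcing <- estimate_forcing(fit, o$bubble, o$fluid, o$beam)
    report$effective_forcing <- list(f0_n = forcing$f0_n,
                                     p0_pa = forcing$p0_pa)
  }
  write_json_report(report, file.path(out_dir, "fit.json"))
  write_manifest(config, out_dir, "fit")
  invisible(fit)
}

#' Run and analyze a beam-power sweep
#'
#' Sweeps the configured powers through the physical model, analyzes
#' monotonicity and the speed-power exponent, and writes
#' `power_sweep.csv` (power_fraction, p0_pa, peak_speed_mm_s),
#' `power_sweep.json` and a manifest.
#'
#' @inheritParams run_simulate
#' @return Invisibly, the `onb_sweep` analysis.
#' @export
run_power_sweep <- function(config = default_run_config(), out_dir) {
  config <- as_config(config)
  ensure_dir(out_dir)
  o <- config_objects(config)
  powers <- sort(config$sweep$powers_percent) / 100
  tab <- power_sweep(o$bubble, o$fluid, o$beam, powers,
                     horizon = config$sweep$horizon_s %||% 5,
                     v0 = o$v0, forces = o$forces,
                     beam_vertical_angle = o$beam_vertical_angle,
                     added_mass = o$added_mass)
  sweep <- analyze_power_sweep(tab)
  writeLines(c("power_fraction,p0_pa,peak_speed_mm_s",
               sprintf("%s,%s,%s", format_num(tab$power_fraction),
                       format_num(tab$p0_pa),
                       format_num(tab$peak_speed * 1e3))),
             file.path(out_dir, "power_sweep.csv"))
  write_json_report(
    list(verdict = sweep$verdict, spearman_rho = sweep$spearman_rho,
         gamma = sweep$gamma, gamma_se = sweep$gamma_se,
         peak_speed_mm_s = sweep$table$peak_speed * 1e3,
         power_fraction = sweep$table$power_fraction),
    file.path(out_dir, "power_sweep.json"))
  write_manifest(config, out_dir, "power-sweep")
  invisible(sweep)
}

#' Analyze a depth-profile file
#'
#' Reads the profile named in `config$profile$path`, compares each depth to
#' the control baseline, fits the exponential decay, calls the penetration
#' depth, and writes `depth_profile.json` plus a manifest.
#'
#' @inheritParams run_simulate
#' @return Invisibly, a list with the comparison table, decay fit and
#'   penetration depth (um).
#' @export
run_depth_profile <- function(config, out_dir) {
  config <- as_config(config)
  ensure_dir(out_dir)
  path <- config$profile$path
  if (is.null(path)) {
    validation_abort("config field `profile.path` is required.")
  }
  profile <- read_depth_profile(path)
  comparison <- compare_to_baseline(profile,
                                    alpha_level = config$alpha_level)
  decay <- fit_decay(profile)
  depth <- penetration_depth(profile, comparison)
  write_json_report(
    list(profile = path,
         alpha_level = config$alpha_level,
         penetration_depth_um = depth,
         decay = list(lambda_um = decay$lambda, d0_au = decay$d0,
                      floor_au = decay$floor, r_squared = decay$r_squared,
                      converged = decay$converged, flat = decay$flat),
         per_depth = lapply(seq_len(nrow(comparison)), function(i) {
           as.list(comparison[i, c("depth_um", "n", "mean_density",
                                   "mean_diff", "statistic", "p_value",
                                   "p_adjusted", "significant_raw",
                                   "significant", "testable")])
         })),
    file.path(out_dir, "depth_profile.json"))
  write_manifest(config, out_dir, "depth-profile")
  invisible(list(comparison = comparison, decay = decay,
                 penetration_depth_um = depth))
}

#' Generate synthetic fixtures from a configuration
#'
#' Writes one velocity trace per configured power (child-seeded from the
#' master seed), a depth profile with baseline, and a manifest.
#'
#' @inheritParams run_simulate
#' @return Invisibly, the written file paths.
#' @export
run_synth <- function(config = default_run_config(), out_dir) {
  config <- as_config(config)
  ensure_dir(out_dir)
  spec <- synthesis_spec(seed = config$seed)
  powers <- config$synth$powers_percent / 100
  traces <- synth_power_series(spec, powers)
  files <- vapply(seq_along(traces), function(i) {
    path <- file.path(out_dir,
                      sprintf("trace_power_%03d.csv",
                              round(100 * powers[i])))
    write_velocity_trace(traces[[i]], path)
    path
  }, character(1))
  profile_path <- file.path(out_dir, "depth_profile.csv")
  write_depth_profile(
    synth_depth_profile(spec, seed = child_seed(spec$seed, 0L)),
    profile_path)
  write_manifest(config, out_dir, "synth")
  invisible(c(files, profile = profile_path))
}

#' Materialize the canonical fixture directory
#'
#' The fixed test-data set: traces at 30/70/80/100% power and one depth
#' profile, regenerated byte-identically from the packaged defaults and the
#' given seed.
#'
#' @param dir Target directory.
#' @param seed Master seed. Default 20240901.
#' @return Invisibly, the written file paths.
#' @export
write_fixtures <- function(dir, seed = 20240901L) {
  cfg <- default_run_config()
  cfg$seed <- as.integer(seed)
  run_synth(cfg, dir)
}
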