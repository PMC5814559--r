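# Seeded synthetic-data generator: noisy velocity traces with the decay
# model's structure (emulating second-scale kymograph measurements at
# several beam powers) and spot-density depth profiles (emulating serial
# dark-field sections over a control baseline).

#' Synthesis specification
#'
#' Ground truth and sampling settings for the generator. The defaults mirror
#' the study conditions the package targets: a peak cycle-averaged speed of
#' 40 mm/s at 100% power decaying at alpha = 1.2 1/s, sampled at 100
#' frames/s for 5 s with 2 mm/s additive Gaussian noise; and depth profiles
#' over 0-500 um in 100 um steps with decay length 180 um, amplitude 1000 au
#' over a 100 +/- 20 au control baseline, 10% amplitude noise and 5 imaged
#' fields per depth. Traces use the empirical coefficient route: the
#' seconds-scale decay of measured traces is an effective timescale, not one
#' a literal nanoscale parameter set produces.
#'
#' @param alpha Decay rate of the cycle-averaged speed (1/s).
#' @param peak_speed Truth peak speed at 100% power (m/s).
#' @param v_offset Steady speed component (m/s).
#' @param power_mapping `"sqrt"` (default) or `"linear"` power-to-pressure
#'   mapping applied to the truth amplitude.
#' @param frame_rate Sampling rate (1/s).
#' @param duration Trace duration (s); `duration * frame_rate` must be >= 8.
#' @param noise_sd Additive Gaussian noise on speed (m/s).
#' @param depths Sectioned depths (um), strictly increasing.
#' @param lambda Truth decay length of the depth profile (um); may be `Inf`.
#' @param d0 Truth amplitude at the periphery (au).
#' @param baseline_mean,baseline_sd Control-baseline density mean/sd (au).
#' @param profile_noise_sd Treated-density noise sd (au); default 10% of
#'   `d0`.
#' @param fields_per_depth Imaged fields (replicates) per depth.
#' @param n_baseline Baseline replicates.
#' @param seed Master seed (integer).
#' @return An object of class `synthesis_spec`.
#' @export
synthesis_spec <- function(alpha = 1.2, peak_speed = 0.04, v_offset = 0,
                           power_mapping = c("sqrt", "linear"),
                           frame_rate = 100, duration = 5, noise_sd = 0.002,
                           depths = seq(0, 500, by = 100), lambda = 180,
                           d0 = 1000, baseline_mean = 100, baseline_sd = 20,
                           profile_noise_sd = 0.1 * d0,
                           fields_per_depth = 5, n_baseline = 10,
                           seed = 1L) {
  power_mapping <- match.arg(power_mapping)
  check_positive(alpha, "alpha")
  check_positive(peak_speed, "peak_speed", strict = FALSE)
  check_positive(v_offset, "v_offset", strict = FALSE)
  check_positive(frame_rate, "frame_rate")
  check_positive(duration, "duration")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  if (duration * frame_rate < 8) {
    validation_abort("`duration * frame_rate` must give at least 8 samples.")
  }
  if (length(depths) < 2L || any(diff(depths) <= 0)) {
    validation_abort("`depths` must be strictly increasing.")
  }
  if (!(is.numeric(lambda) && length(lambda) == 1L && lambda > 0)) {
    validation_abort("`lambda` must be positive (Inf allowed).")
  }
  check_positive(d0, "d0", strict = FALSE)
  check_positive(baseline_mean, "baseline_mean", strict = FALSE)
  check_positive(baseline_sd, "baseline_sd", strict = FALSE)
  check_positive(profile_noise_sd, "profile_noise_sd", strict = FALSE)
  if (fields_per_depth < 1 || n_baseline < 2) {
    validation_abort(
      "need >= 1 field per depth and >= 2 baseline replicates.")
  }
  seed <- as.integer(seed)
  structure(
    list(alpha = alpha, peak_speed = peak_speed, v_offset = v_offset,
         power_mapping = power_mapping, frame_rate = frame_rate,
         duration = duration, noise_sd = noise_sd, depths = depths,
         lambda = lambda, d0 = d0, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, profile_noise_sd = profile_noise_sd,
         fields_per_depth = as.integer(fields_per_depth),
         n_baseline = as.integer(n_baseline), seed = seed),
    class = "synthesis_spec"
  )
}

#' Deterministic child seed derivation
#'
#' Children of a master seed are derived with a fixed multiplicative rule,
#' `(seed * 48271 + index * 104729) mod (2^31 - 1)` (mapped to \[1, 2^31-2\]),
#' so that per-power traces and other sub-streams are reproducible across
#' implementations of the same rule.
#'
#' @param seed Master seed.
#' @param index Non-negative child index.
#' @return An integer seed.
#' @export
child_seed <- function(seed, index) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m) * 48271 + as.numeric(index) * 104729
  as.integer(s %% m + 1)
}

truth_coefficients <- function(spec, power_fraction) {
  model_coefficients(
    A = 0, B = 0,
    C = spec$peak_speed * power_to_pressure(power_fraction,
                                            spec$power_mapping),
    alpha = spec$alpha, v_offset = spec$v_offset
  )
}

#' Generate one noisy velocity trace
#'
#' Samples the cycle-averaged truth speed at the spec's frame rate, adds
#' independent Gaussian noise and clips negative speeds at 0 (speed data
#' are magnitudes; the clipping is a documented bias source at low SNR).
#' Byte-identical for identical (spec, seed).
#'
#' @param spec A [synthesis_spec()].
#' @param power_fraction Transmit power fraction in (0, 1].
#' @param seed Seed; defaults to the spec's master seed.
#' @return A [velocity_trace()].
#' @export
synth_velocity_trace <- function(spec, power_fraction = 1,
                                 seed = spec$seed) {
  if (!inherits(spec, "synthesis_spec")) {
    validation_abort("`spec` must be a synthesis_spec.")
  }
  check_fraction(power_fraction, "power_fraction")
  co <- truth_coefficients(spec, power_fraction)
  n <- floor(spec$duration * spec$frame_rate)
  t <- (seq_len(n) - 1) / spec$frame_rate
  truth <- cycle_averaged_velocity(co, t)
  speed <- withr::with_seed(seed, {
    pmax(truth + rnorm(n, 0, spec$noise_sd), 0)
  })
  velocity_trace(time = t, speed = speed, power_fraction = power_fraction,
                 frame_rate = spec$frame_rate,
                 label = sprintf("synthetic-power-%g", power_fraction))
}

#' Generate a set of traces across beam powers
#'
#' One trace per power, truth amplitudes following the spec's
#' power-to-pressure mapping, each with a child seed derived from the
#' master seed via [child_seed()].
#'
#' @inheritParams synth_velocity_trace
#' @param powers Power fractions in (0, 1].
#' @return Named list of [velocity_trace()] objects (names are the powers).
#' @export
synth_power_series <- function(spec, powers = c(0.3, 0.7, 0.8)) {
  traces <- purrr::imap(as.list(powers), function(p, i) {
    synth_velocity_trace(spec, power_fraction = p,
                         seed = child_seed(spec$seed, i))
  })
  names(traces) <- as.character(powers)
  traces
}

#' Generate a synthetic depth profile with baseline
#'
#' Treated densities follow D0 exp(-(d_max - d)/lambda) + baseline_mean
#' plus Gaussian noise (sd `profile_noise_sd`), replicated over imaged
#' fields; baseline densities are baseline_mean plus Gaussian noise
#' (sd `baseline_sd`). Negative draws are truncated at 0.
#'
#' @inheritParams synth_velocity_trace
#' @return A [depth_profile()] containing treated and baseline rows.
#' @export
synth_depth_profile <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "synthesis_spec")) {
    validation_abort("`spec` must be a synthesis_spec.")
  }
  d_max <- max(spec$depths)
  truth <- spec$d0 * exp(-(d_max - spec$depths) / spec$lambda) +
    spec$baseline_mean
  withr::with_seed(seed, {
    treated <- tidyr::expand_grid(depth_um = spec$depths,
                                  replicate_id = seq_len(spec$fields_per_depth))
    treated$density_au <- pmax(
      rep(truth, each = spec$fields_per_depth) +
        rnorm(nrow(treated), 0, spec$profile_noise_sd), 0)
    treated$group <- "treated"
    base <- tibble(
      depth_um = NA_real_,
      replicate_id = seq_len(spec$n_baseline),
      density_au = pmax(spec$baseline_mean +
                          rnorm(spec$n_baseline, 0, spec$baseline_sd), 0),
      group = "baseline"
    )
    depth_profile(dplyr::bind_rows(treated, base))
  })
}

#' Write a depth profile to CSV
#'
#' Columns `depth_um`, `density_au`, `replicate_id`, `group`; baseline rows
#' have an empty depth. Fixed formatting for byte-identical regeneration.
#'
#' @param profile A [depth_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_depth_profile <- function(profile, path) {
  lines <- c(
    "depth_um,density_au,replicate_id,group",
    sprintf("%s,%s,%d,%s",
            ifelse(is.na(profile$depth_um), "",
                   format_num(profile$depth_um)),
            format_num(profile$density_au),
            as.integer(profile$replicate_id), profile$group)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a depth profile from CSV
#'
#' @param path File written by [write_depth_profile()].
#' @return A [depth_profile()].
#' @export
read_depth_profile <- function(path) {
  if (!file.exists(path)) {
    validation_abort("profile file '%s' does not exist.", path)
  }
  df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  depth_profile(df)
}
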