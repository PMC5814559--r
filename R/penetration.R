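# Penetration-depth analysis of spot-density-vs-depth tables from serial
# tissue sections.
#
# Depth convention: 0 at the bladder wall, increasing outward toward the
# tumor periphery (the maximum sectioned depth). Bubbles enter from the
# periphery, so the density profile decays from d_max inward:
# density(d) = D0 exp(-(d_max - d)/lambda) + floor.

#' Depth profile of bubble spot density
#'
#' Builds the container consumed by [compare_to_baseline()], [fit_decay()]
#' and [penetration_depth()] from a long table with columns `depth_um`
#' (NA for baseline rows), `density_au`, `replicate_id` and `group`
#' (`"treated"` or `"baseline"`). Baseline rows carry the background signal
#' from control tissue.
#'
#' @param data Data frame with the four columns above.
#' @return A tibble of class `onb_profile`.
#' @export
depth_profile <- function(data) {
  need <- c("depth_um", "density_au", "replicate_id", "group")
  if (!all(need %in% names(data))) {
    validation_abort("`data` needs columns %s.", paste(need, collapse = ", "))
  }
  if (!all(data$group %in% c("treated", "baseline"))) {
    validation_abort("`group` must be 'treated' or 'baseline'.")
  }
  tr <- data[data$group == "treated", ]
  if (nrow(tr) == 0L) {
    validation_abort("at least one treated measurement is required.")
  }
  if (any(!is.finite(tr$depth_um))) {
    validation_abort("treated rows must have finite `depth_um`.")
  }
  if (any(!is.finite(data$density_au)) || any(data$density_au < 0)) {
    validation_abort("`density_au` must be finite and non-negative.")
  }
  out <- as_tibble(data[need])
  class(out) <- c("onb_profile", class(out))
  out
}

profile_treated <- function(profile) {
  profile[profile$group == "treated", , drop = FALSE]
}

profile_baseline <- function(profile) {
  profile$density_au[profile$group == "baseline"]
}

#' Per-depth significance of bubble signal over the control baseline
#'
#' For every sectioned depth, compares the treated spot densities against
#' the pooled control-baseline densities with an unpaired two-sample
#' Student's t-test, then adjusts across depths with Benjamini-Hochberg.
#' Both the unadjusted 5%-level call (the conventional per-depth test) and
#' the BH-adjusted call are reported; the adjusted call is authoritative
#' and is what [penetration_depth()] consumes.
#'
#' @param profile A [depth_profile()] with non-empty baseline.
#' @param alpha_level Significance level. Default 0.05.
#' @return Tibble with one row per depth: `depth_um`, `n`, `mean_density`,
#'   `mean_diff`, `statistic`, `df`, `p_value`, `p_adjusted`,
#'   `significant_raw`, `significant`, `testable`.
#' @export
compare_to_baseline <- function(profile, alpha_level = 0.05) {
  check_fraction(alpha_level, "alpha_level")
  base <- profile_baseline(profile)
  if (length(base) < 2L) {
    validation_abort("at least 2 baseline replicates are required.")
  }
  tr <- profile_treated(profile)
  out <- tr |>
    dplyr::group_by(depth_um = .data$depth_um) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_density = mean(.data$density_au),
      test = list(depth_t_test(.data$density_au, base)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("test") |>
    dplyr::arrange(.data$depth_um)
  out$p_adjusted <- NA_real_
  out$p_adjusted[out$testable] <- p.adjust(out$p_value[out$testable],
                                           method = "BH")
  out$significant_raw <- out$testable & !is.na(out$p_value) &
    out$p_value < alpha_level
  out$significant <- out$testable & !is.na(out$p_adjusted) &
    out$p_adjusted < alpha_level
  out
}

depth_t_test <- function(x, base) {
  if (length(x) < 2L) {
    return(list(mean_diff = mean(x) - mean(base), statistic = NA_real_,
                df = NA_real_, p_value = NA_real_, testable = FALSE))
  }
  diff <- mean(x) - mean(base)
  res <- tryCatch(
    t.test(x, base, var.equal = TRUE),
    error = function(e) NULL  # "data are essentially constant"
  )
  if (is.null(res)) {
    # zero pooled variance: identical means are a null result, any
    # difference is infinitely significant
    if (abs(diff) < .Machine$double.eps * max(abs(mean(base)), 1)) {
      return(list(mean_diff = diff, statistic = 0,
                  df = length(x) + length(base) - 2, p_value = 1,
                  testable = TRUE))
    }
    return(list(mean_diff = diff, statistic = sign(diff) * Inf,
                df = length(x) + length(base) - 2, p_value = 0,
                testable = TRUE))
  }
  list(mean_diff = diff, statistic = unname(res$statistic),
       df = unname(res$parameter), p_value = res$p.value, testable = TRUE)
}

#' Fit an exponential decay to a depth profile
#'
#' Least-squares fit of density(d) = D0 exp(-(d_max - d)/lambda) + floor,
#' where d_max is the tumor-periphery depth (signal enters from the
#' periphery and decays inward). Initialisation is deterministic from the
#' endpoint mean densities. A flat profile (no depth structure) is flagged
#' with lambda = Inf rather than fitted.
#'
#' The floor of the decay is physically the background signal, which the
#' control-baseline replicates measure directly; with only a handful of
#' sectioned depths a freely fitted floor is strongly confounded with
#' lambda and inflates its variance severalfold. By default
#' (`floor = "auto"`) the floor is therefore anchored at the baseline mean
#' whenever baseline replicates are present and only D0 and lambda are
#' fitted; `floor = "estimate"` forces the 3-parameter fit.
#'
#' @param profile A [depth_profile()] with >= 4 distinct treated depths.
#' @param floor `"auto"` (default), `"baseline"` or `"estimate"`.
#' @param max_iter Maximum Levenberg-Marquardt iterations. Default 200.
#' @return An object of class `onb_decay_fit` with fields `lambda` (um),
#'   `d0`, `floor`, standard errors, `r_squared`, `converged`, `flat`.
#' @export
fit_decay <- function(profile, floor = c("auto", "baseline", "estimate"),
                      max_iter = 200) {
  floor <- match.arg(floor)
  tr <- profile_treated(profile)
  base <- profile_baseline(profile)
  if (floor == "auto") {
    floor <- if (length(base) >= 2L) "baseline" else "estimate"
  }
  if (floor == "baseline" && length(base) < 2L) {
    validation_abort("floor = \"baseline\" needs >= 2 baseline replicates.")
  }
  depths <- sort(unique(tr$depth_um))
  if (length(depths) < 4L) {
    validation_abort("at least 4 distinct depths are required.")
  }
  d_max <- max(depths)
  means <- vapply(depths, function(d) {
    mean(tr$density_au[tr$depth_um == d])
  }, numeric(1))

  if (diff(range(means)) < 1e-10 * max(abs(means), 1)) {
    return(new_decay_fit(lambda = Inf, d0 = 0, floor = mean(means),
                         se = c(lambda = NA, d0 = NA, floor = NA),
                         r_squared = NA_real_, converged = TRUE, flat = TRUE,
                         d_max = d_max, fit = NULL, profile = profile))
  }

  floor0 <- if (floor == "baseline") mean(base) else min(means)
  d0_0 <- max(means[length(means)] - floor0, 0.01 * diff(range(means)))
  # decades of decay between the wall-side and periphery-side endpoints
  ratio <- max((means[1] - floor0) / d0_0, 0.05)
  lambda0 <- (d_max - depths[1]) / max(-log(ratio), 0.5)

  df <- data.frame(d = tr$depth_um, y = tr$density_au, d_max = d_max)
  if (floor == "baseline") {
    df$fl <- floor0
    start <- list(d0 = d0_0, lambda = lambda0)
    lower <- c(d0 = 0, lambda = 1e-6)
    formula <- y ~ d0 * exp(-(d_max - d) / lambda) + fl
  } else {
    start <- list(d0 = d0_0, lambda = lambda0, fl = floor0)
    lower <- c(d0 = 0, lambda = 1e-6, fl = 0)
    formula <- y ~ d0 * exp(-(d_max - d) / lambda) + fl
  }
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    formula, data = df, start = start, lower = lower,
    control = minpack.lm::nls.lm.control(maxiter = max_iter)
  )), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(new_decay_fit(lambda = NA_real_, d0 = NA_real_, floor = NA_real_,
                         se = c(lambda = NA, d0 = NA, floor = NA),
                         r_squared = NA_real_, converged = FALSE,
                         flat = FALSE, d_max = d_max, fit = NULL,
                         profile = profile))
  }
  est <- coef(fit)
  se_raw <- tryCatch(sqrt(diag(vcov(fit))),
                     error = function(e) setNames(rep(NA_real_, length(est)),
                                                  names(est)))
  floor_est <- if (floor == "baseline") floor0 else est[["fl"]]
  floor_se <- if (floor == "baseline") sd(base) / sqrt(length(base))
              else se_raw[["fl"]]
  rss <- sum(residuals(fit)^2)
  tss <- sum((df$y - mean(df$y))^2)
  new_decay_fit(lambda = est[["lambda"]], d0 = est[["d0"]],
                floor = floor_est,
                se = c(lambda = se_raw[["lambda"]], d0 = se_raw[["d0"]],
                       floor = floor_se),
                r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                converged = TRUE, flat = FALSE, d_max = d_max, fit = fit,
                profile = profile)
}

new_decay_fit <- function(lambda, d0, floor, se, r_squared, converged, flat,
                          d_max, fit, profile) {
  structure(
    list(lambda = lambda, d0 = d0, floor = floor, se = se,
         r_squared = r_squared, converged = converged, flat = flat,
         d_max = d_max, fit = fit, profile = profile),
    class = "onb_decay_fit"
  )
}

#' @export
print.onb_decay_fit <- function(x, ...) {
  cat(sprintf(
    "<onb_decay_fit> lambda = %s um, D0 = %.4g, floor = %.4g, R^2 = %s%s\n",
    format(x$lambda), x$d0, x$floor, format(x$r_squared),
    if (x$flat) " (flat profile)" else ""))
  invisible(x)
}

#' @export
tidy.onb_decay_fit <- function(x, ...) {
  tibble(term = c("lambda", "d0", "floor"),
         estimate = c(x$lambda, x$d0, x$floor),
         std.error = as.numeric(x$se[c("lambda", "d0", "floor")]))
}

#' @export
glance.onb_decay_fit <- function(x, ...) {
  tibble(lambda = x$lambda, r.squared = x$r_squared,
         converged = x$converged, flat = x$flat,
         nobs = nrow(profile_treated(x$profile)))
}

#' Penetration depth from a significance table
#'
#' The maximum contiguous depth span, measured from the tumor periphery
#' (the deepest sectioned depth) inward, over which the BH-adjusted
#' significance from [compare_to_baseline()] holds. Contiguity is anchored
#' at the periphery because physical bubble transport into the tissue is
#' continuous: isolated deep hits do not extend the span. Returns 0 when no
#' depth (including the periphery itself) is significant.
#'
#' @param profile A [depth_profile()] (supplies the depth grid).
#' @param comparison Output of [compare_to_baseline()].
#' @return Penetration depth (um).
#' @export
penetration_depth <- function(profile, comparison) {
  tab <- dplyr::arrange(comparison, dplyr::desc(.data$depth_um))
  if (!nrow(tab) || !tab$significant[1]) {
    return(0)
  }
  periphery <- tab$depth_um[1]
  run_end <- periphery
  for (i in seq_len(nrow(tab))) {
    if (!tab$significant[i]) break
    run_end <- tab$depth_um[i]
  }
  periphery - run_end
}
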