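# Baseline comparison, decay-length fitting and the penetration-depth call.

test_that("baseline comparison flags exactly the separated depths", {
  # treated replicates sit 10 baseline-SDs above baseline at the hot depths
  # and straddle the baseline mean symmetrically (t = 0) elsewhere
  prof <- constructed_profile(hot_depths = c(0, 100, 200, 300))
  cmp <- compare_to_baseline(prof)
  expect_equal(cmp$depth_um, seq(0, 500, by = 100))
  expect_equal(cmp$significant, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(cmp$testable))
  expect_true(all(cmp$p_adjusted >= cmp$p_value, na.rm = TRUE))

  # equal-to-baseline everywhere: nothing significant
  cmp_null <- compare_to_baseline(constructed_profile(hot_depths = numeric(0)))
  expect_false(any(cmp_null$significant))
  expect_false(any(cmp_null$significant_raw))
})

test_that("single-replicate depths are flagged untestable", {
  prof <- constructed_profile(hot_depths = 500)
  one_rep <- rbind(
    as.data.frame(prof),
    data.frame(depth_um = 600, density_au = 400, replicate_id = 1,
               group = "treated"))
  cmp <- compare_to_baseline(depth_profile(one_rep))
  row <- cmp[cmp$depth_um == 600, ]
  expect_false(row$testable)
  expect_false(row$significant)
  expect_true(is.na(row$p_value))
})

test_that("decay fitting recovers the length scale and flags flat profiles", {
  # noiseless profile: lambda recovered within 1%
  spec0 <- synthesis_spec(profile_noise_sd = 0, baseline_sd = 0)
  fit0 <- fit_decay(synth_depth_profile(spec0))
  expect_true(fit0$converged)
  expect_equal(fit0$lambda, 180, tolerance = 0.01)
  expect_equal(fit0$d0, 1000, tolerance = 0.01)
  expect_equal(fit0$floor, 100, tolerance = 0.01)
  expect_gt(fit0$r_squared, 1 - 1e-10)
  expect_equal(tidy(fit0)$estimate[1], fit0$lambda)

  # the free-floor variant also recovers the noiseless truth
  fit0e <- fit_decay(synth_depth_profile(spec0), floor = "estimate")
  expect_equal(fit0e$lambda, 180, tolerance = 0.01)

  # flat profile: infinite decay length flag
  flat_spec <- synthesis_spec(lambda = Inf, d0 = 0, profile_noise_sd = 0,
                              baseline_sd = 0)
  fit_flat <- fit_decay(synth_depth_profile(flat_spec))
  expect_true(fit_flat$flat)
  expect_equal(fit_flat$lambda, Inf)
  expect_true(glance(fit_flat)$flat)

  expect_error(
    fit_decay(constructed_profile(hot_depths = 500,
                                  depths = c(0, 100, 200))),
    class = "bubblesteer_validation_error")
})

test_that("decay-length bias vanishes as noise shrinks", {
  errs <- sapply(c(50, 10, 1), function(sd_au) {
    spec <- synthesis_spec(profile_noise_sd = sd_au, baseline_sd = 0,
                           seed = 31)
    lam <- sapply(1:25, function(i) {
      fit_decay(synth_depth_profile(spec, seed = child_seed(31, i)))$lambda
    })
    abs(mean(lam) - 180)
  })
  expect_true(errs[3] < errs[1])
  expect_lt(errs[3], 1)
})

test_that("penetration depth is the periphery-anchored significant span", {
  # all depths significant: full 500 um span
  prof_all <- constructed_profile(hot_depths = seq(0, 500, by = 100))
  cmp_all <- compare_to_baseline(prof_all)
  expect_equal(penetration_depth(prof_all, cmp_all), 500)

  # significance only near the periphery: span measured inward from 500 um
  prof_p <- constructed_profile(hot_depths = c(300, 400, 500))
  expect_equal(penetration_depth(prof_p, compare_to_baseline(prof_p)), 200)

  # nothing significant: zero
  prof_0 <- constructed_profile(hot_depths = numeric(0))
  expect_equal(penetration_depth(prof_0, compare_to_baseline(prof_0)), 0)

  # an isolated deep hit does not extend the contiguous span
  prof_i <- constructed_profile(hot_depths = c(0, 400, 500))
  expect_equal(penetration_depth(prof_i, compare_to_baseline(prof_i)), 100)

  # periphery itself not significant: zero, wherever else signal sits
  prof_w <- constructed_profile(hot_depths = c(0, 100))
  expect_equal(penetration_depth(prof_w, compare_to_baseline(prof_w)), 0)
})

test_that("penetration depth grows with the signal-to-baseline effect size", {
  depths_called <- sapply(c(0.05, 1, 5), function(mult) {
    prof <- constructed_profile(hot_depths = c(300, 400, 500),
                                shift = mult * 10 * 8.66)
    penetration_depth(prof, compare_to_baseline(prof))
  })
  expect_true(all(diff(depths_called) >= 0))
  expect_equal(depths_called[3], 200)
})

test_that("depth profiles round-trip through CSV", {
  spec <- synthesis_spec(seed = 12)
  prof <- synth_depth_profile(spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_depth_profile(prof, path)
  back <- read_depth_profile(path)
  expect_equal(as.data.frame(back)$density_au,
               as.data.frame(prof)$density_au, tolerance = 1e-10)
  expect_equal(back$group, prof$group)
  expect_error(read_depth_profile("no/such/file.csv"),
               class = "bubblesteer_validation_error")
})
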