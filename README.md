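# bubblesteer

Physics and statistics for ultrasound-Doppler-propelled oxygen nanobubbles.

Oxygen nanobubbles (ONBs, ~200 nm gas-filled particles with a cellulosic
shell) can be pushed through liquid by a pulsed-wave Doppler ultrasound beam
and steered toward a target — for example into a bladder tumor after
intravesical instillation, where they deliver oxygen and drug to hypoxic
tissue. `bubblesteer` is for modellers and experimentalists working with
this kind of acoustically driven nanoparticle transport. It provides:

* **the force model and its closed-form velocity profile.** Primary
  Bjerknes forcing from a harmonic plane pressure wave
  (F = −V ∂p/∂x, constant bubble volume), buoyancy of the displaced fluid,
  and Stokes drag (−6πμRv, valid because Re = ρv·2R/μ ≪ 1) assemble into

  m v̇ = F₀ cos(ωt) + F_b − b v,  b = 6πμR,

  whose solution is v(t) = A cos(ωt) − B sin(ωt) + C e^(−αt) + v_off with
  α = b/m, A = F₀b/(b² + (mω)²), B = −F₀mω/(b² + (mω)²), v_off = F_b/b;
* **an independent numerical oracle** (`numerical_velocity()`, adaptive
  Dormand–Prince on the time-rescaled system) validating the closed form
  to < 10⁻⁶ relative error across decay rates 10⁻¹–10⁹ s⁻¹;
* **trace fitting** (`fit_transient()`): censored-normal nonlinear least
  squares of the cycle-averaged decay v̄(t) = v_off + C e^(−αt) to measured
  speed traces, with broom-style `tidy()`/`glance()`/`augment()` methods;
* **beam-power sweep analysis** (`power_sweep()`,
  `analyze_power_sweep()`): monotonicity verdict and the speed ∝ power^γ
  exponent (γ = 0.5 under the default √power pressure mapping);
* **tissue penetration profiling** (`compare_to_baseline()`,
  `fit_decay()`, `penetration_depth()`): per-depth Student's t against a
  control baseline with Benjamini–Hochberg adjustment, exponential
  decay-length estimation, and the contiguous significant span from the
  tumor periphery;
* **a seeded synthetic-data generator** (`synthesis_spec()`,
  `synth_velocity_trace()`, `synth_power_series()`,
  `synth_depth_profile()`) emulating the measured data structures with
  byte-identical reproducibility;
* **a config-driven pipeline** (`run_simulate()`, `run_fit()`,
  `run_power_sweep()`, `run_depth_profile()`, `run_synth()`) writing CSV
  data, JSON reports and run manifests.

## Worked example

Generate synthetic measurement-style traces at three beam powers, fit the decay
model, and analyse the power dependence:

```r
library(bubblesteer)

spec <- synthesis_spec(seed = 20240901)          # 40 mm/s peak, alpha = 1.2/s
traces <- synth_power_series(spec, powers = c(0.3, 0.7, 0.8))

fit <- fit_transient(traces[["0.8"]])
tidy(fit)
#> # A tibble: 3 × 4
#>   term     estimate std.error statistic
#>   <chr>       <dbl>     <dbl>     <dbl>
#> 1 C        0.0366    0.000371     98.7
#> 2 alpha    1.27      0.0274       46.2
#> 3 v_offset 0.000269  0.000174      1.54
```

The fitted transient amplitude C is 36.6 mm/s (the truth at 80% power is
40·√0.8 ≈ 35.8 mm/s) and the decay rate α is 1.27 s⁻¹ against a truth of
1.2 s⁻¹; v_offset is indistinguishable from zero, as generated.

```r
analyze_power_sweep(traces)
#> <onb_sweep> 3 powers, verdict: monotone-increasing
#>   spearman rho = 1.000, gamma = 0.5148 (se 0.023)
#> # A tibble: 3 × 2
#>   power_fraction peak_speed
#>            <dbl>      <dbl>
#> 1            0.3     0.0221
#> 2            0.7     0.0336
#> 3            0.8     0.0369
```

Peak speed rises strictly with power and the fitted exponent γ ≈ 0.51
recovers the √power pressure mapping. The same workflow applies to real
traces read with `read_velocity_trace()` (CSV columns `time_s`,
`speed_mm_s`, `#`-prefixed metadata).

Penetration analysis of a synthetic depth profile with its control
baseline:

```r
prof <- synth_depth_profile(spec)                # 0-500 um, lambda = 180 um
dec  <- fit_decay(prof)
dec
#> <onb_decay_fit> lambda = 182.3707 um, D0 = 959.4, floor = 95.58, R^2 = 0.924
penetration_depth(prof, compare_to_baseline(prof))
#> [1] 500
```

The decay length comes back at 182 µm (truth 180 µm) and the signal is
significantly above baseline over the full 500 µm span from the tumor
periphery.

Physical mode works from first principles — for a 100 nm-radius bubble in
urine under a 40 MHz, 1 MPa beam:

```r
derive_coefficients(nanobubble(), fluid_medium(), ultrasound_beam())
#> <model_coefficients> A = 0.3663, B = -0.02046, C = -0.3663 m/s;
#>   alpha = 4.5e+09 1/s; v_offset = -1.995e-08 m/s; omega = 2.513e+08 rad/s
reynolds_number(nanobubble(), fluid_medium(), 0.02)
#> [1] 0.00406
```

Note the physical transient decays in nanoseconds (α ≈ 4.5×10⁹ s⁻¹):
second-scale decays in measured traces are an *effective* timescale, which
is why fitting runs in empirical mode (see the vignette).

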