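# uvcdose

Dose equivalence and germicidal-effect analysis for continuous and pulsed
UV-C LED disinfection of fresh produce.

UV-C LEDs can run continuously or pulsed. A pulsed lamp is off most of each
cycle, so a pulsed treatment only matches a continuous one if its settings
are rebalanced to deliver the same fluence (dose). `uvcdose` implements that
rebalancing and the downstream microbiological analysis for the two standard
pulsed strategies:

* **CL (continuous light)** — constant irradiance `I_CL` for time `t_CL`,
  delivering dose `D = I_CL · t_CL` (mJ·cm⁻², with `I` in mW·cm⁻² and `t`
  in s).
* **Mode 1 / PPL (power-pulsed light)** — same exposure time as CL, but the
  pulse peak irradiance is raised to `I_PPL = I_CL · 100 / DutyCycle`, so
  the average power (and dose) is conserved.
* **Mode 2 / TPL (time-pulsed light)** — same irradiance as CL as the pulse
  amplitude, with the exposure prolonged by `v_t = 100 / DutyCycle`.

Around that planner the package provides:

* a **waveform renderer** (`pulse_train()`, `integrate_dose()`) that turns a
  plan into an explicit square-wave irradiance trace and integrates its
  fluence numerically — an independent check that the closed forms are the
  area under the curve;
* **germicidal-effect metrics** from plate counts: the log reduction value
  `LRV = log10(N0/N)` (`log_reduction()`, `summarize_ge()`), the percent of
  the initial population inactivated `100·(1 − 10^(−LRV))`
  (`percent_inactivated()`), and the **effective germicidal effect (EGE)**
  profile (`ege_profile()`) — the incremental percent inactivated in each
  dose interval, which shows where along a dose ladder the killing actually
  happens;
* **energy accounting** (`energy_ws()`, `percent_saving()`,
  `savings_table()`) comparing the electrical consumption `W = A·V·t` of
  pulsed techniques against continuous light;
* the standard small-design **statistics stage** (`normality_screen()`,
  `compare_groups()`): Shapiro–Wilk screening, one-way ANOVA at α = 0.05,
  Tukey HSD all-pairs comparison and a compact letter display;
* a **synthetic plate-count generator** (`simulate_counts()`) emulating a
  completely randomized disinfection trial (Poisson counting noise plus
  lognormal between-replicate variation), so the whole pipeline is testable
  without wet-lab data;
* `run_pipeline()` to bind everything into a reproducible CSV report
  bundle.

All functions take data frames and return tibbles, so stages chain with the
pipe; fitted comparisons support `tidy()`/`glance()`, and result types have
`autoplot()` methods.

## Worked example

Plan the 5/15/25 mJ·cm⁻² dose ladder at 0.15 mW·cm⁻² and 500 Hz (30% duty
cycle shown):

```r
library(uvcdose)
library(dplyr)

plans <- plan_grid(doses = c(5, 15, 25), cl_irradiance = 0.15,
                   frequency = 500, duty_cycles = c(30, 50, 80))
plans |>
  filter(duty_pct %in% c(30, 100)) |>
  select(condition_id, mode, dose_mj_cm2, irradiance_mw_cm2, time_s, np, t_on_s)
#> # A tibble: 9 × 7
#>   condition_id mode  dose_mj_cm2 irradiance_mw_cm2 time_s      np t_on_s
#>   <chr>        <chr>       <dbl>             <dbl>  <dbl>   <dbl>  <dbl>
#> 1 CL_d5        CL              5              0.15    33   16500  0.002
#> 2 CL_d15       CL             15              0.15   100   50000  0.002
#> 3 CL_d25       CL             25              0.15   167   83500  0.002
#> 4 PPL_d5_dc30  PPL             5              0.5     33   16500  0.0006
#> 5 PPL_d15_dc30 PPL            15              0.5    100   50000  0.0006
#> 6 PPL_d25_dc30 PPL            25              0.5    167   83500  0.0006
#> 7 TPL_d5_dc30  TPL             5              0.15   110   55000  0.0006
#> 8 TPL_d15_dc30 TPL            15              0.15   333. 166667. 0.0006
#> 9 TPL_d25_dc30 TPL            25              0.15   557. 278333. 0.0006
```

At 30% duty the power-pulsed plans raise the peak to 0.50 mW·cm⁻² over the
CL times, while the time-pulsed plans keep 0.15 mW·cm⁻² and run 100/30×
longer (33 s → 110 s). Simulate the trial and analyse it:

```r
counts <- simulate_counts(study_conditions(), seed = 101)
counts |>
  mutate(lrv = log_reduction(cfu_before, cfu_after),
         technique = recode(mode, PPL = "Mode 1", TPL = "Mode 2")) |>
  compare_groups(lrv, technique)
#> <uvc_comparison> one-way ANOVA with Tukey HSD all-pairs comparison
#> Omnibus: F(2, 81) = 13.5, p = 8.687e-06 (alpha = 0.05)
#> # A tibble: 3 × 3
#>   group   mean letter
#>   <chr>  <dbl> <chr>
#> 1 CL     0.800 a
#> 2 Mode 1 0.800 a
#> 3 Mode 2 0.490 b
```

Continuous light and Mode 1 share a letter (statistically
indistinguishable germicidal effect, about 0.8 log reduction pooled over
the design) while Mode 2 is significantly weaker. The EGE profile of
Mode 1 at 30% duty shows the first 5 mJ·cm⁻² do almost all the work:

```r
summarize_ge(counts) |>
  filter(mode == "PPL", duty_pct == 30) |>
  arrange(dose_mj_cm2) |>
  ege_profile(dose_mj_cm2, mean_lrv)
#> # A tibble: 3 × 4
#>   dose_from dose_to ege_pct cum_pct
#>       <dbl>   <dbl>   <dbl>   <dbl>
#> 1         0       5   73.9     73.9
#> 2         5      15    7.58    81.5
#> 3        15      25    9.01    90.5
```

About 74% of the initial population is inactivated in the first dose
interval and under 10% in each later one. Finally, the measured
consumption table shows Mode 1's energy advantage at 25 mJ·cm⁻²:

```r
savings_table(tomato_study_results()) |>
  filter(technique == "Mode 1", dose_mj_cm2 == 25)
#> # A tibble: 3 × 6
#>   technique duty_pct dose_mj_cm2 ec_cl_ws ec_ws saving_pct
#>   <chr>        <dbl>       <dbl>    <dbl> <dbl>      <dbl>
#> 1 Mode 1          30          25     1.09  0.97         12
#> 2 Mode 1          50          25     1.09  0.98         11
#> 3 Mode 1          80          25     1.09  1.03          6
```

Mode 1 matches continuous light's germicidal effect while consuming 6–12%
less energy, the central practical finding this toolchain reproduces.

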