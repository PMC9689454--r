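---
title: "Dose equivalence and germicidal analysis for pulsed UV-C LEDs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose equivalence and germicidal analysis for pulsed UV-C LEDs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvcdose)
library(dplyr)
```

## The problem

UV-C light inactivates surface microorganisms on fresh produce, and LED
sources can emit it either continuously or as a square-wave pulse train
controlled by a frequency `f` and a duty cycle (the percent of each period
`T = 1/f` the lamp is on). Pulsed operation is attractive — less lamp
heating, lower electrical consumption — but a pulsed treatment is only
comparable to a continuous one if both deliver the same germicidal dose
(fluence, mJ·cm⁻²). `uvcdose` implements the closed-form dose-equivalence
model for the two standard pulsed strategies, the numerical waveform check,
the microbiological outcome metrics, the energy comparison, and the
statistical stage of a completely randomized disinfection trial.

Units are fixed package-wide: mJ·cm⁻² (dose), mW·cm⁻² (irradiance), seconds,
Hz, percent. Callers convert anything else.

## The dose-equivalence model

All modes obey `D = I · t` with `I` the *average* irradiance. The planner
exposes this as three closed forms:

* **Continuous light (CL).** `D = I_CL · t_CL`; `required_exposure_time()`
  inverts it.
* **Power-pulsed light (PPL, "Mode 1").** The exposure time stays `t_CL`;
  the peak irradiance is raised to `I_PPL = I_CL · 100/duty`. The dose is
  `Np · I_PPL · t_on` with `Np = f·t` pulses of on-time
  `t_on = (duty/100)·T` each, which collapses to `I_CL · t_CL`: average
  power is conserved exactly (an invariant tested as
  `I_PPL · duty/100 = I_CL`).
* **Time-pulsed light (TPL, "Mode 2").** The pulse amplitude stays `I_CL`;
  the exposure is prolonged by `v_t = 100/duty`, so
  `D = v_t · Np' · I_CL · t_on` with `Np'` counted over the *reference CL
  duration*. Counting instead `f · t_TPL` pulses without the `v_t`
  prefactor is algebraically identical; the tests assert both. The
  reciprocity `t_TPL · duty/100 = t_CL` is exact.

Two representation choices matter:

* **`Np` is real-valued.** All the study settings give whole pulse counts
  (500 Hz with 33/100/167 s), but forcing integers would break equivalence
  for arbitrary inputs, so a fractional final pulse is permitted in the
  closed form.
* **CL is a duty-100 pulsed plan.** One code path covers all modes; a
  duty cycle of 100% reproduces CL identically.

### Rounding: model vs bench protocol

A bench protocol programs whole seconds. `plan_grid()` therefore defaults
to rounding the CL time to the nearest second *before* deriving pulsed
equivalents (`25/0.15 = 166.67 → 167 s`, and the 50%-duty TPL time is
`2 × 167 = 334 s`). The delivered-dose column then reports the dose the
rounded plan actually delivers (33 s at 0.15 mW·cm⁻² delivers 4.95, not 5,
mJ·cm⁻²); the nominal target is kept alongside. With
`round_cl_time = FALSE` the grid is exact and delivered dose equals the
target to 1e-9 relative — the equivalence-closure property tested across
frequencies of 50–5000 Hz and duty cycles of 1–100%. Internal values are
never rounded; rounding is display/protocol only.

## The waveform oracle

`pulse_train()` renders a plan as samples of a square wave: rectangles of
width `t_on` at the start of each period (phase is not physically
meaningful for dose, so the PWM start-of-period convention is cosmetic),
half-open `[on-start, on-end)` edges, final pulse truncated at the exposure
time. `integrate_dose()` uses the rectangle rule — the natural choice for a
piecewise-constant signal; a trapezoid would smear the edges.

Numerical choices and their consequences:

* The sampling step must satisfy `step ≤ t_on/10`; coarser requests raise a
  resolution error rather than returning an aliased integral.
* At `step = t_on/20` the integrated fluence of every planned study
  condition agrees with the closed form to well within 0.5%; for whole
  duty cycles the sampling pattern locks to the period and the agreement is
  exact to float precision.
* When the exposure time cuts a final pulse, the rendered train carries a
  fixed truncation deficit relative to the closed form (which admits a
  fractional pulse). No step refinement removes it; it is below 0.5% for
  any plan with more than ~200 pulses, which is why the oracle tolerance
  absorbs it. The refinement-convergence test therefore uses whole-period
  exposures, where the measured error is discretization alone.

The heaviest rendered condition (the 30%-duty TPL plan at 25 mJ·cm⁻²,
556.67 s at a 30 µs step) is ~1.9 × 10⁷ samples, integrated in a few
seconds; that is the problem size the test suite and oracle checks run at.

## Germicidal-effect metrics

The germicidal effect of one replicate is the log reduction value
`LRV = log10(N0/N)` from the colony counts before and after treatment.
Per condition the package reports the replicate-level mean ± sample SD
(n−1), matching how such trials are summarized; pooling counts first and
taking one log is offered as an option (`pooled = TRUE`) but documented as
generally unequal — the log of a mean is not the mean of logs.

`percent_inactivated()` converts decades to percent kill,
`100·(1 − 10^(−LRV))`, and satisfies the exact identity
`percent_inactivated(log_reduction(N0, N)) = 100·(1 − N/N0)`.

**Effective germicidal effect (EGE).** Over an ascending dose ladder with
an implicit (0, 0) origin, the EGE of interval *i* is the *incremental*
percent of the initial population inactivated:
`EGE_i = percent_inactivated(LRV_i) − percent_inactivated(LRV_{i−1})`,
equivalently `100·(N_{i−1} − N_i)/N0` from pooled counts — the two routes
agree exactly and the increments sum to the total percent inactivated at
the final dose (both are tested invariants). A bare count difference
`N − N0` is dimensionally a count, not a percentage; it is exposed only as
the diagnostic `ege_count_difference()`. The interpretable profile is the
incremental one: it shows directly that the first 5 mJ·cm⁻² interval does
~75% of the killing while later intervals add single digits, i.e. where
added dose (and energy) stops paying.

**Zero-survivor plates.** `N = 0` cannot be logged; it is censored at half
the detection limit (0.5 CFU for a 1-CFU limit) and flagged
(`n_censored`), never mapped to infinity. Apparent growth
(`N > N0`) is kept but flagged (`n_growth`), since discarding it would bias
small designs.

## Energy accounting

Consumption is the wattmeter model `W = A·V·t` (watt-seconds). Measured
consumption tables are treated as inputs — deriving them from irradiance ×
area × time is not attempted, since optical output and wall-plug power
differ by the (unmodelled) driver and thermal efficiency.
`percent_saving()` reports `round(100·(EC_CL − EC_pulsed)/EC_pulsed)`: the
saving relative to the *pulsed* consumption. This denominator convention is
the one consistent with the published 12/11/6% figures at 25 mJ·cm⁻²
(1.09 vs 0.97/0.98/1.03 Ws give 12.37/11.22/5.83 → 12/11/6; a CL
denominator would give 11.0/10.1/5.5). The CL-denominator form remains
available via `denominator = "cl"`.

## The statistics stage

`normality_screen()` runs Shapiro–Wilk per condition (skipping n < 3 with a
warning; all-identical replicates are degenerate and flagged rather than
tested — a zero-variance sample has no normality to test). Failures do not
abort the pipeline; the screen is reported alongside the ANOVA, mirroring
the sequential screen-then-test protocol of small food-microbiology
designs.

`compare_groups()` fits the one-way ANOVA and, when the omnibus test
rejects at α (default 0.05), runs Tukey's HSD all-pairs comparison — the
standard companion to a one-way ANOVA when no specific post-hoc procedure
is mandated — and summarizes it as a compact letter display built by the
insert-and-absorb algorithm: start with all groups in one letter class,
split every class containing a significantly different pair, absorb
subset classes, and order letters from the largest group mean down. By
construction two groups share a letter exactly when their adjusted
difference is not significant; a test cross-checks the partition against
`multcomp::cld()`. If every group has zero within-group variance the F
statistic is undefined; the comparison falls back to exact ties (equal
means share a letter).

With the published means and SDs as simulation truth (n = 4 per cell,
3 doses × 3 duty cycles per technique), the technique-factor comparison
pools 12–36 replicates per technique; dose-to-dose spread dominates the
within-technique variance, so CL and Mode 1 (pooled means ≈ 0.80 vs 0.80)
are indistinguishable while Mode 2 (≈ 0.50) separates — the qualitative
pattern the pipeline recovers in essentially every simulated trial.

## The synthetic-data generator

`simulate_counts()` emulates the trial design: per condition and replicate

1. `N0 ~ Poisson(baseline_mean)` — plate counting noise on the untreated
   sample;
2. `lrv_r = true_lrv + Normal(0, between_replicate_sd)` — lognormal
   biological variation between samples;
3. `N ~ Poisson(N0 · 10^(−lrv_r))` — Poisson thinning of survivors.

Defaults and why:

* `replicates = 4` — the completely randomized design's four repetitions
  per condition.
* `baseline_mean = 500` CFU per plated sample. The source study does not
  print its baseline counts; 500 keeps the Poisson counting error of a
  1-decade reduction near 0.05–0.07 log10, commensurate with the 0.01–0.06
  replicate SDs reported. It is a knob, not a claim about the study.
* `between_replicate_sd = 0.02` log10 — the residual biological component
  that, added to counting noise, keeps simulated replicate SDs in the
  reported band.
* `dispersion` — optional negative-binomial size for extra-Poisson
  overdispersion; off by default, as Poisson + lognormal is the minimal
  model matching mean ± SD reporting.

The random stream is split per condition (sub-seeds drawn once from the
master seed), so appending conditions never perturbs earlier conditions'
draws — a property the tests pin down. Estimated LRVs carry a small
positive Jensen bias of order `1/(2·N·ln10)` (≈ 0.005 at N ≈ 45 survivors);
it is well inside the Monte-Carlo error of the parameter-recovery checks
(100 seeds × 4 replicates).

What the generator does *not* emulate: spatial dose non-uniformity across
the irradiation zone, shadowing on the fruit surface, tailing/shoulder
dose-response kinetics (the latent effect is a fixed per-condition LRV, not
a survival-curve model), and plate dilution series. Passing tests
therefore demonstrate that the pipeline recovers known effects under
idealized counting statistics — not that the wet-lab effects themselves are
reproducible from first principles. The measured log reductions and
consumption values enter only as simulation truth and measured inputs.

## The pipeline

`run_pipeline()` chains the stages — plan grid, counts (synthetic or CSV),
germicidal summary, normality screen, dose- and technique-factor
comparisons, EGE profiles per technique × duty cycle, energy savings — and
optionally writes a CSV bundle plus a run log carrying the seed and package
version. With a fixed seed the CSVs are byte-identical across runs
(timestamps are confined to the log). CSV dialect: comma-separated, UTF-8,
header row, `.` decimal, full precision (display rounding belongs to
reports, not data files). Malformed count files are rejected with the
offending line numbers.

## Known limitations

* The planner treats the irradiation zone as uniform; no lamp aging,
  thermal derating, or LED rise/fall-time (µs-scale) modelling — at 500 Hz
  with on-times of 0.6–1.6 ms, edge effects are below the oracle
  tolerance.
* Single-waveband treatment; no action-spectrum weighting across species.
* The compact letter display inherits Tukey HSD's assumptions (normality,
  variance homogeneity); with n = 4 per cell the normality screen has low
  power, which is why it is a report, not a gate.
* `percent_saving()` rounds to whole percent by design; callers needing
  fractions can compute them from the consumption columns of
  `savings_table()`.
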