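# Published planner settings: dose ladder at 0.15 mW/cm2, 500 Hz,
# duty cycles 30/50/80%. `printed` values carry the precision at which
# the source table prints them (half-unit tolerance of the last digit);
# the three print-truncated cells (556.1, 208.7, 0.187) are excluded.
table1_printed <- function() {
  tibble::tribble(
    ~mode, ~dose, ~duty, ~field,        ~printed, ~tol,
    "CL",     5,   100,  "time_s",        33,     0.5,
    "CL",    15,   100,  "time_s",       100,     0.5,
    "CL",    25,   100,  "time_s",       167,     0.5,
    "PPL",    5,    30,  "irradiance",     0.50,  0.005,
    "PPL",   15,    30,  "irradiance",     0.50,  0.005,
    "PPL",   25,    30,  "irradiance",     0.50,  0.005,
    "PPL",    5,    50,  "irradiance",     0.30,  0.005,
    "PPL",   15,    50,  "irradiance",     0.30,  0.005,
    "PPL",   25,    50,  "irradiance",     0.30,  0.005,
    "TPL",    5,    30,  "time_s",       110,     0.5,
    "TPL",   15,    30,  "time_s",       333,     0.5,
    "TPL",    5,    50,  "time_s",        66,     0.5,
    "TPL",   15,    50,  "time_s",       200,     0.5,
    "TPL",   25,    50,  "time_s",       334,     0.5,
    "TPL",    5,    80,  "time_s",        41.3,   0.05,
    "TPL",   15,    80,  "time_s",       125,     0.5
  )
}

study_plan_grid <- function(round_cl_time = TRUE) {
  plan_grid(doses = c(5, 15, 25), cl_irradiance = 0.15, frequency = 500,
            duty_cycles = c(30, 50, 80), round_cl_time = round_cl_time)
}

# A sampling step that divides the pulse period exactly (and, for whole
# duty cycles, the on-window too), so whole-period averages are exact up
# to float rounding. Always <= t_on / 20.
aligned_step <- function(plan) {
  k <- 100 * ceiling(20 / plan$duty_pct)
  plan$period_s / k
}

random_valid_plans <- function(n, seed) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n), function(i) {
      dose <- stats::runif(1, 0.5, 5)
      irr <- stats::runif(1, 0.1, 1)
      freq <- sample(c(50, 100, 200, 500, 1000), 1)
      duty <- sample(10:90, 1)
      mode <- sample(c("PPL", "TPL"), 1)
      equivalent_plan(cl_plan(dose, irr, freq), mode, freq, duty)
    })
  })
}
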