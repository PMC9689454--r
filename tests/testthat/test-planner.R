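test_that("exposure time follows the dose law D = I * t", {
  expect_equal(required_exposure_time(15, 0.15), 100)
  expect_equal(required_exposure_time(0, 0.15), 0)
  expect_equal(required_exposure_time(25, 0.15), 500 / 3)
  expect_error(required_exposure_time(15, 0), class = "uvcdose_error_invalid")
  expect_error(required_exposure_time(-1, 0.15), class = "uvcdose_error_invalid")
})

test_that("power-pulsed peak irradiance scales CL irradiance by 100/duty", {
  expect_equal(ppl_peak_irradiance(0.15, 30), 0.50)
  expect_equal(ppl_peak_irradiance(0.15, 100), 0.15)
  expect_equal(ppl_peak_irradiance(0.15, 80), 0.1875)
  expect_error(ppl_peak_irradiance(0.15, 0), class = "uvcdose_error_invalid")
  expect_error(ppl_peak_irradiance(0.15, 101), class = "uvcdose_error_invalid")
})

test_that("time-pulsed prolongation factor and exposure time", {
  expect_equal(tpl_time_factor(50), 2)
  expect_equal(tpl_time_factor(100), 1)
  expect_equal(tpl_time_factor(30), 10 / 3)
  expect_equal(tpl_exposure_time(33, 30), 110)
  expect_equal(tpl_exposure_time(100, 50), 200)
  expect_equal(tpl_exposure_time(42.5, 100), 42.5)
  expect_error(tpl_exposure_time(0, 50), class = "uvcdose_error_invalid")
})

test_that("pulse count and on-time per period", {
  expect_equal(pulse_count(500, 33), 16500)
  expect_equal(pulse_count(500, 0), 0)
  expect_equal(pulse_count(500, 100), 50000)
  expect_error(pulse_count(500, -1), class = "uvcdose_error_invalid")
  expect_equal(on_time_per_period(30, 500), 6e-4)
  expect_equal(on_time_per_period(100, 500), 2e-3)
  expect_equal(on_time_per_period(80, 500), 1.6e-3)
})

test_that("pulsed equivalents preserve the CL dose and reject identity", {
  cl <- cl_plan(25, 0.15, round_time = TRUE)  # 167 s as the bench programs it
  ppl <- equivalent_plan(cl, "PPL", 500, 50)
  expect_equal(ppl$irradiance_mw_cm2, 0.30)
  expect_equal(ppl$time_s, 167)
  tpl <- equivalent_plan(cl_plan(15, 0.15), "TPL", 500, 80)
  expect_equal(tpl$irradiance_mw_cm2, 0.15)
  expect_equal(tpl$time_s, 125)
  same <- equivalent_plan(cl_plan(5, 0.15), "PPL", 500, 100)
  expect_equal(same$irradiance_mw_cm2, 0.15)
  expect_equal(same$time_s, 100 / 3)
  expect_error(equivalent_plan(cl_plan(5, 0.15), "CL", 500, 50))
})

test_that("closed-form delivered dose matches mode-specific formulas", {
  expect_equal(delivered_dose(cl_plan(15, 0.15)), 15)
  ppl <- equivalent_plan(cl_plan(5, 0.15, round_time = TRUE), "PPL", 500, 30)
  # 16500 pulses x 0.50 mW/cm2 x 6e-4 s
  expect_equal(delivered_dose(ppl), 4.95)
  tpl <- equivalent_plan(cl_plan(15, 0.15), "TPL", 500, 50)
  # vt = 2, Np over the 100 s reference, t_on = 1e-3
  expect_equal(tpl$time_s, 200)
  expect_equal(delivered_dose(tpl), 2 * 500 * 100 * 0.15 * 1e-3)
})

test_that("inconsistent plan fields are rejected", {
  p <- equivalent_plan(cl_plan(5, 0.15), "PPL", 500, 30)
  p$irradiance_mw_cm2 <- 0.4  # breaks average-power conservation
  expect_error(delivered_dose(p), class = "uvcdose_error_validation")
  q <- cl_plan(5, 0.15)
  q$t_on_s <- NULL
  expect_error(delivered_dose(q), class = "uvcdose_error_validation")
})

test_that("equivalence closure holds over a frequency/duty sweep", {
  cl <- cl_plan(7.3, 0.21)
  for (f in c(50, 137, 500, 1250, 5000)) {
    for (d in c(1, 7, 23, 50, 77, 99, 100)) {
      for (m in c("PPL", "TPL")) {
        p <- equivalent_plan(cl, m, f, d)
        expect_equal(delivered_dose(p), cl$dose_mj_cm2, tolerance = 1e-9)
      }
    }
  }
})

test_that("average-power conservation and time-duty reciprocity are exact", {
  plans <- random_valid_plans(50, seed = 11)
  ppl <- plans[plans$mode == "PPL", ]
  expect_equal(ppl$irradiance_mw_cm2 * ppl$duty_pct / 100,
               ppl$cl_irradiance_mw_cm2)
  tpl <- plans[plans$mode == "TPL", ]
  expect_equal(tpl$time_s * tpl$duty_pct / 100, tpl$cl_time_s)
})

test_that("peak irradiance and prolonged time decrease as duty cycle rises", {
  duties <- seq(5, 100, by = 5)
  peaks <- ppl_peak_irradiance(0.15, duties)
  times <- tpl_exposure_time(100, duties)
  expect_true(all(diff(peaks) < 0))
  expect_true(all(diff(times) < 0))
})

test_that("the plan grid reproduces the published settings table", {
  grid <- study_plan_grid()
  exp <- table1_printed()
  for (i in seq_len(nrow(exp))) {
    row <- grid[grid$mode == exp$mode[i] &
                  grid$dose_mj_cm2 == exp$dose[i] &
                  grid$duty_pct == exp$duty[i], ]
    expect_equal(nrow(row), 1)
    got <- if (exp$field[i] == "time_s") row$time_s else row$irradiance_mw_cm2
    expect_lt(abs(got - exp$printed[i]), exp$tol[i] + 1e-12)
  }
  # the three print-truncated cells resolve to the exact model values
  expect_equal(grid$time_s[grid$mode == "TPL" & grid$dose_mj_cm2 == 25 &
                             grid$duty_pct == 30], 167 * 10 / 3)
  expect_equal(grid$time_s[grid$mode == "TPL" & grid$dose_mj_cm2 == 25 &
                             grid$duty_pct == 80], 208.75)
  expect_equal(unique(grid$irradiance_mw_cm2[grid$mode == "PPL" &
                                               grid$duty_pct == 80]), 0.1875)
})

test_that("plan grid validates its dose ladder", {
  expect_error(plan_grid(doses = numeric(0)), class = "uvcdose_error_invalid")
  expect_error(plan_grid(doses = c(15, 5)), class = "uvcdose_error_invalid")
})
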