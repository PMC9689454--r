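#' Exposure time required to deliver a UV-C dose
#'
#' The fluence (dose) delivered by a constant-irradiance source is the
#' product of irradiance and exposure time, `D = I * t`, so the time
#' needed to reach a target dose is `t = D / I`.
#'
#' @param dose Target fluence in mJ·cm^-2 (non-negative).
#' @param irradiance Irradiance in mW·cm^-2 (strictly positive).
#'
#' @return Exposure time in seconds, unrounded. Vectorised over both
#'   arguments.
#' @examples
#' required_exposure_time(15, 0.15)   # 100 s
#' required_exposure_time(25, 0.15)   # 166.67 s
#' @export
required_exposure_time <- function(dose, irradiance) {
  check_nonnegative(dose, "dose")
  check_positive(irradiance, "irradiance")
  dose / irradiance
}

#' Peak irradiance of a power-pulsed (Mode 1) treatment
#'
#' Power-pulsed light (PPL) keeps the continuous-light exposure time but
#' raises the pulse amplitude by `100 / duty_cycle`, so the *average*
#' irradiance — and hence the dose over the same time — matches
#' continuous light exactly.
#'
#' @param cl_irradiance Continuous-light irradiance in mW·cm^-2.
#' @param duty_cycle Duty cycle in percent, in (0, 100].
#'
#' @return Peak pulse irradiance in mW·cm^-2.
#' @examples
#' ppl_peak_irradiance(0.15, 30)  # 0.50
#' ppl_peak_irradiance(0.15, 50)  # 0.30
#' @export
ppl_peak_irradiance <- function(cl_irradiance, duty_cycle) {
  check_positive(cl_irradiance, "cl_irradiance")
  check_duty_cycle(duty_cycle)
  cl_irradiance * 100 / duty_cycle
}

#' Time-prolongation factor of a time-pulsed (Mode 2) treatment
#'
#' Time-pulsed light (TPL) keeps the continuous-light irradiance as the
#' pulse amplitude; since the lamp is only on `duty_cycle`% of the time,
#' the exposure must be prolonged by `vt = 100 / duty_cycle` to deliver
#' the same dose.
#'
#' @inheritParams ppl_peak_irradiance
#' @return Dimensionless factor `>= 1`.
#' @examples
#' tpl_time_factor(50)  # 2
#' tpl_time_factor(30)  # 3.333...
#' @export
tpl_time_factor <- function(duty_cycle) {
  check_duty_cycle(duty_cycle)
  100 / duty_cycle
}

#' Exposure time of a time-pulsed (Mode 2) treatment
#'
#' @param cl_time Continuous-light exposure time in seconds.
#' @inheritParams ppl_peak_irradiance
#' @return Prolonged exposure time `cl_time * 100 / duty_cycle` in seconds.
#' @examples
#' tpl_exposure_time(33, 30)   # 110
#' tpl_exposure_time(100, 50)  # 200
#' @export
tpl_exposure_time <- function(cl_time, duty_cycle) {
  check_positive(cl_time, "cl_time")
  check_duty_cycle(duty_cycle)
  cl_time * tpl_time_factor(duty_cycle)
}

#' Number of pulses in a pulsed exposure
#'
#' `Np = f * t`. The count is kept as a real number: a fractional final
#' pulse is permitted so that dose equivalence holds for arbitrary
#' frequency/time combinations, not only those giving whole pulses.
#'
#' @param frequency Pulse frequency in Hz (strictly positive).
#' @param time Exposure time in seconds (non-negative).
#' @return Pulse count (real-valued).
#' @examples
#' pulse_count(500, 33)   # 16500
#' @export
pulse_count <- function(frequency, time) {
  check_positive(frequency, "frequency")
  check_nonnegative(time, "time")
  frequency * time
}

#' On-time per pulse period
#'
#' The lamp is on for `duty_cycle`% of each period `T = 1/f`.
#'
#' @inheritParams pulse_count
#' @inheritParams ppl_peak_irradiance
#' @return On-time per period in seconds.
#' @examples
#' on_time_per_period(30, 500)  # 6e-4
#' @export
on_time_per_period <- function(duty_cycle, frequency) {
  check_duty_cycle(duty_cycle)
  check_positive(frequency, "frequency")
  (duty_cycle / 100) * (1 / frequency)
}

plan_columns <- c(
  "mode", "dose_mj_cm2", "irradiance_mw_cm2", "time_s", "freq_hz",
  "duty_pct", "period_s", "t_on_s", "np", "time_factor",
  "cl_irradiance_mw_cm2", "cl_time_s", "dose_delivered_mj_cm2"
)

new_plan_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  class(x) <- c("uvc_plan", class(x))
  x
}

#' Continuous-light treatment plan
#'
#' Builds one plan row per dose. Internally a continuous-light plan is a
#' pulsed plan with a 100% duty cycle, so a single representation covers
#' all three emission modes.
#'
#' @param dose Target fluence(s) in mJ·cm^-2.
#' @param irradiance Lamp irradiance in mW·cm^-2.
#' @param frequency Pulse frequency in Hz used when pulsed equivalents
#'   are later derived; carried along but irrelevant to a continuous plan.
#' @param round_time If `TRUE`, the exposure time is rounded to the
#'   nearest second, as a bench protocol would program it; the delivered
#'   dose column then reflects the rounded time (e.g. 33 s at
#'   0.15 mW·cm^-2 delivers 4.95 mJ·cm^-2 against a nominal 5).
#'
#' @return A plan tibble (class `uvc_plan`) with one row per dose and
#'   columns `mode`, `dose_mj_cm2` (nominal target), `irradiance_mw_cm2`,
#'   `time_s`, `freq_hz`, `duty_pct`, `period_s`, `t_on_s`, `np`,
#'   `time_factor`, `cl_irradiance_mw_cm2`, `cl_time_s`,
#'   `dose_delivered_mj_cm2`.
#' @examples
#' cl_plan(c(5, 15, 25), 0.15)
#' @seealso [equivalent_plan()], [delivered_dose()], [plan_grid()]
#' @export
cl_plan <- function(dose, irradiance, frequency = 500, round_time = FALSE) {
  check_positive(dose, "dose")
  check_positive(irradiance, "irradiance")
  check_positive(frequency, "frequency")
  t <- required_exposure_time(dose, irradiance)
  if (round_time) t <- round(t)
  new_plan_tbl(tibble::tibble(
    mode = "CL",
    dose_mj_cm2 = dose,
    irradiance_mw_cm2 = irradiance,
    time_s = t,
    freq_hz = frequency,
    duty_pct = 100,
    period_s = 1 / frequency,
    t_on_s = 1 / frequency,
    np = pulse_count(frequency, t),
    time_factor = 1,
    cl_irradiance_mw_cm2 = irradiance,
    cl_time_s = t,
    dose_delivered_mj_cm2 = irradiance * t
  ))
}

#' Pulsed treatment plan equivalent to a continuous-light plan
#'
#' Derives, for each row of a continuous-light plan, the pulsed plan
#' that delivers the same dose:
#'
#' * **PPL (Mode 1, power-pulsed)** keeps the CL exposure time and scales
#'   the pulse peak irradiance by `100 / duty_cycle`, so average power is
#'   conserved.
#' * **TPL (Mode 2, time-pulsed)** keeps the CL irradiance as the pulse
#'   amplitude and prolongs the exposure time by `100 / duty_cycle`.
#'
#' @param cl A plan tibble of continuous-light rows (see [cl_plan()]).
#' @param mode `"PPL"` or `"TPL"`. `"CL"` is rejected: the identity is
#'   not an equivalence.
#' @param frequency Pulse frequency in Hz.
#' @param duty_cycle Duty cycle in percent, in (0, 100].
#'
#' @return A plan tibble with the same columns as [cl_plan()].
#' @examples
#' cl <- cl_plan(25, 0.15, round_time = TRUE)
#' equivalent_plan(cl, "PPL", 500, 50)  # peak 0.30 mW·cm^-2 over 167 s
#' equivalent_plan(cl, "TPL", 500, 80)  # 0.15 mW·cm^-2 over 208.75 s
#' @export
equivalent_plan <- function(cl, mode, frequency = 500, duty_cycle) {
  stopifnot(is.data.frame(cl))
  if (!all(cl$mode == "CL")) {
    abort("`cl` must contain only continuous-light (mode \"CL\") rows.",
          class = "uvcdose_error_invalid")
  }
  mode <- match.arg(mode, c("PPL", "TPL"))
  check_positive(frequency, "frequency")
  check_duty_cycle(duty_cycle)

  t_on <- on_time_per_period(duty_cycle, frequency)
  if (mode == "PPL") {
    irr <- ppl_peak_irradiance(cl$cl_irradiance_mw_cm2, duty_cycle)
    t <- cl$cl_time_s
    vt <- 1
  } else {
    irr <- cl$cl_irradiance_mw_cm2
    t <- tpl_exposure_time(cl$cl_time_s, duty_cycle)
    vt <- tpl_time_factor(duty_cycle)
  }
  new_plan_tbl(tibble::tibble(
    mode = mode,
    dose_mj_cm2 = cl$dose_mj_cm2,
    irradiance_mw_cm2 = irr,
    time_s = t,
    freq_hz = frequency,
    duty_pct = duty_cycle,
    period_s = 1 / frequency,
    t_on_s = t_on,
    np = pulse_count(frequency, t),
    time_factor = vt,
    cl_irradiance_mw_cm2 = cl$cl_irradiance_mw_cm2,
    cl_time_s = cl$cl_time_s,
    dose_delivered_mj_cm2 = delivered_dose_impl(
      mode, irr, t, frequency, duty_cycle, cl$cl_time_s
    )
  ))
}

delivered_dose_impl <- function(mode, irradiance, time_s, freq_hz,
                                duty_pct, cl_time_s) {
  t_on <- (duty_pct / 100) / freq_hz
  dplyr::case_when(
    mode == "CL" ~ irradiance * time_s,
    # Np pulses of width t_on at peak amplitude
    mode == "PPL" ~ freq_hz * time_s * irradiance * t_on,
    # vt * Np' * I * t_on with Np' counted over the reference CL duration
    mode == "TPL" ~ (100 / duty_pct) * freq_hz * cl_time_s * irradiance * t_on
  )
}

validate_plan <- function(plan) {
  stopifnot(is.data.frame(plan))
  missing <- setdiff(plan_columns, names(plan))
  if (length(missing) > 0) {
    abort(paste0("Plan is missing columns: ", paste(missing, collapse = ", ")),
          class = "uvcdose_error_validation")
  }
  bad_mode <- !plan$mode %in% c("CL", "PPL", "TPL")
  rel_ok <- function(a, b) abs(a - b) <= 1e-9 * pmax(abs(a), abs(b), 1)
  with(plan, {
    problems <- character(0)
    if (any(bad_mode)) problems <- c(problems, "unknown mode")
    if (!all(dose_mj_cm2 > 0 & irradiance_mw_cm2 > 0 & time_s > 0))
      problems <- c(problems, "dose, irradiance and time must be positive")
    if (!all(duty_pct > 0 & duty_pct <= 100))
      problems <- c(problems, "duty cycle must lie in (0, 100]")
    if (!all(freq_hz > 0))
      problems <- c(problems, "frequency must be positive")
    if (!all(rel_ok(t_on_s[mode != "CL"],
                    (duty_pct[mode != "CL"] / 100) * period_s[mode != "CL"])))
      problems <- c(problems, "t_on_s must equal duty_pct * period_s / 100")
    if (!all(rel_ok(irradiance_mw_cm2[mode == "PPL"] *
                      duty_pct[mode == "PPL"] / 100,
                    cl_irradiance_mw_cm2[mode == "PPL"])))
      problems <- c(problems, "PPL peak must average back to the CL irradiance")
    if (!all(rel_ok(time_s[mode == "TPL"] * duty_pct[mode == "TPL"] / 100,
                    cl_time_s[mode == "TPL"])))
      problems <- c(problems, "TPL time must fold back to the CL time")
    if (length(problems) > 0) {
      abort(paste0("Invalid treatment plan: ",
                   paste(problems, collapse = "; "), "."),
            class = "uvcdose_error_validation")
    }
  })
  invisible(plan)
}

#' Closed-form dose delivered by a treatment plan
#'
#' Computes the fluence each plan row delivers from the mode-specific
#' closed form: `I * t` for continuous light, `Np * I_peak * t_on` for
#' power-pulsed light, and `vt * Np' * I * t_on` for time-pulsed light
#' (with `Np'` the pulse count over the reference continuous-light
#' duration). All three reduce algebraically to average irradiance times
#' the continuous-light-equivalent time.
#'
#' @param plan A plan tibble ([cl_plan()], [equivalent_plan()],
#'   [plan_grid()]). Plans with internally inconsistent fields are
#'   rejected.
#' @return Numeric vector of doses in mJ·cm^-2, one per row.
#' @examples
#' delivered_dose(cl_plan(15, 0.15))  # 15
#' @export
delivered_dose <- function(plan) {
  validate_plan(plan)
  delivered_dose_impl(plan$mode, plan$irradiance_mw_cm2, plan$time_s,
                      plan$freq_hz, plan$duty_pct, plan$cl_time_s)
}

#' Full treatment-plan grid for a dose ladder
#'
#' Crosses the dose ladder with the pulsed-light settings and returns
#' the continuous-light reference plan plus both pulsed equivalents for
#' every dose x duty-cycle combination — the planner's analogue of a
#' published settings table.
#'
#' @param doses Dose ladder in mJ·cm^-2 (defaults to the 5/15/25 ladder
#'   of the tomato study).
#' @param cl_irradiance Continuous-light irradiance in mW·cm^-2.
#' @param frequency Pulse frequency in Hz.
#' @param duty_cycles Duty cycles in percent.
#' @param round_cl_time If `TRUE` (default) the continuous-light time is
#'   rounded to the nearest second before pulsed equivalents are derived,
#'   as the bench protocol programs it (167 s doubled gives 334 s); use
#'   `FALSE` for exact unrounded equivalence.
#'
#' @return A plan tibble with a `condition_id` column
#'   (`"<mode>_d<dose>_dc<duty>"`) ahead of the plan columns.
#' @examples
#' plan_grid()  # the study's 21 planned conditions
#' @export
plan_grid <- function(doses = c(5, 15, 25), cl_irradiance = 0.15,
                      frequency = 500, duty_cycles = c(30, 50, 80),
                      round_cl_time = TRUE) {
  if (length(doses) == 0) {
    abort("`doses` must be a non-empty ascending dose ladder.",
          class = "uvcdose_error_invalid")
  }
  check_positive(doses, "doses")
  if (is.unsorted(doses, strictly = TRUE)) {
    abort("`doses` must be strictly ascending.",
          class = "uvcdose_error_invalid")
  }
  cl <- cl_plan(doses, cl_irradiance, frequency, round_time = round_cl_time)
  pulsed <- purrr::map_dfr(duty_cycles, function(dc) {
    dplyr::bind_rows(
      equivalent_plan(cl, "PPL", frequency, dc),
      equivalent_plan(cl, "TPL", frequency, dc)
    )
  })
  out <- dplyr::bind_rows(cl, pulsed)
  out <- dplyr::mutate(
    out,
    condition_id = condition_id(.data$mode, .data$dose_mj_cm2, .data$duty_pct),
    .before = 1
  )
  new_plan_tbl(dplyr::arrange(out, factor(.data$mode, c("CL", "PPL", "TPL")),
                              .data$duty_pct, .data$dose_mj_cm2))
}

condition_id <- function(mode, dose, duty) {
  ifelse(mode == "CL",
         sprintf("CL_d%g", dose),
         sprintf("%s_d%g_dc%g", mode, dose, duty))
}
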