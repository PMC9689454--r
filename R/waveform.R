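#' Render a treatment plan as an explicit irradiance pulse train
#'
#' Samples the irradiance-vs-time waveform of a single plan row on a
#' regular grid: rectangular pulses of width `t_on` at the start of each
#' period (the usual square-wave PWM convention), amplitude equal to the
#' plan irradiance, and a final partial period truncated at the exposure
#' time. Continuous-light plans render as a constant level. The train is
#' the numerical oracle for the planner's closed forms: its integrated
#' area is the delivered dose.
#'
#' @param plan A one-row plan tibble.
#' @param sample_step Sampling step in seconds. For pulsed plans it must
#'   resolve the pulse: `sample_step <= t_on / 10`.
#'
#' @return A tibble of class `uvc_pulse_train` with columns `time_s`
#'   (left edge of each sampling rectangle) and `irradiance_mw_cm2`,
#'   carrying the plan and step as attributes.
#' @examples
#' train <- pulse_train(equivalent_plan(cl_plan(5, 0.15), "PPL", 500, 30),
#'                      sample_step = 3e-5)
#' integrate_dose(train)
#' @export
pulse_train <- function(plan, sample_step) {
  validate_plan(plan)
  if (nrow(plan) != 1) {
    abort("`plan` must be a single plan row.", class = "uvcdose_error_invalid")
  }
  check_positive(sample_step, "sample_step")
  pulsed <- plan$mode != "CL"
  if (pulsed && sample_step > plan$t_on_s / 10 + 1e-15) {
    abort(sprintf(
      "`sample_step` = %g s is too coarse to resolve the %g s pulse; need <= t_on / 10 = %g s.",
      sample_step, plan$t_on_s, plan$t_on_s / 10
    ), class = "uvcdose_error_resolution")
  }
  n <- ceiling(plan$time_s / sample_step - 1e-9)
  times <- (seq_len(n) - 1) * sample_step
  if (pulsed) {
    # half-open on-window [period start, period start + t_on); the small
    # shifts guard against float round-off at pulse edges
    cycles <- times * plan$freq_hz
    phase <- cycles - floor(cycles + 1e-9)
    irr <- ifelse(phase < plan$duty_pct / 100 - 1e-9,
                  plan$irradiance_mw_cm2, 0)
  } else {
    irr <- rep(plan$irradiance_mw_cm2, n)
  }
  out <- tibble::tibble(time_s = times, irradiance_mw_cm2 = irr)
  attr(out, "plan") <- plan
  attr(out, "sample_step") <- sample_step
  class(out) <- c("uvc_pulse_train", class(out))
  out
}

#' Integrate the fluence of a rendered pulse train
#'
#' Rectangle-rule integration of irradiance over time. The signal is
#' piecewise constant, so rectangles (not trapezoids) are the natural
#' rule; the last rectangle is truncated at the plan's exposure time.
#'
#' @param train A `uvc_pulse_train` from [pulse_train()], or any data
#'   frame with `time_s` and `irradiance_mw_cm2` columns (then the final
#'   rectangle reuses the preceding width).
#' @return Integrated dose in mJ·cm^-2 (0 for an empty train).
#' @export
integrate_dose <- function(train) {
  stopifnot(is.data.frame(train))
  n <- nrow(train)
  if (n == 0) return(0)
  plan <- attr(train, "plan")
  end <- if (!is.null(plan)) plan$time_s else {
    last_w <- if (n > 1) train$time_s[n] - train$time_s[n - 1] else 0
    train$time_s[n] + last_w
  }
  widths <- diff(c(train$time_s, end))
  sum(widths * train$irradiance_mw_cm2)
}

#' Average irradiance of a pulse train over whole periods
#'
#' Mean irradiance over the largest whole number of periods contained in
#' the train. For a power-pulsed plan this recovers the continuous-light
#' irradiance (average-power conservation).
#'
#' @inheritParams integrate_dose
#' @return Average irradiance in mW·cm^-2.
#' @export
average_irradiance <- function(train) {
  plan <- attr(train, "plan")
  if (is.null(plan)) {
    abort("`train` must come from pulse_train().",
          class = "uvcdose_error_invalid")
  }
  n_periods <- floor(plan$time_s * plan$freq_hz)
  t_end <- n_periods * plan$period_s
  keep <- train$time_s < t_end - 1e-12
  step <- attr(train, "sample_step")
  sum(train$irradiance_mw_cm2[keep]) * step / t_end
}

#' @export
print.uvc_pulse_train <- function(x, ...) {
  plan <- attr(x, "plan")
  cat(sprintf(
    "<uvc_pulse_train> %s plan, %g s at step %g s (%d samples)\n",
    plan$mode, plan$time_s, attr(x, "sample_step"), nrow(x)
  ))
  NextMethod()
}

#' Plot a rendered pulse train
#'
#' Step plot of irradiance against time. For long trains only the first
#' `max_periods` pulse periods are drawn, which is what a schematic of
#' the emission technique shows.
#'
#' @param object A `uvc_pulse_train`.
#' @param max_periods Number of leading periods to draw for pulsed plans.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uvc_pulse_train <- function(object, max_periods = 5, ...) {
  plan <- attr(object, "plan")
  df <- object
  if (plan$mode != "CL") {
    df <- df[df$time_s < max_periods * plan$period_s, , drop = FALSE]
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$irradiance_mw_cm2)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "Time (s)", y = expression(Irradiance~(mW~cm^-2)),
      title = sprintf("%s emission, duty cycle %g%%", plan$mode, plan$duty_pct)
    )
}
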