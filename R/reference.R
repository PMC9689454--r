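#' Published germicidal-effect and energy-consumption results
#'
#' The measured outcome table of the tomato disinfection study: mean
#' log reduction value (+/- SD, n = 4) and wattmeter energy consumption
#' for every combination of technique (continuous light "CL",
#' power-pulsed "Mode 1", time-pulsed "Mode 2"), dose (5/15/25
#' mJ·cm^-2) and duty cycle (30/50/80%). Continuous light is the same
#' physical treatment in every duty-cycle block, so its rows repeat, as
#' in the source table.
#'
#' These are wet-lab measurements: the package uses them as inputs —
#' simulation parameters for [simulate_counts()] and measured
#' consumption for [savings_table()] — never as quantities it derives.
#'
#' @return A 27-row tibble with columns `duty_pct`, `dose_mj_cm2`,
#'   `technique`, `mode` (`CL`/`PPL`/`TPL`), `mean_lrv`, `sd_lrv`,
#'   `ec_ws`.
#' @examples
#' tomato_study_results()
#' @export
tomato_study_results <- function() {
  base <- tibble::tribble(
    ~duty_pct, ~dose_mj_cm2, ~technique, ~mean_lrv, ~sd_lrv, ~ec_ws,
    30,  5, "CL",     0.62, 0.06, 0.22,
    30,  5, "Mode 1", 0.61, 0.03, 0.19,
    30,  5, "Mode 2", 0.15, 0.01, 0.46,
    30, 15, "CL",     0.77, 0.03, 0.65,
    30, 15, "Mode 1", 0.74, 0.01, 0.58,
    30, 15, "Mode 2", 0.44, 0.01, 1.39,
    30, 25, "CL",     0.99, 0.02, 1.09,
    30, 25, "Mode 1", 1.06, 0.01, 0.97,
    30, 25, "Mode 2", 0.94, 0.01, 2.32,
    50,  5, "CL",     0.62, 0.06, 0.22,
    50,  5, "Mode 1", 0.60, 0.02, 0.19,
    50,  5, "Mode 2", 0.12, 0.02, 0.33,
    50, 15, "CL",     0.77, 0.03, 0.65,
    50, 15, "Mode 1", 0.77, 0.01, 0.59,
    50, 15, "Mode 2", 0.45, 0.02, 1.00,
    50, 25, "CL",     0.99, 0.02, 1.09,
    50, 25, "Mode 1", 1.06, 0.01, 0.98,
    50, 25, "Mode 2", 0.92, 0.02, 1.66,
    80,  5, "CL",     0.62, 0.06, 0.22,
    80,  5, "Mode 1", 0.58, 0.01, 0.20,
    80,  5, "Mode 2", 0.11, 0.01, 0.25,
    80, 15, "CL",     0.77, 0.03, 0.65,
    80, 15, "Mode 1", 0.74, 0.01, 0.62,
    80, 15, "Mode 2", 0.44, 0.01, 0.74,
    80, 25, "CL",     0.99, 0.02, 1.09,
    80, 25, "Mode 1", 1.08, 0.01, 1.03,
    80, 25, "Mode 2", 0.90, 0.02, 1.22
  )
  dplyr::mutate(
    base,
    mode = dplyr::recode(.data$technique,
                         "CL" = "CL", "Mode 1" = "PPL", "Mode 2" = "TPL"),
    .after = "technique"
  )
}

#' Study conditions as a synthetic-simulation configuration
#'
#' Maps the measured outcome table to the condition list
#' [simulate_counts()] consumes: one row per technique x dose x duty
#' cell with its published mean log reduction as the true effect.
#' Continuous light, being the same treatment in every duty block, is
#' de-duplicated to one condition per dose (its `duty_pct` is 100).
#'
#' @param results An outcome table shaped like [tomato_study_results()].
#' @return A tibble with columns `condition_id`, `mode`, `dose_mj_cm2`,
#'   `duty_pct`, `true_lrv`.
#' @examples
#' study_conditions()
#' @export
study_conditions <- function(results = tomato_study_results()) {
  results |>
    dplyr::mutate(duty_pct = ifelse(.data$mode == "CL", 100, .data$duty_pct)) |>
    dplyr::distinct(.data$mode, .data$dose_mj_cm2, .data$duty_pct,
                    true_lrv = .data$mean_lrv) |>
    dplyr::mutate(
      condition_id = condition_id(.data$mode, .data$dose_mj_cm2,
                                  .data$duty_pct),
      .before = 1
    )
}
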