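#' Pipeline configuration
#'
#' Collects and validates everything a full analysis run needs. The
#' defaults are the tomato study's settings: doses 5/15/25 mJ·cm^-2 at
#' 0.15 mW·cm^-2 continuous-light irradiance, 500 Hz pulsing at
#' 30/50/80% duty cycles, synthetic plate counts at the published mean
#' log reductions, and the published consumption table for the energy
#' comparison.
#'
#' @param doses Ascending dose ladder, mJ·cm^-2.
#' @param cl_irradiance Continuous-light irradiance, mW·cm^-2.
#' @param frequency Pulse frequency, Hz.
#' @param duty_cycles Duty cycles, percent.
#' @param counts `"synthetic"` (generate plate counts with
#'   [simulate_counts()]) or a path to a counts CSV (see
#'   [read_counts()]).
#' @param synthetic Named list of [simulate_counts()] arguments
#'   (`baseline_mean`, `replicates`, `between_replicate_sd`,
#'   `dispersion`).
#' @param energy A measured-consumption table (see [savings_table()]);
#'   defaults to the study's, or a path to an energy CSV (see
#'   [read_energy()]).
#' @param alpha Significance level for the comparison stage.
#' @param seed Integer seed for the synthetic stage.
#'
#' @return A validated list of class `uvc_config`.
#' @examples
#' pipeline_config(seed = 1)
#' @export
pipeline_config <- function(doses = c(5, 15, 25), cl_irradiance = 0.15,
                            frequency = 500, duty_cycles = c(30, 50, 80),
                            counts = "synthetic", synthetic = list(),
                            energy = tomato_study_results(), alpha = 0.05,
                            seed = NULL) {
  if (length(doses) == 0 || is.unsorted(doses, strictly = TRUE) ||
      any(doses <= 0)) {
    abort("`doses` must be a non-empty, positive, strictly ascending ladder.",
          class = "uvcdose_error_invalid")
  }
  check_positive(cl_irradiance, "cl_irradiance")
  check_positive(frequency, "frequency")
  check_duty_cycle(duty_cycles)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               allow_equal_lower = FALSE, allow_equal_upper = FALSE)
  if (is.character(counts) && counts != "synthetic" && !file.exists(counts)) {
    abort(sprintf("Counts file not found: %s", counts),
          class = "uvcdose_error_invalid")
  }
  structure(
    list(doses = doses, cl_irradiance = cl_irradiance, frequency = frequency,
         duty_cycles = duty_cycles, counts = counts, synthetic = synthetic,
         energy = energy, alpha = alpha, seed = seed),
    class = "uvc_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; `energy`
#' may be a path to an energy CSV.
#'
#' @param path Path to a YAML file.
#' @return A validated `uvc_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("doses", "cl_irradiance", "frequency", "duty_cycles", "counts",
             "synthetic", "energy", "alpha", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration keys: ",
                 paste(unknown, collapse = ", ")),
          class = "uvcdose_error_invalid")
  }
  if (!is.null(raw$energy) && is.character(raw$energy)) {
    raw$energy <- read_energy(raw$energy)
  }
  do.call(pipeline_config, raw)
}

#' Read and validate a plate-count CSV
#'
#' Expected columns: `condition_id`, `mode`, `dose_mj_cm2`, `duty_pct`,
#' `replicate`, `cfu_before`, `cfu_after`. Rows with missing, negative
#' or non-positive-baseline counts are rejected with their line numbers
#' (header is line 1).
#'
#' @param path Path to a CSV file.
#' @return A tibble of plate-count records.
#' @export
read_counts <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("condition_id", "mode", "dose_mj_cm2", "duty_pct", "replicate",
              "cfu_before", "cfu_after")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("Counts CSV is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "uvcdose_error_validation")
  }
  bad <- which(is.na(df$cfu_before) | is.na(df$cfu_after) |
                 df$cfu_before <= 0 | df$cfu_after < 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid CFU counts (need cfu_before > 0 and cfu_after >= 0) on line(s): %s.",
      paste(bad + 1, collapse = ", ")
    ), class = "uvcdose_error_validation")
  }
  df
}

#' Read and validate an energy-consumption CSV
#'
#' Expected columns: `condition_id` or (`technique`, `dose_mj_cm2`,
#' `duty_pct`), plus either a directly measured `ec_ws` or the trio
#' `amperes`, `volts`, `time_s` from which consumption is derived via
#' [energy_ws()].
#'
#' @param path Path to a CSV file.
#' @return A tibble with an `ec_ws` column.
#' @export
read_energy <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"ec_ws" %in% names(df)) {
    trio <- c("amperes", "volts", "time_s")
    if (!all(trio %in% names(df))) {
      abort("Energy CSV needs either `ec_ws` or `amperes`,`volts`,`time_s`.",
            class = "uvcdose_error_validation")
    }
    df$ec_ws <- energy_ws(df$amperes, df$volts, df$time_s)
  }
  df
}

#' Run the full analysis pipeline
#'
#' Binds the stages end to end: treatment planning (dose-equivalence
#' table), plate counts (synthetic or from file), germicidal-effect
#' summary, normality screen, dose-wise and technique-wise comparisons
#' with compact letters, effective-germicidal-effect profiles, and the
#' energy-saving comparison. Optionally writes the bundle as CSV files
#' plus a run log; with a fixed seed the CSV outputs are reproduced
#' byte-identically (timestamps live only in the log).
#'
#' @param config A `uvc_config` from [pipeline_config()] or
#'   [read_config()].
#' @param output_dir Directory to write `plans.csv`, `counts.csv`,
#'   `ge_summary.csv`, `normality.csv`, `comparison_dose.csv`,
#'   `comparison_technique.csv`, `letters_*.csv`, `ege.csv`,
#'   `savings.csv` and `run_log.txt` into (created if needed). `NULL`
#'   skips writing.
#' @return Invisibly, a named list with elements `plans`, `counts`,
#'   `ge`, `normality`, `comparison_dose`, `comparison_technique`,
#'   `ege`, `savings`, `config`.
#' @examples
#' bundle <- run_pipeline(pipeline_config(seed = 1))
#' bundle$ge
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  if (!inherits(config, "uvc_config")) {
    abort("`config` must come from pipeline_config() or read_config().",
          class = "uvcdose_error_invalid")
  }
  plans <- plan_grid(config$doses, config$cl_irradiance, config$frequency,
                     config$duty_cycles)

  counts <- if (identical(config$counts, "synthetic")) {
    conds <- study_conditions()
    conds <- conds[conds$dose_mj_cm2 %in% config$doses &
                     (conds$mode == "CL" |
                        conds$duty_pct %in% config$duty_cycles), ]
    do.call(simulate_counts,
            c(list(conditions = conds, seed = config$seed), config$synthetic))
  } else if (is.data.frame(config$counts)) {
    config$counts
  } else {
    read_counts(config$counts)
  }

  ge <- summarize_ge(counts)
  normality <- normality_screen(
    dplyr::mutate(counts,
                  lrv = log_reduction(.data$cfu_before, .data$cfu_after)),
    lrv, condition_id
  )

  replicate_lrv <- counts |>
    dplyr::mutate(lrv = log_reduction(.data$cfu_before, .data$cfu_after),
                  technique = technique_label(.data$mode))
  cmp_dose <- compare_groups(replicate_lrv, lrv, dose_mj_cm2,
                             alpha = config$alpha)
  cmp_technique <- compare_groups(replicate_lrv, lrv, technique,
                                  alpha = config$alpha)

  ege <- ge |>
    dplyr::mutate(technique = technique_label(.data$mode)) |>
    dplyr::group_by(.data$technique, .data$duty_pct) |>
    dplyr::arrange(.data$dose_mj_cm2, .by_group = TRUE) |>
    ege_profile(dose_mj_cm2, mean_lrv)

  savings <- if (is.data.frame(config$energy)) {
    savings_table(config$energy)
  } else {
    NULL
  }

  bundle <- list(plans = plans, counts = counts, ge = ge,
                 normality = normality, comparison_dose = cmp_dose,
                 comparison_technique = cmp_technique, ege = ege,
                 savings = savings, config = config)
  if (!is.null(output_dir)) {
    write_bundle(bundle, output_dir)
  }
  invisible(bundle)
}

technique_label <- function(mode) {
  dplyr::recode(mode, CL = "CL", PPL = "Mode 1", TPL = "Mode 2")
}

write_bundle <- function(bundle, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    readr::write_csv(df, file.path(output_dir, name))
  }
  wr(bundle$plans, "plans.csv")
  wr(bundle$counts, "counts.csv")
  wr(bundle$ge, "ge_summary.csv")
  wr(bundle$normality, "normality.csv")
  wr(glance(bundle$comparison_dose), "comparison_dose.csv")
  wr(bundle$comparison_dose$letters, "letters_dose.csv")
  wr(glance(bundle$comparison_technique), "comparison_technique.csv")
  wr(bundle$comparison_technique$letters, "letters_technique.csv")
  wr(bundle$ege, "ege.csv")
  if (!is.null(bundle$savings)) wr(bundle$savings, "savings.csv")
  log_lines <- c(
    sprintf("uvcdose %s", as.character(packageVersion("uvcdose"))),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("seed: %s", if (is.null(bundle$config$seed)) "none"
            else bundle$config$seed),
    sprintf("doses: %s mJ/cm2", paste(bundle$config$doses, collapse = ", ")),
    sprintf("duty cycles: %s %%",
            paste(bundle$config$duty_cycles, collapse = ", ")),
    sprintf("alpha: %g", bundle$config$alpha)
  )
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  invisible(output_dir)
}
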