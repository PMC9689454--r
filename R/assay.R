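#' Log reduction value from plate counts
#'
#' The germicidal effect of a treatment is the decimal log reduction
#' `LRV = log10(N0 / N)` of viable counts, with `N0` and `N` the
#' colony-forming units before and after irradiation.
#'
#' Zero-survivor plates cannot be log-transformed; they are censored at
#' half the detection limit (0.5 CFU for a limit of 1 CFU) rather than
#' mapped to infinity. Use [is_censored()] to flag such records.
#'
#' @param cfu_before Counts before treatment (`N0 > 0`).
#' @param cfu_after Counts after treatment (`N >= 0`).
#' @param detection_limit Smallest countable number of CFU (default 1).
#' @return Log reduction in log10 units. Vectorised.
#' @examples
#' log_reduction(1000, 100)  # 1
#' log_reduction(1000, 87)   # 1.0605
#' @export
log_reduction <- function(cfu_before, cfu_after, detection_limit = 1) {
  check_positive(cfu_before, "cfu_before")
  check_nonnegative(cfu_after, "cfu_after")
  check_positive(detection_limit, "detection_limit")
  n <- ifelse(cfu_after == 0, detection_limit / 2, cfu_after)
  log10(cfu_before / n)
}

#' Flag zero-survivor (censored) plate counts
#'
#' @inheritParams log_reduction
#' @return Logical vector: `TRUE` where the after-count fell below the
#'   detection limit and the log reduction was censored.
#' @export
is_censored <- function(cfu_after) {
  check_nonnegative(cfu_after, "cfu_after")
  cfu_after == 0
}

#' Percent of the initial population inactivated
#'
#' Converts a log reduction to the fraction of the starting population
#' killed: `100 * (1 - 10^-LRV)`. One decade of reduction inactivates
#' 90%; 0.61 decades inactivates 75.5%.
#'
#' @param lrv Log reduction value(s) in log10 units (non-negative).
#' @return Percent inactivated in \[0, 100).
#' @examples
#' percent_inactivated(0.61)  # 75.5
#' percent_inactivated(1)     # 90
#' @export
percent_inactivated <- function(lrv) {
  check_nonnegative(lrv, "lrv")
  100 * (1 - 10^(-lrv))
}

#' Summarise germicidal effect per condition
#'
#' Computes per-replicate log reductions and aggregates them to a mean
#' and sample standard deviation (n - 1 denominator) per condition — the
#' "mean +/- SD" a disinfection study reports. Records where the
#' after-count exceeds the before-count (apparent growth) are kept but
#' counted in `n_growth`; zero-survivor records are censored at half the
#' detection limit and counted in `n_censored`.
#'
#' @param counts A data frame of plate counts with columns `cfu_before`,
#'   `cfu_after` and `replicate`, plus any of the condition identifiers
#'   `condition_id`, `mode`, `dose_mj_cm2`, `duty_pct` to group by.
#' @param pooled If `TRUE`, additionally reports `pooled_lrv`, the log
#'   reduction of the summed counts. Pooling first and taking logs is
#'   generally not equal to averaging per-replicate log reductions; the
#'   replicate-level path is the primary summary.
#' @param detection_limit Passed to [log_reduction()].
#'
#' @return A tibble with one row per condition: the grouping columns,
#'   `n`, `mean_lrv`, `sd_lrv`, `n_censored`, `n_growth` (and
#'   `pooled_lrv` when requested).
#' @examples
#' counts <- tibble::tibble(
#'   condition_id = "PPL_d25_dc30", replicate = 1:4,
#'   cfu_before = c(500, 480, 510, 495), cfu_after = c(44, 42, 45, 43)
#' )
#' summarize_ge(counts)
#' @export
summarize_ge <- function(counts, pooled = FALSE, detection_limit = 1) {
  stopifnot(is.data.frame(counts))
  needed <- c("cfu_before", "cfu_after")
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0 || nrow(counts) == 0) {
    abort("`counts` must be a non-empty data frame with `cfu_before` and `cfu_after`.",
          class = "uvcdose_error_validation")
  }
  keys <- intersect(c("condition_id", "mode", "dose_mj_cm2", "duty_pct"),
                    names(counts))
  out <- counts |>
    dplyr::mutate(
      .lrv = log_reduction(.data$cfu_before, .data$cfu_after, detection_limit)
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_lrv = mean(.data$.lrv),
      sd_lrv = if (dplyr::n() > 1) sd(.data$.lrv) else 0,
      n_censored = sum(is_censored(.data$cfu_after)),
      n_growth = sum(.data$cfu_after > .data$cfu_before),
      pooled_lrv = log_reduction(sum(.data$cfu_before),
                                 sum(pmax(.data$cfu_after, 0)),
                                 detection_limit),
      .groups = "drop"
    )
  if (!pooled) out$pooled_lrv <- NULL
  out
}

#' Effective germicidal effect profile over a dose ladder
#'
#' The effective germicidal effect (EGE) of a dose interval is the
#' percentage of the *initial* population inactivated within that
#' interval: the difference in [percent_inactivated()] between
#' consecutive points of the dose ladder, with an implicit starting
#' point of zero kill at zero dose. It diagnoses diminishing returns —
#' where along the ladder most of the inactivation happens.
#'
#' Equivalently, from mean counts `N_i` at each dose,
#' `EGE_i = 100 * (N_{i-1} - N_i) / N0`; both routes agree exactly when
#' computed from the same pooled counts. The increments sum to the total
#' percent inactivated at the final dose.
#'
#' @param lrv_by_dose A data frame with one row per dose; respects
#'   existing `dplyr::group_by()` groups (e.g. per technique).
#' @param dose,lrv Columns (tidy-eval) holding the dose ladder in
#'   mJ·cm^-2 (strictly increasing, all positive) and the mean log
#'   reduction at each dose.
#'
#' @return A tibble of class `uvc_ege` with columns `dose_from`,
#'   `dose_to`, `ege_pct` (incremental percent inactivated) and
#'   `cum_pct` (cumulative), per input group.
#' @examples
#' ege_profile(
#'   tibble::tibble(dose = c(5, 15, 25), lrv = c(0.61, 0.74, 1.06)),
#'   dose, lrv
#' )
#' @export
ege_profile <- function(lrv_by_dose, dose = dose_mj_cm2, lrv = mean_lrv) {
  stopifnot(is.data.frame(lrv_by_dose))
  dose_q <- rlang::enquo(dose)
  lrv_q <- rlang::enquo(lrv)
  one_group <- function(df, key) {
    d <- dplyr::pull(df, !!dose_q)
    l <- dplyr::pull(df, !!lrv_q)
    if (length(d) == 0 || anyNA(d) || anyNA(l)) {
      abort("Dose ladder must be non-empty with no missing values.",
            class = "uvcdose_error_validation")
    }
    if (is.unsorted(d, strictly = TRUE) || any(d <= 0)) {
      abort("Doses must be positive and strictly increasing.",
            class = "uvcdose_error_validation")
    }
    cum <- percent_inactivated(l)
    tibble::tibble(
      dose_from = c(0, d[-length(d)]),
      dose_to = d,
      ege_pct = diff(c(0, cum)),
      cum_pct = cum
    )
  }
  out <- if (dplyr::is_grouped_df(lrv_by_dose)) {
    dplyr::group_modify(lrv_by_dose, one_group) |> dplyr::ungroup()
  } else {
    one_group(lrv_by_dose, NULL)
  }
  class(out) <- c("uvc_ege", class(out))
  out
}

#' Raw-count difference behind the effective germicidal effect
#'
#' Diagnostic only: the literal difference `N - N0` in CFU between the
#' counts after and before irradiation. It is a (negative) count, not a
#' percentage; the interpretable EGE statistic is the incremental
#' percent of the initial population inactivated, via [ege_profile()].
#'
#' @inheritParams log_reduction
#' @return `cfu_after - cfu_before` (CFU).
#' @export
ege_count_difference <- function(cfu_before, cfu_after) {
  check_positive(cfu_before, "cfu_before")
  check_nonnegative(cfu_after, "cfu_after")
  cfu_after - cfu_before
}

#' Plot an effective germicidal effect profile
#'
#' Column chart of the incremental percent inactivated per dose
#' interval, faceted by any grouping columns present.
#'
#' @param object A `uvc_ege` tibble from [ege_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uvc_ege <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    interval = factor(sprintf("%g-%g", .data$dose_from, .data$dose_to),
                      levels = unique(sprintf("%g-%g", .data$dose_from,
                                              .data$dose_to)))
  )
  extra <- setdiff(names(object),
                   c("dose_from", "dose_to", "ege_pct", "cum_pct"))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$interval, .data$ege_pct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(Dose~interval~(mJ~cm^-2)),
                  y = "Effective germicidal effect (%)")
  if (length(extra) > 0) {
    p <- p + ggplot2::facet_wrap(extra)
  }
  p
}
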