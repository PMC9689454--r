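#' Simulate plate counts for a disinfection experiment
#'
#' Generates synthetic colony counts emulating a completely randomized
#' UV-C disinfection trial: for each condition and replicate, a baseline
#' count `N0 ~ Poisson(baseline_mean)`, a replicate-level latent log
#' reduction `true_lrv + Normal(0, between_replicate_sd)` capturing
#' biological variation between samples, and a survivor count
#' `N ~ Poisson(N0 * 10^-lrv)` (Poisson thinning counting noise).
#' Optionally the counts are negative-binomial to model extra-Poisson
#' overdispersion.
#'
#' The random stream is split per condition: each condition draws from
#' its own sub-stream derived from `seed`, so appending conditions to
#' the design never perturbs the counts of earlier conditions.
#'
#' @param conditions A data frame with one row per condition and columns
#'   `true_lrv` (log10 units, >= 0) plus any identifier columns among
#'   `condition_id`, `mode`, `dose_mj_cm2`, `duty_pct` (carried through
#'   to the output). See [study_conditions()].
#' @param baseline_mean Expected CFU per plated sample before treatment
#'   (default 500).
#' @param replicates Replicates per condition (default 4, the study's
#'   completely randomized design).
#' @param between_replicate_sd SD of the replicate-level log reduction
#'   in log10 units (default 0.02, giving replicate SDs in the 0.01-0.06
#'   range reported for this kind of assay once counting noise is
#'   added).
#' @param dispersion If non-`NULL`, counts are negative-binomial with
#'   this `size` parameter instead of Poisson (smaller = more
#'   overdispersed).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#'   `NULL` draws from the current stream.
#'
#' @return A tibble of plate-count records: the condition identifier
#'   columns, `replicate`, `cfu_before`, `cfu_after`.
#' @examples
#' simulate_counts(study_conditions(), seed = 1)
#' @export
simulate_counts <- function(conditions, baseline_mean = 500, replicates = 4,
                            between_replicate_sd = 0.02, dispersion = NULL,
                            seed = NULL) {
  stopifnot(is.data.frame(conditions))
  if (!"true_lrv" %in% names(conditions) || nrow(conditions) == 0) {
    abort("`conditions` must be a non-empty data frame with a `true_lrv` column.",
          class = "uvcdose_error_validation")
  }
  check_nonnegative(conditions$true_lrv, "true_lrv")
  check_positive(baseline_mean, "baseline_mean")
  check_number(replicates, "replicates", lower = 1)
  check_nonnegative(between_replicate_sd, "between_replicate_sd")

  n_cond <- nrow(conditions)
  cond_seeds <- if (is.null(seed)) {
    sample.int(.Machine$integer.max, n_cond)
  } else {
    withr::with_seed(seed, sample.int(.Machine$integer.max, n_cond))
  }

  draw_counts <- function(lambda) {
    if (is.null(dispersion)) rpois(length(lambda), lambda)
    else rnbinom(length(lambda), size = dispersion, mu = lambda)
  }
  keys <- intersect(c("condition_id", "mode", "dose_mj_cm2", "duty_pct"),
                    names(conditions))
  purrr::map_dfr(seq_len(n_cond), function(i) {
    withr::with_seed(cond_seeds[i], {
      n0 <- draw_counts(rep(baseline_mean, replicates))
      n0 <- pmax(n0, 1)  # a plated sample with zero baseline is re-drawn as 1
      lrv <- conditions$true_lrv[i] + rnorm(replicates, 0, between_replicate_sd)
      n_after <- draw_counts(n0 * 10^(-lrv))
      dplyr::bind_cols(
        conditions[rep(i, replicates), keys, drop = FALSE],
        tibble::tibble(replicate = seq_len(replicates),
                       cfu_before = n0, cfu_after = n_after)
      )
    })
  })
}
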