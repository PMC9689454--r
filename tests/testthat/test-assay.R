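test_that("log reduction is log10(N0/N) with zero-survivor censoring", {
  expect_equal(log_reduction(1000, 1000), 0)
  expect_equal(log_reduction(1000, 100), 1)
  expect_equal(log_reduction(1000, 87), log10(1000 / 87))
  expect_equal(round(log_reduction(1000, 87), 4), 1.0605)
  # zero survivors: censored at half the detection limit, never infinite
  expect_equal(log_reduction(1000, 0), log10(1000 / 0.5))
  expect_true(is.finite(log_reduction(1000, 0)))
  expect_true(is_censored(0))
  expect_false(is_censored(3))
  expect_error(log_reduction(0, 10), class = "uvcdose_error_invalid")
})

test_that("percent inactivated converts decades to percent kill", {
  expect_equal(round(percent_inactivated(0.61), 1), 75.5)
  expect_equal(percent_inactivated(0), 0)
  expect_equal(round(percent_inactivated(1.06), 1), 91.3)
  expect_equal(percent_inactivated(1), 90)
})

test_that("percent inactivated of a log reduction is the survivor complement", {
  withr::with_seed(4, {
    n0 <- sample(100:5000, 50, replace = TRUE)
    n <- pmax(1, rpois(50, n0 * 0.2))
  })
  expect_equal(percent_inactivated(pmax(log_reduction(n0, n), 0)),
               100 * (1 - n / n0))
})

test_that("EGE profile gives incremental percent kill per dose interval", {
  prof <- ege_profile(
    tibble::tibble(dose = c(5, 15, 25), lrv = c(0.61, 0.74, 1.06)),
    dose, lrv
  )
  expect_equal(prof$dose_from, c(0, 5, 15))
  expect_equal(prof$dose_to, c(5, 15, 25))
  # frozen from the closed form 100*(10^-lrv_{i-1} - 10^-lrv_i)
  expect_equal(prof$ege_pct, c(75.45291, 6.35008, 9.48737), tolerance = 1e-6)
  expect_equal(ege_profile(tibble::tibble(dose = 5, lrv = 0),
                           dose, lrv)$ege_pct, 0)
  expect_equal(ege_profile(tibble::tibble(dose = 5, lrv = 1),
                           dose, lrv)$ege_pct, 90)
  expect_error(
    ege_profile(tibble::tibble(dose = c(15, 5), lrv = c(0.5, 0.3)),
                dose, lrv),
    class = "uvcdose_error_validation"
  )
})

test_that("EGE increments sum to the total percent inactivated", {
  withr::with_seed(9, {
    for (rep in 1:20) {
      k <- sample(2:6, 1)
      lrv <- cumsum(stats::runif(k, 0, 0.6))
      prof <- ege_profile(tibble::tibble(dose = seq_len(k) * 5, lrv = lrv),
                          dose, lrv)
      expect_equal(sum(prof$ege_pct), percent_inactivated(lrv[k]),
                   tolerance = 1e-9)
      expect_true(all(prof$ege_pct >= 0))
    }
  })
})

test_that("count path and LRV path of the EGE agree on pooled counts", {
  withr::with_seed(13, {
    n0 <- sum(rpois(4, 500))
    n_by_dose <- c(sum(rpois(4, 120)), sum(rpois(4, 80)), sum(rpois(4, 40)))
  })
  lrv <- log10(n0 / n_by_dose)
  via_lrv <- ege_profile(tibble::tibble(dose = c(5, 15, 25), lrv = lrv),
                         dose, lrv)$ege_pct
  via_counts <- 100 * diff(c(0, n0 - n_by_dose)) / n0
  expect_equal(via_lrv, via_counts, tolerance = 1e-9)
})

test_that("EGE profiles respect grouped input", {
  df <- tibble::tibble(
    technique = rep(c("CL", "Mode 1"), each = 3),
    dose = rep(c(5, 15, 25), 2),
    lrv = c(0.62, 0.77, 0.99, 0.61, 0.74, 1.06)
  )
  prof <- ege_profile(dplyr::group_by(df, technique), dose, lrv)
  expect_equal(nrow(prof), 6)
  expect_equal(sum(prof$technique == "CL"), 3)
  expect_equal(prof$ege_pct[prof$technique == "Mode 1"],
               c(75.45291, 6.35008, 9.48737), tolerance = 1e-6)
})

test_that("the raw count difference diagnostic is N - N0", {
  expect_equal(ege_count_difference(500, 120), -380)
})

test_that("germicidal-effect summary reports replicate mean and sample SD", {
  counts <- tibble::tibble(
    condition_id = "c1", replicate = 1:4,
    cfu_before = 1000, cfu_after = round(1000 * 10^(-0.62))
  )
  ge <- summarize_ge(counts)
  expect_equal(ge$n, 4)
  expect_equal(ge$sd_lrv, 0)
  expect_equal(ge$mean_lrv, log10(1000 / 240))

  two <- tibble::tibble(condition_id = "c2", replicate = 1:2,
                        cfu_before = c(1000, 1000),
                        cfu_after = round(1000 * 10^(-c(0.60, 0.64))))
  ge2 <- summarize_ge(two)
  expect_equal(ge2$mean_lrv, mean(log10(1000 / c(251, 229))))
  expect_equal(ge2$sd_lrv, sd(log10(1000 / c(251, 229))))
  expect_equal(round(ge2$sd_lrv, 2), 0.03)

  expect_error(summarize_ge(counts[0, ]), class = "uvcdose_error_validation")
})

test_that("summary flags censored and growth records and can pool counts", {
  counts <- tibble::tibble(
    condition_id = "c1", replicate = 1:4,
    cfu_before = c(500, 480, 510, 495),
    cfu_after = c(0, 42, 45, 520)
  )
  ge <- summarize_ge(counts, pooled = TRUE)
  expect_equal(ge$n_censored, 1)
  expect_equal(ge$n_growth, 1)
  expect_equal(ge$pooled_lrv, log10(sum(counts$cfu_before) / sum(counts$cfu_after)))
  # pooled and replicate-level summaries are generally different
  expect_false(isTRUE(all.equal(ge$pooled_lrv, ge$mean_lrv)))
})

test_that("synthetic condition at a known true LRV is recovered", {
  conds <- tibble::tibble(condition_id = "c", true_lrv = 1.06)
  reps <- purrr::map_dbl(1:50, function(s) {
    summarize_ge(simulate_counts(conds, baseline_mean = 500, replicates = 4,
                                 seed = 1000 + s))$mean_lrv
  })
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 1.06), 3 * se + 1e-12)
})
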