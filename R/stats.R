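#' Shapiro-Wilk normality screen per condition
#'
#' Runs the Shapiro-Wilk test within each condition, the usual screen
#' before a one-way ANOVA on small disinfection designs. Conditions with
#' fewer than 3 replicates are skipped with a warning; conditions whose
#' replicates are all identical are degenerate (the test is undefined)
#' and flagged rather than tested.
#'
#' @param data A data frame of replicate-level values.
#' @param value,group Columns (tidy-eval) holding the response (e.g. log
#'   reduction) and the condition key.
#' @return A tibble with one row per condition: `n`, `p_value` (`NA`
#'   when skipped or degenerate), `degenerate`, `note`.
#' @examples
#' df <- data.frame(cond = rep(c("a", "b"), each = 4),
#'                  lrv = c(0.6, 0.62, 0.65, 0.61, 0.9, 0.95, 0.91, 0.93))
#' normality_screen(df, lrv, cond)
#' @export
normality_screen <- function(data, value, group) {
  stopifnot(is.data.frame(data))
  value_q <- rlang::enquo(value)
  group_q <- rlang::enquo(group)
  out <- data |>
    dplyr::group_by(group = !!group_q) |>
    dplyr::summarise(
      n = dplyr::n(),
      .values = list(!!value_q),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      degenerate = purrr::map_lgl(.data$.values,
                                  ~ length(unique(.x)) == 1 && length(.x) >= 3),
      p_value = purrr::map2_dbl(.data$.values, .data$degenerate, function(v, dg) {
        if (length(v) < 3 || dg) NA_real_ else shapiro.test(v)$p.value
      }),
      note = dplyr::case_when(
        n < 3 ~ "skipped: fewer than 3 replicates",
        degenerate ~ "degenerate: all replicates identical",
        TRUE ~ ""
      )
    ) |>
    dplyr::select("group", "n", "p_value", "degenerate", "note")
  if (any(out$n < 3)) {
    warn("Some conditions have fewer than 3 replicates; normality test skipped for them.")
  }
  out
}

#' One-way comparison of germicidal effect across groups
#'
#' The study-style comparison stage: an omnibus one-way ANOVA on the
#' response across groups at significance `alpha`; when the omnibus test
#' rejects, Tukey's honestly-significant-difference all-pairs comparison
#' (family-wise error controlled), summarised as a compact letter
#' display — groups sharing a letter are not significantly different.
#' Letters are ordered from the largest group mean downward, so the
#' best-performing group carries "a".
#'
#' If every group has zero within-group variance the F statistic is
#' undefined; pairs are then compared exactly (equal means share a
#' letter, unequal means do not).
#'
#' @param data A data frame of replicate-level values.
#' @param value,group Columns (tidy-eval) holding the response and the
#'   grouping factor (>= 2 groups with >= 2 replicates each).
#' @param alpha Family-wise significance level (default 0.05).
#' @return An object of class `uvc_comparison`: a list with `omnibus`
#'   (one-row tibble), `pairwise` (tibble of Tukey-adjusted pairs, or
#'   exact ties), `letters` (tibble `group`, `mean`, `letter`), `alpha`,
#'   and `method`. Use [tidy()] for the pairwise table, [glance()] for
#'   the omnibus row.
#' @examples
#' df <- data.frame(g = rep(c("CL", "M1", "M2"), each = 4),
#'                  y = c(rnorm(4, 0.8, 0.05), rnorm(4, 0.8, 0.05),
#'                        rnorm(4, 0.5, 0.05)))
#' compare_groups(df, y, g)
#' @export
compare_groups <- function(data, value, group, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  check_number(alpha, "alpha", lower = 0, upper = 1,
               allow_equal_lower = FALSE, allow_equal_upper = FALSE)
  value_q <- rlang::enquo(value)
  group_q <- rlang::enquo(group)
  df <- tibble::tibble(
    value = dplyr::pull(data, !!value_q),
    group = as.character(dplyr::pull(data, !!group_q))
  )
  sizes <- table(df$group)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("Need at least 2 groups with at least 2 replicates each.",
          class = "uvcdose_error_validation")
  }
  means <- vapply(split(df$value, df$group), mean, numeric(1))
  groups <- names(sort(means, decreasing = TRUE))
  means <- means[groups]

  within_var <- tapply(df$value, df$group, stats::var)
  if (all(within_var == 0)) {
    # exact-tie handling: no residual variance, compare means directly
    pairs <- utils::combn(groups, 2)
    pairwise <- tibble::tibble(
      group1 = pairs[1, ], group2 = pairs[2, ],
      estimate = unname(means[pairs[1, ]] - means[pairs[2, ]]),
      adj_p_value = unname(ifelse(means[pairs[1, ]] == means[pairs[2, ]], 1, 0))
    )
    omnibus <- tibble::tibble(
      statistic = NA_real_, df_between = length(groups) - 1,
      df_within = nrow(df) - length(groups),
      p_value = if (length(unique(means)) == 1) 1 else 0
    )
  } else {
    fit <- aov(value ~ group, data = df)
    an <- summary(fit)[[1]]
    omnibus <- tibble::tibble(
      statistic = an[["F value"]][1],
      df_between = an[["Df"]][1],
      df_within = an[["Df"]][2],
      p_value = an[["Pr(>F)"]][1]
    )
    tk <- TukeyHSD(fit)$group
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- tibble::tibble(
      group1 = purrr::map_chr(nm, 1),
      group2 = purrr::map_chr(nm, 2),
      estimate = unname(tk[, "diff"]),
      conf_low = unname(tk[, "lwr"]),
      conf_high = unname(tk[, "upr"]),
      adj_p_value = unname(tk[, "p adj"])
    )
  }

  # Pairs are only declared different when the omnibus test rejects,
  # mirroring the sequential ANOVA-then-post-hoc protocol.
  if (omnibus$p_value >= alpha) {
    significant <- pairwise[0, c("group1", "group2")]
  } else {
    significant <- pairwise[pairwise$adj_p_value < alpha,
                            c("group1", "group2")]
  }
  letters_tbl <- tibble::tibble(
    group = groups,
    mean = unname(means),
    letter = compact_letters(groups, significant)
  )
  structure(
    list(
      omnibus = omnibus,
      pairwise = pairwise,
      letters = letters_tbl,
      alpha = alpha,
      method = "one-way ANOVA with Tukey HSD all-pairs comparison"
    ),
    class = "uvc_comparison"
  )
}

# Compact letter display by insert-and-absorb: start with all groups in
# one letter column; for each significantly different pair split every
# column containing both; drop columns that became subsets of others.
# `groups` must be ordered by decreasing mean so "a" lands on the top
# group.
compact_letters <- function(groups, significant_pairs) {
  cols <- list(groups)
  if (nrow(significant_pairs) > 0) {
    for (i in seq_len(nrow(significant_pairs))) {
      g1 <- significant_pairs$group1[i]
      g2 <- significant_pairs$group2[i]
      new_cols <- list()
      for (col in cols) {
        if (g1 %in% col && g2 %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, g1)), list(setdiff(col, g2)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop any column contained in another
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[b] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  # order columns by the best (first-listed) group they contain
  first_rank <- purrr::map_int(cols, ~ min(match(.x, groups)))
  cols <- cols[order(first_rank)]
  out <- purrr::map_chr(groups, function(g) {
    paste0(letters[which(purrr::map_lgl(cols, ~ g %in% .x))], collapse = "")
  })
  out
}

#' @export
print.uvc_comparison <- function(x, ...) {
  cat("<uvc_comparison>", x$method, "\n")
  cat(sprintf("Omnibus: F(%g, %g) = %s, p = %s (alpha = %g)\n",
              x$omnibus$df_between, x$omnibus$df_within,
              format(x$omnibus$statistic, digits = 4),
              format(x$omnibus$p_value, digits = 4), x$alpha))
  print(x$letters)
  invisible(x)
}

#' @rdname compare_groups
#' @param x,object A `uvc_comparison` object.
#' @param ... Unused.
#' @export
tidy.uvc_comparison <- function(x, ...) {
  x$pairwise
}

#' @rdname compare_groups
#' @export
glance.uvc_comparison <- function(x, ...) {
  dplyr::mutate(x$omnibus, alpha = x$alpha, method = x$method,
                n_groups = nrow(x$letters))
}

#' Plot group means with compact letters
#'
#' @param object A `uvc_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uvc_comparison <- function(object, ...) {
  df <- object$letters
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$group, -.data$mean),
                                   .data$mean)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$letter), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "Group mean")
}
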