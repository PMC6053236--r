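# Protocol, order-of-draw, material and platform comparison statistics, and
# the paired-means sample-size calculation.

#' Compare centrifugation protocols per assay and strategy
#'
#' Student t-test of normalized levels between the dual and prolonged single
#' centrifugation groups, per assay x strategy (x platform). The default is
#' the unpaired equal-variance two-sample form; `"paired_by_adjacent_tube"`
#' pairs each dual tube with the next single tube in order of draw (tubes
#' 1&2, 3&4, ...), reflecting that all tubes came from one venipuncture.
#'
#' @param levels Normalized-level tibble from [normalize_levels()], with
#'   `protocol` populated (`"dual"`/`"single"`).
#' @param pairing `"unpaired"` (default) or `"paired_by_adjacent_tube"`.
#' @return Tibble with one row per assay x strategy x platform:
#'   `statistic`, `p_value`, `n1` (dual), `n2` (single), `test_kind`.
#' @export
compare_protocols <- function(levels,
                              pairing = c("unpaired", "paired_by_adjacent_tube")) {
  pairing <- match.arg(pairing)
  one_group <- function(df) {
    dual <- df[df$protocol == "dual", ]
    single <- df[df$protocol == "single", ]
    if (nrow(dual) < 2 || nrow(single) < 2) {
      abort("each protocol group needs at least 2 levels",
            class = "mirvar_validation_error")
    }
    if (pairing == "unpaired") {
      if (var(dual$level) + var(single$level) == 0) {
        # degenerate groups: identical means carry no evidence, differing
        # constant groups are separated with certainty
        same <- mean(dual$level) == mean(single$level)
        return(tibble(statistic = if (same) 0 else Inf,
                      p_value = if (same) 1 else 0,
                      n1 = nrow(dual), n2 = nrow(single),
                      test_kind = "student_t_two_sample"))
      }
      tt <- t.test(dual$level, single$level, var.equal = TRUE)
      kind <- "student_t_two_sample"
    } else {
      if (nrow(dual) != nrow(single) || any(is.na(dual$draw_order))) {
        abort("paired mode needs equal groups with draw_order set",
              class = "mirvar_validation_error")
      }
      dual <- dual[order(dual$draw_order), ]
      single <- single[order(single$draw_order), ]
      diffs <- dual$level - single$level
      if (var(diffs) == 0) {
        same <- mean(diffs) == 0
        return(tibble(statistic = if (same) 0 else Inf,
                      p_value = if (same) 1 else 0,
                      n1 = nrow(dual), n2 = nrow(single),
                      test_kind = "student_t_paired"))
      }
      tt <- t.test(dual$level, single$level, paired = TRUE)
      kind <- "student_t_paired"
    }
    tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
           n1 = nrow(dual), n2 = nrow(single), test_kind = kind)
  }
  levels |>
    dplyr::group_by(.data$assay, .data$strategy, .data$platform) |>
    dplyr::group_modify(~ one_group(.x)) |>
    dplyr::ungroup()
}

#' Test for an order-of-draw effect
#'
#' Compares normalized levels in the first `n_each` tubes drawn against the
#' last `n_each` (default 10 and 10 of 30, the middle third excluded) with
#' an unpaired equal-variance Student t-test, per assay x strategy.
#'
#' @param levels Normalized-level tibble with `draw_order` populated.
#' @param n_each Tubes in each tail group.
#' @param on_degenerate What to do when the levels are constant:
#'   `"error"` (default) or `"null"` (report t = 0, p = 1 — constant data
#'   cannot show an order effect).
#' @return Tibble per assay x strategy x platform with `statistic`,
#'   `p_value`, `n1`, `n2`, `test_kind`.
#' @export
order_of_draw_test <- function(levels, n_each = 10,
                               on_degenerate = c("error", "null")) {
  on_degenerate <- match.arg(on_degenerate)
  if (any(is.na(levels$draw_order))) {
    abort("draw_order must be present for every record",
          class = "mirvar_validation_error")
  }
  one_group <- function(df) {
    df <- df[order(df$draw_order), ]
    if (nrow(df) < 2 * n_each) {
      abort(sprintf("need at least %d tubes for first/last %d comparison",
                    2 * n_each, n_each), class = "mirvar_validation_error")
    }
    first <- df$level[seq_len(n_each)]
    last <- df$level[seq(nrow(df) - n_each + 1, nrow(df))]
    if (var(first) + var(last) == 0) {
      if (on_degenerate == "null" && mean(first) == mean(last)) {
        return(tibble(statistic = 0, p_value = 1, n1 = n_each, n2 = n_each,
                      test_kind = "student_t_two_sample"))
      }
      abort("levels are constant: t-test degenerate",
            class = "mirvar_validation_error")
    }
    tt <- t.test(first, last, var.equal = TRUE)
    tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
           n1 = n_each, n2 = n_each, test_kind = "student_t_two_sample")
  }
  levels |>
    dplyr::group_by(.data$assay, .data$strategy, .data$platform) |>
    dplyr::group_modify(~ one_group(.x)) |>
    dplyr::ungroup()
}

# Spearman rho with average ranks; p from the exact permutation null for
# small tie-free samples, otherwise the t-approximation on n - 2 df.
spearman_test <- function(x, y) {
  n <- length(x)
  if (n < 5) {
    abort("need at least 5 matched pairs", class = "mirvar_validation_error")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort("zero variance: correlation undefined",
          class = "mirvar_validation_error")
  }
  rho <- cor(x, y, method = "spearman")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 8 && !ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else if (abs(rho) == 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = min(p, 1), n = n)
}

correlation_label <- function(rho) {
  a <- abs(rho)
  ifelse(a > 0.7, "good", ifelse(a >= 0.3, "intermediate", "none"))
}

#' Spearman correlation between matched measurement series
#'
#' Rank correlation (average ranks for ties) between two normalized-level
#' series matched by sample. Inputs are either two numeric vectors already
#' in matching order, or two normalized-level tables which are joined on
#' `subject_id` and compared per assay x strategy. The p-value uses the
#' exact permutation null for n <= 8 without ties, and the t-approximation
#' on n - 2 degrees of freedom otherwise. The qualitative `label`
#' (|rho| < 0.3 "none", 0.3–0.7 "intermediate", > 0.7 "good") is a
#' presentation convention only.
#'
#' @param levels_x,levels_y Numeric vectors, or normalized-level tibbles
#'   with `subject_id`, `assay`, `strategy`, `level`.
#' @return For vectors, a one-row tibble with `rho`, `p_value`, `n`,
#'   `label`; for tables, one row per assay x strategy.
#' @examples
#' correlate(1:6, c(2, 4, 5, 7, 8, 12))  # rho = 1
#' @export
correlate <- function(levels_x, levels_y) {
  if (is.numeric(levels_x) && is.numeric(levels_y)) {
    if (length(levels_x) != length(levels_y)) {
      abort("vectors must have equal length", class = "mirvar_validation_error")
    }
    st <- spearman_test(levels_x, levels_y)
    return(tibble(rho = st$rho, p_value = st$p_value, n = st$n,
                  label = correlation_label(st$rho)))
  }
  need <- c("subject_id", "assay", "strategy", "level")
  if (!all(need %in% names(levels_x)) || !all(need %in% names(levels_y))) {
    abort("level tables need subject_id, assay, strategy and level columns",
          class = "mirvar_schema_error")
  }
  joined <- dplyr::inner_join(
    dplyr::select(levels_x, dplyr::all_of(need)),
    dplyr::select(levels_y, dplyr::all_of(need)),
    by = c("subject_id", "assay", "strategy"), suffix = c("_x", "_y"))
  joined |>
    dplyr::group_by(.data$assay, .data$strategy) |>
    dplyr::group_modify(function(df, key) {
      st <- spearman_test(df$level_x, df$level_y)
      tibble(rho = st$rho, p_value = st$p_value, n = st$n,
             label = correlation_label(st$rho))
    }) |>
    dplyr::ungroup()
}

#' Sample size for detecting a relative difference in paired means
#'
#' Number of pairs needed for a paired t-test to detect a relative
#' difference `relative_difference` in the mean when the per-measurement SD
#' is `relative_sd` of the mean and the within-pair correlation is
#' `pair_correlation`. The SD of a paired difference is
#' `relative_sd * sqrt(2 * (1 - pair_correlation))`, giving standardised
#' effect size `d = relative_difference / (relative_sd *
#' sqrt(2 * (1 - pair_correlation)))`; the sample size solves the fixed
#' point `n = (t_{1-alpha/2, n-1} + t_{power, n-1})^2 / d^2`, rounded up.
#' With very large effects the formula floors at n = 2–3 pairs, below which
#' a t-test has no degrees of freedom to spare.
#'
#' @param relative_difference Difference to detect, as a fraction of the
#'   mean (default 0.10).
#' @param relative_sd Per-measurement SD as a fraction of the mean
#'   (default 0.20).
#' @param pair_correlation Correlation within a pair (default 0.85).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @return Integer sample size per group.
#' @examples
#' paired_sample_size()  # 12 at the defaults
#' @export
paired_sample_size <- function(relative_difference = 0.10,
                               relative_sd = 0.20,
                               pair_correlation = 0.85,
                               alpha = 0.05,
                               power = 0.8) {
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1) {
    abort("alpha and power must lie strictly between 0 and 1",
          class = "mirvar_validation_error")
  }
  if (pair_correlation >= 1) {
    abort("pair_correlation must be < 1", class = "mirvar_validation_error")
  }
  if (relative_difference == 0 || relative_sd <= 0) {
    abort("need a non-zero difference and a positive SD",
          class = "mirvar_validation_error")
  }
  d <- abs(relative_difference) /
    (relative_sd * sqrt(2 * (1 - pair_correlation)))
  # Fixed point on the real-valued n, starting from the normal approximation.
  # The update is damped (averaged with the current iterate): near df = 1 the
  # raw map is non-contractive for large effects and would cycle.
  f <- function(n) {
    df <- max(n - 1, 1)
    max((qt(1 - alpha / 2, df = df) + qt(power, df = df))^2 / d^2, 2)
  }
  n <- max((stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 / d^2, 2)
  for (i in 1:200) {
    n_new <- (n + f(n)) / 2
    if (abs(n_new - n) < 1e-9) break
    n <- n_new
  }
  as.integer(ceiling(n - 1e-9))
}
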