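# Nested-duplicate precision statistics and the preanalytical attribution
# statistic.

#' Coefficient of variation
#'
#' `CV = (SD / mean) * 100`, with the sample SD (n - 1 denominator).
#'
#' @param values Numeric vector, at least two values with a positive mean.
#' @return CV in percent.
#' @examples
#' cv(c(8, 12))  # 28.28
#' @export
cv <- function(values) {
  if (length(values) < 2) {
    abort("need at least 2 values to compute a CV",
          class = "mirvar_validation_error")
  }
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    abort("CV requires a positive mean", class = "mirvar_validation_error")
  }
  100 * sd(values) / m
}

#' Round half away from zero
#'
#' Presentation rounding used for reported CVs (1 decimal) and attribution
#' percentages (integers): exact halves round up, unlike [base::round()]'s
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Intra- and inter-assay CVs from a nested duplicate design
#'
#' Takes normalized levels from a precision experiment in which each run
#' contributes one duplicate pair per assay, platform and strategy (the two
#' RT replicates, each already averaged over its PCR wells) and separates:
#'
#' * repeatability (intra-assay CV): the pooled within-run duplicate SD
#'   (Dahlberg form), `100 * sqrt(sum(d_i^2) / (2k)) / grand_mean` over the
#'   `k` within-run differences `d_i`;
#' * precision (inter-assay CV): by default the CV of the `k` run means
#'   (`inter_method = "run_means"`); `"all_values"` instead takes the CV of
#'   all `2k` individual levels, a common alternative reading of an
#'   inter-assay CV from this design.
#'
#' Runs missing one member of the pair are dropped with a warning; fewer
#' than 3 complete runs is an error.
#'
#' @param levels Normalized-level tibble from [normalize_levels()] with
#'   `run_day` and `rt_replicate` populated.
#' @param inter_method `"run_means"` (default) or `"all_values"`.
#' @return Tibble with one row per assay x platform x strategy:
#'   `grand_mean`, `sd_total`, `cv_inter`, `cv_intra`, `n_runs`.
#' @export
precision_from_duplicates <- function(levels,
                                      inter_method = c("run_means", "all_values")) {
  inter_method <- match.arg(inter_method)
  need <- c("assay", "platform", "strategy", "run_day", "level")
  missing <- setdiff(need, names(levels))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
          class = "mirvar_schema_error")
  }
  one_group <- function(df) {
    runs <- split(df$level, df$run_day)
    complete <- vapply(runs, function(v) length(v) == 2, logical(1))
    if (any(!complete)) {
      warn(sprintf("dropping %d run(s) without a complete duplicate pair (%s, %s, %s)",
                   sum(!complete), df$assay[1], df$platform[1], df$strategy[1]))
      runs <- runs[complete]
    }
    k <- length(runs)
    if (k < 3) {
      abort(sprintf("fewer than 3 complete runs for %s / %s / %s",
                    df$assay[1], df$platform[1], df$strategy[1]),
            class = "mirvar_validation_error")
    }
    all_vals <- unlist(runs)
    gm <- mean(all_vals)
    d <- vapply(runs, function(v) v[1] - v[2], numeric(1))
    run_means <- vapply(runs, mean, numeric(1))
    tibble(
      grand_mean = gm,
      sd_total = sd(all_vals),
      cv_inter = if (inter_method == "run_means") cv(run_means) else cv(all_vals),
      cv_intra = 100 * sqrt(sum(d^2) / (2 * k)) / gm,
      n_runs = k
    )
  }
  levels |>
    dplyr::group_by(.data$assay, .data$platform, .data$strategy) |>
    dplyr::group_modify(~ one_group(dplyr::mutate(.x,
      assay = .y$assay, platform = .y$platform, strategy = .y$strategy))) |>
    dplyr::ungroup()
}

#' Attribute intra-assay variation to centrifugation and purification
#'
#' The whole-procedure CV of the centrifugation experiment (one CV per
#' protocol) includes plasma preparation, purification and the RT-qPCR
#' measurement, whereas the repeatability CV of the pooled-sample precision
#' experiment covers the RT-qPCR measurement alone. Their comparison
#' attributes the excess to the preanalytical steps:
#' `cv_total = (cv_single + cv_dual) / 2` and
#' `fraction = 100 * (cv_total - cv_rt_qpcr) / cv_total`.
#'
#' A repeatability CV exceeding the whole-procedure CV yields a negative
#' fraction, reported as-is with a warning (it signals estimation noise, not
#' a physical share). Rounding to integer percent is left to presentation
#' ([round_half_up()]).
#'
#' @param cv_single,cv_dual Whole-procedure CVs (%) under the prolonged
#'   single and dual centrifugation protocols (vectorised).
#' @param cv_repeatability Intra-assay CV (%) of qPCR from the precision
#'   experiment.
#' @param assay,strategy Optional labels carried into the result.
#' @return Tibble with `assay`, `strategy`, `cv_total`, `cv_rt_qpcr`,
#'   `fraction_preanalytical` (percent).
#' @examples
#' attribute_preanalytical(19.0, 19.4, 5.2)  # ~72.9% -> presents as 73
#' @export
attribute_preanalytical <- function(cv_single, cv_dual, cv_repeatability,
                                    assay = NA_character_,
                                    strategy = NA_character_) {
  if (any(cv_single <= 0) || any(cv_dual <= 0) || any(cv_repeatability <= 0)) {
    abort("all CV inputs must be positive", class = "mirvar_validation_error")
  }
  cv_total <- (cv_single + cv_dual) / 2
  fraction <- 100 * (cv_total - cv_repeatability) / cv_total
  if (any(fraction < 0)) {
    warn("repeatability CV exceeds whole-procedure CV: negative attribution fraction")
  }
  tibble(assay = assay, strategy = strategy, cv_total = cv_total,
         cv_rt_qpcr = cv_repeatability, fraction_preanalytical = fraction)
}

#' Fold difference implied by a Ct difference
#'
#' One PCR cycle corresponds to a doubling, so a Ct difference of `delta_ct`
#' cycles corresponds to a `2^|delta_ct|`-fold abundance difference.
#'
#' @param delta_ct Ct difference in cycles.
#' @return Fold difference (>= 1).
#' @examples
#' fold_difference(8)  # 256
#' @export
fold_difference <- function(delta_ct) {
  2^abs(delta_ct)
}
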