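# End-to-end orchestration of the four study designs over synthetic (or
# loaded) measurement tables, emitting tabular reports shaped like the
# study's summary tables plus a machine-readable JSON summary.

normalize_all <- function(measurements,
                          strategies = mirvar_strategies()) {
  dplyr::bind_rows(lapply(strategies, function(s)
    normalize_levels(measurements, s)))
}

#' Run the centrifugation-protocol experiment end-to-end
#'
#' Simulates (or takes) the 30-tube experiment, normalizes under each
#' strategy and reports per assay x protocol x strategy the mean level, CV
#' and protocol-comparison p-value, plus the order-of-draw test table.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @param measurements Optional pre-loaded measurement table (skips
#'   simulation).
#' @param strategies Normalization strategies to run.
#' @param pairing Passed to [compare_protocols()].
#' @return List with `levels`, `summary` (the table-1-shaped report),
#'   `protocol_tests` and `order_of_draw`.
#' @export
run_experiment_1 <- function(config, seed = config$seed, measurements = NULL,
                             strategies = mirvar_strategies(),
                             pairing = "unpaired") {
  if (is.null(measurements)) {
    measurements <- generate_centrifugation_experiment(config, seed = seed)
  }
  levels <- normalize_all(measurements, strategies)
  tests <- compare_protocols(levels, pairing = pairing)
  summary <- levels |>
    dplyr::group_by(.data$assay, .data$strategy, .data$protocol) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$level),
                     cv = if (dplyr::n() >= 2 && mean(.data$level) > 0)
                       cv(.data$level) else NA_real_,
                     .groups = "drop") |>
    dplyr::left_join(dplyr::select(tests, "assay", "strategy", "p_value"),
                     by = c("assay", "strategy"))
  # first/last thirds of the draw sequence (10 and 10 in the 30-tube design)
  n_each <- max(2, floor(length(unique(levels$draw_order)) / 3))
  list(levels = levels, summary = summary, protocol_tests = tests,
       order_of_draw = order_of_draw_test(levels, n_each = n_each,
                                          on_degenerate = "null"))
}

#' Run the material- and platform-agreement experiments end-to-end
#'
#' Simulates (or takes) the patient cohort and reports Spearman agreement
#' per assay x strategy for (a) platelet-poor vs standard plasma on single
#' TaqMan assays and (b) single TaqMan assays vs TLDA on platelet-poor
#' plasma.
#'
#' @inheritParams run_experiment_1
#' @return List with `levels`, `ppp_vs_standard` and `single_vs_tlda`
#'   correlation tables.
#' @export
run_experiments_2_3 <- function(config, seed = config$seed,
                                measurements = NULL,
                                strategies = mirvar_strategies()) {
  if (is.null(measurements)) {
    measurements <- generate_patient_cohort(config, seed = seed)
  }
  levels <- normalize_all(measurements, strategies)
  qpcr <- dplyr::filter(levels, .data$platform == "qPCR")
  # zero-variance (fully deterministic) inputs make rank correlation
  # undefined; report an empty table rather than failing the whole run
  safe_correlate <- function(x, y) {
    tryCatch(correlate(x, y),
             mirvar_validation_error = function(e) {
               warn(conditionMessage(e))
               tibble(assay = character(), strategy = character(),
                      rho = numeric(), p_value = numeric(), n = integer(),
                      label = character())
             })
  }
  ppp_vs_standard <- safe_correlate(
    dplyr::filter(qpcr, .data$material == "PPP"),
    dplyr::filter(qpcr, .data$material == "standard_plasma"))
  single_vs_tlda <- safe_correlate(
    dplyr::filter(qpcr, .data$material == "PPP"),
    dplyr::filter(levels, .data$platform == "TLDA"))
  list(levels = levels, ppp_vs_standard = ppp_vs_standard,
       single_vs_tlda = single_vs_tlda)
}

#' Run the precision/repeatability experiment end-to-end
#'
#' Simulates (or takes) the pooled-sample precision experiment (15 runs x
#' duplicate RT x duplicate wells on qPCR and ddPCR), reports the
#' table-2-shaped precision/repeatability CVs per assay x platform x
#' strategy, and — when a cohort table is supplied or simulated — the
#' qPCR-vs-ddPCR agreement on the patient cohort.
#'
#' @inheritParams run_experiment_1
#' @param cohort Optional cohort measurement table for the platform
#'   agreement part; `NULL` simulates one from `config`.
#' @param inter_method Passed to [precision_from_duplicates()].
#' @return List with `levels`, `precision` and `qpcr_vs_ddpcr`.
#' @export
run_experiment_4 <- function(config, seed = config$seed, measurements = NULL,
                             cohort = NULL,
                             strategies = mirvar_strategies(),
                             inter_method = "run_means") {
  if (is.null(measurements)) {
    measurements <- generate_precision_experiment(config, platform = "both",
                                                  seed = seed)
  }
  levels <- normalize_all(measurements, strategies)
  precision <- precision_from_duplicates(levels, inter_method = inter_method)
  if (is.null(cohort)) {
    cohort <- generate_patient_cohort(config, seed = seed)
  }
  cohort_levels <- normalize_all(cohort, strategies)
  qpcr_vs_ddpcr <- tryCatch(
    correlate(
      dplyr::filter(cohort_levels, .data$platform == "qPCR",
                    .data$material == "PPP"),
      dplyr::filter(cohort_levels, .data$platform == "ddPCR")),
    mirvar_validation_error = function(e) {
      warn(conditionMessage(e))
      tibble(assay = character(), strategy = character(), rho = numeric(),
             p_value = numeric(), n = integer(), label = character())
    })
  list(levels = levels, precision = precision, qpcr_vs_ddpcr = qpcr_vs_ddpcr)
}

#' Attribute intra-assay variation using the two experiments' reports
#'
#' Joins the whole-procedure CVs of the centrifugation experiment (per
#' protocol) with the qPCR repeatability CVs of the precision experiment
#' and applies [attribute_preanalytical()] per assay x strategy.
#'
#' @param exp1_summary `summary` element of [run_experiment_1()].
#' @param exp4_precision `precision` element of [run_experiment_4()].
#' @return Tibble per assay x strategy with `cv_total`, `cv_rt_qpcr`,
#'   `fraction_preanalytical` and the integer-rounded `fraction_presented`.
#' @export
attribution_report <- function(exp1_summary, exp4_precision) {
  wide <- exp1_summary |>
    dplyr::select("assay", "strategy", "protocol", "cv") |>
    tidyr::pivot_wider(names_from = "protocol", values_from = "cv")
  rep_cv <- exp4_precision |>
    dplyr::filter(.data$platform == "qPCR") |>
    dplyr::select("assay", "strategy", "cv_intra")
  joined <- dplyr::inner_join(wide, rep_cv, by = c("assay", "strategy"))
  out <- attribute_preanalytical(joined$single, joined$dual, joined$cv_intra,
                                 assay = joined$assay,
                                 strategy = joined$strategy)
  out$fraction_presented <- round_half_up(out$fraction_preanalytical)
  out
}

#' Run the whole study and optionally write a report directory
#'
#' Executes all four experiment designs from one configuration and seed
#' (the same simulated patient cohort serves the material, platform and
#' agreement analyses, mirroring a single cohort measured on every
#' platform), and derives the preanalytical attribution table. With
#' `out_dir` set, writes each report as CSV plus a `summary.json` holding
#' the run manifest and headline numbers; outputs are byte-identical across
#' re-runs with the same config and seed.
#'
#' @inheritParams run_experiment_1
#' @param out_dir Optional output directory (created if needed).
#' @return (Invisibly, when writing) a list with `exp1`, `exp23`, `exp4`,
#'   `attribution` and `manifest`.
#' @export
run_study <- function(config, seed = config$seed, out_dir = NULL) {
  validate_config(config)
  cohort <- generate_patient_cohort(config, seed = seed)
  exp1 <- run_experiment_1(config, seed = seed)
  exp23 <- run_experiments_2_3(config, seed = seed, measurements = cohort)
  exp4 <- run_experiment_4(config, seed = seed, cohort = cohort)
  attribution <- attribution_report(exp1$summary, exp4$precision)
  manifest <- list(
    seed = seed,
    preset = "synthetic",
    stages = c("simulate", "normalize", "protocol_comparison",
               "order_of_draw", "material_agreement", "platform_agreement",
               "precision", "attribution"),
    n_tubes = config$n_tubes, n_patients = config$n_patients,
    n_runs = config$n_runs
  )
  result <- list(exp1 = exp1, exp23 = exp23, exp4 = exp4,
                 attribution = attribution, manifest = manifest)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(exp1$summary, file.path(out_dir, "table1_centrifugation.csv"))
    readr::write_csv(exp1$order_of_draw, file.path(out_dir, "order_of_draw.csv"))
    readr::write_csv(exp23$ppp_vs_standard, file.path(out_dir, "ppp_vs_standard.csv"))
    readr::write_csv(exp23$single_vs_tlda, file.path(out_dir, "single_vs_tlda.csv"))
    readr::write_csv(exp4$precision, file.path(out_dir, "table2_precision.csv"))
    readr::write_csv(exp4$qpcr_vs_ddpcr, file.path(out_dir, "qpcr_vs_ddpcr.csv"))
    readr::write_csv(attribution, file.path(out_dir, "attribution.csv"))
    summary_json <- list(
      manifest = manifest,
      attribution = stats::setNames(
        as.list(attribution$fraction_presented),
        paste(attribution$assay, attribution$strategy, sep = "|"))
    )
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(result))
  }
  result
}
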