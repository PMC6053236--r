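# Relative quantification: replicate averaging on the measurement scale,
# then reference normalization. qPCR/TLDA work on the Ct scale
# (level = 2^-deltaCt); ddPCR works on the concentration scale obtained from
# the Poisson occupancy model.

#' Reference assays used by each normalization strategy
#'
#' @param strategy `"spike"` (cel-miR-39), `"endogenous"` (miR-16) or
#'   `"combined"` (both).
#' @return Character vector of reference assay names.
#' @export
reference_assays <- function(strategy = c("spike", "endogenous", "combined")) {
  switch(match.arg(strategy),
         spike = "cel-miR-39",
         endogenous = "miR-16",
         combined = c("cel-miR-39", "miR-16"))
}

#' Average replicate wells of one sample
#'
#' Collapses PCR replicate wells to one readout per sample, assay, platform
#' and (run, RT replicate): qPCR/TLDA wells are averaged on the Ct scale,
#' ddPCR wells are first converted to concentrations via
#' [estimate_concentration()] and then averaged (set `pool_counts = TRUE` to
#' instead pool raw droplet counts across the wells before a single Poisson
#' inversion). Undetermined wells are excluded; a group in which every well
#' is undetermined is an error naming the sample and assay.
#'
#' @param measurements A measurement tibble (see [measurement_columns()]).
#' @param pool_counts Pool ddPCR droplet counts across wells instead of
#'   averaging per-well concentrations. Default `FALSE`.
#' @return A tibble with one row per group: the grouping metadata,
#'   `mean_ct` (qPCR/TLDA), `mean_conc` (ddPCR, copies/µL) and
#'   `n_wells_used`.
#' @export
aggregate_replicates <- function(measurements, pool_counts = FALSE) {
  keys <- c("experiment_id", "sample_id", "subject_id", "material",
            "protocol", "draw_order", "run_day", "rt_replicate",
            "platform", "assay")
  missing <- setdiff(c(keys, "pcr_replicate", "ct"), names(measurements))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
          class = "mirvar_schema_error")
  }
  qpcr <- dplyr::filter(measurements, .data$platform %in% c("qPCR", "TLDA"))
  dd <- dplyr::filter(measurements, .data$platform == "ddPCR")
  out <- list()
  if (nrow(qpcr) > 0) {
    agg <- qpcr |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(
        mean_ct = mean(.data$ct[!is.na(.data$ct)]),
        n_wells_used = sum(!is.na(.data$ct)),
        .groups = "drop"
      )
    dead <- dplyr::filter(agg, .data$n_wells_used == 0)
    if (nrow(dead) > 0) {
      abort(sprintf("all wells undetermined for sample '%s', assay '%s'",
                    dead$sample_id[1], dead$assay[1]),
            class = "mirvar_missing_level_error")
    }
    agg$mean_conc <- NA_real_
    out$qpcr <- agg
  }
  if (nrow(dd) > 0) {
    if (pool_counts) {
      agg <- dd |>
        dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
        dplyr::summarise(
          mean_conc = estimate_concentration(
            sum(.data$positives), sum(.data$total_droplets),
            .data$droplet_volume_nl[1])$copies_per_microlitre,
          n_wells_used = dplyr::n(),
          .groups = "drop"
        )
    } else {
      conc <- estimate_concentration(dd$positives, dd$total_droplets,
                                     dd$droplet_volume_nl)
      dd$.conc <- conc$copies_per_microlitre
      agg <- dd |>
        dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
        dplyr::summarise(
          mean_conc = mean(.data$.conc),
          n_wells_used = dplyr::n(),
          .groups = "drop"
        )
    }
    agg$mean_ct <- NA_real_
    out$dd <- agg
  }
  if (length(out) == 0) {
    abort("no measurements to aggregate", class = "mirvar_validation_error")
  }
  dplyr::bind_rows(out)
}

#' Estimate a ddPCR concentration from droplet counts
#'
#' Inverts the Poisson occupancy model: with `k` positive droplets out of
#' `n`, the mean copies per droplet is `lambda = -ln(1 - k/n)` and the
#' concentration is `lambda / droplet_volume` (volume in µL). A fully
#' positive well (`k = n`) is saturated: `lambda` is unbounded and the
#' conversion raises an error unless `allow_saturated = TRUE`, in which case
#' the row is flagged and its estimates are `NA`.
#'
#' @param positives Positive droplet count(s) `k`.
#' @param total_droplets Accepted droplet count(s) `n`.
#' @param droplet_volume_nl Droplet volume in nanolitres (default 0.85).
#' @param allow_saturated Return flagged `NA` rows for saturated wells
#'   instead of raising an error.
#' @return Tibble with `lambda` (copies/droplet), `copies_per_microlitre`
#'   and `saturated`.
#' @examples
#' estimate_concentration(10000, 20000)  # lambda = ln 2, ~815 copies/uL
#' @export
estimate_concentration <- function(positives, total_droplets,
                                   droplet_volume_nl = 0.85,
                                   allow_saturated = FALSE) {
  k <- positives
  n <- total_droplets
  if (any(is.na(k)) || any(is.na(n)) || any(k < 0) || any(n < 1) || any(k > n)) {
    abort("require 0 <= positives <= total_droplets with total_droplets >= 1",
          class = "mirvar_validation_error")
  }
  saturated <- k == n
  if (any(saturated) && !allow_saturated) {
    abort(sprintf(
      "saturated well (positives = total_droplets = %d): concentration not estimable",
      n[which(saturated)[1]]), class = "mirvar_saturation_error")
  }
  lambda <- ifelse(saturated, NA_real_, -log1p(-k / n))
  tibble(lambda = lambda,
         copies_per_microlitre = lambda / (droplet_volume_nl * 1e-3),
         saturated = saturated)
}

#' Normalize a qPCR Ct against reference Cts
#'
#' Computes `delta_ct = ct_target - r` and the relative level
#' `2^-delta_ct`, where `r` is the single reference Ct (spike or endogenous
#' strategy) or the arithmetic mean of the two reference Cts (combined
#' strategy). On the level scale the combined strategy is exactly the
#' geometric mean of the two single-reference levels.
#'
#' @param ct_target Ct of the target microRNA (vectorised).
#' @param ct_refs Reference Ct(s): a single value (or vector parallel to
#'   `ct_target`) for `"spike"`/`"endogenous"`; two values (or a
#'   two-column matrix) for `"combined"`.
#' @param strategy Normalization strategy.
#' @return Tibble with `strategy`, `delta_ct`, `level`.
#' @examples
#' normalize_qpcr(24, c(25, 27), "combined")  # r = 26, level = 4
#' @export
normalize_qpcr <- function(ct_target,
                           ct_refs,
                           strategy = c("spike", "endogenous", "combined")) {
  strategy <- match.arg(strategy)
  if (any(is.na(ct_target)) || any(is.na(unlist(ct_refs)))) {
    abort("all Ct values must be determined for normalization",
          class = "mirvar_validation_error")
  }
  if (strategy == "combined") {
    if (is.matrix(ct_refs)) {
      refs <- ct_refs
    } else {
      if (length(ct_refs) != 2) {
        abort("combined strategy requires two reference Cts",
              class = "mirvar_validation_error")
      }
      refs <- matrix(ct_refs, ncol = 2)
    }
    if (ncol(refs) != 2) {
      abort("combined strategy requires two reference Cts",
            class = "mirvar_validation_error")
    }
    r <- rowMeans(refs)
  } else {
    if (is.matrix(ct_refs) || (length(ct_refs) != 1 &&
                               length(ct_refs) != length(ct_target))) {
      abort(sprintf("strategy '%s' takes a single reference Ct per target",
                    strategy), class = "mirvar_validation_error")
    }
    r <- ct_refs
  }
  delta_ct <- ct_target - r
  tibble(strategy = strategy, delta_ct = delta_ct, level = 2^(-delta_ct))
}

#' Normalize a ddPCR concentration against reference concentrations
#'
#' The relative level is `conc_target / ref`, where `ref` is the single
#' reference concentration or, for the combined strategy, the geometric mean
#' `sqrt(c_spike * c_endo)` of the two references.
#'
#' @param conc_target Target concentration(s), copies/µL.
#' @param conc_refs Reference concentration(s); two values (or two-column
#'   matrix) for `"combined"`.
#' @param strategy Normalization strategy.
#' @return Tibble with `strategy`, `level`.
#' @export
normalize_ddpcr <- function(conc_target,
                            conc_refs,
                            strategy = c("spike", "endogenous", "combined")) {
  strategy <- match.arg(strategy)
  refs <- unlist(conc_refs)
  if (any(is.na(conc_target)) || any(is.na(refs)) || any(refs <= 0)) {
    abort("reference concentrations must be positive and unsaturated",
          class = "mirvar_validation_error")
  }
  if (strategy == "combined") {
    if (is.matrix(conc_refs)) {
      m <- conc_refs
    } else {
      if (length(conc_refs) != 2) {
        abort("combined strategy requires two reference concentrations",
              class = "mirvar_validation_error")
      }
      m <- matrix(conc_refs, ncol = 2)
    }
    if (ncol(m) != 2) {
      abort("combined strategy requires two reference concentrations",
            class = "mirvar_validation_error")
    }
    ref <- sqrt(m[, 1] * m[, 2])
  } else {
    if (is.matrix(conc_refs) || (length(conc_refs) != 1 &&
                                 length(conc_refs) != length(conc_target))) {
      abort(sprintf("strategy '%s' takes a single reference concentration",
                    strategy), class = "mirvar_validation_error")
    }
    ref <- conc_refs
  }
  tibble(strategy = strategy, level = conc_target / ref)
}

#' Normalize a full measurement table
#'
#' The table-level workhorse: averages replicate wells with
#' [aggregate_replicates()], then normalizes every target assay against the
#' strategy's reference assay(s) measured in the same sample, run and RT
#' replicate. Reference assays are never normalized against themselves:
#' under the endogenous and combined strategies miR-16 (and cel-miR-39) rows
#' produce no level.
#'
#' @inheritParams aggregate_replicates
#' @param strategy Normalization strategy, see [reference_assays()].
#' @return A tibble of normalized levels: sample metadata, `platform`,
#'   `assay`, `strategy`, `delta_ct` (`NA` for ddPCR), `level`,
#'   `n_wells_used`.
#' @examples
#' cfg <- synthetic_config(n_tubes = 4)
#' meas <- generate_centrifugation_experiment(cfg)
#' normalize_levels(meas, "spike")
#' @export
normalize_levels <- function(measurements,
                             strategy = c("spike", "endogenous", "combined"),
                             pool_counts = FALSE) {
  strategy <- match.arg(strategy)
  refs <- reference_assays(strategy)
  agg <- aggregate_replicates(measurements, pool_counts = pool_counts)
  keys <- c("experiment_id", "sample_id", "subject_id", "material",
            "protocol", "draw_order", "run_day", "rt_replicate", "platform")
  ref_tbl <- agg |>
    dplyr::filter(.data$assay %in% refs) |>
    dplyr::select(dplyr::all_of(keys), "assay", "mean_ct", "mean_conc") |>
    tidyr::pivot_wider(names_from = "assay",
                       values_from = c("mean_ct", "mean_conc"))
  # reference assays are never their own targets; the spike is only ever a
  # reference, so endogenous/combined strategies target miR-92a and miR-126
  excluded <- if (strategy == "spike") refs else union(refs, "cel-miR-39")
  targets <- dplyr::filter(agg, !.data$assay %in% excluded)
  if (nrow(targets) == 0) {
    abort("no target assays left after excluding the reference assay(s)",
          class = "mirvar_validation_error")
  }
  joined <- dplyr::left_join(targets, ref_tbl, by = keys)
  ct_ref_cols <- paste0("mean_ct_", refs)
  conc_ref_cols <- paste0("mean_conc_", refs)
  if (!all(c(ct_ref_cols, conc_ref_cols) %in% names(joined))) {
    abort(sprintf("reference assay(s) %s missing from the table",
                  paste(refs, collapse = ", ")),
          class = "mirvar_validation_error")
  }
  is_dd <- joined$platform == "ddPCR"
  ref_na <- if (length(refs) == 1) {
    ifelse(is_dd, is.na(joined[[conc_ref_cols]]), is.na(joined[[ct_ref_cols]]))
  } else {
    ifelse(is_dd,
           is.na(joined[[conc_ref_cols[1]]]) | is.na(joined[[conc_ref_cols[2]]]),
           is.na(joined[[ct_ref_cols[1]]]) | is.na(joined[[ct_ref_cols[2]]]))
  }
  if (any(ref_na)) {
    i <- which(ref_na)[1]
    abort(sprintf("no reference measurement for sample '%s' (%s, run %s)",
                  joined$sample_id[i], joined$platform[i], joined$run_day[i]),
          class = "mirvar_validation_error")
  }
  delta_ct <- rep(NA_real_, nrow(joined))
  level <- rep(NA_real_, nrow(joined))
  if (any(!is_dd)) {
    r <- if (length(refs) == 1) joined[[ct_ref_cols]][!is_dd] else
      (joined[[ct_ref_cols[1]]][!is_dd] + joined[[ct_ref_cols[2]]][!is_dd]) / 2
    delta_ct[!is_dd] <- joined$mean_ct[!is_dd] - r
    level[!is_dd] <- 2^(-delta_ct[!is_dd])
  }
  if (any(is_dd)) {
    ref <- if (length(refs) == 1) joined[[conc_ref_cols]][is_dd] else
      sqrt(joined[[conc_ref_cols[1]]][is_dd] * joined[[conc_ref_cols[2]]][is_dd])
    if (any(ref <= 0)) {
      abort("zero reference concentration: cannot normalize",
            class = "mirvar_validation_error")
    }
    level[is_dd] <- joined$mean_conc[is_dd] / ref
  }
  joined |>
    dplyr::mutate(strategy = strategy, delta_ct = delta_ct, level = level) |>
    dplyr::select(dplyr::all_of(keys), "assay", "strategy", "delta_ct",
                  "level", "n_wells_used")
}
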