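# Hierarchical forward model for the four study designs: noise is additive on
# the Ct (log2) scale, contamination terms are added to copy numbers in the
# linear domain before conversion back to Ct. This makes the CV of any
# normalized level exactly lognormal, so closed-form oracles exist for every
# variance configuration.

#' Configuration of the synthetic-data generator
#'
#' Collects every variance component, effect term and design size of the
#' hierarchical measurement model. All `sigma_*` components are standard
#' deviations in PCR cycles (one cycle = one doubling); setting every SD and
#' load to zero makes the generators deterministic functions of `mu_ct`.
#'
#' The default values are the shipped preset. Baseline Cts encode the
#' fold-structure among the assays (miR-16 about 8 cycles below miR-126,
#' 3–4 cycles below miR-92a; cel-miR-39 about 2 cycles below miR-126); the
#' variance components are calibrated so that whole-procedure and
#' repeatability CVs land in the few-percent to few-tens-of-percent range
#' typical of plasma microRNA work. The split between the run-level and
#' RT-level components is illustrative: only their combined effect is
#' identifiable from a duplicate design.
#'
#' @param mu_ct Named numeric, baseline Ct per assay in platelet-poor plasma.
#' @param sigma_day Between-run SD (cycles), drawn per assay and run.
#' @param sigma_prep Centrifugation + purification SD (cycles), drawn per
#'   assay within each plasma aliquot. Independent across assays: the
#'   recovery of each microRNA through the column varies individually, which
#'   is what keeps purification noise visible after reference normalization.
#' @param sigma_rt Reverse-transcription SD (cycles), per assay and RT
#'   reaction.
#' @param sigma_pcr Per-well SD (cycles).
#' @param sigma_extraction SD (cycles) of the overall extraction efficiency
#'   of an aliquot, shared by all assays including the spike; it cancels in
#'   every Delta-Ct, which is precisely what spike-in normalization buys.
#' @param sigma_spike_pipette SD (cycles) of the spike-dispensing error, per
#'   aliquot, applied to cel-miR-39 only.
#' @param sigma_preamp TLDA pre-amplification SD (cycles), per assay and
#'   card; the 14-cycle pre-amplification magnifies assay-specific
#'   efficiency differences, so this component is large.
#' @param platelet_load Named numeric, linear-domain copies (relative units)
#'   added per unit residual-platelet index in standard plasma.
#' @param hemolysis_load Linear-domain copies added to miR-16 per unit
#'   hemolysis index in standard plasma.
#' @param biological_sd SD of the true log2 level across subjects.
#' @param draw_trend Cycles added per tube position to endogenous assays in
#'   the centrifugation experiment (0 = no order-of-draw effect, the null).
#' @param n_tubes,n_patients,n_runs Design sizes (30 tubes, 50 patients,
#'   15 runs).
#' @param droplets_per_well Accepted droplets per ddPCR well.
#' @param droplet_volume_nl Droplet volume in nanolitres.
#' @param conc0 Named numeric, baseline ddPCR concentration (copies/µL) per
#'   assay, chosen so occupancies stay in the informative Poisson range.
#' @param seed Integer seed; all randomness in the generators flows from it.
#' @return A validated `mirvar_config` list.
#' @examples
#' cfg <- synthetic_config(n_tubes = 10, seed = 42)
#' cfg$sigma_prep
#' @export
synthetic_config <- function(mu_ct = c("miR-92a" = 17.7, "miR-126" = 23.0,
                                       "miR-16" = 14.3, "cel-miR-39" = 21.0),
                             sigma_day = 0.30,
                             sigma_prep = 0.15,
                             sigma_rt = 0.06,
                             sigma_pcr = 0.05,
                             sigma_extraction = 0.50,
                             sigma_spike_pipette = 0.20,
                             sigma_preamp = 3.0,
                             platelet_load = c("miR-92a" = 2, "miR-126" = 2,
                                               "miR-16" = 4, "cel-miR-39" = 0),
                             hemolysis_load = 1.0,
                             biological_sd = 0.8,
                             draw_trend = 0,
                             n_tubes = 30L,
                             n_patients = 50L,
                             n_runs = 15L,
                             droplets_per_well = 15000L,
                             droplet_volume_nl = 0.85,
                             conc0 = c("miR-92a" = 116, "miR-126" = 15.6,
                                       "miR-16" = 530, "cel-miR-39" = 20),
                             seed = 1L) {
  cfg <- structure(list(
    mu_ct = mu_ct, sigma_day = sigma_day, sigma_prep = sigma_prep,
    sigma_rt = sigma_rt, sigma_pcr = sigma_pcr,
    sigma_extraction = sigma_extraction,
    sigma_spike_pipette = sigma_spike_pipette, sigma_preamp = sigma_preamp,
    platelet_load = platelet_load, hemolysis_load = hemolysis_load,
    biological_sd = biological_sd, draw_trend = draw_trend,
    n_tubes = as.integer(n_tubes), n_patients = as.integer(n_patients),
    n_runs = as.integer(n_runs),
    droplets_per_well = as.integer(droplets_per_well),
    droplet_volume_nl = droplet_volume_nl, conc0 = conc0,
    seed = as.integer(seed)
  ), class = "mirvar_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  assays <- mirvar_assays()
  if (!all(assays %in% names(cfg$mu_ct))) {
    abort("'mu_ct' must name every assay", class = "mirvar_validation_error")
  }
  if (!all(assays %in% names(cfg$platelet_load))) {
    abort("'platelet_load' must name every assay",
          class = "mirvar_validation_error")
  }
  if (!all(assays %in% names(cfg$conc0)) || any(cfg$conc0 <= 0)) {
    abort("'conc0' must name every assay with positive concentrations",
          class = "mirvar_validation_error")
  }
  sds <- c(cfg$sigma_day, cfg$sigma_prep, cfg$sigma_rt, cfg$sigma_pcr,
           cfg$sigma_extraction, cfg$sigma_spike_pipette, cfg$sigma_preamp,
           cfg$biological_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    abort("all SD components must be finite and >= 0",
          class = "mirvar_validation_error")
  }
  if (any(cfg$platelet_load < 0) || cfg$hemolysis_load < 0) {
    abort("contamination loads must be >= 0", class = "mirvar_validation_error")
  }
  if (cfg$n_tubes < 2 || cfg$n_patients < 1 || cfg$n_runs < 1 ||
      cfg$droplets_per_well < 1) {
    abort("design sizes must be positive (n_tubes >= 2)",
          class = "mirvar_validation_error")
  }
  invisible(cfg)
}

# TRUE when the generator output is a deterministic function of mu_ct.
config_is_noise_free <- function(cfg) {
  all(c(cfg$sigma_day, cfg$sigma_prep, cfg$sigma_rt, cfg$sigma_pcr,
        cfg$sigma_extraction, cfg$sigma_spike_pipette, cfg$sigma_preamp,
        cfg$biological_sd, cfg$platelet_load, cfg$hemolysis_load,
        cfg$draw_trend) == 0)
}

#' Read or write a generator configuration
#'
#' Configurations are serialised as YAML mappings mirroring the
#' [synthetic_config()] field names.
#'
#' @param path File path.
#' @param cfg A `mirvar_config` object.
#' @return `read_config()` returns a `mirvar_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  for (f in c("mu_ct", "platelet_load", "conc0")) {
    if (!is.null(vals[[f]])) vals[[f]] <- unlist(vals[[f]])
  }
  do.call(synthetic_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(lapply(unclass(cfg), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  }), path)
  invisible(path)
}

# Shared row scaffold ---------------------------------------------------------

empty_meas <- function(n) {
  tibble(
    experiment_id = character(n), sample_id = character(n),
    subject_id = character(n), material = character(n),
    protocol = character(n), draw_order = NA_integer_,
    run_day = NA_integer_, rt_replicate = NA_integer_,
    pcr_replicate = NA_integer_, platform = character(n),
    assay = character(n), ct = NA_real_, positives = NA_integer_,
    total_droplets = NA_integer_, droplet_volume_nl = NA_real_
  )
}

#' Simulate droplet counts for a ddPCR well
#'
#' Forward model of droplet partitioning: a well holding `concentration`
#' copies/µL in droplets of `droplet_volume_nl` nanolitres has mean occupancy
#' `lambda = concentration * volume(µL)` copies per droplet, and each of the
#' `n_droplets` droplets is positive independently with probability
#' `1 - exp(-lambda)`, so the positive count is binomial. With `sampling =
#' FALSE` the count is fixed at its rounded expectation (used for strict
#' determinism checks of zero-variance configurations).
#'
#' @param concentration Copies per microlitre (vectorised), must be >= 0.
#' @param n_droplets Accepted droplets per well.
#' @param droplet_volume_nl Droplet volume in nanolitres.
#' @param sampling Draw binomial counts (default) or return the expectation.
#' @return A tibble with `positives`, `total_droplets`, `droplet_volume_nl`.
#' @examples
#' withr::with_seed(1, generate_droplets(800, 20000))
#' @export
generate_droplets <- function(concentration, n_droplets = 15000L,
                              droplet_volume_nl = 0.85, sampling = TRUE) {
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    abort("'concentration' must be finite and >= 0",
          class = "mirvar_validation_error")
  }
  lambda <- concentration * droplet_volume_nl * 1e-3
  p_pos <- -expm1(-lambda)
  k <- if (sampling) {
    rbinom(length(p_pos), size = n_droplets, prob = p_pos)
  } else {
    as.integer(round(n_droplets * p_pos))
  }
  tibble(positives = as.integer(k),
         total_droplets = as.integer(n_droplets),
         droplet_volume_nl = droplet_volume_nl)
}

# Experiment generators -------------------------------------------------------

#' Simulate the centrifugation-protocol experiment
#'
#' Thirty blood tubes drawn consecutively from one volunteer; odd draw
#' positions are processed by dual centrifugation, even positions by
#' prolonged single centrifugation. Each tube yields one plasma aliquot,
#' purified once and measured by qPCR in duplicate wells for all four
#' assays. The well model is
#' `ct = mu_ct[assay] - e + prep + rt + eps`, where the extraction
#' efficiency `e` is shared by all assays of the aliquot, `prep` and `rt`
#' are per-assay purification and reverse-transcription effects, `eps` is
#' well noise, and cel-miR-39 additionally receives the spike-dispensing
#' term.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return A measurement tibble (see [measurement_columns()]).
#' @export
generate_centrifugation_experiment <- function(config, seed = config$seed) {
  validate_config(config)
  withr::with_seed(seed, {
    assays <- mirvar_assays()
    n <- config$n_tubes
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      protocol <- if (i %% 2 == 1) "dual" else "single"
      e <- rnorm(1, 0, config$sigma_extraction)
      spike_pip <- rnorm(1, 0, config$sigma_spike_pipette)
      prep <- rnorm(length(assays), 0, config$sigma_prep)
      rt <- rnorm(length(assays), 0, config$sigma_rt)
      eps <- matrix(rnorm(2 * length(assays), 0, config$sigma_pcr),
                    nrow = length(assays))
      trend <- config$draw_trend * (i - (n + 1) / 2)
      ct <- unname(config$mu_ct[assays] - e + prep + rt +
        ifelse(assays == "cel-miR-39", spike_pip, trend))
      tube <- empty_meas(2 * length(assays))
      tube$experiment_id <- "centrifugation"
      tube$sample_id <- sprintf("tube%02d", i)
      tube$subject_id <- "volunteer1"
      tube$material <- "PPP"
      tube$protocol <- protocol
      tube$draw_order <- i
      tube$run_day <- 1L
      tube$rt_replicate <- 1L
      tube$pcr_replicate <- rep(1:2, each = length(assays))
      tube$platform <- "qPCR"
      tube$assay <- rep(assays, 2)
      tube$ct <- c(ct + eps[, 1], ct + eps[, 2])
      rows[[i]] <- tube
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate the two-material patient cohort
#'
#' Fifty subjects, each with a true per-assay log2 level drawn with SD
#' `biological_sd`, measured in platelet-poor plasma (PPP) and standard
#' plasma by qPCR, plus TLDA and ddPCR measurements of the PPP aliquot.
#' Standard plasma receives a linear-domain platelet contamination term
#' `c_s * platelet_load[assay]` with a per-subject residual-platelet index
#' `c_s > 0`, and miR-16 an additional hemolysis term, so the PPP vs
#' standard-plasma agreement degrades as the loads grow. TLDA wells add a
#' per-assay, per-card pre-amplification effect with SD `sigma_preamp`;
#' ddPCR wells share the qPCR aliquot's RT products and derive droplet
#' counts via [generate_droplets()].
#'
#' @inheritParams generate_centrifugation_experiment
#' @return A measurement tibble.
#' @export
generate_patient_cohort <- function(config, seed = config$seed) {
  validate_config(config)
  withr::with_seed(seed, {
    assays <- mirvar_assays()
    endo <- setdiff(assays, "cel-miR-39")
    tlda_assays <- c("miR-92a", "miR-16", "cel-miR-39")
    sampling <- !config_is_noise_free(config)
    rows <- list()
    for (s in seq_len(config$n_patients)) {
      subject <- sprintf("pt%02d", s)
      b <- stats::setNames(c(rnorm(length(endo), 0, config$biological_sd), 0),
                           c(endo, "cel-miR-39"))
      c_s <- rlnorm(1, 0, 0.5)                 # residual-platelet index
      h_s <- rlnorm(1, -1.2, 0.8)              # hemolysis index
      for (mat in c("PPP", "standard_plasma")) {
        lvl <- 2^b[assays]
        if (mat == "standard_plasma") {
          lvl <- lvl + c_s * config$platelet_load[assays]
          lvl["miR-16"] <- lvl["miR-16"] + h_s * config$hemolysis_load
        }
        # one purified aliquot per subject x material
        e <- rnorm(1, 0, config$sigma_extraction)
        spike_pip <- rnorm(1, 0, config$sigma_spike_pipette)
        prep <- stats::setNames(rnorm(length(assays), 0, config$sigma_prep), assays)
        rt <- stats::setNames(rnorm(length(assays), 0, config$sigma_rt), assays)
        tech <- -e + prep + rt + ifelse(assays == "cel-miR-39", spike_pip, 0)
        names(tech) <- assays
        ct0 <- config$mu_ct[assays] - log2(lvl) + tech

        qp <- empty_meas(2 * length(assays))
        qp$experiment_id <- "cohort"
        qp$sample_id <- paste0(subject, "_", mat)
        qp$subject_id <- subject
        qp$material <- mat
        qp$protocol <- "none"
        qp$run_day <- 1L
        qp$rt_replicate <- 1L
        qp$pcr_replicate <- rep(1:2, each = length(assays))
        qp$platform <- "qPCR"
        qp$assay <- rep(assays, 2)
        qp$ct <- unname(ct0[qp$assay]) + rnorm(nrow(qp), 0, config$sigma_pcr)
        rows[[length(rows) + 1]] <- qp

        if (mat == "PPP") {
          # TLDA: separate RT of the same purified microRNA, one card per
          # sample, triplicate wells, pre-amplification effect per assay/card.
          rt_t <- stats::setNames(rnorm(length(tlda_assays), 0, config$sigma_rt),
                                  tlda_assays)
          preamp <- stats::setNames(rnorm(length(tlda_assays), 0, config$sigma_preamp),
                                    tlda_assays)
          ct_t <- config$mu_ct[tlda_assays] - log2(lvl[tlda_assays]) -
            e + prep[tlda_assays] + rt_t + preamp +
            ifelse(tlda_assays == "cel-miR-39", spike_pip, 0)
          tl <- empty_meas(3 * length(tlda_assays))
          tl$experiment_id <- "cohort"
          tl$sample_id <- paste0(subject, "_", mat)
          tl$subject_id <- subject
          tl$material <- mat
          tl$protocol <- "none"
          tl$run_day <- 1L
          tl$rt_replicate <- 1L
          tl$pcr_replicate <- rep(1:3, each = length(tlda_assays))
          tl$platform <- "TLDA"
          tl$assay <- rep(tlda_assays, 3)
          tl$ct <- unname(ct_t[tl$assay]) + rnorm(nrow(tl), 0, config$sigma_pcr)
          rows[[length(rows) + 1]] <- tl

          # ddPCR: same cDNA as the single assays, duplicate wells.
          dd <- empty_meas(2 * length(assays))
          dd$experiment_id <- "cohort"
          dd$sample_id <- paste0(subject, "_", mat)
          dd$subject_id <- subject
          dd$material <- mat
          dd$protocol <- "none"
          dd$run_day <- 1L
          dd$rt_replicate <- 1L
          dd$pcr_replicate <- rep(1:2, each = length(assays))
          dd$platform <- "ddPCR"
          dd$assay <- rep(assays, 2)
          conc <- config$conc0[dd$assay] *
            2^(-(tech[dd$assay] - log2(lvl[dd$assay])) ) *
            2^rnorm(nrow(dd), 0, config$sigma_pcr)
          drp <- generate_droplets(conc, config$droplets_per_well,
                                   config$droplet_volume_nl, sampling = sampling)
          dd$positives <- drp$positives
          dd$total_droplets <- drp$total_droplets
          dd$droplet_volume_nl <- drp$droplet_volume_nl
          rows[[length(rows) + 1]] <- dd
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate the pooled-sample precision experiment
#'
#' One pooled microRNA aliquot measured in `n_runs` independent runs on
#' different days; in each run the pool is reverse transcribed in duplicate
#' and each cDNA is measured in duplicate wells per assay, on qPCR, ddPCR or
#' both. The run effect (SD `sigma_day`, per assay) is shared by everything
#' within a run; the RT effect (SD `sigma_rt`, per assay) is nested within
#' run and shared between platforms, mirroring a design where the same cDNA
#' feeds both instruments.
#'
#' @inheritParams generate_centrifugation_experiment
#' @param platform `"both"` (default), `"qPCR"` or `"ddPCR"`.
#' @param n_runs Number of independent runs; defaults to `config$n_runs`.
#' @return A measurement tibble.
#' @export
generate_precision_experiment <- function(config,
                                          platform = c("both", "qPCR", "ddPCR"),
                                          seed = config$seed,
                                          n_runs = config$n_runs) {
  platform <- match.arg(platform)
  validate_config(config)
  withr::with_seed(seed, {
    assays <- mirvar_assays()
    sampling <- !config_is_noise_free(config)
    rows <- list()
    for (r in seq_len(n_runs)) {
      day <- stats::setNames(rnorm(length(assays), 0, config$sigma_day), assays)
      for (t in 1:2) {
        rt <- stats::setNames(rnorm(length(assays), 0, config$sigma_rt), assays)
        base_ct <- config$mu_ct[assays] + day + rt
        if (platform %in% c("both", "qPCR")) {
          qp <- empty_meas(2 * length(assays))
          qp$experiment_id <- "precision"
          qp$sample_id <- "pool"
          qp$subject_id <- "pool"
          qp$material <- "pool"
          qp$protocol <- "none"
          qp$run_day <- r
          qp$rt_replicate <- t
          qp$pcr_replicate <- rep(1:2, each = length(assays))
          qp$platform <- "qPCR"
          qp$assay <- rep(assays, 2)
          qp$ct <- unname(base_ct[qp$assay]) + rnorm(nrow(qp), 0, config$sigma_pcr)
          rows[[length(rows) + 1]] <- qp
        }
        if (platform %in% c("both", "ddPCR")) {
          dd <- empty_meas(2 * length(assays))
          dd$experiment_id <- "precision"
          dd$sample_id <- "pool"
          dd$subject_id <- "pool"
          dd$material <- "pool"
          dd$protocol <- "none"
          dd$run_day <- r
          dd$rt_replicate <- t
          dd$pcr_replicate <- rep(1:2, each = length(assays))
          dd$platform <- "ddPCR"
          dd$assay <- rep(assays, 2)
          conc <- config$conc0[dd$assay] *
            2^(-(base_ct[dd$assay] - config$mu_ct[dd$assay])) *
            2^rnorm(nrow(dd), 0, config$sigma_pcr)
          drp <- generate_droplets(conc, config$droplets_per_well,
                                   config$droplet_volume_nl, sampling = sampling)
          dd$positives <- drp$positives
          dd$total_droplets <- drp$total_droplets
          dd$droplet_volume_nl <- drp$droplet_volume_nl
          rows[[length(rows) + 1]] <- dd
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
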