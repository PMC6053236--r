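# Hierarchical generator: determinism, design arithmetic, closed-form CV
# recovery, droplet forward model.

test_that("zero-variance configs are deterministic fixed points of mu_ct", {
  cfg <- config_zero(n_tubes = 6, n_patients = 3, n_runs = 3)
  cents <- generate_centrifugation_experiment(cfg)
  expect_equal(cents$ct, unname(cfg$mu_ct[cents$assay]))
  prec <- generate_precision_experiment(cfg, platform = "both")
  qp <- prec[prec$platform == "qPCR", ]
  expect_equal(qp$ct, unname(cfg$mu_ct[qp$assay]))
  dd <- prec[prec$platform == "ddPCR", ]
  # droplet occupancy fixed at its expectation per assay
  expect_equal(unique(tapply(dd$positives, dd$assay, function(x)
    length(unique(x)))), 1L, ignore_attr = TRUE)
  coh <- generate_patient_cohort(cfg)
  qp_coh <- coh[coh$platform == "qPCR", ]
  expect_equal(qp_coh$ct, unname(cfg$mu_ct[qp_coh$assay]))
})

test_that("generation is reproducible from the seed alone", {
  cfg <- synthetic_config(n_tubes = 8, n_patients = 4, n_runs = 3, seed = 5)
  expect_identical(generate_centrifugation_experiment(cfg),
                   generate_centrifugation_experiment(cfg))
  expect_identical(generate_patient_cohort(cfg),
                   generate_patient_cohort(cfg))
  expect_identical(generate_precision_experiment(cfg),
                   generate_precision_experiment(cfg))
  expect_false(identical(
    generate_centrifugation_experiment(cfg, seed = 6),
    generate_centrifugation_experiment(cfg, seed = 7)))
})

test_that("design arithmetic matches the study layout", {
  cfg <- synthetic_config()
  cents <- generate_centrifugation_experiment(cfg)
  expect_equal(length(unique(cents$sample_id)), 30)
  odd <- cents$draw_order %% 2 == 1
  expect_true(all(cents$protocol[odd] == "dual"))
  expect_true(all(cents$protocol[!odd] == "single"))
  expect_equal(nrow(cents), 30 * 4 * 2)

  prec <- generate_precision_experiment(cfg, platform = "both")
  per <- dplyr::count(prec, platform, assay)
  expect_true(all(per$n == 15 * 2 * 2))

  coh <- generate_patient_cohort(cfg)
  expect_equal(length(unique(coh$subject_id)), 50)
  expect_setequal(unique(coh$material), c("PPP", "standard_plasma"))
  expect_setequal(unique(coh$platform), c("qPCR", "TLDA", "ddPCR"))
})

test_that("configurations survive a YAML round trip and reject bad values", {
  cfg <- synthetic_config(sigma_day = 0.42, n_tubes = 12, seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back, cfg)
  expect_error(synthetic_config(sigma_prep = -0.1),
               class = "mirvar_validation_error")
  expect_error(synthetic_config(mu_ct = c("miR-92a" = 20)),
               class = "mirvar_validation_error")
})

test_that("droplet forward model follows binomial occupancy", {
  expect_equal(withr::with_seed(1, generate_droplets(0, 20000))$positives, 0L)
  # lambda = ln 2 -> expected half the droplets positive
  conc <- log(2) / 0.00085
  k <- withr::with_seed(2, generate_droplets(conc, 20000))$positives
  expect_lt(abs(k - 10000), 5 * sqrt(20000 * 0.5 * 0.5))
  # saturating occupancy
  k_sat <- withr::with_seed(3, generate_droplets(20 / 0.00085, 20000))$positives
  expect_equal(k_sat, 20000L)
  expect_error(generate_droplets(-1, 100), class = "mirvar_validation_error")
})

test_that("per-protocol CV of spike-normalized levels matches the lognormal closed form", {
  cfg <- synthetic_config(sigma_day = 0, sigma_prep = 0.25, sigma_rt = 0,
                          sigma_pcr = 0.05, sigma_extraction = 0.5,
                          sigma_spike_pipette = 0, n_tubes = 2000, seed = 31)
  lv <- normalize_levels(generate_centrifugation_experiment(cfg), "spike")
  # delta-Ct variance: prep enters for target and spike, well noise averaged
  # over duplicate wells on both sides
  sigma_tot <- sqrt(2 * 0.25^2 + 2 * 0.05^2 / 2)
  expected <- lognormal_cv(sigma_tot)
  for (p in c("dual", "single")) {
    for (a in unique(lv$assay)) {
      observed <- cv(lv$level[lv$protocol == p & lv$assay == a])
      expect_lt(abs(observed - expected) / expected, 0.10)
    }
  }
})

test_that("dominant variance components are ordered correctly by the estimators", {
  base <- list(sigma_prep = 0, sigma_extraction = 0, sigma_spike_pipette = 0)
  cfg_day <- do.call(synthetic_config, c(base, list(
    sigma_day = 0.5, sigma_rt = 0.02, sigma_pcr = 0.02, n_runs = 40, seed = 8)))
  cfg_rt <- do.call(synthetic_config, c(base, list(
    sigma_day = 0.02, sigma_rt = 0.5, sigma_pcr = 0.02, n_runs = 40, seed = 8)))
  prec_day <- precision_from_duplicates(normalize_levels(
    generate_precision_experiment(cfg_day, platform = "qPCR"), "spike"))
  prec_rt <- precision_from_duplicates(normalize_levels(
    generate_precision_experiment(cfg_rt, platform = "qPCR"), "spike"))
  # day-driven noise shows up in precision but not repeatability
  expect_true(all(prec_day$cv_inter > 2 * prec_day$cv_intra))
  # RT-driven noise inflates repeatability toward precision
  expect_true(all(prec_rt$cv_intra > 0.5 * prec_rt$cv_inter))
  expect_true(mean(prec_rt$cv_intra) > 3 * mean(prec_day$cv_intra))
})

test_that("patient cohort degrades PPP vs standard-plasma agreement with platelet load", {
  cfg0 <- synthetic_config(platelet_load = c("miR-92a" = 0, "miR-126" = 0,
                                             "miR-16" = 0, "cel-miR-39" = 0),
                           hemolysis_load = 0, sigma_day = 0, sigma_prep = 0,
                           sigma_rt = 0, sigma_pcr = 0, sigma_extraction = 0,
                           sigma_spike_pipette = 0, n_patients = 20, seed = 3)
  lv0 <- normalize_levels(generate_patient_cohort(cfg0), "spike")
  lv0 <- lv0[lv0$platform == "qPCR", ]
  co0 <- correlate(lv0[lv0$material == "PPP", ],
                   lv0[lv0$material == "standard_plasma", ])
  expect_equal(co0$rho, rep(1, nrow(co0)))

  # platelet contamination large relative to biological spread
  rhos <- vapply(1:50, function(s) {
    cfg <- synthetic_config(platelet_load = c("miR-92a" = 4, "miR-126" = 4,
                                              "miR-16" = 8, "cel-miR-39" = 0),
                            n_patients = 50, seed = 100 + s)
    lv <- normalize_levels(generate_patient_cohort(cfg), "spike")
    lv <- lv[lv$platform == "qPCR", ]
    out <- correlate(lv[lv$material == "PPP", ],
                     lv[lv$material == "standard_plasma", ])
    mean(out$rho)
  }, numeric(1))
  expect_lt(mean(rhos), 0.3)
})
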