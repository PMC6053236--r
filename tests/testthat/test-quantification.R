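# Replicate averaging, delta-Ct normalization and Poisson concentration
# estimation.

well_row <- function(ct, pcr_replicate) {
  tibble::tibble(
    experiment_id = "e1", sample_id = "s1", subject_id = "x",
    material = "PPP", protocol = "dual", draw_order = 1L, run_day = 1L,
    rt_replicate = 1L, pcr_replicate = pcr_replicate, platform = "qPCR",
    assay = "miR-92a", ct = ct, positives = NA_integer_,
    total_droplets = NA_integer_, droplet_volume_nl = NA_real_
  )
}

test_that("replicate wells average on the Ct scale, excluding undetermined", {
  agg <- aggregate_replicates(well_row(c(24.0, 24.2), 1:2))
  expect_equal(agg$mean_ct, 24.1)
  expect_equal(agg$n_wells_used, 2L)

  agg1 <- aggregate_replicates(well_row(c(24.0, NA), 1:2))
  expect_equal(agg1$mean_ct, 24.0)
  expect_equal(agg1$n_wells_used, 1L)

  expect_error(aggregate_replicates(well_row(c(NA_real_, NA_real_), 1:2)),
               "s1", class = "mirvar_missing_level_error")
})

test_that("qPCR normalization reproduces the delta-Ct identities", {
  expect_equal(normalize_qpcr(25, 25, "spike")$level, 1.0)

  # 8-cycle separation between two targets is a 256-fold level ratio
  lv_high <- normalize_qpcr(17, 25, "spike")$level
  lv_low <- normalize_qpcr(25, 25, "spike")$level
  expect_equal(lv_high / lv_low, 256)

  comb <- normalize_qpcr(24, c(25, 27), "combined")
  expect_equal(comb$delta_ct, -2)
  expect_equal(comb$level, 4.0)
  expect_equal(comb$level, sqrt(2 * 8))  # geometric mean of single levels

  expect_error(normalize_qpcr(24, 25, "combined"), "two reference",
               class = "mirvar_validation_error")
  expect_error(normalize_qpcr(24, c(25, 27), "spike"),
               class = "mirvar_validation_error")
  expect_error(normalize_qpcr(NA_real_, 25, "spike"),
               class = "mirvar_validation_error")
})

test_that("combined qPCR normalization equals the geometric mean of single-reference levels", {
  withr::with_seed(42, {
    for (i in 1:100) {
      cts <- runif(3, 15, 35)
      comb <- normalize_qpcr(cts[1], matrix(cts[2:3], ncol = 2), "combined")$level
      g <- sqrt(normalize_qpcr(cts[1], cts[2], "spike")$level *
                  normalize_qpcr(cts[1], cts[3], "endogenous")$level)
      expect_equal(comb, g)
    }
  })
})

test_that("levels are invariant to a constant Ct shift", {
  withr::with_seed(9, {
    for (i in 1:25) {
      cts <- runif(3, 15, 35)
      shift <- runif(1, -5, 5)
      expect_equal(
        normalize_qpcr(cts[1] + shift, matrix(cts[2:3] + shift, ncol = 2),
                       "combined")$level,
        normalize_qpcr(cts[1], matrix(cts[2:3], ncol = 2), "combined")$level)
    }
  })
})

test_that("Poisson occupancy inversion matches hand-computed values", {
  z <- estimate_concentration(0, 20000)
  expect_equal(z$lambda, 0)
  expect_equal(z$copies_per_microlitre, 0)

  one <- estimate_concentration(round(20000 * (1 - exp(-1))), 20000)
  expect_equal(one$lambda, 1, tolerance = 1e-3)

  half <- estimate_concentration(10000, 20000, droplet_volume_nl = 0.85)
  expect_equal(half$lambda, log(2))
  expect_equal(half$copies_per_microlitre, -log(0.5) / 0.00085)
  expect_equal(half$copies_per_microlitre, 815.467, tolerance = 1e-3)

  expect_error(estimate_concentration(20000, 20000),
               class = "mirvar_saturation_error")
  sat <- estimate_concentration(20000, 20000, allow_saturated = TRUE)
  expect_true(sat$saturated)
  expect_true(is.na(sat$copies_per_microlitre))
  expect_error(estimate_concentration(200, 100),
               class = "mirvar_validation_error")
})

test_that("the concentration estimate is strictly increasing in positives", {
  k <- 0:19999
  conc <- estimate_concentration(k, 20000)$copies_per_microlitre
  expect_true(all(diff(conc) > 0))
})

test_that("ddPCR normalization uses the geometric-mean reference", {
  expect_equal(normalize_ddpcr(100, 100, "spike")$level, 1.0)
  expect_equal(normalize_ddpcr(80, c(40, 90), "combined")$level, 80 / 60)
  withr::with_seed(12, {
    for (i in 1:100) {
      c3 <- runif(3, 1, 1000)
      comb <- normalize_ddpcr(c3[1], matrix(c3[2:3], ncol = 2), "combined")$level
      g <- sqrt(normalize_ddpcr(c3[1], c3[2], "spike")$level *
                  normalize_ddpcr(c3[1], c3[3], "endogenous")$level)
      expect_equal(comb, g)
    }
  })
  expect_error(normalize_ddpcr(10, 0, "spike"),
               class = "mirvar_validation_error")
})

test_that("reference assays are excluded from their own normalization", {
  cfg <- synthetic_config(n_tubes = 4)
  meas <- generate_centrifugation_experiment(cfg)
  spike <- normalize_levels(meas, "spike")
  expect_setequal(unique(spike$assay), c("miR-92a", "miR-126", "miR-16"))
  endo <- normalize_levels(meas, "endogenous")
  expect_setequal(unique(endo$assay), c("miR-92a", "miR-126"))
  comb <- normalize_levels(meas, "combined")
  expect_setequal(unique(comb$assay), c("miR-92a", "miR-126"))
  # qPCR level is exactly 2^-delta_ct
  expect_equal(spike$level, 2^(-spike$delta_ct))
})
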