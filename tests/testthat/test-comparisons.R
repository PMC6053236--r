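# Protocol/order tests, rank correlation, paired sample size.

test_that("protocol comparison reproduces the two-sample t closed form", {
  # identical groups carry no evidence
  lv0 <- levels_from_tubes(rep(3.5, 10))
  t0 <- compare_protocols(lv0)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)

  lv_sep <- levels_from_tubes(c(1, 101, 2, 102, 3, 103),
                              protocol = rep(c("dual", "single"), 3))
  expect_lt(compare_protocols(lv_sep)$p_value, 0.001)

  # 4 + 4 fixed dataset against the pooled-variance formula
  x <- c(9.1, 10.2, 8.7, 9.8)   # dual
  y <- c(10.9, 11.4, 10.1, 12.0) # single
  lv <- levels_from_tubes(as.numeric(rbind(x, y)),
                          protocol = rep(c("dual", "single"), 4))
  res <- compare_protocols(lv)
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * pt(-abs(t_hand), df = 6)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$p_value, p_hand)
  expect_equal(res$test_kind, "student_t_two_sample")

  expect_error(compare_protocols(levels_from_tubes(c(1, 2),
                                                   protocol = c("dual", "single"))),
               class = "mirvar_validation_error")
})

test_that("paired mode pairs adjacent tubes in order of draw", {
  x <- c(9.1, 10.2, 8.7, 9.8)
  y <- c(10.9, 11.4, 10.1, 12.0)
  lv <- levels_from_tubes(as.numeric(rbind(x, y)),
                          protocol = rep(c("dual", "single"), 4))
  res <- compare_protocols(lv, pairing = "paired_by_adjacent_tube")
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(res$statistic, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)
  expect_equal(res$test_kind, "student_t_paired")
})

test_that("protocol-test p-values are uniform under a true null", {
  set.seed(77)
  pvals <- replicate(500, {
    compare_protocols(levels_from_tubes(rlnorm(30, 0, 0.2)))$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("order-of-draw p-values are calibrated under the null and detect trends", {
  set.seed(61)
  pvals <- replicate(200, {
    lv <- levels_from_tubes(rlnorm(30, 0, 0.3))
    order_of_draw_test(lv)$p_value
  })
  expect_lt(abs(mean(pvals) - 0.5), 0.07)

  trended <- levels_from_tubes(seq(1, 4, length.out = 30) +
                                 rnorm(30, 0, 0.05))
  expect_lt(order_of_draw_test(trended)$p_value, 0.01)

  expect_error(order_of_draw_test(levels_from_tubes(rep(2, 30))),
               "constant", class = "mirvar_validation_error")
  lv_na <- levels_from_tubes(rlnorm(30))
  lv_na$draw_order <- NA_integer_
  expect_error(order_of_draw_test(lv_na), class = "mirvar_validation_error")
})

test_that("rank correlation is exact on monotone maps and invariant to them", {
  expect_equal(correlate(1:8, exp(1:8))$rho, 1)
  expect_equal(correlate(1:8, rev(1:8))$rho, -1)
  withr::with_seed(14, {
    x <- rlnorm(20); y <- x + rnorm(20, 0, 0.5)
    base <- correlate(x, y)
    mono <- correlate(log(x), y^3)
    expect_equal(mono$rho, base$rho)
    expect_equal(mono$p_value, base$p_value)
  })
  expect_error(correlate(1:4, 4:1), class = "mirvar_validation_error")
  expect_error(correlate(rep(1, 6), 1:6), class = "mirvar_validation_error")
})

test_that("small-sample Spearman p matches exhaustive permutation at n = 6", {
  cases <- list(
    list(x = c(3, 1, 4, 1.5, 9, 2.6), y = c(2, 7, 1, 8, 2.8, 1.8)),
    list(x = 1:6, y = c(2, 1, 4, 3, 6, 5)),
    list(x = c(10, 20, 5, 40, 2, 7), y = c(1.2, 0.3, 2.2, 0.1, 5, 3))
  )
  perms <- all_perms(1:6)
  for (cs in cases) {
    obs <- correlate(cs$x, cs$y)
    rhos <- vapply(perms, function(p) cor(cs$x, cs$y[p], method = "spearman"),
                   numeric(1))
    p_enum <- mean(abs(rhos) >= abs(obs$rho) - 1e-12)
    expect_lt(abs(obs$p_value - p_enum), 0.01)
  }
})

test_that("correlation labels follow the presentation thresholds", {
  expect_equal(correlate(1:8, exp(1:8))$label, "good")
  withr::with_seed(2, {
    x <- rnorm(200); y <- rnorm(200)
    expect_equal(correlate(x, y)$label, "none")
  })
})

test_that("paired sample size solves the iterative t fixed point", {
  expect_equal(paired_sample_size(), 12L)

  # monotone in the design quantities
  expect_lte(paired_sample_size(relative_difference = 0.2),
             paired_sample_size(relative_difference = 0.1))
  expect_lte(paired_sample_size(pair_correlation = 0.95),
             paired_sample_size(pair_correlation = 0.85))
  expect_gte(paired_sample_size(relative_sd = 0.4),
             paired_sample_size(relative_sd = 0.2))

  # large effects floor at a handful of pairs
  big <- paired_sample_size(relative_difference = 1.0, relative_sd = 0.2,
                            pair_correlation = 0.5)  # d = 5
  expect_lte(big, 3L)
  expect_gte(big, 2L)

  expect_error(paired_sample_size(pair_correlation = 1),
               class = "mirvar_validation_error")
  expect_error(paired_sample_size(relative_difference = 0),
               class = "mirvar_validation_error")
})
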