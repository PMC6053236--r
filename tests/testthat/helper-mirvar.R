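# Shared fixtures and independent closed-form oracles.

# Lognormal CV (percent) of 2^-Z for Z ~ N(., sigma_ct^2) on the Ct scale.
lognormal_cv <- function(sigma_ct) {
  100 * sqrt(exp((log(2) * sigma_ct)^2) - 1)
}

# Closed-form large-k limits of the nested duplicate estimators when the
# normalized level factorises as (between-run lognormal) x (within-run
# lognormal): between_var and within_var are Ct-scale variances of the
# delta-Ct decomposition.
analytic_cv_intra <- function(between_var, within_var) {
  a2 <- (log(2))^2 * between_var
  s2 <- (log(2))^2 * within_var
  100 * sqrt(exp(a2) * (exp(s2) - 1))
}
analytic_cv_inter <- function(between_var, within_var) {
  a2 <- (log(2))^2 * between_var
  s2 <- (log(2))^2 * within_var
  100 * sqrt(exp(a2) * (1 + (exp(s2) - 1) / 2) - 1)
}

# All permutations of a vector (used for the exhaustive Spearman null).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  unlist(lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(p) c(v[i], p))
  }), recursive = FALSE)
}

# A small noise-free configuration.
config_zero <- function(...) {
  synthetic_config(sigma_day = 0, sigma_prep = 0, sigma_rt = 0,
                   sigma_pcr = 0, sigma_extraction = 0,
                   sigma_spike_pipette = 0, sigma_preamp = 0,
                   platelet_load = c("miR-92a" = 0, "miR-126" = 0,
                                     "miR-16" = 0, "cel-miR-39" = 0),
                   hemolysis_load = 0, biological_sd = 0, ...)
}

# Minimal normalized-level table for the duplicate-pair design: one row per
# run x RT replicate with the given levels.
levels_from_pairs <- function(pairs, assay = "miR-92a", platform = "qPCR",
                              strategy = "spike") {
  k <- nrow(pairs)
  tibble::tibble(
    sample_id = "pool", subject_id = "pool", material = "pool",
    protocol = "none", draw_order = NA_integer_,
    run_day = rep(seq_len(k), each = 2),
    rt_replicate = rep(1:2, k),
    platform = platform, assay = assay, strategy = strategy,
    delta_ct = NA_real_,
    level = as.numeric(t(as.matrix(pairs))),
    n_wells_used = 2L
  )
}

# Minimal level table for protocol / order-of-draw tests.
levels_from_tubes <- function(level, protocol = rep(c("dual", "single"),
                                                    length.out = length(level)),
                              assay = "miR-92a", strategy = "spike") {
  tibble::tibble(
    sample_id = sprintf("tube%02d", seq_along(level)),
    subject_id = "volunteer1", material = "PPP", protocol = protocol,
    draw_order = seq_along(level), run_day = 1L, rt_replicate = 1L,
    platform = "qPCR", assay = assay, strategy = strategy,
    delta_ct = NA_real_, level = level, n_wells_used = 2L
  )
}
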