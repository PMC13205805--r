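test_that("daily_reduction does the period arithmetic and guards its domain", {
  expect_equal(daily_reduction(10, 8.6, 14), 0.1)
  expect_equal(daily_reduction(5, 5, 14), 0)
  expect_equal(daily_reduction(5, 6.4, 14), -0.1)
  expect_error(daily_reduction(5, 4, 0), "period_days")
  expect_error(daily_reduction(-1, 0, 14), ">= 0")
})

test_that("Delta equals the difference of period means on any cohort", {
  for (seed in c(4, 8, 15)) {
    coh <- generate_cohort(generator_spec(seed = seed))
    eff <- estimate_effects(coh)
    reds <- daily_reductions(coh)
    expect_equal(eff$delta_mean, mean(reds$red_es) - mean(reds$red_pl),
                 tolerance = 1e-12)
    expect_equal(eff$delta_mean, eff$mean_red_es - eff$mean_red_pl,
                 tolerance = 1e-12)
    expect_lte(eff$delta_ci_low, eff$delta_mean)
    expect_gte(eff$delta_ci_high, eff$delta_mean)
    expect_equal(eff$r_mean, eff$mean_red_es / eff$mean_red_pl)
  }
})

test_that("calibrated study cohorts reproduce Delta = 0.128 cm^2/day", {
  for (seed in 1:10) {
    eff <- estimate_effects(study_cohort(seed))
    expect_equal(eff$delta_mean, 0.128, tolerance = 1e-12)
  }
})

test_that("small-cohort inference matches hand-checkable oracles", {
  # reductions ES {0.2, 0.3, 0.4}, placebo {0.1, 0.1, 0.1}
  coh <- cohort_from_reductions(c(0.2, 0.3, 0.4), c(0.1, 0.1, 0.1))
  eff <- estimate_effects(coh)
  d <- c(0.1, 0.2, 0.3)
  expect_equal(eff$delta_mean, 0.2, tolerance = 1e-12)
  tstat <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(eff$p_paired_t, 2 * pt(-abs(tstat), df = 2), tolerance = 1e-12)
  expect_equal(eff$p_wilcoxon, wilcoxon_enum_p(d))
  expect_equal(eff$p_wilcoxon, 0.25)
})

test_that("exact Wilcoxon p matches exhaustive sign enumeration on 3-5 patients", {
  cases <- list(
    list(es = c(0.2, 0.3, 0.4), pl = c(0.1, 0.1, 0.1)),
    list(es = c(0.2, 0.05, 0.4), pl = c(0.25, 0.1, 0.15)),
    list(es = c(0.11, 0.42, 0.03, 0.3), pl = c(0.12, 0.05, 0.3, 0.02)),
    list(es = c(0.5, 0.1, 0.2, 0.05, 0.4), pl = c(0.1, 0.3, 0.05, 0.2, 0.15))
  )
  for (cs in cases) {
    d <- cs$es - cs$pl
    eff <- estimate_effects(cohort_from_reductions(cs$es, cs$pl))
    expect_equal(eff$p_wilcoxon, wilcoxon_enum_p(d), tolerance = 1e-12)
    if (!any(duplicated(abs(d)))) {
      # untied cases: cross-check against the independent exact implementation
      expect_equal(eff$p_wilcoxon,
                   wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
    }
  }
})

test_that("identical periods are flagged degenerate with a null effect", {
  red <- c(0.1, 0.2, 0.3, 0.15)
  coh <- cohort_from_reductions(red, red)
  eff <- estimate_effects(coh)
  expect_equal(eff$delta_mean, 0)
  expect_equal(eff$p_paired_t, 1)
  expect_true(eff$degenerate)
  expect_error(estimate_effects(cohort_from_reductions(0.1, 0.1)), ">= 2")
})

test_that("paired-t CI width shrinks as the cohort grows at fixed dispersion", {
  widths <- sapply(c(6, 12, 24, 48), function(n) {
    mean(sapply(1:60, function(seed) {
      spec <- generator_spec(n_patients = n,
                             strata = data.frame(category = ">=19",
                                                 depth = "deep", count = n),
                             seed = seed)
      coh <- generate_cohort(spec, calibrate = FALSE)
      eff <- estimate_effects(coh)
      eff$delta_ci_high - eff$delta_ci_low
    }))
  })
  expect_true(all(diff(widths) < 0))
})

test_that("ratio summaries follow their definitions and polarity rules", {
  # zero-variance calibrated cohort: mean ratio is exactly the target ratio
  coh0 <- generate_cohort(generator_spec(sd_red_es = 0, sd_red_pl = 0, seed = 1))
  expect_equal(ratio_summary(coh0, "mean"), 0.179 / 0.051, tolerance = 1e-12)
  expect_equal(ratio_summary(coh0, "median_based"), 0.179 / 0.051,
               tolerance = 1e-12)

  red <- c(0.12, 0.2, 0.07)
  expect_equal(ratio_summary(cohort_from_reductions(red, red), "mean"), 1)

  coh <- cohort_from_reductions(c(0.2, 0.1, 0.3), c(-0.1, 0.1, 0.0))
  expect_error(ratio_summary(coh, "mean"), "undefined-ratio")

  neg <- cohort_from_reductions(c(0.2, 0.1, 0.3), c(-0.2, -0.1, -0.3))
  expect_warning(r <- ratio_summary(neg, "mean"), "polarity")
  expect_true(attr(r, "polarity_warning"))
  expect_lt(as.numeric(r), 0)

  # per-patient variant: median of elementwise ratios {2, 3, 2}
  coh2 <- cohort_from_reductions(c(0.2, 0.3, 0.4), c(0.1, 0.1, 0.2))
  expect_equal(ratio_summary(coh2, "per_patient_median"), 2)
})

test_that("crossover diagnostics recover injected period effects and stay null under the null", {
  # constructed cohort with zero period/sequence effect: treatment = Delta
  es <- c(0.25, 0.1, 0.3, 0.2); pl <- c(0.1, 0.05, 0.15, 0.1)
  coh <- cohort_from_reductions(es, pl,
                                sequence = c("ES_first", "ES_first",
                                             "placebo_first", "placebo_first"))
  dg <- crossover_diagnostics(coh)
  delta <- mean(es - pl)
  # groups differ, so the contrast is an estimate, not exactly Delta
  expect_equal(sign(dg$treatment_effect), sign(delta))

  # parameter recovery: inject +0.05 cm^2/day on period 2 across 400 seeds
  inject_period <- function(seed, shift = 0.05) {
    coh <- generate_cohort(generator_spec(seed = seed), calibrate = FALSE)
    rec <- coh$records
    es_first <- rec$sequence == "ES_first"
    L <- coh$period_length_days
    # period 2 is placebo for ES_first patients, ES otherwise
    rec$area_pl_end[es_first] <- pmax(0, rec$area_pl_end[es_first] - shift * L)
    rec$area_es_end[!es_first] <- pmax(0, rec$area_es_end[!es_first] - shift * L)
    crossover_diagnostics(pi_cohort(rec, L))
  }
  dgs <- lapply(1:400, inject_period)
  mean_period <- mean(sapply(dgs, `[[`, "period_effect"))
  mean_treat <- mean(sapply(dgs, `[[`, "treatment_effect"))
  expect_lt(abs(mean_period - 0.05), 0.01)
  expect_lt(abs(mean_treat - 0.128), 0.01)

  # type-I behaviour: no treatment effect -> mean estimate ~ 0
  null_effects <- sapply(1:400, function(seed) {
    spec <- generator_spec(target_mean_red_es = 0.1, target_mean_red_pl = 0.1,
                           seed = seed)
    crossover_diagnostics(generate_cohort(spec, calibrate = FALSE))$treatment_effect
  })
  expect_lt(abs(mean(null_effects)), 0.01)

  one_seq <- cohort_from_reductions(c(0.1, 0.2), c(0.05, 0.1),
                                    sequence = c("ES_first", "ES_first"))
  expect_error(crossover_diagnostics(one_seq), "sequence group")
})
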