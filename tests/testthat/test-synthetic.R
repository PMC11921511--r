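test_that("identical seed and config give identical cohorts", {
  a <- generate_cohort(generator_config(seed = 99))
  b <- generate_cohort(generator_config(seed = 99))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_cohort(generator_config(seed = 100))
  expect_false(identical(a$age, c$age))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_cohort(generator_config(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("zero noise collapses log10 AMH onto the trajectory", {
  cfg <- generator_config(group_log10_sd = rep(0, 5), seed = 2)
  cohort <- derive_cohort(generate_cohort(cfg))
  expect_false(any(cohort$amh_imputed))  # trajectory stays above both LoDs
  expect_equal(cohort$log10_amh, trajectory_mean(cohort$age),
               tolerance = 1e-12)
})

test_that("stratum sizes and age bins are exactly as configured", {
  cohort <- generate_cohort(generator_config(seed = 8))
  expect_equal(nrow(cohort), 670L)
  idx <- findInterval(cohort$age, c(25, 30, 35, 40, 45, 50.8),
                      rightmost.closed = TRUE)
  expect_equal(unname(table(idx)), c(148L, 111L, 117L, 135L, 159L),
               ignore_attr = TRUE)
  expect_equal(unique(cohort$amh_assay[cohort$age < 40]), "ultrasensitive")
  expect_equal(unique(cohort$amh_assay[cohort$age >= 40]), "pico")
})

test_that("marginals are recovered within 3 SEs at n = 10^4", {
  cfg <- generator_config(group_sizes = c(2209L, 1657L, 1746L, 2015L,
                                          2373L), seed = 31)
  n <- sum(cfg$group_sizes)
  cohort <- derive_cohort(generate_cohort(cfg))
  within3se <- function(phat, p) {
    abs(phat - p) < 3 * sqrt(p * (1 - p) / n)
  }
  expect_true(within3se(mean(cohort$hyperandrogenemia), 0.090))
  expect_true(within3se(mean(cohort$om_am), 0.146))
  expect_true(within3se(mean(cohort$hyperandrogenemia & cohort$om_am),
                        6 / 670))
  expect_true(within3se(mean(cohort$insulin_resistant), 0.346))
  expect_true(within3se(mean(cohort$smoker), 0.272))
  expect_true(within3se(mean(cohort$hc_assumed_no), 154 / 670))
  mu_trunc <- oracle_truncnorm_mean(34.6, 6.9, 18.0, 59.9)
  expect_true(abs(mean(cohort$bmi) - mu_trunc) < 3 * 6.9 / sqrt(n))
  expect_true(abs(median(cohort$fai) - 2.51) < 0.15)
})

test_that("the below-LoD fraction matches the integration oracle", {
  cfg <- generator_config(seed = 17)
  expected <- oracle_below_lod_fraction(cfg)
  fracs <- vapply(1:40, function(s) {
    cohort <- generate_cohort(generator_config(seed = 1000 + s))
    mean(cohort$amh_below_lod)
  }, numeric(1L))
  se <- sqrt(expected * (1 - expected) / (670 * 40))
  expect_true(abs(mean(fracs) - expected) < 3 * se)
})

test_that("stratum AMH medians decline monotonically across seeds", {
  for (s in 1:50) {
    cohort <- derive_cohort(generate_cohort(generator_config(seed = s)))
    med <- age_group_summary(cohort)$median
    expect_true(all(diff(med) < 0), info = paste("seed", s))
  }
})

test_that("the Table-1 fixture reproduces every published margin", {
  d <- derive_cohort(generate_table1_fixture())
  expect_equal(nrow(d), 670L)
  expect_equal(sum(d$hyperandrogenemia), 60L)
  expect_equal(sum(d$om_am), 98L)
  expect_equal(sum(d$hyperandrogenemia & d$om_am), 6L)
  expect_equal(nrow(reference_subpopulation(d)), 518L)
  expect_equal(sum(d$amh_imputed), 84L)
  expect_equal(unname(table(d$bmi_class)), c(64L, 190L, 416L),
               ignore_attr = TRUE)
  expect_equal(sum(d$insulin_resistant), 232L)
  expect_equal(sum(d$smoker), 182L)
  expect_equal(sum(d$hc_assumed_no), 154L)
  expect_equal(age_group_summary(d)$n, c(148L, 111L, 117L, 135L, 159L))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(p_om_am = 1.2), "probabilities")
  expect_error(generator_config(p_overlap_ha_om = 0.5), "marginal")
  expect_error(generator_config(group_log10_sd = c(0.3, 0.4)),
               "group_log10_sd")
  expect_error(generate_cohort(list(seed = 1)), "generator_config")
})
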