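test_that("AMH SI conversion follows the published factor", {
  expect_equal(convert_amh_to_si(1.0), 7.14)
  expect_equal(convert_amh_to_si(0.0), 0.0)
  expect_equal(round(convert_amh_to_si(0.005), 3), 0.036)
  expect_error(convert_amh_to_si(-0.1), "non-negative")
})

test_that("left-censored AMH is substituted per assay LoD", {
  expect_equal(impute_amh(0.004, "pico"),
               data.frame(amh_ng_ml = 0.005, amh_imputed = TRUE))
  expect_equal(impute_amh(0.10, "ultrasensitive"),
               data.frame(amh_ng_ml = 0.10, amh_imputed = FALSE))
  # the blanket rule replaces ultrasensitive values in (0.005, 0.08) too
  expect_equal(impute_amh(0.05, "ultrasensitive")$amh_ng_ml, 0.005)
  # both censoring encodings route identically
  flagged <- impute_amh(NA_real_, "pico", below_lod = TRUE)
  expect_equal(flagged$amh_ng_ml, 0.005)
  expect_true(flagged$amh_imputed)
  expect_error(impute_amh(1, "elisa_x"), "unknown AMH assay")
})

test_that("FAI applies TT substitution and strict hyperandrogenemia cutoff", {
  expect_equal(compute_fai(40, 500), 8.0)   # TT above LoD: direct formula
  expect_equal(compute_fai(10, 100), 19.0)  # TT 10 < LoD 20 -> 19
  boundary <- compute_fai(42.5, 500)
  expect_equal(boundary, 8.5)
  expect_false(boundary > amh_cutoffs()$fai_hyperandrogenemia)
  expect_true(is.na(compute_fai(30, NA)))
  expect_true(is.na(compute_fai(30, 0)))
})

test_that("FAI is invariant to joint rescaling of TT and SHBG", {
  set.seed(7)
  tt <- runif(50, 20, 100)  # above LoD so substitution is a no-op
  shbg <- runif(50, 10, 200)
  expect_equal(compute_fai(2 * tt, 2 * shbg), compute_fai(tt, shbg))
})

test_that("HOMA-IR follows the published formula with a strict cutoff", {
  expect_equal(compute_homa_ir(10, 81), 2.0)
  expect_equal(compute_homa_ir(19, 81), 3.8)
  expect_false(compute_homa_ir(19, 81) >
                 amh_cutoffs()$homa_ir_insulin_resistance)
  expect_true(compute_homa_ir(20, 81) >
                amh_cutoffs()$homa_ir_insulin_resistance)
  expect_true(is.na(compute_homa_ir(NA, 81)))
  expect_error(compute_homa_ir(-1, 81), "positive")
})

test_that("Polynesian BMI classes partition the positive reals", {
  expect_equal(as.character(classify_bmi(25.9)), "normal_or_under")
  expect_equal(as.character(classify_bmi(26.0)), "overweight")
  expect_equal(as.character(classify_bmi(32.0)), "overweight")  # inclusive
  expect_equal(as.character(classify_bmi(33.9)), "obese")
  set.seed(11)
  bmi <- runif(500, 0.1, 80)
  classes <- classify_bmi(bmi)
  expect_false(anyNA(classes))
  expect_equal(sum(table(classes)), 500L)
})

test_that("menstrual answers map to the collapsed OM/AM flag", {
  expect_false(classify_menstrual("within_1mo"))
  expect_false(classify_menstrual("1_3mo"))
  expect_true(classify_menstrual("3_6mo"))
  expect_true(classify_menstrual("6_9mo"))
  expect_true(classify_menstrual("none_12mo"))
  expect_true(is.na(classify_menstrual(NA)))
  expect_error(classify_menstrual("sometimes"), "unknown")
})

test_that("missing hormonal-contraceptive answers are assumed 'no'", {
  out <- impute_hc(c(NA, "yes", "no"))
  expect_equal(out$hc_use, c("no", "yes", "no"))
  expect_equal(out$hc_assumed_no, c(TRUE, FALSE, FALSE))
})

test_that("derivation is idempotent and never drops rows", {
  set.seed(5)
  cohort <- random_raw_cohort(40L)
  once <- derive_cohort(cohort)
  twice <- derive_cohort(once)
  expect_identical(as.data.frame(once), as.data.frame(twice))
  expect_equal(nrow(once), nrow(cohort))

  fx <- derive_cohort(generate_table1_fixture())
  expect_identical(as.data.frame(derive_cohort(fx)), as.data.frame(fx))
})

test_that("substituted AMH sits strictly below every measured pico value", {
  cohort <- derive_cohort(generate_cohort(generator_config(seed = 3)))
  measured_pico <- cohort$amh_ng_ml[!cohort$amh_imputed &
                                      cohort$amh_assay == "pico"]
  expect_true(all(measured_pico > 0.005))
  expect_true(all(cohort$amh_ng_ml[cohort$amh_imputed] == 0.005))
})
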