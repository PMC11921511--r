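test_that("a noise-free linear signal is recovered exactly", {
  age <- seq(25, 50.8, length.out = 100)
  dat <- data.frame(age = age,
                    log10_amh = 4.4356 - 0.1045 * age)
  fit <- fit_amh_trajectory(dat, degree = 1)
  expect_equal(unname(coef(fit)), c(4.4356, -0.1045), tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("coefficients match the normal-equations oracle", {
  set.seed(51)
  for (i in 1:100) {
    degree <- sample(1:3, 1L)
    n <- sample((degree + 3):30, 1L)
    age <- runif(n, 1, 10)
    y <- rnorm(n)
    fit <- fit_amh_trajectory(data.frame(age = age, log10_amh = y),
                              degree)
    expect_equal(unname(coef(fit)), oracle_polyfit(age, y, degree),
                 tolerance = 1e-8)
  }
})

test_that("adjusted R2 never exceeds R2 and residuals are orthogonal", {
  set.seed(52)
  for (i in 1:20) {
    age <- runif(40, 25, 50)
    y <- 4 - 0.1 * age + rnorm(40, 0, 0.5)
    fit <- fit_amh_trajectory(data.frame(age = age, log10_amh = y),
                              sample(1:3, 1L))
    expect_lte(fit$adj_r2, fit$r2)
    X <- stats::model.matrix(fit$lm)
    expect_equal(max(abs(crossprod(X, residuals(fit)))), 0,
                 tolerance = 1e-8)
  }
})

test_that("model selection maximizes adjusted R2 with ties to lower degree", {
  mk <- function(deg, adj) {
    structure(list(degree = as.integer(deg), adj_r2 = adj),
              class = "amh_trajfit")
  }
  expect_equal(select_best_model(list(mk(1, 0.64), mk(3, 0.69)))$degree, 3L)
  expect_equal(select_best_model(list(mk(2, 0.5)))$degree, 2L)
  expect_equal(select_best_model(list(mk(1, 0.6), mk(2, 0.6),
                                      mk(3, 0.6)))$degree, 1L)
})

test_that("degree validation and rank checks reject bad inputs", {
  dat <- data.frame(age = runif(10, 25, 50), log10_amh = rnorm(10))
  expect_error(fit_amh_trajectory(dat, degree = 4), "degree")
  expect_error(fit_amh_trajectory(dat, degree = 0), "degree")
  expect_error(fit_amh_trajectory(dat[1:2, ], degree = 2), "observations")
  const <- data.frame(age = rep(30, 10), log10_amh = rnorm(10))
  expect_error(fit_amh_trajectory(const, 1), "constant")
})

test_that("predict and fitted agree with the raw-scale coefficients", {
  cohort <- derive_cohort(generate_cohort(generator_config(seed = 6)))
  fit <- fit_amh_trajectory(cohort, 2)
  ages <- c(25, 37.5, 50)
  expect_equal(predict(fit, ages), trajectory_mean(ages, coef(fit)))
  expect_equal(unname(predict(fit)), unname(fitted(fit)),
               tolerance = 1e-10)
})

test_that("stratified fits recover distinct planted slopes", {
  age <- rep(seq(25, 50, length.out = 40), 2)
  stratum <- rep(c("a", "b"), each = 40)
  y <- ifelse(stratum == "a", 4 - 0.10 * age, 3 - 0.15 * age)
  dat <- data.frame(age = age, log10_amh = y, grp = stratum)
  fits <- stratified_fits(dat, by = "grp", degree = 1)
  expect_named(fits, c("a", "b"))
  expect_equal(unname(coef(fits$a)), c(4, -0.10), tolerance = 1e-8)
  expect_equal(unname(coef(fits$b)), c(3, -0.15), tolerance = 1e-8)
  expect_equal(fits$a$stratum, "grp=a")
})

test_that("a single-stratum table matches the unstratified fit", {
  cohort <- derive_cohort(generate_cohort(generator_config(seed = 9)))
  df <- as.data.frame(cohort)
  df$one <- "all"
  fits <- stratified_fits(df, by = "one", degree = 1)
  expect_equal(unname(coef(fits$all)),
               unname(coef(fit_amh_trajectory(cohort, 1))))
})

test_that("undersized strata are skipped with a warning", {
  df <- data.frame(age = c(25, 30, 35, 40, 26), log10_amh = rnorm(5),
                   grp = c("big", "big", "big", "big", "tiny"))
  expect_warning(fits <- stratified_fits(df, by = "grp", degree = 1),
                 "tiny")
  expect_named(fits, "big")
})

test_that("BMI strata share the decline when coupling is zero", {
  slopes <- unlist(lapply(1:5, function(s) {
    cohort <- derive_cohort(generate_cohort(generator_config(seed = s)))
    vapply(stratified_fits(cohort, "bmi_class", 1),
           function(f) coef(f)[["age"]], numeric(1L))
  }))
  expect_lt(max(slopes) - min(slopes), 0.05)
})

test_that("excluding censoring-substituted values attenuates the decline", {
  oracle_subset_slope <- function(cohort) {
    sub <- as.data.frame(cohort)[!cohort$amh_imputed, ]
    oracle_polyfit(sub$age, sub$log10_amh, 1)[2L]
  }
  for (s in 1:5) {
    cohort <- derive_cohort(generate_cohort(generator_config(seed = s)))
    full <- fit_amh_trajectory(cohort, 1)
    sens <- sensitivity_excluding_imputed(cohort, 1)
    expect_false(sens$included_imputed)
    expect_lt(abs(coef(sens)[["age"]]), abs(coef(full)[["age"]]))
    expect_equal(coef(sens)[["age"]], oracle_subset_slope(cohort),
                 tolerance = 1e-8)
  }
})

test_that("sensitivity refit is the identity when nothing was censored", {
  cfg <- generator_config(group_log10_sd = rep(0.1, 5), seed = 4)
  cohort <- derive_cohort(generate_cohort(cfg))
  expect_false(any(cohort$amh_imputed))
  full <- fit_amh_trajectory(cohort, 1)
  sens <- sensitivity_excluding_imputed(cohort, 1)
  expect_equal(coef(sens), coef(full))

  all_imp <- as.data.frame(derive_cohort(generate_table1_fixture()))
  all_imp <- all_imp[all_imp$amh_imputed, ]
  expect_error(sensitivity_excluding_imputed(
    as_amh_cohort(all_imp, validate = FALSE), 1), "nothing to refit")
})

test_that("the seed-averaged slope recovers the generating slope", {
  slopes <- vapply(1:30, function(s) {
    cohort <- derive_cohort(generate_cohort(generator_config(seed = s)))
    coef(fit_amh_trajectory(cohort, 1))[["age"]]
  }, numeric(1L))
  se <- sd(slopes) / sqrt(length(slopes))
  # censoring substitution slightly steepens the raw slope; 3-SE check on
  # the generating value uses the oracle-free parameter-recovery margin
  expect_lt(abs(mean(slopes) - (-0.1045)), max(3 * se, 0.01))
})
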