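test_that("quantile conventions agree with the sort-based oracle", {
  set.seed(41)
  for (i in 1:1000) {
    x <- runif(sample(1:40, 1L), 0, 100)
    p <- runif(2, 0.01, 0.99)
    conv <- sample(c("linear_interpolation", "inverse_ecdf",
                     "nearest_rank"), 1L)
    expect_equal(unname(percentile_thresholds(x, p, conv)),
                 oracle_quantile(x, p, conv), tolerance = 1e-12)
  }
})

test_that("quantile edge cases behave as documented", {
  expect_equal(unname(percentile_thresholds(1:10, 0.5)), 5.5)
  expect_equal(unname(percentile_thresholds(rep(3.2, 7), c(0.1, 0.9))),
               c(3.2, 3.2))
  expect_equal(unname(percentile_thresholds(4.7, c(0.25, 0.95))),
               c(4.7, 4.7))
  expect_error(percentile_thresholds(numeric(0), 0.9), "empty")
  expect_error(percentile_thresholds(1:5, 1.0), "inside")
})

test_that("thresholds are monotone in prob and order-invariant", {
  set.seed(42)
  for (i in 1:50) {
    x <- rlnorm(60)
    p <- sort(runif(3, 0.05, 0.95))
    th <- percentile_thresholds(x, p)
    expect_true(all(diff(th) >= 0))
    expect_equal(percentile_thresholds(sample(x), p), th)
  }
})

test_that("the reference subpopulation keeps normal-FAI regular-cycle women", {
  d <- derive_cohort(generate_table1_fixture())
  sub <- reference_subpopulation(d)
  expect_equal(nrow(sub), 518L)
  expect_true(all(sub$fai <= 8.5))
  expect_false(any(sub$om_am))

  all_ha <- as.data.frame(d)
  all_ha$shbg <- 10  # FAI = 300 everywhere
  expect_equal(nrow(reference_subpopulation(
    derive_cohort(as_amh_cohort(all_ha, validate = FALSE)))), 0L)

  no_om <- as.data.frame(d)[!d$om_am, ]
  sub2 <- reference_subpopulation(as_amh_cohort(no_om, validate = FALSE),
                                  fai_threshold = Inf)
  expect_equal(nrow(sub2), nrow(no_om))
})

test_that("subpopulation membership commutes with row order", {
  set.seed(43)
  d <- derive_cohort(generate_table1_fixture())
  shuffled <- as_amh_cohort(as.data.frame(d)[sample.int(nrow(d)), ],
                            validate = FALSE)
  expect_setequal(reference_subpopulation(d)$subject_id,
                  reference_subpopulation(shuffled)$subject_id)
})

test_that("high-AMH flags use a strict comparison on the whole cohort", {
  d <- derive_cohort(generate_table1_fixture())
  rng <- amh_reference_range(d)
  flags <- flag_high_amh(d, rng)
  expect_equal(sum(flags$above_p90), 83L)
  expect_equal(sum(flags$above_p95), 45L)

  at <- as.data.frame(d)[1L, ]
  at$amh_raw <- rng$thresholds[["p90"]] / 7.14  # exactly at the threshold
  one <- derive_cohort(as_amh_cohort(at, validate = FALSE))
  expect_false(flag_high_amh(one, rng)$above_p90)
})

test_that("reference range records provenance and rejects empty input", {
  d <- derive_cohort(generate_table1_fixture())
  rng <- amh_reference_range(d, convention = "nearest_rank")
  expect_s3_class(rng, "amh_refrange")
  expect_equal(rng$n_reference, 518L)
  expect_equal(rng$convention, "nearest_rank")
  expect_true(all(diff(rng$thresholds) >= 0))

  empty <- as_amh_cohort(as.data.frame(d)[0L, ], validate = FALSE)
  expect_error(amh_reference_range(empty), "empty")
})

test_that("age-group summary computes per-bin statistics", {
  d <- derive_cohort(generate_table1_fixture())
  s <- age_group_summary(d)
  expect_equal(s$n, c(148L, 111L, 117L, 135L, 159L))
  expect_true(all(s$min <= s$median & s$median <= s$max))

  sub <- as.data.frame(d)[1:3, ]
  sub$age <- c(26, 27, 28)
  sub$amh_raw <- c(1, 2, 3) / 7.14
  s1 <- age_group_summary(derive_cohort(as_amh_cohort(sub,
                                                      validate = FALSE)),
                          bins = list(c(25, 30)))
  expect_equal(s1$median, 2)
  expect_equal(s1$mean, 2)

  bad <- as.data.frame(d)[1:2, ]
  bad$age[2L] <- 60
  expect_error(age_group_summary(derive_cohort(
    as_amh_cohort(bad, validate = FALSE))), "row 2")
})
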