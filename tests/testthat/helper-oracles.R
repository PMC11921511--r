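# Independent oracles and random-cohort builders shared across tests.

# quantile by explicit sort + convention formula (independent of
# percentile_thresholds)
oracle_quantile <- function(x, p, convention) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    switch(convention,
      linear_interpolation = {
        h <- (n - 1) * pp + 1
        lo <- floor(h)
        if (lo >= n) x[n] else x[lo] + (h - lo) * (x[lo + 1L] - x[lo])
      },
      inverse_ecdf = {
        k <- n * pp
        if (abs(k - round(k)) < 1e-9) x[round(k)] else x[ceiling(k)]
      },
      nearest_rank = x[max(1L, ceiling(n * pp))])
  }, numeric(1L))
}

# OLS polynomial fit by raw normal equations
oracle_polyfit <- function(age, y, degree) {
  X <- outer(age, 0:degree, `^`)
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Pearson r straight from the definition
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# one-way ANOVA F from between/within mean squares
oracle_anova_f <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# expected fraction below the assay LoD under the generator's own model:
# Gaussian mass below log10(LoD in pmol/L) integrated over uniform ages
oracle_below_lod_fraction <- function(config) {
  total <- 0
  for (i in seq_along(config$group_bins)) {
    b <- config$group_bins[[i]]
    f <- stats::integrate(function(a) {
      lod_ng <- ifelse(a < config$assay_switch_age,
                       config$lod$assay_lod[["ultrasensitive"]],
                       config$lod$assay_lod[["pico"]])
      thr <- log10(lod_ng * config$cutoffs$amh_si_factor)
      stats::pnorm((thr - trajectory_mean(a, config$trajectory)) /
                     config$group_log10_sd[i])
    }, b[1L], b[2L])$value / (b[2L] - b[1L])
    total <- total + f * config$group_sizes[i]
  }
  total / sum(config$group_sizes)
}

# mean of a normal truncated to [lo, hi]
oracle_truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# random valid raw cohort for round-trip and derivation properties
random_raw_cohort <- function(n = 8L) {
  amh <- round(stats::runif(n, 0, 15), 4)
  amh[stats::runif(n) < 0.2] <- NA
  df <- data.frame(
    subject_id = sprintf("R%03d", sample.int(999, n)),
    age = stats::runif(n, 25, 50.8),
    amh_raw = amh,
    amh_below_lod = is.na(amh),
    amh_assay = sample(c("ultrasensitive", "pico"), n, replace = TRUE),
    tt_raw = stats::runif(n, 15, 80),
    shbg = stats::runif(n, 20, 120),
    insulin = stats::runif(n, 2, 40),
    glucose = stats::runif(n, 70, 130),
    bmi = stats::runif(n, 18, 59.9),
    menstrual_answer = sample(c("now", "within_1mo", "1_3mo", "3_6mo",
                                "6_9mo", "9_12mo", "none_12mo"), n,
                              replace = TRUE),
    hc_use = sample(c("yes", "no", NA), n, replace = TRUE),
    reproductive_surgery = stats::runif(n) < 0.1,
    smoker = stats::runif(n) < 0.3,
    stringsAsFactors = FALSE)
  as_amh_cohort(df, provenance = "test", validate = FALSE)
}

# small paper-like generator for fast stochastic tests
small_generator <- function(seed, per_bin = 12L) {
  generator_config(group_sizes = rep(per_bin, 5L), seed = seed)
}
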