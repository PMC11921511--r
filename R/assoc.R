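# Descriptive and bivariate statistics layer: Pearson correlations,
# two-group t-tests / one-way ANOVA, and report tables.

#' Pearson correlation with p-value
#'
#' Product-moment correlation with the p-value from the t transform.
#' Zero-variance input gives a missing result rather than an error.
#'
#' @param x,y numeric vectors; pairs with missing values are dropped.
#' @return list with `r`, `p` and `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Compare log10 AMH (or any response) across groups
#'
#' Two groups: two-sample t-test, equal-variance (Student) by default with
#' Welch available. More than two groups: one-way ANOVA. Reports per-group
#' mean (sd, n). A group with fewer than 2 observations makes the
#' comparison unavailable (`p = NA`, `test = "unavailable"`).
#'
#' @param values numeric response.
#' @param groups categorical grouping vector.
#' @param var_equal use the equal-variance t-test for two groups?
#' @return list with `means`, `sds`, `ns` (named per group), `statistic`,
#'   `p`, `test`.
#' @export
group_comparison <- function(values, groups, var_equal = TRUE) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  means <- tapply(values, groups, mean)
  sds <- tapply(values, groups, stats::sd)
  ns <- tapply(values, groups, length)
  if (any(ns < 2L)) {
    return(list(means = means, sds = sds, ns = ns,
                statistic = NA_real_, p = NA_real_, test = "unavailable"))
  }
  if (nlevels(groups) == 2L) {
    tt <- stats::t.test(values ~ groups, var.equal = var_equal)
    list(means = means, sds = sds, ns = ns,
         statistic = unname(tt$statistic), p = tt$p.value,
         test = if (var_equal) "t_test" else "welch_t_test")
  } else {
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1L]]
    list(means = means, sds = sds, ns = ns,
         statistic = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L],
         test = "anova")
  }
}

# significance stars per the report legend: ns p>0.05, * p<0.02, ** p<0.001
signif_star <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "**",
                       ifelse(p < 0.02, "*",
                       ifelse(p > 0.05, "ns", ""))))
}

#' Bivariate report of AMH against cohort covariates
#'
#' Pearson correlations of AMH and log10 AMH with the continuous covariates
#' (age, BMI, HOMA-IR, FAI), and group comparisons of both scales across
#' the categorical covariates (BMI class, insulin resistance, OM/AM,
#' smoking, hyperandrogenemia), with the test name and significance stars
#' (ns p > 0.05, * p < 0.02, ** p < 0.001).
#'
#' @param cohort a derived `amh_cohort`.
#' @return list with `correlations` and `comparisons` data.frames.
#' @export
bivariate_report <- function(cohort) {
  if (!is_derived(cohort)) {
    stop("bivariate_report requires a derived cohort", call. = FALSE)
  }
  cont <- c(age = "age", bmi = "bmi", homa_ir = "homa_ir", fai = "fai")
  correlations <- do.call(rbind, lapply(names(cont), function(v) {
    r1 <- pearson_r(cohort[[cont[[v]]]], cohort$amh_pmol_l)
    r2 <- pearson_r(cohort[[cont[[v]]]], cohort$log10_amh)
    data.frame(variable = v,
               r_amh = r1$r, star_amh = signif_star(r1$p),
               r_log10_amh = r2$r, star_log10_amh = signif_star(r2$p))
  }))
  cats <- c("bmi_class", "insulin_resistant", "om_am", "smoker",
            "hyperandrogenemia")
  comparisons <- do.call(rbind, lapply(cats, function(v) {
    g1 <- group_comparison(cohort$amh_pmol_l, cohort[[v]])
    g2 <- group_comparison(cohort$log10_amh, cohort[[v]])
    data.frame(variable = v, test = g2$test,
               p_amh = g1$p, star_amh = signif_star(g1$p),
               p_log10_amh = g2$p, star_log10_amh = signif_star(g2$p))
  }))
  list(correlations = correlations, comparisons = comparisons)
}

#' n-weighted pooled mean of stratum means
#'
#' The overall mean of a partitioned sample equals the n-weighted average of
#' the stratum means; used to cross-check stratum tables against printed
#' overall summaries.
#'
#' @param n stratum sizes.
#' @param means stratum means.
#' @return numeric pooled mean.
#' @export
pooled_mean <- function(n, means) {
  stopifnot(length(n) == length(means), all(n >= 0), sum(n) > 0)
  sum(n * means) / sum(n)
}

fmt_pct <- function(k, n) sprintf("%.1f (%d)", 100 * k / n, k)

#' Descriptive cohort summary table
#'
#' One row per characteristic: mean (sd) / median (IQR) / range for the
#' continuous variables; percent (n) for the categorical ones; AMH
#' reference-percentile exceedance and PCOS rows when a reference range is
#' supplied.
#'
#' @param cohort a derived `amh_cohort`.
#' @param range optional [amh_reference_range()] used to add high-AMH and
#'   PCOS rows.
#' @return data.frame with `characteristic` and `value` columns.
#' @export
descriptive_table <- function(cohort, range = NULL) {
  if (!is_derived(cohort)) {
    stop("descriptive_table requires a derived cohort", call. = FALSE)
  }
  n <- nrow(cohort)
  cont_row <- function(label, v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) {
      return(data.frame(characteristic = label,
                        value = sprintf("%.2f (NA)", mean(v))))
    }
    data.frame(characteristic = label, value = sprintf(
      "%.2f (%.2f) / %.2f (%.2f) / %.2f-%.2f",
      mean(v), stats::sd(v), stats::median(v), stats::IQR(v),
      min(v), max(v)))
  }
  cat_row <- function(label, flag) {
    data.frame(characteristic = label,
               value = fmt_pct(sum(flag, na.rm = TRUE), n))
  }
  rows <- list(
    cont_row("Age (yrs)", cohort$age),
    cont_row("AMH (pmol/L)", cohort$amh_pmol_l),
    cont_row("BMI (kg/m2)", cohort$bmi),
    cont_row("HOMA-IR", cohort$homa_ir),
    cont_row("FAI", cohort$fai),
    cat_row("BMI normal/under", cohort$bmi_class == "normal_or_under"),
    cat_row("BMI overweight", cohort$bmi_class == "overweight"),
    cat_row("BMI obese", cohort$bmi_class == "obese"),
    cat_row("Insulin resistance", cohort$insulin_resistant),
    cat_row("Current smoking", cohort$smoker),
    cat_row("OM/AM", cohort$om_am),
    cat_row("Hyperandrogenemia", cohort$hyperandrogenemia))
  if (!is.null(range)) {
    flags <- flag_high_amh(cohort, range)
    for (col in names(flags)) {
      rows[[length(rows) + 1L]] <-
        cat_row(sprintf("AMH %s", sub("above_", "> ", col)), flags[[col]])
    }
    for (prob in range$probs) {
      pc <- pcos_prevalence(cohort, range, prob = prob)
      rows[[length(rows) + 1L]] <- data.frame(
        characteristic = sprintf("PCOS (> %gth percentile AMH)", prob * 100),
        value = fmt_pct(pc$n_positive, n))
    }
  }
  do.call(rbind, rows)
}
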