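# End-to-end orchestration: configuration, staged execution, provenance.

#' Pipeline run configuration
#'
#' Exactly one input source: a cohort CSV (`input = "file"`, with `path`),
#' the seeded generator (`input = "simulate"`), or the deterministic
#' Table-1 fixture (`input = "fixture"`).
#'
#' @param input one of `"file"`, `"simulate"`, `"fixture"`.
#' @param path cohort CSV path when `input = "file"`.
#' @param generator a [generator_config()] when `input = "simulate"`.
#' @param cutoffs an [amh_cutoffs()].
#' @param lod a [lod_policy()].
#' @param fai_threshold FAI cutoff for the reference subpopulation.
#' @param probs reference percentiles.
#' @param convention quantile convention.
#' @param age_bins list of age intervals for the group summary.
#' @param age_range eligible age window (half-open).
#' @param degrees polynomial degrees to fit.
#' @param seed top-level seed; when `input = "simulate"` it overrides the
#'   generator's seed so all randomness flows from one place.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return list of class `amh_run_config`.
#' @export
run_config <- function(input = c("fixture", "simulate", "file"),
                       path = NULL, generator = generator_config(),
                       cutoffs = amh_cutoffs(), lod = lod_policy(),
                       fai_threshold = 8.5, probs = c(0.90, 0.95),
                       convention = "linear_interpolation",
                       age_bins = default_age_bins(),
                       age_range = c(25, 51), degrees = 1:3,
                       seed = 1L, out_dir = NULL) {
  input <- match.arg(input)
  if (input == "file" && (is.null(path) || !file.exists(path))) {
    stop("input = 'file' requires an existing cohort CSV path",
         call. = FALSE)
  }
  if (input == "simulate" && !is.null(seed)) generator$seed <- seed
  structure(list(input = input, path = path, generator = generator,
                 cutoffs = cutoffs, lod = lod,
                 fai_threshold = fai_threshold, probs = probs,
                 convention = convention, age_bins = age_bins,
                 age_range = age_range, degrees = degrees, seed = seed,
                 out_dir = out_dir),
            class = "amh_run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields override [run_config()] defaults; nested `cutoffs`, `lod`
#' and `generator` blocks override the corresponding constructor defaults
#' field by field.
#'
#' @param path YAML file.
#' @return An `amh_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cutoffs <- do.call(amh_cutoffs, y$cutoffs %||% list())
  lod_args <- y$lod %||% list()
  if (!is.null(lod_args$assay_lod)) {
    lod_args$assay_lod <- unlist(lod_args$assay_lod)
  }
  lod <- do.call(lod_policy, lod_args)
  gen_args <- y$generator %||% list()
  if (!is.null(gen_args$group_bins)) {
    gen_args$group_bins <- lapply(gen_args$group_bins, as.numeric)
  }
  generator <- do.call(generator_config, gen_args)
  args <- y[intersect(names(y),
                      c("input", "path", "fai_threshold", "probs",
                        "convention", "age_range", "degrees", "seed",
                        "out_dir"))]
  args$generator <- generator
  args$cutoffs <- cutoffs
  args$lod <- lod
  do.call(run_config, args)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::serializeJSON(config, digits = 15), tmp)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline halted at stage '%s': %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages: read/simulate input, derive biomarkers, apply eligibility,
#' derive the AMH reference range and age-group summary, fit the age
#' trajectory at each configured degree (with adjusted-R2 selection,
#' BMI-class and OM/AM stratified fits, and the censoring-sensitivity
#' refit), estimate PCOS prevalence at each reference percentile, and build
#' the descriptive and bivariate reports. Any stage failure halts with the
#' stage name. When `config$out_dir` is set, versioned CSV/JSON artifacts
#' and a log embedding the seed and a config hash are written there.
#'
#' @param config an [run_config()].
#' @return list of class `amh_run` with every stage's output.
#' @export
run_amh_pipeline <- function(config = run_config()) {
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  hash <- config_hash(config)
  say("run: input=%s seed=%s config_hash=%s", config$input,
      config$seed %||% "none", hash)

  cohort <- stage("input", switch(config$input,
    file = read_cohort(config$path),
    simulate = generate_cohort(config$generator),
    fixture = generate_table1_fixture()))
  say("input: %d records", nrow(cohort))

  derived <- stage("derive", derive_cohort(cohort, config$cutoffs,
                                           config$lod))
  say("derive: %d records, %d below-LoD substituted", nrow(derived),
      sum(derived$amh_imputed, na.rm = TRUE))

  elig <- stage("eligibility",
                apply_eligibility(derived, config$age_range))
  for (r in names(elig$ledger$counts)) {
    say("eligibility: excluded %s = %d", r, elig$ledger$counts[[r]])
  }
  say("eligibility: retained %d of %d", elig$ledger$n_out,
      elig$ledger$n_in)
  eligible <- elig$cohort

  range <- stage("reference_range",
                 amh_reference_range(eligible, config$probs,
                                     config$fai_threshold,
                                     config$convention))
  say("reference range: n=%d, thresholds %s pmol/L", range$n_reference,
      paste(sprintf("%.2f", range$thresholds), collapse = " / "))

  summary_tab <- stage("age_group_summary",
                       age_group_summary(eligible, config$age_bins,
                                         config$convention))

  traj <- stage("trajectory_fits", fit_trajectories(eligible,
                                                    config$degrees))
  say("trajectory: best degree %d (adjusted R2 = %.4f)",
      traj$best$degree, traj$best$adj_r2)
  strata_bmi <- stage("stratified_fits_bmi",
                      stratified_fits(eligible, "bmi_class", 1L))
  strata_om <- stage("stratified_fits_om_am",
                     stratified_fits(eligible, "om_am", 1L))
  sensitivity <- stage("sensitivity_fit",
                       sensitivity_excluding_imputed(eligible, 1L))

  pcos <- stage("pcos", lapply(config$probs, function(p) {
    pcos_prevalence(eligible, range, prob = p)
  }))
  names(pcos) <- sprintf("p%g", config$probs * 100)
  for (p in pcos) {
    say("pcos: %gth percentile threshold -> %d positive, %.1f%%",
        p$threshold_prob * 100, p$n_positive, p$prevalence)
  }

  descriptive <- stage("descriptive_table",
                       descriptive_table(eligible, range))
  bivariate <- stage("bivariate_report", bivariate_report(eligible))

  result <- structure(list(
    config = config, config_hash = hash,
    cohort = cohort, derived = derived, eligible = eligible,
    ledger = elig$ledger, reference_range = range,
    age_group_summary = summary_tab, trajectory = traj,
    stratified = list(bmi_class = strata_bmi, om_am = strata_om),
    sensitivity = sensitivity, pcos = pcos,
    descriptive = descriptive, bivariate = bivariate,
    log = log_lines), class = "amh_run")
  if (!is.null(config$out_dir)) write_run_artifacts(result)
  result
}

#' @export
print.amh_run <- function(x, ...) {
  cat("amh_run pipeline result\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

write_run_artifacts <- function(run) {
  dir.create(run$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(run$config$out_dir, f)
  provenance <- list(config_hash = run$config_hash,
                     seed = run$config$seed,
                     package_version = as.character(
                       utils::packageVersion("amhref")))
  write_cohort(run$eligible, out("eligible_cohort.csv"))
  utils::write.csv(run$age_group_summary, out("age_group_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(run$descriptive, out("descriptive_table.csv"),
                   row.names = FALSE)
  exclusions_json(run$ledger, out("exclusions.json"))
  fits_js <- lapply(run$trajectory$fits, function(f) {
    list(degree = f$degree, coefficients = as.list(f$coefficients),
         r2 = f$r2, adj_r2 = f$adj_r2, n = f$n)
  })
  report <- c(provenance, list(
    reference_range = list(
      thresholds = as.list(run$reference_range$thresholds),
      n_reference = run$reference_range$n_reference,
      convention = run$reference_range$convention,
      subpopulation = run$reference_range$subpopulation),
    trajectory_fits = fits_js,
    best_degree = run$trajectory$best$degree,
    sensitivity_excluding_imputed = list(
      coefficients = as.list(run$sensitivity$coefficients),
      r2 = run$sensitivity$r2, n = run$sensitivity$n),
    pcos = lapply(run$pcos, function(p) {
      list(threshold_prob = p$threshold_prob, threshold = p$threshold,
           n_positive = p$n_positive, prevalence = p$prevalence)
    })))
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), out("report.json"))
  writeLines(run$log, out("run.log"))
  invisible(run)
}
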